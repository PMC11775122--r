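test_that("species trees are ultrametric, deterministic, grouped by root clade", {
  expect_error(simulate_species_tree(1), "n_taxa")

  cherry <- simulate_species_tree(2, seed = 1)
  expect_equal(length(cherry$tip.label), 2)

  t1 <- simulate_species_tree(30, 1, seed = 5)
  t2 <- simulate_species_tree(30, 1, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_false(identical(write_newick(t1),
                         write_newick(simulate_species_tree(30, 1, seed = 6))))
  expect_true(ape::is.ultrametric(t1, tol = 1e-6))
  expect_setequal(names(t1$group), t1$tip.label)
  # groups are exactly the two root-adjacent clades
  root <- length(t1$tip.label) + 1
  kids <- t1$edge[t1$edge[, 1] == root, 2]
  tips_a <- t1$tip.label[phangorn::Descendants(t1, kids[1], "tips")[[1]]]
  expect_true(all(t1$group[tips_a] == t1$group[tips_a][1]))
  expect_true(all(t1$group[setdiff(t1$tip.label, tips_a)] !=
                    t1$group[tips_a][1]))

  # stem elongation keeps the tree ultrametric and deepens the root split
  ts <- simulate_species_tree(30, 1, seed = 5, stem_length = 2)
  expect_true(ape::is.ultrametric(ts, tol = 1e-6))
  expect_equal(max(ape::node.depth.edgelength(ts)),
               max(ape::node.depth.edgelength(t1)) + 2, tolerance = 1e-6)
})

test_that("tree depth matches the Yule waiting-time expectation", {
  # time to go from 2 to n lineages is a sum of Exp(k * lambda) waits plus
  # one final Exp(n * lambda) wait, so E[depth] = (sum_{k=2}^{n-1} 1/k + 1/n)
  # divided by lambda
  n <- 100; lambda <- 2
  depths <- vapply(1:200, function(r) {
    tr <- simulate_species_tree(n, lambda, seed = r)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expected <- (sum(1 / (2:(n - 1))) + 1 / n) / lambda
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 4 * se + 1e-9)
})

test_that("family evolution is indel-free, seeded, and near-identity at rate ~ 0", {
  tr <- simulate_species_tree(10, 1, seed = 3)
  root <- with_seed_local(1, random_protein(120))
  expect_error(evolve_family(root, tr, rate = 0), "rate")
  expect_error(evolve_family(strrep("M", 10), tr, 1), "50")

  h0 <- evolve_family(root, tr, rate = 1e-12, seed = 2)
  expect_true(all(h0$leaf_seqs == root))

  h1 <- evolve_family(root, tr, rate = 0.2, seed = 2)
  h2 <- evolve_family(root, tr, rate = 0.2, seed = 2)
  expect_identical(h1$leaf_seqs, h2$leaf_seqs)
  expect_false(identical(h1$leaf_seqs,
                         evolve_family(root, tr, 0.2, seed = 3)$leaf_seqs))
  expect_true(all(nchar(h1$leaf_seqs) == nchar(root)))
})

test_that("cherry divergence matches the per-site substitution kernel", {
  root <- with_seed_local(11, random_protein(500))
  cherry <- parse_newick("(A:1.2,B:0.8);")
  rate <- 0.3
  expected <- cherry_pdiff_oracle(root, 1.2, 0.8, rate)
  pdiffs <- vapply(1:20, function(s) {
    h <- evolve_family(root, cherry, rate, seed = s)
    mean(chars(h$leaf_seqs[["A"]]) != chars(h$leaf_seqs[["B"]]))
  }, numeric(1))
  se <- sqrt(expected * (1 - expected) / 500) / sqrt(20)
  expect_lt(abs(mean(pdiffs) - expected), 5 * se)
})

test_that("planted genomes follow the truth table and operon layout", {
  sp <- sim_spec(n_taxa = 8, fraction_with_pathway = 1, fraction_decoy = 0,
                 genes_per_genome = c(20, 30), n_distractor_families = 5,
                 seed = 21)
  pg <- plant_genomes(spec = sp)
  expect_true(all(pg$truth$satisfied))
  expect_true(all(pg$truth$status == "complete"))

  sp2 <- sim_spec(n_taxa = 10, fraction_with_pathway = 0.4,
                  fraction_decoy = 0.4, genes_per_genome = c(20, 30),
                  n_distractor_families = 5, seed = 22)
  pg2 <- plant_genomes(spec = sp2)
  expect_true(all(!pg2$truth$satisfied[pg2$truth$status == "decoy"]))
  expect_true(all(!pg2$truth$satisfied[pg2$truth$status == "negative"]))
  expect_true(all(pg2$truth$satisfied[pg2$truth$status == "complete"]))

  # planted clusters are co-operonic under the default gap threshold
  for (g in pg2$truth$genome_id[pg2$truth$status != "negative"]) {
    ops <- infer_operons(pg2$genomes[[g]])
    cl <- pg2$gene_truth[pg2$gene_truth$genome_id == g &
                           pg2$gene_truth$in_cluster, "locus_tag"]
    ids <- ops$operon_id[match(cl, ops$locus_tag)]
    expect_equal(length(unique(ids)), 1)
    # and nothing else joins the planted operon
    expect_equal(sum(ops$operon_id == ids[1]), length(cl))
  }

  expect_warning(
    plant_genomes(spec = sim_spec(n_taxa = 4, fraction_with_pathway = 0,
                                  genes_per_genome = c(10, 12),
                                  n_distractor_families = 2, seed = 1)),
    "no pathway"
  )
})

test_that("horizontal transfer re-draws the recipient from the donor clade", {
  tr <- simulate_species_tree(14, 1, seed = 31, stem_length = 2)
  while (min(table(tr$group)) < 4) {
    tr <- simulate_species_tree(14, 1, seed = derive_seed(31, "retry"),
                                stem_length = 2)
  }
  groups <- tr$group
  donors <- names(groups)[groups == "phylumA"]
  recipient <- sort(names(groups)[groups == "phylumB"])[1]
  root <- with_seed_local(31, random_protein(250))
  h <- list(fam = evolve_family(root, tr, 0.1, seed = 31))
  before <- h$fam$leaf_seqs[[recipient]]
  h1 <- inject_hgt(h, tr, donors, recipient, seed = 4)
  h2 <- inject_hgt(h, tr, donors, recipient, seed = 4)
  expect_identical(h1$fam$leaf_seqs, h2$fam$leaf_seqs)
  expect_false(identical(h1$fam$leaf_seqs[[recipient]], before))
  expect_length(attr(h1, "hgt_events"), 1)

  # nearest sequence neighbor of the recipient is now a donor-clade member
  D <- distance_matrix(h1$fam$leaf_seqs)
  nn <- names(which.min(D[recipient, setdiff(rownames(D), recipient)]))
  expect_true(nn %in% donors)

  expect_error(inject_hgt(h, tr, donors, "nope", seed = 1), "nope")
})

test_that("negative-binomial counts match their moments and planted effect", {
  expect_error(simulate_counts(nb_dispersion = 0), "dispersion")

  cm <- simulate_counts(c(nonIBD = 9996, UC = 2, CD = 2), families = "g1",
                        nb_mean = 100, nb_dispersion = 5, effect_log2fc = 0,
                        lib_size_range = c(1e7, 1e7), seed = 8)
  x <- cm$counts[cm$group == "nonIBD", "g1"]
  expect_lt(abs(mean(x) - 100), 4 * sd(x) / sqrt(length(x)))
  expect_lt(abs(var(x) - (100 + 100^2 / 5)) / (100 + 100^2 / 5), 0.1)

  # no planted effect: group means agree within Monte-Carlo error
  cm0 <- simulate_counts(c(nonIBD = 300, UC = 300, CD = 300), families = "g1",
                         effect_log2fc = 0, lib_size_range = c(1e7, 1e7),
                         seed = 9)
  m <- tapply(cm0$counts[, 1], cm0$group, mean)
  expect_lt(max(m) - min(m), 4 * sqrt(100 + 2000) / sqrt(300) * 2)

  expect_identical(simulate_counts(seed = 3)$counts,
                   simulate_counts(seed = 3)$counts)
})

test_that("simulated reads follow abundance x length weights and error model", {
  set.seed(12)
  prots <- vapply(c(100, 150, 200), random_protein, character(1))
  genes <- setNames(vapply(seq_along(prots),
                           function(i) back_translate(prots[i], seed = i),
                           character(1)),
                    c("gA", "gB", "gC"))
  ab <- c(gA = 3, gB = 1, gC = 0.5)

  expect_error(simulate_reads(genes, c(gA = 0, gB = 0, gC = 0)), "zero")

  rd0 <- simulate_reads(genes, ab, n_reads = 400, read_length = 80,
                        error_rate = 0, seed = 5)
  for (i in seq_len(50)) {
    src <- genes[[rd0$source_gene[i]]]
    frag <- substr(src, rd0$start[i], rd0$start[i] + 79)
    seen <- if (rd0$strand[i] == "-") revcomp(rd0$sequence[i]) else rd0$sequence[i]
    expect_identical(seen, frag)
  }

  rd <- simulate_reads(genes, ab, n_reads = 50000, read_length = 80,
                       error_rate = 0, seed = 6)
  w <- ab * nchar(genes); w <- w / sum(w)
  obs <- table(factor(rd$source_gene, names(genes))) / nrow(rd)
  for (g in names(genes)) {
    tol <- 5 * sqrt(w[[g]] * (1 - w[[g]]) / nrow(rd))
    expect_lt(abs(obs[[g]] - w[[g]]), tol)
  }

  rde <- simulate_reads(genes, ab, n_reads = 2000, read_length = 100,
                        error_rate = 0.02, seed = 7)
  mism <- vapply(seq_len(nrow(rde)), function(i) {
    src <- genes[[rde$source_gene[i]]]
    frag <- substr(src, rde$start[i], rde$start[i] + 99)
    seen <- if (rde$strand[i] == "-") revcomp(rde$sequence[i]) else rde$sequence[i]
    sum(chars(seen) != chars(frag))
  }, numeric(1))
  expected <- 100 * 0.02 # a drawn substitution always changes the base
  se <- sd(mism) / sqrt(length(mism))
  expect_lt(abs(mean(mism) - expected), 4 * se)
})
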