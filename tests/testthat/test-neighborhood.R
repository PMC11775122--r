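test_that("operon inference applies the gap rule and strand splits", {
  # gaps of 50 and 800 bp at the default 500 bp threshold -> sizes 2 and 1
  g <- mk_genes("G", starts = c(1, 351, 1452), ends = c(300, 650, 1800),
                strands = c("+", "+", "+"))
  ops <- infer_operons(g)
  tab <- table(ops$operon_id)
  expect_equal(sort(as.integer(tab)), c(1, 2))
  expect_equal(ops$operon_id[1], ops$operon_id[2])

  # a strand change always splits, regardless of gap
  g2 <- mk_genes("G", starts = c(1, 310), ends = c(300, 600),
                 strands = c("+", "-"))
  ops2 <- infer_operons(g2)
  expect_equal(length(unique(ops2$operon_id)), 2)

  # same-strand overlap counts as gap 0
  g3 <- mk_genes("G", starts = c(1, 250), ends = c(300, 500),
                 strands = c("+", "+"))
  expect_equal(length(unique(infer_operons(g3)$operon_id)), 1)

  expect_error(infer_operons(g, max_gap_bp = -1))
})

test_that("operon partition equals the transitive-closure oracle", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    starts <- sort(sample(1:8000, n))
    lens <- sample(100:900, n, replace = TRUE)
    g <- mk_genes("G", starts = starts, ends = starts + lens,
                  strands = sample(c("+", "-"), n, TRUE),
                  contig = sample(c("c1", "c2"), n, TRUE))
    gap <- sample(c(100, 500, 1200), 1)
    ops <- infer_operons(g, max_gap_bp = gap)
    # partition: every gene in exactly one operon
    expect_setequal(ops$locus_tag, g$locus_tag)
    expect_equal(anyDuplicated(ops$locus_tag), 0)
    got <- unname(lapply(split(ops$locus_tag, ops$operon_id), sort))
    want <- unname(lapply(operon_oracle_partition(g, gap), sort))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("co-operonic genes without hits become ranked candidates", {
  g <- mk_genes("G", starts = c(1, 320, 640), ends = c(300, 620, 940),
                strands = "+", tags = c("gudD_t", "trnsptX", "garR_t"))
  ops <- infer_operons(g)
  hits <- data.frame(genome_id = "G", locus_tag = c("gudD_t", "garR_t"),
                     family_id = c("gudD", "garR"), stringsAsFactors = FALSE)
  cand <- candidate_members(ops, hits)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$locus_tag, "trnsptX")
  expect_equal(cand$n_pathway_comembers, 2)
  expect_equal(cand$comember_families, "garR,gudD")
  expect_equal(cand$rank, 1)

  # an operon of only hits yields no candidates
  hits_all <- rbind(hits, data.frame(genome_id = "G", locus_tag = "trnsptX",
                                     family_id = "gudP"))
  expect_equal(nrow(candidate_members(ops, hits_all)), 0)

  # an operon with no hits yields no candidates
  expect_equal(nrow(candidate_members(ops, hits[0, ])), 0)

  # ranking: more hit co-members first, then smaller operon, then locus
  g4 <- mk_genes("G", tags = c("a1", "a2", "a3", "b1", "b2"),
                 starts = c(1, 320, 640, 5000, 5320),
                 ends = c(300, 620, 940, 5300, 5620), strands = "+")
  ops4 <- infer_operons(g4)
  hits4 <- data.frame(genome_id = "G", locus_tag = c("a1", "a2", "b1"),
                      family_id = c("gudD", "garR", "garL"),
                      stringsAsFactors = FALSE)
  cand4 <- candidate_members(ops4, hits4)
  expect_equal(cand4$locus_tag, c("a3", "b2"))
})

test_that("cluster similarity links homologous genes greedily", {
  # identical clusters: all pairs at 100, n_shared = size
  set.seed(31)
  prots <- vapply(c(120, 150, 180), random_protein, character(1))
  cl <- mk_genes("A", starts = c(1, 400, 900), ends = c(360, 850, 1440),
                 strands = "+", proteins = prots)
  sim <- cluster_similarity(cl, cl)
  expect_equal(sim$n_shared, 3)
  expect_true(all(sim$links$identity == 100))
  expect_identical(sim$links$locus_a, sim$links$locus_b)

  # two clusters sharing five diverged families link 5 family pairs
  fams <- c("gudD", "gudL", "garK", "garR", "cDaR")
  tr <- parse_newick("(cluA:0.15,cluB:0.15);")
  histories <- lapply(setNames(fams, fams), function(f) {
    evolve_family(with_seed_local(derive_seed(7, f), random_protein(150)),
                  tr, rate = 1, seed = derive_seed(7, paste0("e", f)))
  })
  cluA <- mk_genes("A", starts = (0:4) * 500 + 1, ends = (0:4) * 500 + 453,
                   strands = "+", tags = paste0("A_", fams),
                   proteins = vapply(fams, function(f)
                     histories[[f]]$leaf_seqs[["cluA"]], character(1)))
  cluB <- mk_genes("B", starts = (0:4) * 500 + 1, ends = (0:4) * 500 + 453,
                   strands = "+", tags = paste0("B_", rev(fams)),
                   proteins = vapply(rev(fams), function(f)
                     histories[[f]]$leaf_seqs[["cluB"]], character(1)))
  sim5 <- cluster_similarity(cluA, cluB)
  expect_equal(sim5$n_shared, 5)
  # greedy matching pairs each family with its own homolog
  pair_fams <- data.frame(a = sub("A_", "", sim5$links$locus_a),
                          b = sub("B_", "", sim5$links$locus_b))
  expect_true(all(pair_fams$a == pair_fams$b))

  expect_equal(cluster_similarity(cl[0, ], cl)$n_shared, 0)
})

test_that("greedy matching achieves at least half the optimal weight", {
  set.seed(41)
  for (i in 1:10) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    protsA <- vapply(rep(100, na), random_protein, character(1))
    # cluster B: mutated copies plus unrelated genes -> mixed identity matrix
    protsB <- vapply(seq_len(nb), function(j) {
      if (j <= na && runif(1) < 0.7) {
        h <- evolve_family(protsA[j], parse_newick("(x:0.3,y:0.3);"),
                           rate = 1, seed = i * 10 + j)
        h$leaf_seqs[["x"]]
      } else random_protein(100)
    }, character(1))
    ca <- mk_genes("A", starts = (seq_len(na) - 1) * 400 + 1,
                   ends = (seq_len(na) - 1) * 400 + 303, strands = "+",
                   proteins = protsA)
    cb <- mk_genes("B", starts = (seq_len(nb) - 1) * 400 + 1,
                   ends = (seq_len(nb) - 1) * 400 + 303, strands = "+",
                   proteins = protsB)
    sim <- cluster_similarity(ca, cb, min_identity = 30)
    W <- outer(seq_len(na), seq_len(nb), Vectorize(function(x, y) {
      pairwise_identity(protsA[x], protsB[y])
    }))
    opt <- matching_oracle(W, 30)
    expect_gte(sum(sim$links$identity) + 1e-9, 0.5 * opt)
  }
})

test_that("unequal-length pairs go through the global aligner", {
  a <- "MKVAW"
  b <- "MKAW" # one deletion
  cl_a <- mk_genes("A", 1, 18, "+", proteins = a)
  cl_b <- mk_genes("B", 1, 15, "+", proteins = b)
  sim <- cluster_similarity(cl_a, cl_b, min_identity = 10)
  expect_equal(sim$n_shared, 1)
  expect_equal(sim$links$identity, 80) # 4 matches over 5 aligned columns
})
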