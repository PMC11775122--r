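test_that("pairwise identity counts columns the documented way", {
  expect_equal(pairwise_identity("MKV", "MKV"), 100)
  expect_equal(pairwise_identity("MKV", "MAV"), 66.67, tolerance = 1e-3)
  # a one-sided gap column stays in the denominator, a double gap does not
  expect_equal(pairwise_identity("M-V-", "MKV-"), 100 * 2 / 3)
  expect_error(pairwise_identity("---", "---"), "all-gap")
  expect_error(pairwise_identity("MK", "MKV"), "unequal")

  set.seed(13)
  for (i in 1:50) {
    L <- sample(10:60, 1)
    a <- chars(random_protein(L)); b <- chars(random_protein(L))
    gap <- runif(L) < 0.15; a[gap] <- "-"
    gap2 <- runif(L) < 0.15; b[gap2] <- "-"
    some <- !(a == "-" & b == "-")
    if (!any(some)) next
    hand <- 100 * sum(a == b & a != "-") / sum(some)
    expect_equal(pairwise_identity(paste(a, collapse = ""),
                                   paste(b, collapse = "")), hand)
  }
})

test_that("alignment trimming removes strictly-over-threshold gap columns", {
  rows <- 100
  M <- matrix("A", rows, 3)
  M[1:98, 2] <- "-" # 98% gaps: removed at 0.97
  M[1:97, 3] <- "-" # 97% exactly: kept
  msa <- setNames(apply(M, 1, paste, collapse = ""), paste0("r", 1:rows))
  tr <- trim_msa(msa, 0.97)
  expect_equal(tr$columns, c(1, 3))
  expect_equal(unique(nchar(tr$msa)), 2)

  # idempotence
  tr2 <- trim_msa(tr$msa, 0.97)
  expect_identical(tr2$msa, tr$msa)
  expect_equal(tr2$columns, c(1, 2))

  all_gap <- c(a = "--", b = "--", c = "A-")
  expect_error(trim_msa(all_gap, 0.2), "every column")
})

test_that("Poisson-corrected distances follow the closed form", {
  msa <- c(a = strrep("A", 40), b = strrep("A", 40))
  expect_equal(distance_matrix(msa)["a", "b"], 0)

  # p = 0.5 -> d = ln 2
  msa2 <- c(a = paste0(strrep("A", 20), strrep("C", 20)),
            b = paste0(strrep("A", 20), strrep("D", 20)))
  expect_equal(distance_matrix(msa2)["a", "b"], log(2), tolerance = 1e-12)

  # saturation capped at d_max
  msa3 <- c(a = strrep("A", 30), b = strrep("C", 30))
  expect_equal(distance_matrix(msa3, d_max = 7)["a", "b"], 7)

  # disjoint gap structure errors naming the pair
  msa4 <- c(a = "AA--", b = "--CC", c = "AACC")
  err <- expect_error(distance_matrix(msa4))
  expect_match(conditionMessage(err), "'a'.*'b'")

  set.seed(3)
  M <- vapply(1:6, function(i) random_protein(50), character(1))
  D <- distance_matrix(setNames(M, paste0("t", 1:6)))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("neighbor joining solves the four-taxon worked example exactly", {
  lab <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(lab, lab))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- nj_tree(D)
  # topology AB|CD with exact branch lengths: path lengths reproduce D
  expect_equal(ape::cophenetic.phylo(tr)[lab, lab], D, tolerance = 1e-9)
  split_ab <- ape::prop.part(ape::unroot(tr))
  expect_equal(ape::dist.topo(ape::unroot(tr),
                              ape::unroot(parse_newick("((A:1,B:2):1,(C:3,D:4):0);"))), 0,
               ignore_attr = TRUE)

  # three taxa: closed-form star lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  expect_equal(ape::cophenetic.phylo(t3)[c("x", "y", "z"), c("x", "y", "z")],
               D3, tolerance = 1e-9)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), ".")
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("neighbor joining recovers random additive trees exactly", {
  set.seed(19)
  for (i in 1:30) {
    tr <- ape::rtree(10, br = function(n) runif(n, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    labs <- rownames(D)
    rec <- nj_tree(D)
    expect_equal(ape::cophenetic.phylo(rec)[labs, labs], D, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
  }
  # independent cross-check against ape's NJ on one instance
  tr <- ape::rtree(12, br = function(n) runif(n, 0.2, 1))
  D <- ape::cophenetic.phylo(tr)
  expect_equal(ape::dist.topo(ape::unroot(nj_tree(D)),
                              ape::unroot(ape::nj(D))), 0, ignore_attr = TRUE)
})

test_that("Fitch parsimony matches forced examples and the enumeration oracle", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  fs <- fitch_states(tr, c(A = "M", B = "M", C = "Y", D = "Y"))
  expect_equal(fs$score, 1)
  expect_setequal(fs$sets[[5]], c("M", "Y"))

  expect_equal(fitch_states(tr, c(A = "M", B = "M", C = "M", D = "M"))$score, 0)

  # missing leaf states are uninformative
  fs_na <- fitch_states(tr, c(A = "M", B = "M", C = "Y", D = NA),
                        alphabet = c("M", "Y"))
  expect_equal(fs_na$score, 1)

  set.seed(29)
  for (i in 1:120) {
    n <- sample(4:7, 1)
    k <- sample(2:4, 1)
    alpha <- LETTERS[seq_len(k)]
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    states <- setNames(sample(alpha, n, replace = TRUE), tr$tip.label)
    if (runif(1) < 0.2) states[sample(n, 1)] <- NA
    fs <- fitch_states(tr, states, alphabet = alpha)
    expect_equal(fs$score, fitch_enum_score(fs$tree, states, alpha))
    # the assigned labeling attains the reported score
    cost <- sum(fs$states[fs$tree$edge[, 1]] != fs$states[fs$tree$edge[, 2]])
    expect_equal(cost, fs$score)
  }
})

test_that("planted clade-diagnostic residues are recovered exactly", {
  fx <- diagnostic_fixture()
  res <- diagnostic_residues(fx$msa, fx$tree, fx$focal)
  expect_equal(res$changes$column, c(110, 194))
  expect_equal(res$changes$ancestral_state, c("Y", "N"))
  expect_equal(res$changes$derived_state, c("M", "K"))
  expect_true(all(res$changes$conservation == 1))

  # per-column entropies: uniform column 0, half/half column ln 2
  expect_equal(res$entropy[1], 0)
  expect_equal(res$entropy[130], log(2), tolerance = 1e-12)
  expect_equal(res$entropy[110], -(0.4 * log(0.4) + 0.6 * log(0.6)),
               tolerance = 1e-12)

  # non-monophyletic focal set errors
  expect_error(diagnostic_residues(fx$msa, fx$tree, c("f1", "s1")),
               "monophyletic")
  expect_error(diagnostic_residues(fx$msa, fx$tree, names(fx$msa)), "proper")
})

test_that("nested-clade detection flags the spec toy and skips concordance", {
  groups <- c(B1 = "Bacillota", B2 = "Bacillota", B3 = "Bacillota",
              B4 = "Bacillota", F1 = "Fusobacteriota", F2 = "Fusobacteriota")
  tr <- parse_newick("((B1:1,B2:1):1,((F1:1,F2:1):1,(B3:1,B4:1):1):1);")
  ev <- detect_nested_clades(tr, groups)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$foreign_group, "Fusobacteriota")
  expect_equal(ev$host_group, "Bacillota")
  expect_equal(ev$foreign_leaves, "F1,F2")

  conc <- parse_newick("((B1:1,B2:1):1,(F1:1,F2:1):1);")
  expect_equal(nrow(detect_nested_clades(conc, groups[c("B1", "B2", "F1", "F2")])), 0)

  expect_error(detect_nested_clades(tr, groups[-1]), "B1")

  # support filter suppresses weakly supported foreign clades
  trs <- parse_newick("((B1:1,B2:1):1,((F1:1,F2:1)40:1,(B3:1,B4:1)90:1)95:1);")
  expect_equal(nrow(detect_nested_clades(trs, groups, support_min = 75)), 0)
  expect_equal(nrow(detect_nested_clades(trs, groups, support_min = 30)), 1)
})

test_that("gene-tree incongruence pipeline flags one injected transfer", {
  hit <- 0; clean <- 0; n <- 12
  for (r in 1:n) {
    a <- hgt_replicate(5000 + r, with_transfer = TRUE)
    hit <- hit + (nrow(a$events) == 1 &&
                    a$events$foreign_leaves == a$recipient)
    b <- hgt_replicate(5000 + r, with_transfer = FALSE)
    clean <- clean + (nrow(b$events) == 0)
  }
  expect_gte(hit, n - 1)
  expect_gte(clean, n - 1)
})
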