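# Independent oracles used across the suite. Each re-derives a quantity by
# brute force (enumeration, transitive closure, closed form) without sharing
# code paths with the implementation it checks.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# local copies of small string utilities so tests do not reach into the
# package's internals
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# ---- Fitch parsimony: exhaustive minimization over internal labelings ----
# Leaves with NA states are free variables (uninformative) and enumerated
# alongside the internal nodes.
fitch_enum_score <- function(tree, leaf_states, alphabet) {
  ntip <- length(tree$tip.label)
  states <- leaf_states[tree$tip.label]
  free_leaves <- which(is.na(states))
  nfree <- tree$Nnode + length(free_leaves)
  grid <- expand.grid(rep(list(alphabet), nfree), stringsAsFactors = FALSE)
  val <- function(node) {
    if (node > ntip) return(grid[[node - ntip]])
    if (node %in% free_leaves) {
      return(grid[[tree$Nnode + match(node, free_leaves)]])
    }
    rep(states[[node]], nrow(grid))
  }
  cost <- numeric(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    cost <- cost + (val(tree$edge[e, 1]) != val(tree$edge[e, 2]))
  }
  min(cost)
}

# ---- Mann-Whitney: exact two-sided p by full enumeration ----
mw_enum <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  Us <- apply(idx, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))
  list(U = U_obs, p = min(1, p))
}

# ---- Operon partition: transitive closure of the adjacency-gap relation ----
operon_oracle_partition <- function(genes, max_gap) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (ct in unique(genes$contig_id)) {
    for (st in c("+", "-")) {
      ix <- which(genes$contig_id == ct & genes$strand == st)
      ix <- ix[order(genes$start[ix])]
      if (length(ix) < 2) next
      for (k in seq_len(length(ix) - 1)) {
        gap <- max(genes$start[ix[k + 1]] - genes$end[ix[k]] - 1, 0)
        if (gap <= max_gap) union2(ix[k], ix[k + 1])
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(genes$locus_tag, comp)
}

# ---- Maximum-weight bipartite matching by exhaustive recursion ----
matching_oracle <- function(W, min_w) {
  na <- nrow(W); nb <- ncol(W)
  best <- 0
  rec <- function(i, used_b, acc) {
    if (i > na) { best <<- max(best, acc); return(invisible()) }
    rec(i + 1, used_b, acc)
    for (j in seq_len(nb)) {
      if (!used_b[j] && W[i, j] >= min_w) {
        used_b[j] <- TRUE
        rec(i + 1, used_b, acc + W[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), 0)
  best
}

# ---- Per-site substitution kernel of the protein evolver (closed form) ----
# One application per branch: substitute with probability 1 - exp(-rate*b),
# replacement from the background excluding the current residue.
evolve_branch_kernel <- function(b, rate) {
  bg <- gudgar::aa_background()
  q <- 1 - exp(-rate * b)
  S <- matrix(0, 20, 20, dimnames = list(AA20_T, AA20_T))
  for (i in seq_len(20)) {
    S[i, -i] <- bg[-i] / sum(bg[-i])
  }
  (1 - q) * diag(20) + q * S
}

# expected per-site disagreement between two leaves of a cherry (root fixed)
cherry_pdiff_oracle <- function(root_seq, b1, b2, rate) {
  M1 <- evolve_branch_kernel(b1, rate)
  M2 <- evolve_branch_kernel(b2, rate)
  cs <- strsplit(root_seq, "")[[1]]
  p_same <- vapply(cs, function(a) {
    i <- match(a, AA20_T)
    sum(M1[i, ] * M2[i, ])
  }, numeric(1))
  mean(1 - p_same)
}

# ---- misc fixture builders ----
mk_genes <- function(genome, starts, ends, strands,
                     tags = sprintf("%s_g%02d", genome, seq_along(starts)),
                     contig = paste0(genome, "_c1"),
                     products = rep("hypothetical protein", length(starts)),
                     proteins = rep(strrep("M", 60), length(starts))) {
  data.frame(genome_id = genome, contig_id = contig, start = starts,
             end = ends, strand = strands, locus_tag = tags,
             product = products, protein_seq = proteins,
             stringsAsFactors = FALSE)
}

random_logodds <- function(L, sd = 2) {
  m <- matrix(rnorm(L * 21, sd = sd), L, 21)
  m[, 21] <- 0
  colnames(m) <- c(AA20_T, "X")
  m
}

# build a calibrated profile for a family root
mk_profile <- function(root, family, n_seeds = 6, divergence = 0.3, seed = 1,
                       n_shuffles = 100) {
  sa <- simulate_seed_alignment(root, n_seeds = n_seeds,
                                divergence = divergence,
                                seed = derive_seed(seed, paste0("seed:", family)))
  calibrate_null(build_pssm(sa, family_id = family), n_shuffles = n_shuffles,
                 seed = seed)
}

# one HGT-study replicate: returns the event table and the true recipient
hgt_replicate <- function(rep_seed, with_transfer, n_taxa = 20,
                          protein_length = 300, rate = 0.1, stem = 2) {
  att <- 0
  repeat {
    tr <- simulate_species_tree(n_taxa, 1, seed = rep_seed + 100000 * att,
                                stem_length = stem)
    if (min(table(tr$group)) >= 5 || att >= 60) break
    att <- att + 1
  }
  groups <- tr$group
  root <- with_seed_local(rep_seed, random_protein(protein_length))
  h <- list(fam = evolve_family(root, tr, rate, seed = rep_seed))
  recipient <- NA_character_
  if (with_transfer) {
    donors <- names(groups)[groups == "phylumA"]
    recipient <- sort(names(groups)[groups == "phylumB"])[1]
    h <- inject_hgt(h, tr, donors, recipient, seed = rep_seed)
  }
  gt <- nj_tree(distance_matrix(h$fam$leaf_seqs))
  ev <- detect_nested_clades(gt, groups, min_foreign = 1)
  list(events = ev, recipient = recipient, groups = groups)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# clade-diagnostic-residue fixture: a focal clade nested with outgroup
# context, two planted diagnostic columns and assorted non-diagnostic ones
diagnostic_fixture <- function() {
  nwk <- paste0("((((f1:0.1,f2:0.1):0.1,(f3:0.1,f4:0.1):0.1):0.3,",
                "((s1:0.1,s2:0.1):0.1,(s3:0.1,s4:0.1):0.1):0.2):0.1,",
                "(o1:0.1,o2:0.1):0.4);")
  tree <- parse_newick(nwk)
  labs <- c("f1", "f2", "f3", "f4", "s1", "s2", "s3", "s4", "o1", "o2")
  L <- 220
  base <- with_seed_local(42, sample(AA20_T, L, replace = TRUE))
  M <- matrix(rep(base, each = 10), nrow = 10,
              dimnames = list(labs, NULL))
  focal <- c("f1", "f2", "f3", "f4")
  # planted diagnostic columns: ancestral Y -> derived M, ancestral N -> K
  M[, 110] <- "Y"; M[focal, 110] <- "M"
  M[, 194] <- "N"; M[focal, 194] <- "K"
  # focal-conserved but shared with the ancestor: must not be reported
  M[, 50] <- "A"; M[c("s3", "s4"), 50] <- "G"
  # low focal conservation: must not be reported
  M[, 70] <- "L"; M["f1", 70] <- "I"; M["f2", 70] <- "V"
  # half/half column (entropy ln 2), unconserved in the focal clade
  M[, 130] <- c("A", "A", "C", "C", "A", "A", "C", "C", "A", "C")
  msa <- setNames(apply(M, 1, paste, collapse = ""), labs)
  list(msa = msa, tree = tree, focal = focal)
}
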