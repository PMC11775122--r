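## Alignment utilities, distance-based gene trees, Fitch ancestral states,
## clade-diagnostic residues and gene-tree/species-tree incongruence
## detection. Distance/neighbor-joining trees and Fitch parsimony stand in
## for likelihood tree inference and ML ancestral reconstruction: the
## signals consumed downstream (clade nesting, clade-diagnostic residues)
## are topology-level and well expressed by parsimony/distance methods.

#' Percent identity of two aligned sequences
#'
#' Identity is the number of columns where both rows carry the same residue
#' divided by the number of columns where at least one row carries a
#' residue (columns that are gap in both rows are ignored), times 100. A
#' column with a residue in one row and a gap in the other counts as a
#' mismatch.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (gaps as `-`).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- chars(toupper(seq_a)); b <- chars(toupper(seq_b))
  if (length(a) != length(b)) {
    stop("sequences have unequal lengths; align them first")
  }
  some <- a != "-" | b != "-"
  if (!any(some)) stop("both sequences are all-gap")
  match <- a == b & a != "-"
  100 * sum(match) / sum(some)
}

#' Trim high-gap columns from an alignment
#'
#' Columns whose gap fraction is strictly greater than `max_gap_fraction`
#' are removed (a column at exactly the threshold is kept). Row order is
#' preserved and the provenance of the kept columns is returned.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param max_gap_fraction Threshold in `(0, 1]` (default 0.97).
#' @return List with `msa` (trimmed alignment) and `columns` (original
#'   1-based indices of the kept columns).
#' @export
trim_msa <- function(msa, max_gap_fraction = 0.97) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction <= 1, length(msa) > 0)
  if (length(unique(nchar(msa))) != 1) stop("rows have unequal lengths")
  M <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  gap_frac <- colMeans(M == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  if (length(keep) == 0) stop("trimming removed every column")
  out <- apply(M[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(msa)
  list(msa = out, columns = keep)
}

#' Poisson-corrected pairwise distance matrix
#'
#' For each pair, the p-distance over mutually non-gap columns is corrected
#' as `d = -ln(1 - p)`; saturated pairs (`p = 1`, infinite correction) and
#' any distance above `d_max` are capped at `d_max`.
#'
#' @param msa Named character vector of equal-length aligned sequences
#'   (>= 2 rows).
#' @param d_max Distance cap (default 10).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, d_max = 10) {
  stopifnot(length(msa) >= 2)
  if (length(unique(nchar(msa))) != 1) stop("rows have unequal lengths")
  if (is.null(names(msa)) || anyDuplicated(names(msa))) {
    stop("rows must carry unique names")
  }
  M <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- M[i, ] != "-" & M[j, ] != "-"
      if (!any(shared)) {
        stop("no mutually non-gap columns between '", names(msa)[i],
             "' and '", names(msa)[j], "'")
      }
      p <- mean(M[i, shared] != M[j, shared])
      d <- if (p >= 1) d_max else min(-log(1 - p), d_max)
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (Saitou-Nei Q criterion with Studier-Keppler
#' distance updates). Negative branch lengths are clamped to 0 with the
#' deficit moved to the sibling branch. Ties in the Q matrix are broken by
#' the lexicographically smallest pair of cluster labels (a cluster is
#' labeled by its smallest member leaf). The result is unrooted (basal
#' trifurcation).
#'
#' @param D Symmetric distance matrix with zero diagonal and unique
#'   dimnames (>= 3 taxa).
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 3, nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  labels <- rownames(D)
  stopifnot(!is.null(labels), !anyDuplicated(labels))
  frag <- setNames(labels, labels) # newick fragment per active cluster
  rep_lab <- setNames(labels, labels) # smallest member leaf, for tie-breaks
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3) {
    n <- nrow(D)
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- order(rep_lab[rownames(D)[cand[, 1]]], rep_lab[rownames(D)[cand[, 2]]])
    i <- cand[key[1], 1]; j <- cand[key[1], 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    a <- rownames(D)[i]; b <- rownames(D)[j]
    newlab <- paste0("(", a, ",", b, ")")
    newfrag <- paste0("(", frag[a], ":", fmt(li), ",", frag[b], ":", fmt(lj), ")")
    newrep <- min(rep_lab[a], rep_lab[b])
    dnew <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    rownames(D2)[n - 1] <- colnames(D2)[n - 1] <- newlab
    D <- D2
    frag <- c(frag[rownames(D)[seq_len(n - 2)]], setNames(newfrag, newlab))
    rep_lab <- c(rep_lab[rownames(D)[seq_len(n - 2)]], setNames(newrep, newlab))
  }
  l <- rownames(D)
  # three-point formulas for the final star
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b1 <- max(0, b1); b2 <- max(0, b2); b3 <- max(0, b3)
  nwk <- paste0("(", frag[l[1]], ":", fmt(b1), ",", frag[l[2]], ":", fmt(b2),
                ",", frag[l[3]], ":", fmt(b3), ");")
  ape::read.tree(text = nwk)
}

## deterministic rooted-binary version of a tree (for Fitch traversals)
.as_rooted_binary <- function(tree) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
  }
  tree
}

#' Fitch parsimony ancestral states
#'
#' Bottom-up pass: a node's state set is the intersection of its children's
#' sets when non-empty, else their union with a parsimony-score increment.
#' Top-down pass: the root takes the lexicographically smallest member of
#' its set; every other node takes its parent's state when that state is in
#' the node's set, else the lexicographically smallest member. Leaves with
#' a missing state are treated as carrying the full alphabet
#' (uninformative). Unrooted or multifurcating trees are first resolved
#' into a rooted binary tree deterministically.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaf_states Named character vector (leaf label -> state); `NA` or
#'   absent leaves are uninformative.
#' @param alphabet State alphabet (default: states observed at the
#'   leaves).
#' @return List with `tree` (the resolved tree used), `sets` (bottom-up
#'   state set per node, indexed by ape node number), `states` (assigned
#'   state per node), `score` (parsimony score).
#' @export
fitch_states <- function(tree, leaf_states, alphabet = NULL) {
  tree <- .as_rooted_binary(tree)
  ntip <- length(tree$tip.label)
  obs <- leaf_states[!is.na(leaf_states)]
  if (is.null(alphabet)) alphabet <- sort(unique(as.character(obs)))
  if (length(alphabet) == 0) stop("no observed leaf states")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    s <- leaf_states[tree$tip.label[i]]
    sets[[i]] <- if (is.na(s) || is.null(s) || length(s) == 0) alphabet else as.character(s)
  }
  post <- ape::reorder.phylo(tree, "postorder")
  score <- 0L
  # fold each child set into its parent; postorder guarantees a child's
  # set is complete before its parent edge is visited
  for (k in seq_len(nrow(post$edge))) {
    parent <- post$edge[k, 1]; child <- post$edge[k, 2]
    if (is.null(sets[[parent]])) {
      sets[[parent]] <- sets[[child]]
    } else {
      inter <- intersect(sets[[parent]], sets[[child]])
      if (length(inter) > 0) {
        sets[[parent]] <- inter
      } else {
        sets[[parent]] <- sort(union(sets[[parent]], sets[[child]]))
        score <- score + 1L
      }
    }
  }
  states <- character(ntip + tree$Nnode)
  root <- ntip + 1L
  states[root] <- sort(sets[[root]])[1]
  cw <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(cw$edge))) {
    p <- cw$edge[k, 1]; ch <- cw$edge[k, 2]
    states[ch] <- if (states[p] %in% sets[[ch]]) states[p] else sort(sets[[ch]])[1]
  }
  list(tree = tree, sets = sets, states = states, score = score)
}

#' Clade-diagnostic residues
#'
#' For each alignment column, the focal clade's modal residue and its
#' conservation (modal fraction among non-gap focal residues) are compared
#' with the Fitch-assigned ancestral state at the parent of the focal
#' clade's root. A column is reported when conservation reaches
#' `conservation_min` and the modal residue differs from the ancestral
#' state -- the pattern by which a derived clade's active-site residues
#' (e.g. an ancestral tyrosine replaced by a universally conserved
#' methionine) delineate it from its relatives. Per-column Shannon
#' entropies over all rows are returned alongside.
#'
#' @param msa Named character vector of equal-length aligned sequences;
#'   names must match the tree's leaf labels.
#' @param tree An [ape::phylo] tree containing all alignment rows as
#'   leaves.
#' @param focal_clade_leaves Leaf labels of the focal clade (must be
#'   monophyletic in the tree and a proper subclade).
#' @param conservation_min Minimum focal conservation (default 0.9).
#' @return List with `changes` (data frame `column`, `ancestral_state`,
#'   `derived_state`, `conservation`) and `entropy` (numeric vector, one
#'   value per column).
#' @export
diagnostic_residues <- function(msa, tree, focal_clade_leaves,
                                conservation_min = 0.9) {
  stopifnot(length(focal_clade_leaves) >= 1)
  if (length(unique(nchar(msa))) != 1) stop("rows have unequal lengths")
  if (!all(names(msa) %in% tree$tip.label) ||
      !all(tree$tip.label %in% names(msa))) {
    stop("alignment rows and tree leaves must match")
  }
  unknown <- setdiff(focal_clade_leaves, tree$tip.label)
  if (length(unknown) > 0) {
    stop("focal leaves not in tree: ", paste(unknown, collapse = ", "))
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree <- .as_rooted_binary(tree)
  ntip <- length(tree$tip.label)
  if (length(focal_clade_leaves) >= ntip) {
    stop("focal clade must be a proper subset of the leaves")
  }
  if (!ape::is.monophyletic(tree, focal_clade_leaves)) {
    stop("focal leaves are not monophyletic in the tree")
  }
  mrca <- if (length(focal_clade_leaves) == 1) {
    match(focal_clade_leaves, tree$tip.label)
  } else {
    ape::getMRCA(tree, focal_clade_leaves)
  }
  root <- ntip + 1L
  if (mrca == root) stop("focal clade spans the whole tree; no outside context")
  parent <- tree$edge[tree$edge[, 2] == mrca, 1]
  M <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(M) <- names(msa)
  L <- ncol(M)
  entropy <- numeric(L)
  rows <- list()
  for (j in seq_len(L)) {
    col <- M[, j]
    entropy[j] <- column_entropy(col)
    focal <- col[focal_clade_leaves]
    focal <- focal[focal != "-"]
    if (length(focal) == 0) next
    md <- modal_value(focal)
    conservation <- sum(focal == md) / length(focal)
    if (conservation < conservation_min) next
    states <- ifelse(col == "-", NA_character_, col)
    fs <- fitch_states(tree, states)
    anc <- fs$states[parent]
    if (!identical(anc, md)) {
      rows[[length(rows) + 1]] <- data.frame(
        column = j, ancestral_state = anc, derived_state = md,
        conservation = conservation, stringsAsFactors = FALSE
      )
    }
  }
  changes <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(column = integer(), ancestral_state = character(),
               derived_state = character(), conservation = numeric(),
               stringsAsFactors = FALSE)
  rownames(changes) <- NULL
  list(changes = changes, entropy = entropy)
}

#' Detect foreign clades nested inside another group's clade
#'
#' Reports each maximal clade C whose leaves all belong to one group g,
#' where the smallest proper ancestor clade P carrying at least `min_host`
#' leaves outside C has at least `host_purity` of those outside leaves in a
#' single group h different from g. Such nesting of one taxonomic group
#' inside another's clade in a gene tree, against a concordant species
#' tree, is the package's horizontal-transfer signal. A clade that is a
#' direct child of the root is never reported: a clean two-way group split
#' is concordance, not nesting. When the tree carries numeric internal
#' node labels they are interpreted as support values and clades below
#' `support_min` are skipped; trees without support values skip the
#' filter.
#'
#' @param tree Gene tree ([ape::phylo]); midpoint-rooted if unrooted.
#' @param leaf_groups Named character vector assigning every leaf a group
#'   label.
#' @param min_foreign Minimum foreign clade size (default 2).
#' @param min_host Minimum number of host (non-foreign) leaves in the
#'   enclosing clade (default 4).
#' @param host_purity Minimum fraction of the enclosing clade's
#'   non-foreign leaves in a single other group (default 0.9).
#' @param support_min Minimum support of the foreign clade's subtending
#'   branch (default 75; only applied when supports are present).
#' @return Data frame of events, sorted by foreign clade size descending:
#'   `foreign_group`, `host_group`, `n_foreign`, `n_host`,
#'   `foreign_leaves`, `host_leaves` (comma-separated), `support`.
#' @export
detect_nested_clades <- function(tree, leaf_groups, min_foreign = 2,
                                 min_host = 4, host_purity = 0.9,
                                 support_min = 75) {
  missing <- setdiff(tree$tip.label, names(leaf_groups))
  if (length(missing) > 0) {
    stop("leaves without a group label: ", paste(missing, collapse = ", "))
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  tips_of <- phangorn::Descendants(tree, seq_len(ntip + nnode), "tips")
  parent_of <- integer(ntip + nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  parent_of[root] <- NA_integer_
  root_children <- tree$edge[tree$edge[, 1] == root, 2]
  grp <- leaf_groups[tree$tip.label]
  support <- rep(NA_real_, ntip + nnode)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    support[(ntip + 1):(ntip + nnode)] <- sup
  }
  node_groups <- lapply(tips_of, function(ix) unique(grp[ix]))
  pure_group <- vapply(node_groups, function(g) {
    if (length(g) == 1) g else NA_character_
  }, character(1))

  events <- list()
  for (node in seq_len(ntip + nnode)) {
    if (node == root) next
    g <- pure_group[node]
    if (is.na(g)) next
    p <- parent_of[node]
    if (!is.na(pure_group[p]) && pure_group[p] == g) next # not maximal
    if (node %in% root_children) next # two-way split, not nesting
    c_tips <- tips_of[[node]]
    if (length(c_tips) < min_foreign) next
    if (node > ntip && !is.na(support[node]) && support[node] < support_min) next
    # climb to the smallest ancestor with >= min_host leaves outside C;
    # nesting requires the surrounding leaves to be dominated by one other
    # group h at every enclosing level, not just at the final host clade
    P <- p
    ok <- TRUE
    h <- NA_character_; purity <- NA_real_; outside <- integer(0)
    repeat {
      outside <- setdiff(tips_of[[P]], c_tips)
      if (length(outside) > 0) {
        tab <- sort(table(grp[outside]), decreasing = TRUE)
        lev_h <- names(tab)[1]
        lev_purity <- tab[[1]] / length(outside)
        if (lev_h == g || lev_purity < host_purity ||
            (!is.na(h) && lev_h != h)) { ok <- FALSE; break }
        h <- lev_h; purity <- lev_purity
        if (length(outside) >= min_host) break
      }
      if (is.na(parent_of[P])) { ok <- FALSE; break }
      P <- parent_of[P]
    }
    if (!ok || length(outside) < min_host) next
    events[[length(events) + 1]] <- data.frame(
      foreign_group = unname(g), host_group = h,
      n_foreign = length(c_tips), n_host = length(outside),
      foreign_leaves = paste(sort(tree$tip.label[c_tips]), collapse = ","),
      host_leaves = paste(sort(tree$tip.label[setdiff(tips_of[[P]], c_tips)]),
                          collapse = ","),
      support = support[node],
      stringsAsFactors = FALSE
    )
  }
  if (length(events) == 0) {
    return(data.frame(foreign_group = character(), host_group = character(),
                      n_foreign = integer(), n_host = integer(),
                      foreign_leaves = character(), host_leaves = character(),
                      support = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  out <- out[order(-out$n_foreign, out$foreign_leaves), , drop = FALSE]
  rownames(out) <- NULL
  out
}
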