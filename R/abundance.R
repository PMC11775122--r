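## Gene-catalog abundance profiling: k-mer read assignment (a desk-scale
## stand-in for mapping reads to a gene-catalog reference), library-size
## filtering, counts-per-million normalization, and nonparametric group
## comparisons across the three disease categories (nonIBD, UC, CD).

#' Construct a sample-by-family count matrix
#'
#' @param counts Non-negative integer matrix, samples in rows, gene
#'   families in columns, with dimnames.
#' @param library_size Total reads per sample (mapped + unmapped); must be
#'   at least the per-sample catalog count sum.
#' @param group Group label per sample, from `{nonIBD, UC, CD}`.
#' @return A `count_matrix` object (list with `counts`, `library_size`,
#'   `group`).
#' @export
count_matrix <- function(counts, library_size, group) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0),
            length(library_size) == nrow(counts),
            length(group) == nrow(counts))
  if (!all(group %in% c("nonIBD", "UC", "CD"))) {
    stop("group labels must be nonIBD, UC or CD")
  }
  if (any(library_size <= 0)) stop("library sizes must be positive")
  if (any(rowSums(counts) > library_size)) {
    stop("per-sample catalog counts exceed the library size")
  }
  structure(list(
    counts = counts,
    library_size = setNames(as.numeric(library_size), rownames(counts)),
    group = setNames(as.character(group), rownames(counts))
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "samples x", ncol(x$counts),
      "families\n")
  cat("groups:", paste(sprintf("%s=%d", names(table(x$group)),
                               table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' Build a k-mer index over a nucleotide gene catalog
#'
#' Every k-mer of every catalog gene is recorded with the set of gene
#' families it occurs in (genes are collapsed to families through the
#' catalog map).
#'
#' @param catalog Named character vector of nucleotide gene sequences
#'   (names are catalog headers).
#' @param gene2family Named character vector mapping catalog headers to
#'   family identifiers.
#' @param k Odd k-mer size (default 21).
#' @return A `kmer_index` object (environment-backed).
#' @export
build_kmer_index <- function(catalog, gene2family, k = 21) {
  stopifnot(k %% 2 == 1, k >= 5)
  fams <- gene2family[names(catalog)]
  if (anyNA(fams)) stop("every catalog gene needs a family in gene2family")
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(catalog)) {
    s <- toupper(catalog[[i]])
    L <- nchar(s)
    if (L < k) next
    kms <- unique(substring(s, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1))
    f <- fams[[i]]
    for (km in kms) {
      cur <- env[[km]]
      if (is.null(cur)) env[[km]] <- f
      else if (!f %in% cur) env[[km]] <- c(cur, f)
    }
  }
  structure(list(env = env, k = as.integer(k),
                 families = sort(unique(unname(fams)))),
            class = "kmer_index")
}

#' Assign reads to gene families by k-mer plurality
#'
#' Each read's k-mers (both strands considered) are matched against the
#' catalog index; the read is assigned to the family holding a strict
#' plurality of matching k-mers, provided that plurality covers at least
#' `min_frac` of the read's k-mers. Ties and sub-threshold pluralities are
#' left unassigned; reads shorter than k are tallied separately.
#'
#' @param reads Data frame with a `sequence` column (and optionally
#'   `read_id`), or a character vector of read sequences.
#' @param index A `kmer_index` from [build_kmer_index()].
#' @param min_frac Minimum fraction of a read's k-mers matching the
#'   winning family (default 0.5).
#' @return List with `counts` (named integer vector over the index's
#'   families), `assignments` (per-read family or `NA`), `n_unassigned`,
#'   `n_short`.
#' @export
assign_reads <- function(reads, index, min_frac = 0.5) {
  stopifnot(inherits(index, "kmer_index"), min_frac >= 0, min_frac <= 1)
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  seqs <- toupper(seqs)
  k <- index$k
  counts <- setNames(integer(length(index$families)), index$families)
  assignments <- rep(NA_character_, length(seqs))
  n_short <- 0L
  tally <- function(s) {
    L <- nchar(s)
    starts <- seq_len(L - k + 1)
    kms <- substring(s, starts, starts + k - 1)
    hits <- unlist(mget(kms, envir = index$env, ifnotfound = list(NULL)),
                   use.names = FALSE)
    if (is.null(hits)) integer(0) else table(hits)
  }
  long <- nchar(seqs) >= k
  rc <- character(length(seqs))
  rc[long] <- revcomp(seqs[long])
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    if (L < k) { n_short <- n_short + 1L; next }
    fwd <- tally(seqs[i])
    rev <- tally(rc[i])
    fams <- union(names(fwd), names(rev))
    if (length(fams) == 0) next
    per_fam <- vapply(fams, function(f) {
      max(if (f %in% names(fwd)) fwd[[f]] else 0L,
          if (f %in% names(rev)) rev[[f]] else 0L)
    }, numeric(1))
    o <- order(-per_fam)
    top <- per_fam[o[1]]
    if (length(per_fam) > 1 && per_fam[o[2]] == top) next # tie
    if (top < min_frac * (L - k + 1)) next
    f <- fams[o[1]]
    assignments[i] <- f
    counts[[f]] <- counts[[f]] + 1L
  }
  list(counts = counts, assignments = assignments,
       n_unassigned = sum(is.na(assignments)) ,
       n_short = n_short)
}

#' Filter samples by total library size
#'
#' Samples with fewer total reads than the threshold are dropped
#' (strictly-less-than comparison: a sample at exactly the threshold is
#' kept); sample order is otherwise preserved.
#'
#' @param cm A `count_matrix`.
#' @param min_total_reads Threshold (default 5e6 total reads).
#' @return The filtered `count_matrix`.
#' @export
filter_samples <- function(cm, min_total_reads = 5e6) {
  stopifnot(inherits(cm, "count_matrix"), min_total_reads >= 0)
  keep <- cm$library_size >= min_total_reads
  if (!any(keep)) stop("every sample falls below the read-count threshold")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$library_size[keep],
               cm$group[keep])
}

#' Counts-per-million normalization
#'
#' `cpm[s, g] = counts[s, g] / library_size[s] * 1e6`. The denominator is
#' the sample's total read count (mapped and unmapped), not the
#' catalog-mapped count, so per-sample catalog CPM sums are at most 1e6
#' with equality exactly when every read mapped.
#'
#' @param cm A `count_matrix` (positive library sizes).
#' @return Numeric matrix of CPM values with the same dimnames.
#' @export
cpm_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$library_size <= 0)) stop("library sizes must be positive")
  sweep(cm$counts, 1, cm$library_size, "/") * 1e6
}

#' Mann-Whitney U test
#'
#' U is the rank statistic of the first group, computed from midranks.
#' The two-sided p-value is exact (rank-sum distribution) when there are
#' no ties and `n1 * n2 <= 10000`, else a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @return List with `U`, `p_two_sided`, `n1`, `n2`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  n1 <- length(group_a); n2 <- length(group_b)
  pooled <- c(group_a, group_b)
  U <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && n1 * n2 <= 10000
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(U = unname(U), p_two_sided = min(1, wt$p.value), n1 = n1, n2 = n2,
       method = if (exact) "exact" else "normal_approx")
}

## gene-subset presets: the homologous reference families and the
## divergent aldolase on its own
.GENE_SUBSETS <- list(
  homolog_set = c("gudD", "garD", "garR", "garL"),
  gudL_only = "gudL"
)

#' Compare disease groups on summed pathway CPM
#'
#' Per-sample values are CPM summed over the gene subset. Each group is
#' checked for normality (Shapiro-Wilk), and the three pairwise
#' Mann-Whitney comparisons (CD vs nonIBD, UC vs nonIBD, UC vs CD) are
#' reported with unadjusted p-values by default (Holm adjustment
#' available). A comparison involving a group with fewer than 2 samples is
#' skipped with a warning.
#'
#' @param cpm CPM matrix from [cpm_normalize()] (samples x families).
#' @param groups Named group vector (sample -> nonIBD/UC/CD), e.g.
#'   `cm$group`.
#' @param gene_subset Columns to sum: a character vector of families, or a
#'   preset name (`"homolog_set"` = gudD, garD, garR, garL;
#'   `"gudL_only"`). Default: all columns.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return List with `tests` (data frame `comparison`, `n1`, `n2`, `U`,
#'   `p`, `p_adjusted`, `method`), `normality` (data frame `group`, `n`,
#'   `W`, `p`), `gene_subset`, and `p_adjust`.
#' @export
compare_groups <- function(cpm, groups, gene_subset = NULL,
                           p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(gene_subset)) gene_subset <- colnames(cpm)
  if (length(gene_subset) == 1 && gene_subset %in% names(.GENE_SUBSETS)) {
    gene_subset <- .GENE_SUBSETS[[gene_subset]]
  }
  missing <- setdiff(gene_subset, colnames(cpm))
  if (length(missing) > 0) {
    stop("gene subset not in the matrix: ", paste(missing, collapse = ", "))
  }
  groups <- groups[rownames(cpm)]
  vals <- rowSums(cpm[, gene_subset, drop = FALSE])
  norm_rows <- list()
  for (g in c("nonIBD", "UC", "CD")) {
    v <- vals[groups == g]
    if (length(v) >= 3 && length(v) <= 5000 && length(unique(v)) > 1) {
      sw <- stats::shapiro.test(v)
      norm_rows[[g]] <- data.frame(group = g, n = length(v),
                                   W = unname(sw$statistic),
                                   p = sw$p.value, stringsAsFactors = FALSE)
    } else {
      norm_rows[[g]] <- data.frame(group = g, n = length(v), W = NA_real_,
                                   p = NA_real_, stringsAsFactors = FALSE)
    }
  }
  comparisons <- list(c("CD", "nonIBD"), c("UC", "nonIBD"), c("UC", "CD"))
  test_rows <- list()
  for (cmp in comparisons) {
    a <- vals[groups == cmp[1]]; b <- vals[groups == cmp[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning("skipping ", cmp[1], " vs ", cmp[2], ": a group has < 2 samples")
      next
    }
    mw <- mann_whitney(a, b)
    test_rows[[length(test_rows) + 1]] <- data.frame(
      comparison = paste(cmp[1], "vs", cmp[2]),
      n1 = mw$n1, n2 = mw$n2, U = mw$U, p = mw$p_two_sided,
      method = mw$method, stringsAsFactors = FALSE
    )
  }
  tests <- if (length(test_rows) > 0) do.call(rbind, test_rows) else
    data.frame(comparison = character(), n1 = integer(), n2 = integer(),
               U = numeric(), p = numeric(), method = character(),
               stringsAsFactors = FALSE)
  tests$p_adjusted <- if (p_adjust == "holm") stats::p.adjust(tests$p, "holm")
    else tests$p
  rownames(tests) <- NULL
  list(tests = tests, normality = do.call(rbind, c(norm_rows,
                                                   make.row.names = FALSE)),
       gene_subset = gene_subset, p_adjust = p_adjust)
}
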