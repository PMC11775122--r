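## Profile-based homology search: position-specific scoring models built
## from seed alignments, Smith-Waterman local alignment of proteins against
## profile columns (compiled core), and E-values calibrated on an empirical
## i.i.d.-shuffle null with a Gumbel fit. A PSSM with local alignment
## preserves profile-search semantics at desk scale; a full profile HMM
## (match/insert/delete states) is deliberately out of scope.

#' Build a position-specific scoring model from a seed alignment
#'
#' Columns with more than 50% gaps are dropped. Per-column residue
#' frequencies receive background-proportional pseudocounts with weight
#' `alpha`: `f'(a) = (c(a) + alpha * bg(a)) / (n + alpha)` where `n` counts
#' non-gap, non-X residues in the column; log-odds are `ln(f'(a) / bg(a))`,
#' floored at `score_floor` (relevant only for `alpha = 0` zero counts).
#' The X column scores 0 at every position (ambiguous residues are
#' neutral).
#'
#' @param seed_alignment Named character vector of equal-length aligned
#'   sequences (gaps as `-`).
#' @param family_id Family label stored in the model.
#' @param pseudocount Pseudocount weight alpha (>= 0, default 1).
#' @param background Background frequencies (default [aa_background()]).
#' @param gap_open,gap_extend Affine gap penalties in nats (negative); a
#'   gap of length L costs `gap_open + L * gap_extend`.
#' @param score_floor Lower bound for log-odds scores (default -20 nats).
#' @return A `pssm` object: `family_id`, `length`, `log_odds`
#'   (length x 21 matrix over the 20 residues plus X), `modal` (per-column
#'   modal seed residue, ties broken alphabetically), `background`,
#'   `gap_open`, `gap_extend`, `mean_seed_length`, and (after
#'   [calibrate_null()]) `null_lambda`, `null_K`, `null_n`.
#' @export
build_pssm <- function(seed_alignment, family_id = "family", pseudocount = 1,
                       background = aa_background(),
                       gap_open = -11, gap_extend = -1, score_floor = -20) {
  if (length(seed_alignment) == 0) stop("seed alignment is empty")
  seqs <- toupper(seed_alignment)
  if (length(unique(nchar(seqs))) != 1) {
    stop("seed sequences have unequal lengths: not an alignment")
  }
  stopifnot(pseudocount >= 0, gap_open < 0, gap_extend < 0)
  background <- background[AA20] / sum(background[AA20])
  M <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  gap_frac <- colMeans(M == "-")
  keep <- gap_frac <= 0.5
  if (!any(keep)) stop("all alignment columns exceed 50% gaps")
  M <- M[, keep, drop = FALSE]
  L <- ncol(M)
  log_odds <- matrix(0, nrow = L, ncol = 21, dimnames = list(NULL, AAX))
  modal <- character(L)
  for (j in seq_len(L)) {
    col <- M[, j]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    f <- (as.numeric(cnt) + pseudocount * background) /
      (length(col) + pseudocount)
    log_odds[j, AA20] <- pmax(log(f / background), score_floor)
    modal[j] <- if (length(col) > 0) modal_value(col) else "X"
  }
  structure(list(
    family_id = family_id, length = L, log_odds = log_odds, modal = modal,
    background = background, gap_open = gap_open, gap_extend = gap_extend,
    mean_seed_length = mean(nchar(gsub("-", "", seqs, fixed = TRUE))),
    null_lambda = NULL, null_K = NULL, null_n = NULL
  ), class = "pssm")
}

#' Smith-Waterman local alignment of a protein against a profile
#'
#' Affine-gap local alignment of the query against the profile columns,
#' scored in nats. Percent identity counts aligned columns in which the
#' query residue equals the column's modal seed residue, over all aligned
#' (non-gap) columns. Among equal-scoring end cells the smallest
#' `(query_end, profile_end)` pair is chosen; traceback prefers
#' diagonal over up (query-consuming gap) over left (profile-consuming
#' gap). A query with no positive-scoring alignment returns score 0 and an
#' empty span.
#'
#' @param profile A `pssm` from [build_pssm()].
#' @param query Protein string (residues in the 20-letter alphabet plus X).
#' @return List with `score` (nats), `q_start`, `q_end`, `p_start`,
#'   `p_end` (1-based inclusive; `NA` for an empty alignment),
#'   `n_aligned`, and `pct_identity` in `[0, 100]`.
#' @export
sw_profile_align <- function(profile, query) {
  stopifnot(inherits(profile, "pssm"), nchar(query) >= 1)
  idx <- match(chars(toupper(query)), AAX)
  if (anyNA(idx)) stop("query contains characters outside the protein alphabet")
  res <- sw_align_cpp(profile$log_odds, idx, profile$gap_open,
                      profile$gap_extend, match(profile$modal, AAX))
  res$pct_identity <- if (res$n_aligned > 0) {
    100 * res$n_modal_match / res$n_aligned
  } else 0
  res
}

#' Calibrate a profile's E-value null by random shuffles
#'
#' Scores `n_shuffles` random sequences drawn i.i.d. from the background
#' frequencies (length = mean ungapped seed length) and fits a Gumbel
#' distribution to the scores by the method of moments:
#' `lambda = pi / (sd * sqrt(6))` and `K = exp(lambda * mu) / (m * n)` with
#' `mu` the Gumbel location, `m` the profile length and `n` the shuffle
#' length. The E-value of a hit with score S against a proteome of N
#' residues is then `K * m * N * exp(-lambda * S)`.
#'
#' @param profile A `pssm`.
#' @param n_shuffles Number of shuffles (>= 100).
#' @param shuffle_length Length of the null sequences (default: mean
#'   ungapped seed length, rounded).
#' @param seed Integer seed.
#' @return The profile with `null_lambda`, `null_K`, `null_n` filled in.
#' @export
calibrate_null <- function(profile, n_shuffles = 200, shuffle_length = NULL,
                           seed = 1) {
  stopifnot(inherits(profile, "pssm"))
  if (n_shuffles < 100) stop("n_shuffles must be >= 100 for a stable fit")
  if (is.null(shuffle_length)) shuffle_length <- max(10L, round(profile$mean_seed_length))
  scores <- with_seed(derive_seed(seed, paste0("null:", profile$family_id)), {
    vapply(seq_len(n_shuffles), function(i) {
      sw_profile_align(profile, random_protein(shuffle_length))$score
    }, numeric(1))
  })
  s <- sd(scores)
  if (s == 0) stop("zero variance in shuffle scores; cannot fit the null")
  beta <- s * sqrt(6) / pi
  lambda <- 1 / beta
  mu <- mean(scores) - 0.5772156649015329 * beta
  profile$null_lambda <- lambda
  profile$null_K <- exp(lambda * mu) / (profile$length * shuffle_length)
  profile$null_n <- as.integer(n_shuffles)
  profile
}

#' E-value of an alignment score
#'
#' @param profile A calibrated `pssm`.
#' @param score Alignment score in nats.
#' @param n_residues Size of the searched proteome in residues.
#' @return Expected number of hits of at least this score among random
#'   sequences: `K * m * N * exp(-lambda * S)`.
#' @export
e_value <- function(profile, score, n_residues) {
  if (is.null(profile$null_lambda)) {
    stop("profile '", profile$family_id, "' is not calibrated; run calibrate_null()")
  }
  profile$null_K * profile$length * n_residues * exp(-profile$null_lambda * score)
}

#' Search proteomes with a set of calibrated profiles
#'
#' Scores every (profile, protein) pair; hits with E-value at or below the
#' cutoff are retained, sorted by ascending E-value then locus tag. The
#' E-value search size N is the total residue count of the protein's
#' genome.
#'
#' @param profiles List of calibrated `pssm` objects.
#' @param proteins Gene table with columns `genome_id`, `locus_tag`,
#'   `protein_seq` (one or several genomes).
#' @param e_cutoff E-value cutoff (> 0; `Inf` reports every pair). Default
#'   1e-10.
#' @return Hit table: `genome_id`, `locus_tag`, `family_id`, `score`,
#'   `e_value`, `pct_identity`, `q_start`, `q_end`, `p_start`, `p_end`.
#' @export
search_proteome <- function(profiles, proteins, e_cutoff = 1e-10) {
  stopifnot(e_cutoff > 0)
  empty <- data.frame(genome_id = character(), locus_tag = character(),
                      family_id = character(), score = numeric(),
                      e_value = numeric(), pct_identity = numeric(),
                      q_start = integer(), q_end = integer(),
                      p_start = integer(), p_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(proteins) == 0) return(empty)
  if (inherits(profiles, "pssm")) profiles <- list(profiles)
  n_by_genome <- tapply(nchar(proteins$protein_seq), proteins$genome_id, sum)
  rows <- vector("list", nrow(proteins) * length(profiles))
  k <- 0L
  for (i in seq_len(nrow(proteins))) {
    N <- n_by_genome[[proteins$genome_id[i]]]
    for (pr in profiles) {
      aln <- sw_profile_align(pr, proteins$protein_seq[i])
      ev <- e_value(pr, aln$score, N)
      if (ev <= e_cutoff) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          genome_id = proteins$genome_id[i], locus_tag = proteins$locus_tag[i],
          family_id = pr$family_id, score = aln$score, e_value = ev,
          pct_identity = aln$pct_identity,
          q_start = aln$q_start, q_end = aln$q_end,
          p_start = aln$p_start, p_end = aln$p_end,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) return(empty)
  hits <- do.call(rbind, rows[seq_len(k)])
  hits[order(hits$e_value, hits$locus_tag), , drop = FALSE]
}

#' Serialize a profile to TSV
#'
#' Metadata lines are prefixed with `#`; the body has one row per profile
#' column with the modal residue and the 21 per-residue scores.
#'
#' @param profile A `pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    paste0("# family_id=", profile$family_id),
    paste0("# gap_open=", profile$gap_open),
    paste0("# gap_extend=", profile$gap_extend),
    paste0("# mean_seed_length=", format(profile$mean_seed_length, digits = 17)),
    paste0("# background=", paste(format(profile$background, digits = 17),
                                  collapse = ",")),
    paste0("# null_lambda=", if (is.null(profile$null_lambda)) "NA" else
      format(profile$null_lambda, digits = 17)),
    paste0("# null_K=", if (is.null(profile$null_K)) "NA" else
      format(profile$null_K, digits = 17)),
    paste0("# null_n=", if (is.null(profile$null_n)) "NA" else profile$null_n)
  )
  writeLines(meta, con)
  writeLines(paste(c("column", "modal", AAX), collapse = "\t"), con)
  for (j in seq_len(profile$length)) {
    writeLines(paste(c(j, profile$modal[j],
                       format(profile$log_odds[j, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a profile written by [write_profile()]
#'
#' @param path Path to a profile TSV.
#' @return A `pssm` object.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^#\\s*", "", m)
    eq <- regexpr("=", kv, fixed = TRUE)
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[!startsWith(lines, "#")]
  tab <- read.delim(text = paste(body, collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  lo <- as.matrix(tab[, AAX])
  dimnames(lo) <- list(NULL, AAX)
  num_or_null <- function(x) if (identical(x, "NA")) NULL else as.numeric(x)
  structure(list(
    family_id = meta$family_id, length = nrow(lo), log_odds = lo,
    modal = as.character(tab$modal),
    background = setNames(as.numeric(strsplit(meta$background, ",")[[1]]), AA20),
    gap_open = as.numeric(meta$gap_open),
    gap_extend = as.numeric(meta$gap_extend),
    mean_seed_length = as.numeric(meta$mean_seed_length),
    null_lambda = num_or_null(meta$null_lambda),
    null_K = num_or_null(meta$null_K),
    null_n = if (identical(meta$null_n, "NA")) NULL else as.integer(meta$null_n)
  ), class = "pssm")
}
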