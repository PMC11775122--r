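## Gene-neighborhood analysis: operon inference from coordinates, candidate
## pathway members from co-operonic unannotated genes (the discovery logic
## that surfaced the gudL aldolase and the garABC transporter), and
## cross-genome gene-cluster similarity links.

#' Infer operons from gene coordinates
#'
#' Genes are sorted by contig, strand and start; consecutive same-strand
#' genes on the same contig are merged into an operon while the intergenic
#' gap (`next.start - prev.end - 1`, negative overlaps treated as 0) stays
#' at or below the threshold. A strand change always splits. Singleton
#' operons are allowed, so the result is a partition of the genes.
#'
#' @param genes Gene table for one genome.
#' @param max_gap_bp Maximum intra-operon intergenic gap (default 500 bp).
#' @return The gene table with an added `operon_id` column
#'   (`<genome>_op<k>`), sorted by contig, strand, start.
#' @export
infer_operons <- function(genes, max_gap_bp = 500) {
  stopifnot(max_gap_bp >= 0, nrow(genes) > 0)
  if (length(unique(genes$genome_id)) != 1) {
    stop("infer_operons expects genes from a single genome")
  }
  o <- order(genes$contig_id, genes$strand, genes$start)
  genes <- genes[o, , drop = FALSE]
  n <- nrow(genes)
  new_block <- logical(n)
  new_block[1] <- TRUE
  if (n > 1) {
    same <- genes$contig_id[-1] == genes$contig_id[-n] &
      genes$strand[-1] == genes$strand[-n]
    gap <- pmax(genes$start[-1] - genes$end[-n] - 1L, 0L)
    new_block[-1] <- !(same & gap <= max_gap_bp)
  }
  ids <- cumsum(new_block)
  genes$operon_id <- sprintf("%s_op%03d", genes$genome_id, ids)
  rownames(genes) <- NULL
  genes
}

#' Summarize operons
#'
#' @param genes Gene table with an `operon_id` column ([infer_operons()]).
#' @return Data frame `operon_id`, `contig_id`, `strand`, `n_genes`,
#'   `span_start`, `span_end`.
#' @export
operon_table <- function(genes) {
  stopifnot(!is.null(genes$operon_id))
  sp <- split(genes, genes$operon_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(operon_id = g$operon_id[1], contig_id = g$contig_id[1],
               strand = g$strand[1], n_genes = nrow(g),
               span_start = min(g$start), span_end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$operon_id), , drop = FALSE]
}

#' Candidate pathway members from operon context
#'
#' For every operon containing at least one pathway-family hit, every
#' member without a pathway hit is emitted as a candidate, ranked by
#' (number of pathway-hit co-members, descending), then (operon size,
#' ascending), then locus tag. This automates the manual neighborhood
#' examination that identified an unannotated aldolase in the garR operon
#' and an uncharacterized ABC transporter in the gudD operon.
#'
#' @param genes Gene table with `operon_id` ([infer_operons()]), one
#'   genome.
#' @param hits Best-hit-reduced hit table for the same genome.
#' @return Candidate table: `genome_id`, `locus_tag`, `product`,
#'   `operon_id`, `n_pathway_comembers`, `operon_size`,
#'   `comember_families`, `rank`.
#' @export
candidate_members <- function(genes, hits) {
  stopifnot(!is.null(genes$operon_id))
  hit_fam <- setNames(hits$family_id, hits$locus_tag)
  rows <- list()
  for (op in split(genes, genes$operon_id)) {
    is_hit <- op$locus_tag %in% names(hit_fam)
    if (!any(is_hit) || all(is_hit)) next
    fams <- sort(unique(hit_fam[op$locus_tag[is_hit]]))
    for (i in which(!is_hit)) {
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = op$genome_id[i], locus_tag = op$locus_tag[i],
        product = op$product[i], operon_id = op$operon_id[i],
        n_pathway_comembers = sum(is_hit), operon_size = nrow(op),
        comember_families = paste(fams, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(genome_id = character(), locus_tag = character(),
                      product = character(), operon_id = character(),
                      n_pathway_comembers = integer(), operon_size = integer(),
                      comember_families = character(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_pathway_comembers, out$operon_size, out$locus_tag), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

## Global alignment with match +1 / mismatch 0 / linear gap -1, via
## Biostrings; returns the two gapped strings.
align_global <- function(a, b) {
  alpha <- unique(c(AAX, chars(toupper(a)), chars(toupper(b))))
  mat <- matrix(0, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(mat) <- 1
  pa <- Biostrings::pairwiseAlignment(toupper(a), toupper(b),
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 1,
                                      type = "global")
  c(as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)))
}

#' Compare two gene clusters by greedy homology matching
#'
#' All cross-cluster gene pairs are scored by global pairwise percent
#' identity (equal-length sequences are compared column-wise; unequal
#' lengths are first aligned globally with match +1 / mismatch 0 / linear
#' gap -1). Pairs are then matched greedily by descending identity, each
#' gene used at most once; pairs below `min_identity` are discarded. This
#' mirrors the greedy linking of synteny-diagram tools rather than an
#' optimal assignment.
#'
#' @param cluster_a,cluster_b Gene tables (need `locus_tag`,
#'   `protein_seq`).
#' @param min_identity Minimum percent identity for a link (default 30).
#' @return List with `links` (data frame `locus_a`, `locus_b`,
#'   `identity`) and `n_shared` (number of matched pairs).
#' @export
cluster_similarity <- function(cluster_a, cluster_b, min_identity = 30) {
  stopifnot(min_identity >= 0, min_identity <= 100)
  empty <- list(links = data.frame(locus_a = character(), locus_b = character(),
                                   identity = numeric(), stringsAsFactors = FALSE),
                n_shared = 0L)
  if (nrow(cluster_a) == 0 || nrow(cluster_b) == 0) return(empty)
  na <- nrow(cluster_a); nb <- nrow(cluster_b)
  idm <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      a <- cluster_a$protein_seq[i]; b <- cluster_b$protein_seq[j]
      if (nchar(a) == nchar(b)) {
        idm[i, j] <- pairwise_identity(a, b)
      } else {
        al <- align_global(a, b)
        idm[i, j] <- pairwise_identity(al[1], al[2])
      }
    }
  }
  links <- list()
  used_a <- logical(na); used_b <- logical(nb)
  repeat {
    idm2 <- idm
    idm2[used_a, ] <- -1
    idm2[, used_b] <- -1
    best <- max(idm2)
    if (best < min_identity) break
    cand <- which(idm2 == best, arr.ind = TRUE)
    key <- order(cluster_a$locus_tag[cand[, 1]], cluster_b$locus_tag[cand[, 2]])
    i <- cand[key[1], 1]; j <- cand[key[1], 2]
    links[[length(links) + 1]] <- data.frame(
      locus_a = cluster_a$locus_tag[i], locus_b = cluster_b$locus_tag[j],
      identity = idm[i, j], stringsAsFactors = FALSE
    )
    used_a[i] <- TRUE; used_b[j] <- TRUE
  }
  if (length(links) == 0) return(empty)
  links <- do.call(rbind, links)
  rownames(links) <- NULL
  list(links = links, n_shared = nrow(links))
}
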