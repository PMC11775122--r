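## Readers and writers for the standard formats the pipeline touches
## (FASTA, FASTQ, GFF3, Newick, flat key/value config), plus tree pruning.
## Coordinates are 1-based inclusive everywhere; any half-open conversion is
## internal and never serialized.

#' Read a FASTA file
#'
#' Thin wrapper around Biostrings with strict alphabet validation. Sequence
#' identifiers are the first whitespace-delimited token of each header line;
#' wrapped sequence lines are concatenated and sequences uppercased.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"protein"` (20 residues plus X, `-` and `*`
#'   allowed for alignments/stops), `"dna"` (ACGTN plus `-`), or `"any"`
#'   (no validation).
#' @return Named character vector of sequences (possibly empty). Order of
#'   records is preserved.
#' @export
parse_fasta <- function(path, alphabet = c("protein", "dna", "any")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  allowed <- switch(alphabet,
    protein = c(AAX, "-", "*"),
    dna = c(DNA4, "N", "-"),
    any = NULL
  )
  if (!is.null(allowed)) {
    for (i in seq_along(seqs)) {
      bad <- setdiff(unique(chars(seqs[[i]])), allowed)
      if (length(bad) > 0) {
        stop("record '", ids[i], "' contains character(s) outside the ",
             alphabet, " alphabet: ", paste(bad, collapse = ", "))
      }
    }
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' Qualities are parsed but discarded; the pipeline's read assignment uses
#' flat substitution-error semantics and never consumes base qualities.
#'
#' @param path Path to a FASTQ file.
#' @return Data frame with columns `read_id` and `sequence`.
#' @export
parse_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             sequence = toupper(as.character(set)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file with flat qualities
#'
#' @param reads Data frame with columns `read_id` and `sequence` (as
#'   produced by [simulate_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qual <- vapply(nchar(reads$sequence), function(n) strrep("I", n), character(1))
  out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Parse genome annotations from GFF3 with companion protein sequences
#'
#' Ingests CDS features from a GFF3 file and attaches protein sequences from
#' a companion FASTA keyed by the same identifiers. Gene identity is taken
#' from the `ID` attribute, falling back to `locus_tag`. Coordinates are
#' used verbatim (GFF3 is 1-based inclusive). Only CDS features are
#' ingested; other feature types (including pseudogenes) are skipped.
#'
#' @param path Path to a GFF3 file.
#' @param protein_fasta Path to a protein FASTA, or a named character vector
#'   of protein sequences keyed by locus tag.
#' @param genome_id Genome identifier recorded in every returned row;
#'   defaults to the GFF3 file name without extension.
#' @return A gene table: one row per CDS with columns `genome_id`,
#'   `contig_id`, `start`, `end`, `strand`, `locus_tag`, `product`,
#'   `protein_seq`.
#' @export
parse_gff3 <- function(path, protein_fasta, genome_id = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (line == "" || startsWith(line, "#")) {
      if (startsWith(line, "##FASTA")) break
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9) {
      stop("malformed GFF3 at line ", ln, ": expected 9 tab-separated columns, got ",
           length(fields))
    }
    if (fields[3] != "CDS") next
    start <- suppressWarnings(as.integer(fields[4]))
    end <- suppressWarnings(as.integer(fields[5]))
    if (is.na(start) || is.na(end) || start < 1 || end < start) {
      stop("malformed GFF3 at line ", ln, ": bad coordinates '",
           fields[4], "..", fields[5], "'")
    }
    if (!fields[7] %in% c("+", "-")) {
      stop("malformed GFF3 at line ", ln, ": strand must be '+' or '-'")
    }
    attrs <- .parse_gff_attributes(fields[9])
    tag <- attrs[["ID"]]
    if (is.null(tag)) tag <- attrs[["locus_tag"]]
    if (is.null(tag)) {
      stop("malformed GFF3 at line ", ln, ": CDS lacks both ID and locus_tag")
    }
    product <- attrs[["product"]]
    if (is.null(product)) product <- "."
    rows[[length(rows) + 1]] <- data.frame(
      genome_id = genome_id, contig_id = fields[1],
      start = start, end = end, strand = fields[7],
      locus_tag = tag, product = product,
      stringsAsFactors = FALSE
    )
  }
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               locus_tag = character(), product = character(),
               stringsAsFactors = FALSE)
  dup <- genes$locus_tag[duplicated(genes$locus_tag)]
  if (length(dup) > 0) {
    stop("duplicated locus_tag within genome '", genome_id, "': ",
         paste(unique(dup), collapse = ", "))
  }
  prot <- if (is.character(protein_fasta) && length(protein_fasta) == 1 &&
              is.null(names(protein_fasta))) {
    parse_fasta(protein_fasta, alphabet = "protein")
  } else {
    protein_fasta
  }
  missing <- setdiff(genes$locus_tag, names(prot))
  if (length(missing) > 0) {
    stop("CDS without a matching protein sequence: ",
         paste(missing, collapse = ", "))
  }
  genes$protein_seq <- unname(prot[genes$locus_tag])
  genes
}

.parse_gff_attributes <- function(field) {
  out <- list()
  for (kv in strsplit(field, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (kv == "") next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    out[[substr(kv, 1, eq - 1)]] <- utils::URLdecode(substr(kv, eq + 1, nchar(kv)))
  }
  out
}

#' Write a gene table as GFF3
#'
#' @param genes Gene table (see [parse_gff3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- paste0("ID=", genes$locus_tag, ";locus_tag=", genes$locus_tag,
                  ";product=", genes$product)
  lines <- paste(genes$contig_id, "gudgar", "CDS", genes$start, genes$end,
                 ".", genes$strand, "0", attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write one synthetic genome to disk (GFF3 + protein and nucleotide FASTA)
#'
#' @param genes Gene table for one genome, including `protein_seq` and
#'   (optionally) `nucleotide_seq` columns.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_genome <- function(genes, dir) {
  stopifnot(length(unique(genes$genome_id)) == 1)
  gid <- genes$genome_id[1]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gff <- file.path(dir, paste0(gid, ".gff3"))
  faa <- file.path(dir, paste0(gid, ".faa"))
  write_gff3(genes, gff)
  write_fasta(setNames(genes$protein_seq, genes$locus_tag), faa)
  files <- c(gff3 = gff, faa = faa)
  if (!is.null(genes$nucleotide_seq)) {
    fna <- file.path(dir, paste0(gid, ".fna"))
    write_fasta(setNames(genes$nucleotide_seq, genes$locus_tag), fna)
    files <- c(files, fna = fna)
  }
  invisible(files)
}

#' Parse a Newick tree
#'
#' Supports branch lengths and integer support values stored as internal
#' node labels. Branch lengths absent from the input (cladograms) are read
#' as 0 rather than rejected.
#'
#' @param text Newick string (must end with `;`).
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  depth <- 0
  cs <- chars(text)
  for (i in seq_along(cs)) {
    if (cs[i] == "(") depth <- depth + 1
    if (cs[i] == ")") depth <- depth - 1
    if (depth < 0) stop("unbalanced parenthesis at character ", i, " of Newick string")
  }
  if (depth != 0) {
    stop("unbalanced parentheses in Newick string: ", depth,
         " '(' left open at character ", nchar(text))
  }
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr)) stop("could not parse Newick string")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicated leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree An [ape::phylo] tree.
#' @return Newick string; internal node labels (support values) are kept.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Prune a tree to a set of leaves
#'
#' Leaves outside `keep_labels` are removed and resulting unary internal
#' nodes collapsed with branch lengths summed, so pairwise path lengths
#' between kept leaves are unchanged.
#'
#' @param tree An [ape::phylo] tree.
#' @param keep_labels Character vector of leaf labels to keep (at least 2).
#' @return The pruned [ape::phylo] tree.
#' @export
prune_tree <- function(tree, keep_labels) {
  if (length(keep_labels) == 0) stop("keep_labels is empty: nothing to keep")
  unknown <- setdiff(keep_labels, tree$tip.label)
  if (length(unknown) > 0) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(unique(keep_labels)) < 2) {
    stop("at least two distinct leaves must be kept")
  }
  if (setequal(keep_labels, tree$tip.label)) return(tree)
  ape::keep.tip(tree, unique(keep_labels))
}

#' Default run configuration
#'
#' All tunable thresholds of the pipeline with their documented defaults.
#' A serialized configuration ([write_config()] / [read_config()])
#' reproduces a run byte-for-byte given the same inputs and seed.
#'
#' @return Named list of configuration values:
#' \describe{
#'   \item{e_value_cutoff}{Homology-search E-value cutoff (default 1e-10).
#'     `strict_e_value_cutoff` (1e-100) records the much stricter cutoff
#'     customary with full profile-HMM searches; both are configurable.}
#'   \item{pseudocount_weight}{Background-proportional pseudocount weight
#'     alpha for PSSM construction (default 1).}
#'   \item{gap_open, gap_extend}{Affine gap penalties in nats (-11, -1).}
#'   \item{n_shuffles}{Shuffles used for E-value calibration (default 200).}
#'   \item{operon_max_gap_bp}{Maximum same-strand intergenic gap within an
#'     operon (default 500 bp).}
#'   \item{min_cluster_identity}{Minimum percent identity for a cross-cluster
#'     gene link (default 30).}
#'   \item{kmer_size, kmer_min_frac}{Read-assignment k-mer size (21, odd)
#'     and minimum matching fraction (0.5).}
#'   \item{min_total_reads}{Sample filter on total library size
#'     (default 5e6 reads).}
#'   \item{trim_max_gap_fraction}{Alignment columns with a gap fraction
#'     strictly above this are removed (default 0.97).}
#'   \item{conservation_min}{Minimum within-clade conservation for a
#'     diagnostic residue (default 0.9).}
#'   \item{hgt_min_foreign, hgt_min_host, hgt_host_purity, hgt_support_min}{
#'     Nested-clade detection thresholds (2, 4, 0.9, 75).}
#'   \item{grammar, excluded_families}{Pathway grammar string and families
#'     reported but excluded from calls.}
#'   \item{d_max}{Cap for Poisson-corrected distances (default 10).}
#'   \item{seed}{Global integer seed; every stochastic operation derives a
#'     sub-seed from it via [derive_seed()].}
#' }
#' @export
default_config <- function() {
  list(
    e_value_cutoff = 1e-10,
    strict_e_value_cutoff = 1e-100,
    pseudocount_weight = 1,
    gap_open = -11,
    gap_extend = -1,
    n_shuffles = 200,
    operon_max_gap_bp = 500,
    min_cluster_identity = 30,
    kmer_size = 21,
    kmer_min_frac = 0.5,
    min_total_reads = 5e6,
    trim_max_gap_fraction = 0.97,
    conservation_min = 0.9,
    hgt_min_foreign = 2,
    hgt_min_host = 4,
    hgt_host_purity = 0.9,
    hgt_support_min = 75,
    grammar = "(gudD|garD)&(gudL|garL)&garR",
    excluded_families = "garK",
    d_max = 10,
    seed = 1
  )
}

#' Write a configuration to a flat key/value file
#'
#' @param config Named list (see [default_config()]).
#' @param path Output path; one `key = value` line per entry.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) paste(format(v, digits = 17, scientific = NA), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }, character(1))
  writeLines(paste(names(config), "=", vals), path)
  invisible(path)
}

#' Read a configuration from a flat key/value file
#'
#' Unknown keys are kept verbatim; values parseable as numbers are coerced.
#'
#' @param path Path to a file written by [write_config()].
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  out <- list()
  for (line in readLines(path)) {
    line <- trimws(line)
    if (line == "" || startsWith(line, "#")) next
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", line)
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
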