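## Boolean pathway-grammar calling over homology hits. The grammar is data
## (a config string such as "(gudD|garD)&(gudL|garL)&garR", the minimum
## viable gud/gar pathway), so the engine is reusable for other pathways.
## The glycerate kinase garK is handled as an "excluded" annotation: its
## hits are still reported but never affect the verdict, reflecting its
## polyphyly (kinases recruited independently multiple times).

#' Parse a boolean pathway grammar
#'
#' Grammar strings are boolean expressions over family identifiers with
#' `&` (AND), `|` (OR) and parentheses; `|` binds loosest. Family
#' identifiers must match `[A-Za-z][A-Za-z0-9_.-]*`.
#'
#' @param text Grammar string, e.g. `"(gudD|garD)&(gudL|garL)&garR"`.
#' @param excluded_families Families that may appear in hit tables but must
#'   not appear in the expression (annotation-only families).
#' @return A `pathway_grammar` object with the expression tree and the set
#'   of literals.
#' @export
parse_grammar <- function(text, excluded_families = character(0)) {
  stopifnot(is.character(text), length(text) == 1, nzchar(trimws(text)))
  m <- gregexpr("[A-Za-z][A-Za-z0-9_.-]*|[&|()]|\\S", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  bad <- toks[!grepl("^([A-Za-z][A-Za-z0-9_.-]*|[&|()])$", toks)]
  if (length(bad) > 0) {
    stop("grammar contains invalid token(s): ", paste(unique(bad), collapse = " "))
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    while (!is.na(peek()) && peek() == "|") {
      advance()
      left <- list(op = "or", args = list(left, parse_and()))
    }
    left
  }
  parse_and <- function() {
    left <- parse_atom()
    while (!is.na(peek()) && peek() == "&") {
      advance()
      left <- list(op = "and", args = list(left, parse_atom()))
    }
    left
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of grammar")
    if (t == "(") {
      advance()
      inner <- parse_or()
      if (is.na(peek()) || peek() != ")") stop("missing ')' in grammar")
      advance()
      return(inner)
    }
    if (t %in% c(")", "&", "|")) stop("unexpected '", t, "' in grammar")
    advance()
    list(op = "lit", family = t)
  }
  expr <- parse_or()
  if (pos <= length(toks)) {
    stop("trailing token(s) in grammar: ", paste(toks[pos:length(toks)], collapse = " "))
  }
  lits <- character(0)
  collect <- function(node) {
    if (node$op == "lit") lits <<- c(lits, node$family)
    else for (a in node$args) collect(a)
  }
  collect(expr)
  overlap <- intersect(unique(lits), excluded_families)
  if (length(overlap) > 0) {
    stop("excluded families appear in the grammar: ", paste(overlap, collapse = ", "))
  }
  structure(list(expression = expr, literals = sort(unique(lits)),
                 excluded_families = excluded_families, text = text),
            class = "pathway_grammar")
}

#' Evaluate a grammar against a set of present families
#'
#' @param grammar A `pathway_grammar` (or grammar string).
#' @param present Character vector of families with a surviving hit.
#' @return Logical scalar.
#' @export
eval_grammar <- function(grammar, present) {
  if (is.character(grammar)) grammar <- parse_grammar(grammar)
  ev <- function(node) {
    switch(node$op,
           lit = node$family %in% present,
           and = ev(node$args[[1]]) && ev(node$args[[2]]),
           or = ev(node$args[[1]]) || ev(node$args[[2]]))
  }
  ev(grammar$expression)
}

#' Reduce a hit table to the best hit per (genome, family)
#'
#' Exactly one hit is retained per (genome, family): the minimum E-value,
#' with ties broken by higher raw score, then lexicographic locus tag.
#'
#' @param hits Hit table from [search_proteome()] (finite E-values).
#' @return The reduced hit table.
#' @export
best_hits_per_family <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  stopifnot(all(is.finite(hits$e_value)))
  o <- order(hits$genome_id, hits$family_id, hits$e_value, -hits$score,
             hits$locus_tag)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(hits[, c("genome_id", "family_id")])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call pathway presence per genome
#'
#' Evaluates the pathway grammar per genome with a literal true iff the
#' family has a surviving (best-reduced) hit. Families listed as excluded
#' never affect the verdict. Genomes without any hit still receive a
#' (negative) call when listed in `genome_ids`.
#'
#' @param best_hits Best-hit-reduced hit table ([best_hits_per_family()]).
#' @param grammar A `pathway_grammar` or grammar string (default: the
#'   minimum viable gud/gar pathway).
#' @param genome_ids Genomes to call (default: those present in
#'   `best_hits`).
#' @param excluded_families Families ignored by the grammar (default
#'   `"garK"`).
#' @return Call table: `genome_id`, `satisfied`, `n_families_hit`,
#'   `families_hit`, `missing_families` (grammar literals without a hit,
#'   comma-separated). The best-hit table restricted to called genomes is
#'   attached as `attr(, "best_hits")`.
#' @export
call_pathway <- function(best_hits, grammar = default_config()$grammar,
                         genome_ids = NULL,
                         excluded_families = default_config()$excluded_families) {
  if (is.character(grammar)) grammar <- parse_grammar(grammar, excluded_families)
  if (is.null(genome_ids)) genome_ids <- sort(unique(best_hits$genome_id))
  calls <- lapply(genome_ids, function(g) {
    fams <- best_hits$family_id[best_hits$genome_id == g]
    fams_eff <- setdiff(fams, grammar$excluded_families)
    missing <- setdiff(grammar$literals, fams_eff)
    data.frame(
      genome_id = g,
      satisfied = eval_grammar(grammar, fams_eff),
      n_families_hit = length(unique(fams)),
      families_hit = paste(sort(unique(fams)), collapse = ","),
      missing_families = paste(sort(missing), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, calls)
  attr(out, "best_hits") <- best_hits[best_hits$genome_id %in% genome_ids, ,
                                      drop = FALSE]
  attr(out, "grammar") <- grammar
  out
}

#' Species-level pathway prevalence
#'
#' @param calls Call table from [call_pathway()].
#' @param species_map Named character vector mapping every genome to a
#'   species.
#' @return Data frame `species_id`, `n_genomes`, `n_with_pathway`, ordered
#'   lexicographically by species.
#' @export
prevalence <- function(calls, species_map) {
  missing <- setdiff(calls$genome_id, names(species_map))
  if (length(missing) > 0) {
    stop("genome(s) without a species assignment: ",
         paste(missing, collapse = ", "))
  }
  sp <- species_map[calls$genome_id]
  agg <- aggregate(list(n_with_pathway = as.integer(calls$satisfied)),
                   by = list(species_id = sp), FUN = sum)
  cnt <- aggregate(list(n_genomes = rep(1L, nrow(calls))),
                   by = list(species_id = sp), FUN = sum)
  out <- merge(cnt, agg, by = "species_id")
  out <- out[order(out$species_id), c("species_id", "n_genomes", "n_with_pathway")]
  rownames(out) <- NULL
  out
}

#' Export a nucleotide gene catalog of pathway-positive genomes
#'
#' Collects the nucleotide sequence of every best-hit gene of every
#' pathway-positive genome into a catalog FASTA (headers
#' `genome|locus|family`) with a companion gene-to-family map, the input
#' expected by the read-assignment stage.
#'
#' @param calls Call table from [call_pathway()].
#' @param genes Gene table(s) with `genome_id`, `locus_tag` and
#'   `nucleotide_seq` columns (e.g. rbind of [plant_genomes()] genomes).
#' @param best_hits Best-hit-reduced hit table.
#' @param path Optional output prefix; when given, `<path>.fna` and
#'   `<path>.tsv` are written.
#' @return List with `fasta` (named nucleotide vector) and `map` (data
#'   frame `header`, `genome_id`, `locus_tag`, `family_id`).
#' @export
export_catalog <- function(calls, genes, best_hits, path = NULL) {
  pos <- calls$genome_id[calls$satisfied]
  sel <- best_hits[best_hits$genome_id %in% pos, , drop = FALSE]
  sel <- sel[order(sel$genome_id, sel$family_id), , drop = FALSE]
  if (is.null(genes$nucleotide_seq)) {
    stop("gene table lacks a nucleotide_seq column")
  }
  key <- paste(genes$genome_id, genes$locus_tag, sep = "\r")
  fasta <- character(nrow(sel))
  headers <- character(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    j <- match(paste(sel$genome_id[i], sel$locus_tag[i], sep = "\r"), key)
    if (is.na(j) || is.na(genes$nucleotide_seq[j])) {
      stop("missing nucleotide sequence for ", sel$genome_id[i], " / ",
           sel$locus_tag[i])
    }
    fasta[i] <- genes$nucleotide_seq[j]
    headers[i] <- paste(sel$genome_id[i], sel$locus_tag[i], sel$family_id[i],
                        sep = "|")
  }
  names(fasta) <- headers
  map <- data.frame(header = headers, genome_id = sel$genome_id,
                    locus_tag = sel$locus_tag, family_id = sel$family_id,
                    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  if (!is.null(path)) {
    write_fasta(fasta, paste0(path, ".fna"))
    write.table(map, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(fasta = fasta, map = map)
}
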