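## Synthetic-data generators: species trees, protein families evolved along
## them, annotated genomes with planted gud/gar clusters (optionally with a
## horizontally transferred cluster), negative-binomial count matrices and
## sequencing reads. Every generator is a pure function of (inputs, seed);
## truth tables are emitted alongside each dataset so downstream
## precision/recall is computable without re-deriving ground truth.

#' Simulation specification
#'
#' Bundles every tunable of the synthetic-data module with its default.
#' Defaults describe a moderately diverged gut-microbe-like community: a
#' Yule species tree, indel-free protein families at 0.1 expected
#' substitutions/site per unit branch length, two planted cluster layouts
#' (a permease + garL layout and an ABC-transporter + gudL layout), and
#' negative-binomial counts with a two-fold planted group effect.
#'
#' @param n_taxa Number of species (leaves) in the species tree.
#' @param birth_rate Yule speciation rate per unit time.
#' @param aa_substitution_rate Expected amino-acid substitutions per site
#'   per unit branch length.
#' @param pathway_layouts Cluster layouts available for planting: subset of
#'   `"ecoli_like"` (gudP-gudD-garL-garR-garK, contiguous, same strand) and
#'   `"clostridioformis_like"` (garABC-gudD-gudL-garR-garK).
#' @param fraction_with_pathway Fraction of genomes receiving a complete
#'   planted cluster.
#' @param fraction_decoy Fraction of genomes receiving an incomplete decoy
#'   cluster (one core family deleted).
#' @param hgt_events List of `list(donor = <group label>, recipient =
#'   <leaf label>)` transfer events applied to the cluster families.
#' @param nb_mean Negative-binomial mean count per gene at the reference
#'   library size (geometric mean of `lib_size_range`).
#' @param nb_dispersion Negative-binomial dispersion (`size`); variance is
#'   `mean + mean^2 / nb_dispersion`.
#' @param effect_log2fc Planted log2 fold change of pathway-gene counts in
#'   the UC and CD groups relative to nonIBD.
#' @param read_length Simulated read length (nt); must be at least twice
#'   the downstream k-mer size (default 21).
#' @param error_rate Per-base substitution error rate of simulated reads.
#' @param lib_size_range Library sizes are drawn log-uniformly from this
#'   range (total reads per sample).
#' @param n_distractor_families Number of unrelated protein families shared
#'   across all genomes (search negatives).
#' @param family_length_range Root protein length range (residues).
#' @param genes_per_genome Range of the per-genome gene count.
#' @param seed Integer seed; all module randomness derives from it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_taxa = 50, birth_rate = 1, aa_substitution_rate = 0.1,
                     pathway_layouts = c("ecoli_like", "clostridioformis_like"),
                     fraction_with_pathway = 0.4, fraction_decoy = 0.2,
                     hgt_events = list(),
                     nb_mean = 100, nb_dispersion = 5, effect_log2fc = 1,
                     read_length = 100, error_rate = 0.01,
                     lib_size_range = c(5e6, 5e7),
                     n_distractor_families = 20,
                     family_length_range = c(150, 350),
                     genes_per_genome = c(50, 200),
                     seed = 1) {
  stopifnot(n_taxa >= 2, birth_rate > 0, aa_substitution_rate > 0,
            fraction_with_pathway >= 0, fraction_with_pathway <= 1,
            fraction_decoy >= 0, fraction_decoy <= 1,
            nb_dispersion > 0, error_rate >= 0, error_rate < 1,
            read_length >= 42, length(lib_size_range) == 2,
            n_distractor_families >= 0)
  pathway_layouts <- match.arg(pathway_layouts, several.ok = TRUE)
  structure(list(
    n_taxa = n_taxa, birth_rate = birth_rate,
    aa_substitution_rate = aa_substitution_rate,
    pathway_layouts = pathway_layouts,
    fraction_with_pathway = fraction_with_pathway,
    fraction_decoy = fraction_decoy,
    hgt_events = hgt_events,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    effect_log2fc = effect_log2fc,
    read_length = read_length, error_rate = error_rate,
    lib_size_range = lib_size_range,
    n_distractor_families = n_distractor_families,
    family_length_range = family_length_range,
    genes_per_genome = genes_per_genome,
    seed = seed
  ), class = "sim_spec")
}

#' Simulate an ultrametric pure-birth (Yule) species tree
#'
#' Forward simulation: starting from two lineages at the root, each of the
#' `k` extant lineages splits after an exponential waiting time with total
#' rate `birth_rate * k`; the process stops after the `n_taxa`-th species
#' arises plus one final waiting time, so leaf branches have positive
#' length. Leaves are labeled `sp1..spN`, and the two clades flanking the
#' root define the two "phylum" groups returned in the `group` component.
#'
#' @param n_taxa Number of leaves (at least 2).
#' @param birth_rate Speciation rate per lineage per unit time.
#' @param seed Integer seed.
#' @param stem_length Extra length added to the two root-adjacent branches
#'   (default 0, a pure Yule tree). A positive stem keeps the tree
#'   ultrametric while emulating two anciently diverged phyla whose split
#'   far predates the within-phylum radiations -- the situation of the two
#'   groups this generator mimics.
#' @return An [ape::phylo] tree with an extra `group` component: a named
#'   character vector assigning each leaf to `"phylumA"` or `"phylumB"`.
#' @export
simulate_species_tree <- function(n_taxa, birth_rate = 1, seed = 1,
                                  stem_length = 0) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  stopifnot(birth_rate > 0, stem_length >= 0)
  with_seed(derive_seed(seed, "species_tree"), {
    nmax <- 2L * n_taxa - 1L
    parent <- rep(NA_integer_, nmax)
    tb <- rep(NA_real_, nmax) # time lineage began
    ts <- rep(NA_real_, nmax) # time lineage split (internal nodes)
    parent[2:3] <- 1L
    tb[1] <- 0; ts[1] <- 0; tb[2:3] <- 0
    cnt <- 3L
    active <- c(2L, 3L)
    t <- 0
    k <- 2L
    while (k < n_taxa) {
      t <- t + rexp(1, birth_rate * k)
      i <- active[sample.int(k, 1)]
      ts[i] <- t
      c1 <- cnt + 1L; c2 <- cnt + 2L
      cnt <- cnt + 2L
      parent[c(c1, c2)] <- i
      tb[c(c1, c2)] <- t
      active <- c(active[active != i], c1, c2)
      k <- k + 1L
    }
    t_end <- t + rexp(1, birth_rate * n_taxa)
    kids <- split(seq_len(cnt)[-1], parent[seq_len(cnt)[-1]])
    lab <- rep(NA_character_, cnt)
    lab[sort(active)] <- paste0("sp", seq_len(n_taxa))
    fmt <- function(x) sprintf("%.10f", x)
    build <- function(id) {
      ch <- kids[[as.character(id)]]
      if (is.null(ch)) {
        paste0(lab[id], ":", fmt(t_end - tb[id]))
      } else {
        paste0("(", build(ch[1]), ",", build(ch[2]), "):", fmt(ts[id] - tb[id]))
      }
    }
    leaves_of <- function(id) {
      ch <- kids[[as.character(id)]]
      if (is.null(ch)) lab[id] else c(leaves_of(ch[1]), leaves_of(ch[2]))
    }
    nwk <- paste0("(", build(2L), ",", build(3L), ");")
    tr <- ape::read.tree(text = nwk)
    if (stem_length > 0) {
      root <- length(tr$tip.label) + 1L
      stem_edges <- which(tr$edge[, 1] == root)
      tr$edge.length[stem_edges] <- tr$edge.length[stem_edges] + stem_length
    }
    grp_a <- leaves_of(2L)
    tr$group <- setNames(ifelse(tr$tip.label %in% grp_a, "phylumA", "phylumB"),
                         tr$tip.label)
    tr
  })
}

## substitute sites of a character-vector protein along a branch, using the
## caller's RNG stream
.mutate_chars <- function(s, branch_length, rate) {
  pr <- 1 - exp(-rate * branch_length)
  hit <- which(runif(length(s)) < pr)
  for (i in hit) {
    others <- AA20[AA20 != s[i]]
    s[i] <- sample(others, 1, prob = .AA_BG[others])
  }
  s
}

#' Random protein sequence from the background distribution
#'
#' @param length Number of residues.
#' @return Protein string drawn i.i.d. from [aa_background()] under the
#'   caller's RNG stream (seed externally for reproducibility).
#' @export
random_protein <- function(length) {
  paste(sample(AA20, length, replace = TRUE, prob = .AA_BG), collapse = "")
}

#' Evolve a protein family along a tree (indel-free)
#'
#' Per branch, each site substitutes with probability
#' `1 - exp(-rate * branch_length)`; the replacement residue is drawn from
#' the fixed background frequency table excluding the current residue.
#' Evolution is indel-free, so all leaf sequences have equal length and the
#' true alignment is the identity mapping.
#'
#' @param root_protein Root sequence (>= 50 residues, 20-letter alphabet).
#' @param tree An [ape::phylo] tree.
#' @param rate Expected substitutions per site per unit branch length (> 0).
#' @param seed Integer seed.
#' @return A `family_history` list: `tree` (cladewise-ordered copy),
#'   `leaf_seqs` (named character vector leaf -> protein), `node_seqs`
#'   (internal node number as character -> protein), `rate`, `root_protein`.
#' @export
evolve_family <- function(root_protein, tree, rate, seed = 1) {
  if (rate <= 0) stop("substitution rate must be > 0")
  root_protein <- toupper(root_protein)
  if (nchar(root_protein) < 50) stop("root protein must be at least 50 residues")
  bad <- setdiff(unique(chars(root_protein)), AA20)
  if (length(bad) > 0) stop("root protein contains non-standard residue(s): ",
                            paste(bad, collapse = ", "))
  with_seed(derive_seed(seed, "evolve_family"), {
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- length(tr$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tr$Nnode)
    seqs[[root]] <- chars(root_protein)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      seqs[[ch]] <- .mutate_chars(seqs[[p]], tr$edge.length[e], rate)
    }
    flat <- vapply(seqs, paste, collapse = "", FUN.VALUE = character(1))
    structure(list(
      tree = tr,
      leaf_seqs = setNames(flat[seq_len(ntip)], tr$tip.label),
      node_seqs = setNames(flat[(ntip + 1):(ntip + tr$Nnode)],
                           as.character((ntip + 1):(ntip + tr$Nnode))),
      rate = rate, root_protein = root_protein
    ), class = "family_history")
  })
}

#' Simulate a seed alignment for profile construction
#'
#' Evolves `n_seeds` sequences independently from a common root along a
#' star tree with branch length `divergence` (expected substitutions/site).
#' Because evolution is indel-free the sequences are returned already
#' aligned.
#'
#' @param root_protein Root sequence (>= 50 residues).
#' @param n_seeds Number of seed sequences (>= 2).
#' @param divergence Expected substitutions per site from root to each seed.
#' @param seed Integer seed.
#' @return Named character vector of equal-length aligned sequences.
#' @export
simulate_seed_alignment <- function(root_protein, n_seeds = 8, divergence = 0.3,
                                    seed = 1) {
  stopifnot(n_seeds >= 2, divergence > 0)
  nwk <- paste0("(", paste0("seed", seq_len(n_seeds), ":", divergence,
                            collapse = ","), ");")
  h <- evolve_family(root_protein, parse_newick(nwk), rate = 1,
                     seed = derive_seed(seed, "seed_alignment"))
  h$leaf_seqs
}

#' Back-translate a protein to a nucleotide coding sequence
#'
#' Uses the standard codon table with a uniformly random synonymous codon
#' per residue, plus a TAA stop codon. Only downstream k-mer matching
#' consumes these sequences, so codon-bias realism is deliberately not
#' modeled.
#'
#' @param protein Protein string.
#' @param seed Optional integer seed; when `NULL` the caller's RNG stream
#'   is used.
#' @return Nucleotide string of length `3 * (nchar(protein) + 1)`.
#' @export
back_translate <- function(protein, seed = NULL) {
  run <- function() {
    cs <- chars(toupper(protein))
    codlist <- .CODONS[cs]
    ncod <- lengths(codlist)
    pick <- floor(runif(length(cs)) * ncod) + 1
    all <- unlist(codlist, use.names = FALSE)
    off <- cumsum(c(0L, ncod[-length(ncod)]))
    paste(c(all[off + pick], "TAA"), collapse = "")
  }
  if (is.null(seed)) run() else with_seed(derive_seed(seed, "backtranslate"), run())
}

## cluster layouts (gene order along the contig, all same strand)
.LAYOUTS <- list(
  ecoli_like = c("gudP", "gudD", "garL", "garR", "garK"),
  clostridioformis_like = c("garABC", "gudD", "gudL", "garR", "garK")
)

## families whose deletion breaks the minimum viable pathway grammar
.CORE_OF_LAYOUT <- list(
  ecoli_like = c("gudD", "garL", "garR"),
  clostridioformis_like = c("gudD", "gudL", "garR")
)

.PRODUCTS <- c(
  gudP = "glucarate permease",
  garABC = "ABC transporter",
  gudD = "glucarate dehydratase",
  garD = "galactarate dehydratase",
  garL = "5-keto-4-deoxy-D-glucarate aldolase",
  gudL = "DapA-like protein",
  garR = "tartronate semialdehyde reductase",
  garK = "glycerate kinase"
)

#' Plant annotated genomes with gud/gar clusters along a species tree
#'
#' Every leaf of the species tree becomes a one-contig genome of
#' `genes_per_genome` genes. A fraction of genomes receive a complete
#' cluster in one of the configured layouts (contiguous, same strand, small
#' intergenic gaps); a further fraction receive a decoy cluster with one
#' core family deleted; the rest carry no cluster. All genomes additionally
#' carry one member of each distractor family plus unrelated filler genes.
#' Cluster and distractor proteins are leaves of families evolved along the
#' species tree from random root sequences, so their divergence mirrors the
#' species divergence.
#'
#' @param tree Species tree from [simulate_species_tree()]; simulated from
#'   `spec` when `NULL`.
#' @param spec A [sim_spec()].
#' @return A `planted_genomes` list: `genomes` (named list of gene tables
#'   with `protein_seq`, `nucleotide_seq`), `truth` (per-genome status,
#'   layout, deleted family, families present, grammar verdict),
#'   `gene_truth` (locus tag -> family for every planted gene),
#'   `histories` (per-family [evolve_family()] results), `root_seqs`,
#'   `tree`, `spec`.
#' @export
plant_genomes <- function(tree = NULL, spec = sim_spec()) {
  if (is.null(tree)) {
    tree <- simulate_species_tree(spec$n_taxa, spec$birth_rate, spec$seed)
  }
  genomes <- tree$tip.label
  n <- length(genomes)
  if (spec$fraction_with_pathway * n < 1) {
    warning("fraction_with_pathway * n_taxa < 1: no pathway will be planted")
  }
  core_fams <- c("gudP", "garABC", "gudD", "garD", "garL", "gudL", "garR", "garK")
  dstr_fams <- if (spec$n_distractor_families > 0) {
    sprintf("dstr%02d", seq_len(spec$n_distractor_families))
  } else character(0)
  fams <- c(core_fams, dstr_fams)

  lr <- spec$family_length_range
  roots <- with_seed(derive_seed(spec$seed, "family_roots"), {
    lens <- sample(seq(lr[1], lr[2]), length(fams), replace = TRUE)
    setNames(vapply(lens, random_protein, character(1)), fams)
  })
  histories <- lapply(setNames(fams, fams), function(f) {
    evolve_family(roots[[f]], tree, spec$aa_substitution_rate,
                  seed = derive_seed(spec$seed, paste0("family:", f)))
  })
  for (ev in spec$hgt_events) {
    donors <- names(tree$group)[tree$group == ev$donor]
    histories <- inject_hgt(histories, tree, donors, ev$recipient,
                            seed = spec$seed)
  }

  grammar <- parse_grammar(default_config()$grammar)

  out <- with_seed(derive_seed(spec$seed, "plant_genomes"), {
    ord <- sample.int(n)
    n_pos <- round(spec$fraction_with_pathway * n)
    n_dec <- min(round(spec$fraction_decoy * n), n - n_pos)
    status <- rep("negative", n)
    status[ord[seq_len(n_pos)]] <- "complete"
    if (n_dec > 0) status[ord[n_pos + seq_len(n_dec)]] <- "decoy"

    genome_tabs <- vector("list", n)
    truth_rows <- vector("list", n)
    gene_truth_rows <- list()
    gr <- spec$genes_per_genome
    for (gidx in seq_len(n)) {
      g <- genomes[gidx]
      layout <- NA_character_
      deleted <- NA_character_
      cluster <- character(0)
      if (status[gidx] != "negative") {
        layout <- spec$pathway_layouts[sample.int(length(spec$pathway_layouts), 1)]
        cluster <- .LAYOUTS[[layout]]
        if (status[gidx] == "decoy") {
          core <- .CORE_OF_LAYOUT[[layout]]
          deleted <- core[sample.int(length(core), 1)]
          cluster <- cluster[cluster != deleted]
        }
      }
      n_genes <- sample(seq(gr[1], gr[2]), 1)
      n_fill <- max(0L, n_genes - length(cluster) - length(dstr_fams))
      other_fams <- c(dstr_fams, rep(NA_character_, n_fill))
      other_fams <- other_fams[sample.int(length(other_fams))]
      ins <- sample.int(length(other_fams) + 1L, 1) - 1L # cluster after this many

      fam_seq <- append(other_fams, cluster, after = ins)
      in_cluster <- rep(FALSE, length(fam_seq))
      if (length(cluster) > 0) in_cluster[ins + seq_along(cluster)] <- TRUE

      m <- length(fam_seq)
      prot <- character(m); product <- character(m); strand <- character(m)
      for (i in seq_len(m)) {
        f <- fam_seq[i]
        if (is.na(f)) {
          prot[i] <- random_protein(sample(100:300, 1))
          product[i] <- "hypothetical protein"
          strand[i] <- sample(c("+", "-"), 1)
        } else {
          prot[i] <- histories[[f]]$leaf_seqs[[g]]
          product[i] <- if (f %in% names(.PRODUCTS)) .PRODUCTS[[f]] else "hypothetical protein"
          strand[i] <- if (in_cluster[i]) "+" else sample(c("+", "-"), 1)
        }
      }
      nt <- vapply(prot, back_translate, character(1), USE.NAMES = FALSE)

      # lay genes along the contig; the cluster block is flanked by large
      # gaps so that it forms its own operon under the default threshold
      gap <- integer(m)
      for (i in seq_len(m)) {
        prev_in <- if (i == 1) FALSE else in_cluster[i - 1]
        gap[i] <- if (in_cluster[i] && prev_in) {
          sample(20:100, 1) # intra-cluster: well under the operon threshold
        } else if (in_cluster[i] || prev_in) {
          1000L # cluster boundary: isolate the planted operon
        } else {
          sample(50:700, 1)
        }
      }
      len <- 3L * (nchar(prot) + 1L)
      start <- integer(m); end <- integer(m)
      pos <- 0L
      for (i in seq_len(m)) {
        start[i] <- pos + gap[i] + 1L
        end[i] <- start[i] + len[i] - 1L
        pos <- end[i]
      }
      tag <- sprintf("%s_g%04d", g, seq_len(m))
      genome_tabs[[gidx]] <- data.frame(
        genome_id = g, contig_id = paste0(g, "_c1"),
        start = start, end = end, strand = strand,
        locus_tag = tag, product = product,
        protein_seq = prot, nucleotide_seq = nt,
        stringsAsFactors = FALSE
      )
      planted <- !is.na(fam_seq)
      if (any(planted)) {
        gene_truth_rows[[length(gene_truth_rows) + 1]] <- data.frame(
          genome_id = g, locus_tag = tag[planted], family = fam_seq[planted],
          in_cluster = in_cluster[planted], stringsAsFactors = FALSE
        )
      }
      present <- sort(intersect(unique(fam_seq[!is.na(fam_seq)]), core_fams))
      truth_rows[[gidx]] <- data.frame(
        genome_id = g, status = status[gidx], layout = layout,
        deleted_family = deleted,
        families_present = paste(present, collapse = ","),
        satisfied = eval_grammar(grammar, present),
        stringsAsFactors = FALSE
      )
    }
    list(genomes = setNames(genome_tabs, genomes),
         truth = do.call(rbind, truth_rows),
         gene_truth = do.call(rbind, gene_truth_rows))
  })
  structure(c(out, list(histories = histories, root_seqs = roots,
                        tree = tree, spec = spec)),
            class = "planted_genomes")
}

#' Inject a horizontal transfer of cluster genes into family histories
#'
#' The recipient leaf's sequences for the given families are re-drawn by
#' evolving from a randomly chosen ancestor node inside the donor clade
#' along a short transfer branch, so in the resulting gene trees the
#' recipient nests inside the donor clade while the species tree is
#' unchanged.
#'
#' @param histories Named list of `family_history` objects (one per family,
#'   all evolved on `tree`).
#' @param tree The species tree the histories were evolved on.
#' @param donor_leaves Leaf labels spanning the donor clade (>= 2, disjoint
#'   from the recipient).
#' @param recipient_leaf Leaf receiving the transferred genes.
#' @param families Families to transfer (default: all in `histories`).
#' @param transfer_branch Branch length (time units) from the donor
#'   ancestor to the recipient's new sequence.
#' @param seed Integer seed.
#' @return `histories` with the recipient's sequences replaced; the events
#'   are recorded in `attr(, "hgt_events")`.
#' @export
inject_hgt <- function(histories, tree, donor_leaves, recipient_leaf,
                       families = names(histories), transfer_branch = 0.05,
                       seed = 1) {
  if (!recipient_leaf %in% tree$tip.label) {
    stop("recipient leaf '", recipient_leaf, "' not in tree")
  }
  donor_leaves <- setdiff(donor_leaves, recipient_leaf)
  if (length(donor_leaves) < 2) {
    stop("donor clade must span at least 2 leaves distinct from the recipient")
  }
  events <- attr(histories, "hgt_events")
  node <- NA_integer_
  with_seed(derive_seed(seed, paste0("hgt:", recipient_leaf)), {
    mrca <- ape::getMRCA(tree, donor_leaves)
    desc <- phangorn::Descendants(tree, mrca, "all")
    cand <- unique(c(mrca, desc[desc > length(tree$tip.label)]))
    node <- cand[sample.int(length(cand), 1)]
    for (fam in families) {
      h <- histories[[fam]]
      anc <- chars(h$node_seqs[[as.character(node)]])
      newseq <- .mutate_chars(anc, transfer_branch, h$rate)
      h$leaf_seqs[[recipient_leaf]] <- paste(newseq, collapse = "")
      histories[[fam]] <- h
    }
  })
  attr(histories, "hgt_events") <- c(events, list(list(
    donor_node = node, recipient = recipient_leaf, families = families
  )))
  histories
}

#' Simulate a negative-binomial count matrix with a planted group effect
#'
#' Per-gene counts are negative-binomial with mean proportional to the
#' sample's library size (`nb_mean` is the expected count at the reference
#' library size, the geometric mean of `lib_size_range`), so CPM values are
#' stable across samples. Pathway-gene means in the UC and CD groups are
#' scaled by `2^effect_log2fc`.
#'
#' @param n_per_group Named integer vector with entries `nonIBD`, `UC`,
#'   `CD` (each >= 2).
#' @param families Gene-family (column) identifiers.
#' @param pathway_families Subset of `families` carrying the group effect.
#' @param nb_mean,nb_dispersion,effect_log2fc,lib_size_range See
#'   [sim_spec()].
#' @param seed Integer seed.
#' @return A [count_matrix()] object.
#' @export
simulate_counts <- function(n_per_group = c(nonIBD = 50, UC = 50, CD = 50),
                            families = c("gudD", "garD", "garL", "gudL", "garR"),
                            pathway_families = families,
                            nb_mean = 100, nb_dispersion = 5,
                            effect_log2fc = 1,
                            lib_size_range = c(5e6, 5e7), seed = 1) {
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (!all(c("nonIBD", "UC", "CD") %in% names(n_per_group))) {
    stop("n_per_group must name all of nonIBD, UC, CD")
  }
  if (any(n_per_group < 2)) stop("each group needs at least 2 samples")
  stopifnot(all(pathway_families %in% families))
  with_seed(derive_seed(seed, "simulate_counts"), {
    group <- rep(c("nonIBD", "UC", "CD"),
                 times = n_per_group[c("nonIBD", "UC", "CD")])
    ns <- length(group)
    lib <- round(exp(runif(ns, log(lib_size_range[1]), log(lib_size_range[2]))))
    ref <- sqrt(prod(lib_size_range))
    nf <- length(families)
    mu <- outer(lib / ref, rep(nb_mean, nf))
    fold <- ifelse(group != "nonIBD", 2^effect_log2fc, 1)
    path_col <- families %in% pathway_families
    mu[, path_col] <- mu[, path_col, drop = FALSE] * fold
    counts <- matrix(rnbinom(ns * nf, size = nb_dispersion, mu = as.vector(mu)),
                     nrow = ns, ncol = nf)
    rownames(counts) <- sprintf("S%03d", seq_len(ns))
    colnames(counts) <- families
    lib <- pmax(lib, rowSums(counts))
    count_matrix(counts, lib, group)
  })
}

#' Simulate sequencing reads from a gene catalog
#'
#' Reads are drawn from catalog genes with probability proportional to
#' `abundance * gene length`, with uniform start positions, random strand,
#' and i.i.d. per-base substitution errors. Read names encode the true
#' source gene (`r000001|<gene>`) so downstream assignment accuracy is
#' computable.
#'
#' @param catalog Named character vector of nucleotide gene sequences.
#' @param abundances Named non-negative abundances (same names as
#'   `catalog`); must not be all zero.
#' @param n_reads Number of reads.
#' @param read_length Read length (nt); every gene must be at least this
#'   long.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Data frame with columns `read_id`, `sequence`, `source_gene`,
#'   `start` (1-based position on the source gene) and `strand`.
#' @export
simulate_reads <- function(catalog, abundances, n_reads = 10000,
                           read_length = 100, error_rate = 0.01, seed = 1) {
  stopifnot(length(catalog) > 0, !is.null(names(catalog)))
  abundances <- abundances[names(catalog)]
  if (anyNA(abundances)) stop("abundances must be named for every catalog gene")
  if (all(abundances == 0)) stop("abundances are all zero")
  if (any(nchar(catalog) < read_length)) {
    stop("every catalog gene must be at least read_length nt long")
  }
  with_seed(derive_seed(seed, "simulate_reads"), {
    w <- abundances * nchar(catalog)
    gi <- sample.int(length(catalog), n_reads, replace = TRUE, prob = w)
    len <- nchar(catalog)[gi]
    start <- floor(runif(n_reads) * (len - read_length + 1)) + 1
    seqs <- substring(catalog[gi], start, start + read_length - 1)
    rev <- runif(n_reads) < 0.5
    if (any(rev)) seqs[rev] <- revcomp(seqs[rev])
    if (error_rate > 0) {
      for (i in seq_len(n_reads)) {
        pos <- which(runif(read_length) < error_rate)
        if (length(pos) > 0) {
          s <- chars(seqs[i])
          for (p in pos) s[p] <- sample(DNA4[DNA4 != s[p]], 1)
          seqs[i] <- paste(s, collapse = "")
        }
      }
    }
    data.frame(
      read_id = sprintf("r%06d|%s", seq_len(n_reads), names(catalog)[gi]),
      sequence = unname(seqs),
      source_gene = names(catalog)[gi],
      start = unname(start),
      strand = ifelse(rev, "-", "+"),
      stringsAsFactors = FALSE
    )
  })
}
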