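---
title: "Methods: discovering and quantifying oxidized-sugar (gud/gar) metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and quantifying oxidized-sugar (gud/gar) metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Bacteria that catabolize the oxidized sugars glucarate and galactarate (the
*gud/gar* pathway) convert them through a common
5-keto-4-deoxy-D-glucarate (5-KDG) intermediate to pyruvate and
2-phosphoglycerate. The canonical pathway couples an importer (the GudP/GarP
permeases or, in some lineages, a GarABC-type ABC transporter), a
dehydratase (GudD or GarD), a 5-KDG aldolase (GarL, or the convergently
evolved DapA-like GudL), a tartronate-semialdehyde reductase (GarR) and a
glycerate kinase (GarK). Because two non-homologous aldolases and two
unrelated import systems implement the same chemistry, presence of the
pathway cannot be read off a single gene family: it must be called from a
boolean combination of family-level homology evidence, and new pathway
members must be discovered from operon context rather than sequence
similarity.

`gudgar` implements that discovery-and-quantification pipeline end to end:

1. **profsearch** -- position-specific scoring models (PSSMs) built from
   seed alignments, local profile alignment of every proteome, empirical
   E-value calibration;
2. **pathcall** -- a boolean *pathway grammar* evaluated per genome over
   best hits, species-level prevalence, and export of a nucleotide gene
   catalog;
3. **neighborhood** -- operon inference from gene coordinates, ranking of
   co-operonic unannotated genes as candidate pathway members, and greedy
   cluster-to-cluster homology links;
4. **phylo** -- alignment trimming, Poisson-corrected distances,
   neighbor-joining gene trees, Fitch-parsimony ancestral states,
   clade-diagnostic residues, and detection of one taxonomic group's clade
   nested inside another's (the horizontal-gene-transfer signal);
5. **abundance** -- k-mer assignment of reads to the gene catalog,
   library-size filtering, counts-per-million (CPM) normalization and
   Mann-Whitney comparisons across the three disease groups
   (nonIBD, UC, CD);
6. **synthgen** -- generators for species trees, protein families, genomes
   with planted clusters, count matrices and reads, each emitting a truth
   table, so every stage above is testable without external data.

# Homology search

A family's PSSM is built from a seed alignment after dropping columns with
more than 50% gaps. Column frequencies receive background-proportional
pseudocounts with weight $\alpha$ (default 1):
$f'_i(a) = (c_i(a) + \alpha\,bg(a)) / (n_i + \alpha)$, and scores are
log-odds $\ln f'_i(a)/bg(a)$ in nats, floored at $-20$; the ambiguity
residue X scores 0 everywhere. The background is the fixed Robinson-Robinson
frequency table, which also drives the synthetic-protein generator and the
calibration null, keeping the search self-consistent.

Queries are aligned to profile columns by Smith-Waterman local alignment
with affine gaps (a gap of length $L$ costs `gap_open` $+ L\,$`gap_extend`,
defaults $-11$/$-1$ nats). Among equal-scoring cells the smallest
(query end, profile end) pair wins and traceback prefers
diagonal > up > left, making results order-independent. Percent identity is
counted against each column's modal seed residue over aligned columns only.
A full profile HMM with insert/delete states is deliberately out of scope:
at the divergences involved (clusters evolved at ~0.3-0.7 substitutions per
site from the seeds) the PSSM preserves profile-search semantics while
remaining exhaustively testable against a brute-force alignment enumerator.

E-values come from an empirical null: `n_shuffles` (>= 100, default 200)
i.i.d. background sequences of the mean seed length are scored and a Gumbel
is fitted by the method of moments ($\lambda = \pi/(\sigma\sqrt 6)$,
$K = e^{\lambda\mu}/(mn)$), giving
$E = K\,m\,N\,e^{-\lambda S}$ for a proteome of $N$ residues. The default
reporting cutoff is $10^{-10}$; the far stricter $10^{-100}$ threshold
customary with curated profile-HMM screens is recorded in the configuration
(`strict_e_value_cutoff`) and both are tunable. True homologs in the
synthetic data score hundreds of nats above the null, so calls are
insensitive to the cutoff over many orders of magnitude.

# Pathway grammar

The minimum viable pathway is data, not code:
`"(gudD|garD)&(gudL|garL)&garR"` by default. Per (genome, family) exactly
one hit survives (lowest E-value; ties by higher score, then locus tag) and
the grammar is evaluated with a literal true iff the family has a surviving
hit. The glycerate kinase `garK` is *excluded* rather than deleted: its
hits are still reported (it appears in real clusters) but never affect the
verdict, reflecting its polyphyly -- kinases were recruited independently
multiple times, so garK presence is not evidence for the pathway. Calls are
monotone (adding hits can only flip a genome from negative to positive),
which the suite checks by property testing, and the grammar engine is
verified against a full 2^6 truth table.

# Neighborhood analysis

Operons are runs of consecutive same-strand genes on one contig whose
intergenic gaps (`next.start - prev.end - 1`, overlaps clamped to 0) stay
at or below `operon_max_gap_bp`. The 500 bp default is a conventional
prokaryotic operon gap; the analysis this automates was originally done by
eye, and no published gap rule exists, so the threshold is exposed in the
configuration. A strand change always splits; whether intervening
opposite-strand genes should be tolerated is genuinely open -- this
implementation splits, and a user who disagrees can merge downstream.

Candidate pathway members are the operon members *without* a pathway hit in
any operon containing at least one hit, ranked by number of hit co-members
(descending), operon size (ascending), then locus tag. On genomes carrying
the transporter-aldolase cluster layout searched with homolog profiles
only, the planted DapA-like aldolase and the ABC transporter rank first in
every pathway-positive genome -- the package's re-enactment of how those
two genes were originally found.

Cluster similarity links cross-cluster gene pairs by global pairwise
identity (equal-length pairs column-wise; unequal lengths via a
match +1 / mismatch 0 / linear gap -1 global alignment), matched greedily
by descending identity with each gene used once and links below 30%
identity dropped. Greedy matching mirrors the behavior of synteny-diagram
tools; it is a 1/2-approximation of the optimal assignment, and the test
suite quantifies the gap against an exhaustive matching oracle on small
instances.

# Phylogenetics

Distances are Poisson-corrected p-distances over mutually non-gap columns,
$d = -\ln(1-p)$, capped at `d_max` (default 10) at saturation. Trees are
built by standard neighbor joining (Saitou-Nei Q criterion,
Studier-Keppler updates) with two determinism guarantees: Q ties break by
the lexicographically smallest pair of cluster labels, and negative branch
lengths are clamped to zero with the deficit moved to the sibling. On
additive matrices the reconstruction is exact (topology and lengths), which
the acceptance suite verifies on random trees.

Distance/NJ trees and Fitch parsimony stand in for maximum-likelihood tree
inference and ML ancestral reconstruction. The downstream signals --
a clade of one phylum nested in another's clade, and clade-diagnostic
residues -- are topology-level, and parsimony/distance methods express them
at desk scale with exhaustively testable semantics. This substitution is
the package's largest deliberate departure from common practice at cluster
scale, and results on real data should be confirmed with an ML tree when
compute allows.

**Ancestral states and diagnostic residues.** Fitch's bottom-up pass
computes state sets (intersection if non-empty, else union with a score
increment); the top-down pass assigns the root the lexicographically
smallest member of its set and every other node its parent's state when
possible. A column is clade-diagnostic when the focal clade's modal residue
reaches `conservation_min` (default 0.9) and *differs from the assigned
ancestral state at the focal clade's parent*. The assigned state -- not the
bottom-up state set -- is the right comparator: for any clade-wide
autapomorphy the parent's bottom-up set necessarily unions the derived
state (the intersection at that node is empty), so a set-membership test
can never fire on exactly the pattern of interest, whereas the top-down
assignment lets outgroup evidence pin the ancestral residue. Consequently
the focal clade must sit inside outside context (at least two lineages
outside it); a focal clade that is one of two root children leaves the
ancestral state undecidable by parsimony.

**Nested-clade (HGT) detection.** A maximal clade C whose leaves all carry
group g is an incongruence event when the surrounding leaves are dominated
by a single other group h at every enclosing level out to the smallest
ancestor with at least `min_host` (default 4) leaves outside C, with
dominance threshold `host_purity` (default 0.9). Two guards reflect what
"nested" means: a clade that is a direct child of the root is never an
event (a clean two-way split between groups is concordance), and the
host-size requirement counts leaves *outside* C, so the foreign clade
cannot serve as its own host context. Requiring host dominance at every
level, not only at the final host clade, prevents remnants of a
transfer-poisoned donor clade from being reported as reciprocal events.
When internal node labels carry support values, foreign clades below
`support_min` (default 75) are skipped; trees without supports skip the
filter. Unrooted gene trees are midpoint-rooted first (an outgroup, when
known, can be applied with standard `ape` tools before the call).

# Abundance profiling

Reads are assigned to gene families by k-mer plurality: both strands of a
read are matched against a k-mer index of the catalog (k = 21, odd, so a
k-mer and its reverse complement are never equal), and the read goes to the
family with a strict plurality of matching k-mers covering at least
`kmer_min_frac` (default 0.5) of the read's k-mers; ties and sub-threshold
reads stay unassigned, and reads shorter than k are tallied separately.
This replaces short-read mapping against the catalog with an alignment-free
equivalent that needs no external binaries; at 1% sequencing error and
100 nt reads the expected intact-k-mer fraction is $0.99^{21} \approx 0.81$
per k-mer, comfortably above the 0.5 threshold, and measured assignment
accuracy on truth-labeled synthetic reads is ~1.0.

Samples with fewer than `min_total_reads` (default 5,000,000) total reads
are dropped (strict inequality: a sample at exactly the threshold stays).
CPM divides each count by the sample's *total* read count -- not the
catalog-mapped count -- times 1e6, so per-sample catalog CPM sums are at
most 1e6 with equality exactly when every read mapped.

Group comparisons use the Mann-Whitney U test on per-sample CPM summed over
a gene subset (presets: the homologous reference families
gudD/garD/garR/garL, or the divergent aldolase alone). U is the rank
statistic of the first-named group; p-values are exact when there are no
ties and $n_1 n_2 \le 10{,}000$, else normally approximated with
tie-corrected variance and continuity correction. Shapiro-Wilk normality is
reported per group (CPM counts are far from normal, which is why the rank
test is the primary inference). P-values are reported **unadjusted** by
default, with the no-correction choice recorded in the result object and a
Holm option for users who want family-wise control.

# The synthetic-data generator

The generator emulates the statistical structure of the study's real
inputs, not their biology in detail:

* **Species trees** are forward-simulated pure-birth (Yule) trees, leaves
  `sp1..spN`, with the two clades flanking the root defining two "phylum"
  groups. An optional `stem_length` elongates both root-adjacent branches
  while keeping the tree ultrametric; the HGT study conditions use
  `stem_length = 2` because the two groups stand in for anciently diverged
  phyla whose split far predates the within-phylum radiations -- with a
  pure Yule root the groups are not well separated and no method could
  distinguish nesting from rooting noise.
* **Protein families** evolve indel-free along the tree: per branch, each
  site substitutes with probability $1 - e^{-rate\cdot b}$ and the
  replacement is drawn from the background excluding the current residue.
  Indel-freedom makes the true alignment the identity, isolating
  tree/ancestry logic from aligner quality, at the cost of never exercising
  gap handling on synthetic data (gap paths are covered by hand-built
  fixtures instead). The default rate, 0.1 substitutions/site per unit
  branch length, yields ~55-75% identity between planted genes and profile
  seeds -- "moderate divergence".
* **Genomes** are single contigs of 50-200 genes. Complete clusters are
  planted contiguous and same-strand in one of two layouts
  (permease-dehydratase-aldolase-reductase-kinase, or
  ABC-transporter-dehydratase-DapA-like-aldolase-reductase-kinase); decoys
  have one grammar-relevant family deleted; all genomes carry one member of
  each distractor family plus random filler. Intra-cluster gaps (20-100 bp)
  sit well under the operon threshold and cluster-flanking gaps (1000 bp)
  above it, so the planted operon is recoverable by construction -- the
  operon tests therefore verify the inference rule, not gap-threshold luck.
* **Counts** are negative-binomial with mean proportional to the sample's
  library size (`nb_mean` is the expected count at the reference library
  size, the geometric mean of the range), dispersion `nb_dispersion`
  (variance $\mu + \mu^2/\phi$), and pathway-gene means scaled by
  $2^{\mathrm{effect\_log2fc}}$ in the UC and CD groups. Coupling the mean
  to library size makes CPM the stable quantity, as in real sequencing;
  library sizes are log-uniform over a decade by default.
* **Reads** are drawn proportional to abundance x gene length with uniform
  starts, random strand and i.i.d. substitution errors; read names encode
  the true source gene.

Every generator is a pure function of (inputs, seed): a global seed is
hashed with a per-operation label (`derive_seed`) so modules consume
independent reproducible streams, and generators restore the caller's RNG
state. What passing tests on this data do *not* show: robustness to
indels and alignment error, codon bias, strain-level pangenome structure,
read-quality artifacts, or compositional effects -- all deliberately out of
scope.

# Numerical choices and degenerate inputs

* Log-odds floor $-20$ nats (only reachable at $\alpha = 0$); X column 0.
* Alignment-score ties: smallest (query end, profile end); traceback
  diagonal > up > left; zero-score alignments return an empty span.
* Gumbel fit requires >= 100 shuffles and errors on zero score variance.
* `trim_msa` removes columns with gap fraction strictly greater than the
  threshold ("over 97%" keeps exactly 97%); trimming is idempotent.
* Distances cap at `d_max` when $p \to 1$; a pair with no mutually non-gap
  columns is an error naming the pair.
* NJ requires a symmetric matrix with zero diagonal and >= 3 taxa; the
  final three clusters resolve by the three-point formulas, clamped at 0.
* Fitch resolves unrooted or multifurcating trees with
  `ape::multi2di(random = FALSE)` (deterministic); missing leaf states are
  the full alphabet.
* Empty FASTA files parse to empty vectors; empty proteomes search to empty
  hit tables; a sample filter that would drop everything is an error.

# Problem sizes

The test and acceptance runs use sizes chosen to exercise every code path
at desk scale: 50 genomes of 50-200 genes for end-to-end pathway recovery,
12 genomes for candidate discovery, 20-taxon trees with 300-residue
proteins and 100 replicates per arm for HGT detection, 100 random 10-leaf
trees for NJ exactness, 500 random instances for the Fitch oracle, and
1000/200 replicates for Mann-Whitney null calibration and power. These are
the package's documented study conditions; all thresholds above are
configuration, not constants.

# Known limitations

* Parsimony and distance methods replace ML throughout; deep or
  rate-heterogeneous real datasets deserve ML confirmation.
* The nested-clade detector reports topology-level evidence only; it cannot
  distinguish transfer direction, and a donor context smaller than the
  `min_host` window cannot support a nesting call at all.
* Percent identity against the modal seed residue is not a pairwise BLAST
  identity; compare like with like when mixing sources.
* k-mer plurality assignment has no mapping-quality model and discards
  multi-family ties rather than distributing them.
* The grammar engine evaluates presence/absence only; copy number and
  synteny do not enter the call (they are reported alongside).
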