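---
title: "Screening potential CO oxidizers and their biogeography: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening potential CO oxidizers and their biogeography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coxcensus)
```

# The problem

The large subunit of molybdenum-containing CO dehydrogenase (CoxL)
splits into form I, the CO-oxidizing enzyme, and form II, whose function
is unclear. The two differ in the seven-residue active-site motif
(AYXCSFR homologs versus AYRGAGR) and in operon gene order (coxMSL
versus coxSLM). Homology search alone conflates them, so `coxcensus`
identifies potential CO oxidizers by a conjunction of three independent
lines of evidence, then quantifies where the resulting genomes live and
with whom they co-occur.

# The screening model

Candidates flow through four gates in a fixed order; each gate can only
shrink the set (the "funnel"), and a genome is called a pcox-CO oxidizer
iff at least one of its candidates survives all four.

1. **Homology**: minimum E-value over a protein's hits ≤ `evalue_max`
   (default 1e-5, inclusive, matching the upstream search convention).
2. **Motif**: the active-site window is read off a gapped alignment by
   mapping seven consecutive ungapped reference residues onto alignment
   columns and de-gapping each sequence's slice across that column span.
   A slice that does not de-gap to exactly seven residues (an indel
   against the reference window) is classified `NONE`; this forces the
   extraction to rely on the alignment rather than fixed offsets.
   Windows are classified as `FORM1_KNOWN` (the six accepted motifs),
   `FORM2` (AYRGAGR), `FORM1_LIKE_VARIANT` (`[AS]Y.CS.R` near-misses
   such as AYRCSSR/AYRCSCR, which are reported but not accepted), or
   `NONE`. AYRCSLR carries a substitution in the CSFR core; the
   `include_AYRCSLR` toggle removes it from the accepted set, and
   turning it off can only shrink the accepted set.
3. **Monophyly**: the tree is rooted on the branch separating the three
   form II references (outgroup contract). If no single edge separates
   them, the tree is rooted on the parent edge of their most recent
   common ancestor as read from the input; when that ancestor is already
   the basal node of a rooted input, the input rooting is kept, because
   any clade query below is unchanged by re-rooting at the same spot
   (erroring out would reject trees that have a perfectly usable
   rooting). A candidate passes iff the smallest clade containing it and
   the form I reference holds no form II reference.
4. **Operon**: up to `upstream_window` (default 5) genes upstream of
   coxL in *transcription* direction — decreasing rank on the plus
   strand, increasing on the minus strand — must contain a coxM
   (COG1319) and a coxS (COG2080) with transcription order
   coxM → coxS → coxL. The window is counted in genes, not bases,
   because operon descriptions in this field count genes. Two
   genuinely open choices are exposed as toggles with conservative
   defaults: coxM/coxS must share the coxL strand
   (`require_same_strand = TRUE`, since operons are co-transcribed), and
   unrelated genes may intervene (`allow_intervening_genes = TRUE`,
   since only the order is diagnostic); the strict adjacency mode is
   available for sensitivity analyses. Among multiple valid M/S
   assignments the genes nearest coxL win, making the call
   deterministic.

## Species clustering

Genomes cluster agglomeratively on distance `100 − ANI` with average
linkage by default (single linkage available), merging while the linkage
distance stays strictly below `100 − 95`: the species boundary
"ANI above 95 %" is exclusive, so a pair at exactly 95 % ANI stays
separate. Representatives maximize
`quality = completeness − 5 × contamination`; in clusters containing
pcox genomes the best *pcox* genome wins even against a higher-quality
non-pcox member, so that downstream read mapping retains the operon.
Ties break lexicographically by genome id.

# Abundance model

Alignment records are retained iff identity
`(aligned − edits)/aligned ≥ 0.95`, aligned length ≥ 80 bp, and mapped
fraction `aligned/read ≥ 0.80`, all inclusive. Identity is defined over
the aligned region because the upstream mapper's own definition is not
part of the contract. Read quality control trims maximal terminal runs
below Phred 20 and keeps reads of ≥ 60 bp; it is idempotent and does not
attempt adapter removal (which needs adapter catalogs).

RPKM uses the sample's total QC-passed reads as denominator — read
recruitment is defined against total reads, which implies totals are the
normalizer; mapped-read normalization can be obtained by passing mapped
totals instead. For cluster *i*, `x_i` is the mean RPKM over the
single-copy marker genes present in the representative (a marker with
zero count still enters the mean; clusters with *no* marker gene are
excluded entirely rather than zero-filled), and the two relative
abundances are

$$\mathrm{whole}_i = \frac{x_i}{\sum_k x_k}, \qquad
  \mathrm{pcox}_i = \frac{\mathrm{coxMSL}_i}{\sum_k x_k},$$

with the *whole-community* marker sum in both denominators — the pcox
series is measured on the same scale as the community, not
self-normalized. Whole rows sum to one whenever any cluster has signal;
all-zero samples return `NA` rather than an arbitrary value. A species
cluster is *dominant* when its group-mean pcox abundance reaches 0.1 %
(inclusive) in at least one sample group.

# Sample clustering and stability

Samples cluster hierarchically (complete linkage by default, the base
`hclust` default) on Bray-Curtis dissimilarity for the biogeography and
on Euclidean distance inside the stability selector. For each candidate
`k` (default 5–10; the lower bound is an ecological prior of the study
design, not a statistical one), the selector draws `reps` random 70 %
subsamples, clusters each, and scores every pair of replicate partitions
by the adjusted Rand index restricted to their shared samples; the `k`
with the highest mean agreement wins, ties toward the smaller `k`. The
adjusted Rand index is implemented in-package with a tabulation formula
(the inner loop runs hundreds of thousands of comparisons) and is
cross-checked in the tests against an independent implementation.

One caveat discovered while characterizing the selector: because the
clusterer is deterministic, two subsamples of *any* fixed data set agree
more than independently shuffled labels would, even for structureless
noise. Agreement on pure noise therefore sits well above a random-label
permutation baseline, but far below the near-perfect agreement of
genuinely grouped data; the tests assert that contrast rather than a
baseline-plus-3-sigma bound.

The Mantel test (via vegan) correlates strictly-upper-triangle distance
vectors, permutes one matrix's labels jointly, and reports the one-sided
p-value `(1 + #\{r* ≥ r\})/(1 + n_perm)` for a positive relationship,
Pearson by default with Spearman available. Environmental parameters are
compared all-pairs by Spearman with two-sided t-approximation p-values,
dropping missing values per pair and returning `NA` for constant
columns.

# Co-occurrence network

All node pairs (pcox series, whole-community series, environmental
parameters) are tested by Spearman correlation — average-rank transform,
then product-moment correlation, with two-sided t p-values on `n − 2`
degrees of freedom; constant series are excluded from the testing
universe. P-values are BH-adjusted over *all tested pairs of the run* (a
single family; per-node families would change the meaning of `q` and can
be obtained by slicing the edge table before adjustment). An edge is
retained iff `|ρ| ≥ 0.85` (inclusive), `q < 0.01` (strict), one endpoint
is a pcox node of a dominant cluster, and the other endpoint is not the
whole-community node of the *corresponding* cluster. "Corresponding" is
genuinely ambiguous, so it is a switch: the default `self_cluster`
excludes only the edge's own cluster (pcox nodes may link to other
clusters' whole-community nodes, which is exactly the interesting
signal), while `any_dominant` bars every dominant cluster's
whole-community node. Negative correlations pass the `|ρ|` gate by
definition. Modules are the connected components of the retained graph,
isolated nodes excluded.

# Pangenome contrast

Within a species cluster containing both pcox and coxL-lacking genomes,
the exclusive COGs are the union over pcox genomes minus the union over
lacking genomes, computed on profiles that exclude the operon's own
genes. Absence is strict — one occurrence in a lacking genome
disqualifies a COG — which is conservative under annotation dropouts in
incomplete MAGs. Presence is binary per genome since the contrast counts
genomes, not genes. Clusters without a lacking contingent are skipped
for exclusivity but still contribute genome counts to the recurrence
table, which reports COGs exclusive in at least two clusters with
per-cluster detection counts and proportions in both groups.

# qPCR arithmetic

Standard curves are ordinary least squares of Cq on log10 copies;
amplification efficiency is the standard
`(10^(−1/slope) − 1) × 100`, so the perfect-doubling slope
`−1/log10(2) ≈ −3.3219` gives 100 %. Copy densities are summarized as
mean ± *sample* (n−1) standard deviation over replicates (the usual
triplicate convention). Ratios to the bacterial 16S rRNA gene density
are plain percentages per target plus their total; volume and elution
conversion factors are assumed already applied to the replicate values.

# The synthetic-data generator

The generator emulates the statistical structure of the study inputs at
desk scale, with full determinism (identical spec and seed give
identical output) and truth labels sufficient to score every downstream
module.

* **Genomes** (default 5 clusters × 4 genomes, pcox probability 0.5):
  pcox genomes carry one coxMSL operon with a genuine motif embedded at
  a random interior position of the coxL protein; non-pcox genomes cycle
  through four decoy classes — form II coxSLM loci with the AYRGAGR
  motif, motif-only proteins without an operon, order-violating
  (coxS before coxM) arrangements, and wrong-strand coxM/coxS. ANI is
  generated directly as a block matrix (within clusters 96–99.5 %,
  between 80–90 %); the pipeline consumes ANI as input by design, so no
  sequence-level ANI is simulated.
* **Communities** (default 90 samples, 6 groups): each group up-weights
  its own disjoint block of taxa so that the between-centroid Euclidean
  distance equals `separation` (default 5) times the expected
  within-group pair distance — the separation factor *is* the
  between/within distance ratio by construction. pcox series follow
  their taxon through a log-normal link; environmental covariates couple
  to the group structure. Planted node pairs are driven to a target
  sample Spearman correlation (within ±0.03) by blending ranks and
  re-mapping onto the original marginal, so planted correlations change
  no node's value distribution.
* **Counts**: every taxon carries 14 markers and one operon of
  marker-like length; counts are Poisson with rate
  depth × length-kb × library-millions, and depths are chosen high
  enough (coverage rates 2 000–20 000) that the operon-based abundance
  tracks the marker-based one to within a few percent — the property the
  tests assert.
* **Alignment records and reads**: a planted fraction fails exactly one
  retention filter; reads carry planted low-quality terminal runs.
* **qPCR**: Cq values follow the line implied by the true efficiency
  (default 85 %, a typical mid-range value) with Gaussian cycle noise.

What the generator does **not** emulate: realistic read error profiles,
sequence-level evolution, phylogenetic signal beyond a clean
form I/form II split, compositional correlations between taxa beyond the
planted group structure, or annotation dropout. Passing tests therefore
demonstrate correctness of the arithmetic and the decision rules under
controlled conditions, not robustness to the messiness of real survey
data. Two consequences are worth stating: co-occurrence false-positive
checks use the flat (single-group) configuration, because group-
structured communities genuinely co-vary and any |ρ| ≥ 0.85 edge there
is real, not spurious; and exact screening recovery says nothing about
operons split across contig boundaries, which the screen will miss by
construction.

# Numerical choices and problem sizes

Boundary semantics are fixed throughout: E-value and |ρ| thresholds,
filter identity/length/fraction, and the dominance cutoff are inclusive;
the ANI species boundary and the FDR cutoff are exclusive. Partition
ties in `hclust` follow the implementation's deterministic first-minimum
merge; representative and assignment ties break lexicographically. The
test suite runs the stability selector at 90 samples × 100 replicates
(and 100 seeded repetitions of it), the Mantel null calibration at 500
runs × 999 permutations on 15 samples, and oracle cross-checks at 200
seeded instances per statistic — sizes chosen so the full suite
exercises every claim in minutes on a single CPU while keeping Monte
Carlo error well below the asserted margins.
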