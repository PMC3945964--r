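---
title: "Assessing DNA barcoding markers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing DNA barcoding markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

## The problem

A DNA barcode is useful for species identification only when sequences
from the same species are systematically closer to each other than to
sequences from other species, and when a decision rule can exploit that
separation reliably. `barcodeval` quantifies both halves of this claim
for any candidate marker: the *barcoding gap* (how intra-specific
variation compares to inter-specific divergence) and the *identification
success rate* of four decision rules against a curated reference
library. It was designed with tick barcoding in mind — where COI, 16S
rDNA, ITS2 and 12S rDNA all have advocates, reference databases carry
many unverified sequences, and some congeneric species pairs are nearly
indistinguishable — but nothing in the machinery is taxon-specific.

## Distance model

All stages consume Kimura two-parameter (K2P) distances,

$$d = -\tfrac{1}{2}\ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right],$$

with $P$ and $Q$ the transition and transversion difference proportions
among comparable sites. Design choices:

* **Pairwise deletion.** Columns where either sequence carries a gap or
  an IUPAC ambiguity code are dropped per pair, not per alignment.
  Complete deletion would discard most columns of a length-variable
  marker such as ITS2; pairwise deletion keeps the maximal information
  per pair at the cost of unequal site counts, which the distance matrix
  records per pair.
* **Undefined distances are data.** When $1-2P-Q \le 0$ or $1-2Q \le 0$
  the log is undefined (saturation) — common for deep ITS2 comparisons.
  These pairs carry an explicit flag: divergence summaries skip them
  with a logged count, the threshold scan excludes them from both error
  counts, identification treats them as infinitely far, and
  neighbour-joining imputes them with the matrix maximum. Nothing
  crashes and nothing is silently zeroed.
* **No rate correction.** Plain K2P, no gamma heterogeneity; the six
  divergence parameters are defined on this scale and comparability
  across markers matters more than fit.

## The six divergence parameters

Inter-specific, per genus with at least two species, reported as mean ±
sd over genera:

1. *average inter-specific distance* — mean over congeneric species
   pairs of the species-pair mean distance (each species pair weighs
   equally regardless of how many sequences it has);
2. *theta prime* — mean over all heterospecific congeneric sequence
   pairs (sampling-weighted);
3. *minimum inter-specific distance* — smallest heterospecific
   congeneric distance.

Intra-specific, per species with at least two records:

4. *average intra-specific distance* — pooled mean over all conspecific
   pairs (primary view; the per-species average is also emitted since
   the two conventions differ under unequal sampling);
5. *theta* — mean conspecific distance per species, averaged over
   species, which removes unequal-sampling bias;
6. *coalescent depth* — maximum conspecific distance per species.

The ± values are standard deviations across grouping units, not standard
errors: with a handful of genera the two differ by a factor of two and
sd is the convention these parameters are reported with.

Two views of the "minimum inter-specific distance" exist: per genus (the
tabulated parameter) and per species (each species' distance to its
nearest heterospecific congener). The gap histograms default to the
per-species view, which is what barcoding-gap plots show; both are
available.

## Species-boundary optimization

For a threshold $t$: a conspecific pair with $d > t$ is a **false
positive** (the pair would be split), a heterospecific pair with
$d \le t$ a **false negative** (lumped). `error_curves()` counts both
over a grid from 0 to 0.15 with step $10^{-4}$ — fine enough to resolve
boundaries quoted to two decimals of a percent — and
`optimal_threshold()` takes the minimizer of their sum, breaking ties
toward the smallest threshold and recording the whole tie set. Counting
is over *sequence pairs*: a distance matrix knows nothing about
specimens, and pair counting is the only definition computable from it.
The boundary pair ($d$ exactly at $t$) lumps by default
(`merge_at_threshold = TRUE`); the strict variant is a switch because
the convention is genuinely ambiguous and only affects zero-measure
ties.

Both curves are monotone by construction (FP non-increasing, FN
non-decreasing in $t$), which the test suite asserts across whole grids.

## Identification decision rules

All four rules exclude the query from the reference when it identifies
itself — without self-match removal every success rate is trivially
near 100%.

* **Nearest neighbour (NN).** Assign the species of the
  minimum-distance reference; ties across two or more species yield an
  uncertain call. Ties are detected after rounding distances to 10
  decimal places so that floating-point noise cannot hide the exact ties
  produced by duplicated sequences.
* **Best hit.** Smith–Waterman local alignment with affine gaps against
  each reference (match +2, mismatch −3, gap open 5, gap extend 2 — the
  classic nucleotide scheme), hits kept at ≥ 80% identity and E ≤ 10⁻⁶,
  ranked by bit score $(\lambda S - \ln K)/\ln 2$ with $\lambda = 0.625$,
  $K = 0.41$ and search space $m \times n$ per pair. A shared top bit
  score across species is uncertain; no qualifying hit is a no-hit. The
  alignment engine is `Biostrings::pairwiseAlignment()`; the test suite
  checks its scores against an independent quadratic Gotoh dynamic
  program.
* **Liberal tree-based.** On a neighbour-joining tree of references plus
  queries, look at the query's attachment node: each adjacent subtree
  whose reference leaves are all one species nominates that species. A
  unique nominee is assigned — this reproduces the textbook patterns
  ((X,X),Q) (query sister to a monospecific clade) and ((X,Q),X) (query
  nested within one) — while several distinct nominees, or none, give an
  uncertain call. One tree carries all queries rather than one tree per
  query: rebuilding per query changes almost nothing on data of this
  kind and a single tree keeps runs cheap and reproducible.
* **Liberal tree-based + threshold.** As above, plus a veto: if the
  query's nearest reference is at or beyond the threshold (typically the
  boundary optimized on the same data, or an externally supplied value),
  the call becomes uncertain. The veto can only remove assignments, so
  this rule's success rate is bounded by the plain tree rule's — an
  invariant the tests assert on every run.

Success is strict: an assigned species must equal the query's label
after whitespace/case normalization; synonyms are not resolved, and
uncertain and no-hit calls count as failures.

## Screening unverified references

Public databases carry unpublished sequences of uncertain reliability.
The screening rule admits an unpublished record only if, on the
midpoint-rooted NJ tree, the smallest clade containing it and at least
one *reliable* record (published or locally amplified) contains
exclusively records of its own nominal species. Records of species with
no reliable representative anywhere are rejected outright with a
dedicated reason. Reliable records never change status. The tree here
is neighbour joining, not a Bayesian posterior tree: the decision rule
is identical and NJ keeps the package self-contained and deterministic;
no posterior-support cut-offs are applied.

## Comparing markers and methods

`duncan_multiple_range()` implements Duncan's stepwise procedure:
groups sorted by mean, ranges of $p$ consecutive means tested against
the least significant range $q_{(1-\alpha)^{p-1}, p, \nu} \sqrt{MSE/n_h}$
(studentized-range quantile via `qtukey`, harmonic mean group size for
unequal $n$), with non-significant ranges not subdivided. Groups sharing
a letter are indistinguishable at level $\alpha$ (default 0.05). The
replicate unit in the pipeline is the per-genus success rate — a choice,
exposed as data, since any replicate structure (bootstrap, per-genus,
per-species) can be passed in directly.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates gap-free alignments by a star-within-star
scheme: a random root sequence spawns genus ancestors (branch length =
`inter_divergence`, giving comfortably deep between-genus separation),
each spawns species centroids, and each centroid spawns the individual
records at `intra_divergence / 2`. The centroid branch is
`(inter_divergence − intra_divergence) / 2` so that the *expected
tip-to-tip* K2P distance is exactly `intra_divergence` within species
and `inter_divergence` between congeneric species — targets are defined
at the level where they are measured. Evolution follows the K2P process
itself (transition:transversion rate ratio `kappa`, default 2, with the
exact finite-branch substitution probabilities), so the distance
estimator applied to simulated data is consistent for the branch
lengths used to generate it.

Defaults — 4 genera × 5 species × 4 records, 600 columns,
`intra_divergence = 0.015`, `inter_divergence = 0.17` — mirror the
divergence magnitudes typical of tick barcoding markers (intra-specific
means around 1–2%, congeneric inter-specific means around 14–18%).
Scenario switches reproduce the pathologies that make real libraries
hard:

* `overlap_pairs` forces species-pair centroids to 0.005 separation,
  the "two species closer than typical conspecifics" situation;
* `deep_split_species` gives a species a second centroid at 4×
  `intra_divergence`, the deeply structured species whose conspecific
  distances exceed some inter-specific ones;
* `mislabel_fraction` emits records as "unpublished" under a wrong
  congeneric species label, with the truth table retaining the real
  species.

The simulator does **not** model indels (alignments are gap-free),
rate heterogeneity across sites, base-composition bias, or realistic
coalescent genealogies — the statistics under test need only the
divergence structure. Consequently, passing tests demonstrate that the
*algorithms* behave correctly under controlled divergence, not that any
particular real marker has a gap: on real data, alignment quality,
saturation and taxonomic error enter in ways the simulation deliberately
excludes.

## Dataset handling

Input is an aligned FASTA plus a TSV of metadata (id, species, optional
genus/status/stage; unknown columns ignored). Length filters operate on
*ungapped* lengths (gaps are alignment artifacts, not sequence): COI
≥ 450, 16S ≥ 350, 12S ≥ 240 bases, ITS2 ≥ 70% of the marker's full
length, where "full length" defaults to the longest ungapped record in
the dataset — the quantity is not otherwise defined for a
length-variable spacer — and can be supplied explicitly (and per
dataset, since a global constant is the only defensible reading when
species-level full lengths are unknown). Trimming removes leading and
trailing columns not covered by every record and refuses to proceed if
fewer than 50 columns survive, a guard against accidentally disjoint
fragment sets.

The three evaluation sets follow the standard design: set 1 is the full
screened library (published + amplified + screened-in), set 2 the
records of species with at least two set-1 accessions (the query set),
set 3 drops subadult-derived amplified records and all screened-in
unverified records (the robustness control).

## Numerical and reproducibility choices

* NJ trees may produce negative branch lengths; they are clamped to
  zero with the deficit moved to the sibling branch (and floored at
  zero), preserving local path lengths deterministically.
* Tie handling is explicit everywhere: NN ties after 10-decimal
  rounding, bit-score ties at $10^{-9}$, threshold ties recorded with
  the smallest-threshold convention.
* Every simulation is a pure function of its configuration, including
  the seed; `run_pipeline()` writes no timestamps, so identical
  configurations give byte-identical output trees — asserted in the
  test suite by re-running a pipeline twice and comparing files as raw
  bytes.
* The test suite exercises the statistics on 20–80-record simulated
  libraries (4 × 5 × 4 and smaller designs at 250–600 columns), sizes
  at which every oracle — exhaustive pair enumeration, quadratic
  alignment DP, 20-seed screening replicates — runs in seconds while
  Monte-Carlo standard errors remain small enough for 3-SE recovery
  checks to be meaningful.

## Known limitations

* Species labels are compared as normalized strings; synonymy and
  taxonomic revisions are out of scope.
* The internal best-hit scorer uses fixed Karlin–Altschul parameters
  rather than estimating them from the scoring scheme; rankings are
  unaffected (bit score is monotone in raw score) but absolute E-values
  differ from what a full BLAST implementation reports.
* Screening on an NJ tree inherits NJ's sensitivity to saturation and
  unequal rates; with very noisy markers a model-based tree may place
  borderline unverified sequences differently.
* The threshold scan treats all heterospecific pairs alike; it does not
  weight by taxonomic distance or restrict to congeners (congeneric
  restriction would only relabel the FN curve, since cross-genus pairs
  virtually never fall below candidate thresholds on realistic data).
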