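---
title: "Methods: post-processing metaproteomic protein-group tables with acetoprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-processing metaproteomic protein-group tables with acetoprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetoprot)
```

## The problem

Submerged vinegar fermentation is driven by a community of acetic acid
bacteria (Acetobacteraceae) whose members are hard to isolate and
culture. Label-free LC-MS/MS lets one identify and quantify thousands of
community proteins directly from the vinegar, but the search-engine
export (a protein-group table with per-sample abundances) still needs a
chain of statistical post-processing before any biological statement can
be made: quality filtering, presence filtering across biological
replicates, normalization for per-sample loading, taxonomic and
functional profiling, and differential-quantification analysis across
the sampling times of the acetification cycle (end of fast loading FL,
end of discontinuous loading DL, end of loading EL, just before
unloading UL).

`acetoprot` implements that chain as composable, deterministic R
functions, plus a synthetic-data generator with planted ground truth so
that every stage can be validated without access to raw MS data.

## The processing model

### Filtering

Identification quality. A protein group is retained when it has a
high protein-level FDR confidence (the category corresponding to
FDR < 0.01), a protein score of at least 2 and at least 3 peptides.
The score and peptide gates are applied disjunctively by default —
failing either removes the record — because they are conventionally
independent quality gates; a conjunctive mode (`combine = "and"`,
removing only records that fail both) is provided since the phrasing of
such rules in the literature is often ambiguous.

Replicate presence. A protein is kept if it is detected (present with
positive abundance) in at least 50% of the replicates of at least one
sampling time; the comparison is inclusive, so 2 of 4 passes. Blank and
zero cells are treated as "not detected" rather than as true zeros:
label-free missingness is overwhelmingly a detection phenomenon, and no
imputation is performed anywhere in the pipeline.

Pairwise exclusivity. For a pairwise comparison of two sampling
times, a protein detected in ≥ 50% of one group's replicates and in no
replicate of the other is *exclusive* to the first group; such proteins
are flagged so shared totals can omit them.

### Normalization

Each quantification value is corrected by global sample intensity:

$$q'_{ij} = \frac{q_{ij}}{S_j}\cdot\frac{1}{m}\sum_{k=1}^m S_k,
\qquad S_j = \sum_{i\,\mathrm{detected}} q_{ij}$$

After correction every column (sample) total equals the mean of the
original totals; within-sample ratios and ranks are untouched, and the
operation is idempotent. The sample total $S_j$ is computed over the
proteins present *after* filtering, matching the position of the
correction in the processing order (filter → normalize → analyze).

### Profiling

Taxonomy is parsed from the UniProt-style `OS=` organism field of the
description (genus = first token, species = the binomial; a bundled
genus → family table covers the Acetobacteraceae genera recurrent in
vinegar microbiota). Taxon frequencies are identification counts: the
number of proteins of each taxon out of the total proteins in scope,
as a percentage; proteins without a parsed organism are counted in an
`unassigned` bin so frequencies always total 100%. GO-term frequencies
count distinct annotated proteins per term against the number of
proteins annotated in that aspect; annotations are a file input
(`accession`, `go_id`, `aspect`), never a live database query. Both
profiles depend only on detection, so they are invariant under
normalization. Within a sampling time, "present" uses the same
≥ 50%-of-replicates rule as the presence filter (configurable to "any
replicate"). Species frequencies use the same global denominator as
genus frequencies, so a genus frequency is the sum of its species
frequencies.

### Clustering

The mean quantification value per sampling time (mean over detected
replicates) is computed per protein, z-score scaled and centered per row
(denominator $n-1$), and clustered with the Pearson correlation
distance $d = 1 - r$ (not $(1-r)/2$ nor $1-|r|$) under complete
linkage. The agglomeration is implemented in the package with an
explicit deterministic tie-break — among pairs at the minimal linkage
distance, merge the pair whose smallest-member index pair is
lexicographically smallest — and is cross-checked in the test suite
against both a naive cubic oracle and `stats::hclust`. Proteins need at
least 3 non-missing group means to enter clustering (a Pearson
correlation on 2 points is degenerate); constant rows are dropped and
reported. The number of clusters `k` is a required parameter — the cut
rule is a user decision, and external protein–protein-interaction-based
cluster validation is out of scope (an accession-list export per
cluster is provided for submission to such services). Heat-map matrices
are exported in dendrogram leaf order, with no silent reordering.

### Differential quantification

Per protein, a one-way ANOVA of normalized abundance on sampling time
is fitted, followed by all-pairs Tukey HSD using the studentized-range
distribution with Tukey–Kramer standard errors for unequal group sizes.
A protein is testable when at least two groups have at least two
detected replicates; untestable proteins are reported, not silently
dropped. The model is fitted to natural-log intensities by default:
label-free abundances are approximately log-normal, effects are
multiplicative, and the linear model's equal-variance normal-error
assumptions hold on the log scale (Tukey differences are then log fold
changes). `log_transform = FALSE` restores a raw-scale fit.

p-values are corrected with Storey q-values: $\hat\pi_0$ from the
smoother method (cubic smoothing spline through
$\hat\pi_0(\lambda)=\#\{p>\lambda\}/(m(1-\lambda))$ over
$\lambda = 0.05, 0.10, \ldots, 0.95$, evaluated at $\lambda = 0.95$,
clipped to $(0,1]$). With fewer than 100 tests the estimate is too
unstable, so $\pi_0$ is fixed at 1, which makes the q-values exactly
Benjamini–Hochberg adjusted p-values; `pi0_method = "fixed"` forces
that at any $m$.

Presence sets per sampling time feed an UpSet-style intersection
analysis: every protein of the union is attributed to exactly one
membership combination, so combination counts sum to the union size.

## The synthetic-data generator

`simulate_proteins()` draws protein-group tables with the structure the
pipeline assumes, under defaults chosen once as a realistic
acetification study:

* design: one profile, phases FL/DL/UL with 3 biological replicates per
  sampling time (2-phase EL/UL designs for natural raw materials are a
  parameter away);
* taxonomy: six Acetobacteraceae species with genus weights
  0.90/0.05/0.03/0.02 (Komagataeibacter, Acetobacter,
  Gluconacetobacter, Gluconobacter) and one dominant species at weight
  0.75, emulating a *K. europaeus*-dominated community;
* abundances: log-normal; per-protein baseline `meanlog` ~
  Normal(15, 2) in natural-log area units (median ≈ 3×10⁶),
  replicate noise `sdlog = 0.25` (CV ≈ 25%, typical label-free
  replicate variation);
* differential structure: a fraction (default 0.15) of proteins carry a
  multiplicative shift (default 2×) in one phase, organized in planted
  clusters assigned to phases cyclically — three one-phase-up patterns
  whose z-scored profiles have pairwise correlation ≤ 0, which is the
  forced-geometry regime for cluster-recovery checks;
* missingness: missing-not-at-random by default — detection probability
  is logistic in log-abundance with midpoint 12 and unit scale, since
  label-free missingness is intensity-driven; MCAR and no-missingness
  modes exist for calibration tests;
* identification quality: a planted fraction (default 0.1) of records
  fails exactly one identification gate (low score, low peptide count,
  or non-high confidence).

The generator emulates the *statistical* structure only: it does not
model chromatography, peptide-level quantification roll-up, shared
peptides between organisms, or correlated protein co-regulation beyond
the planted clusters. Tests passing on synthetic data therefore
validate the arithmetic and the statistical calibration of the
pipeline, not the biology of any particular fermentation.

`recovery_report()` scores pipeline output against the planted truth:
exact multinomial taxon-frequency recovery in the noise-free regime,
sensitivity and false-discovery proportion of differential calls at
q < 0.05, and the adjusted Rand index between planted and recovered
clusters.

## Numerical choices and degenerate inputs

* Detection means present **and strictly positive**; zeros from the
  reader become missing (configurable via the dialect).
* Normalization refuses a sample with no detected values (division by
  zero) and names the offending sample.
* The column-total invariant is asserted to a relative 1e-9 in tests;
  the computation itself is exact to rounding.
* z-scoring drops rows with fewer than 2 values or zero variance with a
  warning; Pearson distances are clipped into [0, 2] against rounding;
  a row pair sharing fewer than 2 columns is an error naming the pair.
* Complete-linkage ties are broken by the smallest lexicographic member
  pair; the identity cut (k = n) and the trivial cut (k = 1) are exact.
* ANOVA with zero between-group variance returns F = 0, p = 1; the
  2-group Tukey adjusted p equals the ANOVA p up to the quadrature
  accuracy of R's `ptukey` (~1e-3 relative).
* All pipeline outputs are sorted by accession (or the stated key), so
  results are invariant to input row order; nothing outside
  `simulate_proteins()` consumes randomness.

## Problem sizes used in validation

The test suite validates filtering/presence logic on 200 random tables
of up to 50 proteins × 12 samples against naive per-protein loops;
clustering on 100 random distance matrices of up to 15 observations
against a naive cubic agglomerator; null calibration and power on
simulated studies of 150–200 proteins over 20 seeds; and end-to-end
determinism on 100-protein runs. These sizes give exhaustive coverage
of the combinatorial rules while keeping the whole suite fast to run
routinely.

## Known limitations

* Protein inference, peptide-level FDR and raw-spectrum processing are
  upstream and out of scope; the pipeline starts at the protein-group
  table.
* GO frequencies are plain counts — no enrichment statistics and no
  propagation through the GO graph.
* The q-value smoother needs a few hundred tests to be informative;
  below 100 tests the package deliberately reports BH-equivalent
  values.
* With 3 replicates per sampling time, the power to detect even a
  4-standard-deviation shift at q < 0.05 is modest (closed-form
  noncentral-F power ≈ 0.6–0.7 under the default study shape); designs
  wanting high per-protein sensitivity need more replicates.
* The forced-geometry cluster-recovery guarantee applies when planted
  patterns are mutually non-positively correlated and noise is small;
  overlapping patterns have no exact-recovery guarantee.
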