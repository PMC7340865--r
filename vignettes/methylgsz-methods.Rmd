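---
title: "Models and design choices in methylGSZ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in methylGSZ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylGSZ)
```

This vignette documents the statistical models the package implements, the
tunable parameters and their defaults, what the synthetic data generator does
and does not emulate, and the design decisions taken where the methodology
left genuine freedom.

## Probe-level model

### Scales and conversion

Methylation arrives as β-values in (0, 1). Regression operates on M-values,
`M = log2(β / (1 − β))`, which are closer to homoscedastic across the
methylation range. `beta_to_m()` clamps β to `[1e-6, 1 − 1e-6]` first
(bounding M at about ±19.9): normalized pipelines can emit boundary values,
and an infinite M from a single saturated measurement would poison a probe's
regression. Values outside [0, 1] are treated as corrupt input and rejected
with the offending probe and sample named. The clamping margin is an
argument, not a constant.

### Quality filters

`filter_probes()` applies three sequential filters, each reported with its
own removal count: detection failures, sex chromosomes, blacklists
(cross-reactive and SNP-affected probes, supplied as plain id lists). The
detection rule keeps a probe only if its detection p ≤ 0.01 in at least 99%
of samples. Published filter descriptions of this step are often ambiguous
("detection p > 0.01 in 99% of samples"); read literally that would remove
almost nothing, so the standard QC reading above is implemented, with both
the p cutoff and the tolerated failing fraction configurable. Sample-level QC
(overall detection, sex-prediction concordance) is out of scope: the package
consumes matrices that have already passed sample QC, and the synthetic
generator emits clean samples.

### Regression

`fit_ewas()` fits ordinary least squares per probe, all probes sharing one
design matrix, so the whole fit is a single multi-response least-squares
solve. Model 1 adjusts for age, sex, BMI, five of the six leukocyte
proportions (`Gran` dropped by default — the six sum to one and would be
collinear with the intercept; the choice of which to drop is an argument),
chip, array position and the first two control-probe PCs. Model 2 adds
alcohol (units/week) and socioeconomic status (three occupational classes),
with listwise deletion of samples missing either; no imputation is
attempted, so the model-2 sample size visibly drops, as it does in real
questionnaire-based cohorts. Categorical covariates use indicator coding
with the first observed level as reference. A rank-deficient design is an
error that names the collinear columns; a probe with zero residual variance
gets NA statistics and a warning rather than a spurious zero p-value.

The smoking effect is reported on the M scale with smoking coded
1 = active, 0 = never, so positive effects mean higher methylation among
smokers. Published top tables do not always state their effect scale or
coding direction; this package states its own and asserts nothing about
anyone else's.

### Multiplicity and calibration

`bh_adjust()` is step-up Benjamini–Hochberg with an explicit `m_total`,
because the honest test count is the post-filter probe count even when only
a subset of p-values is in hand — that is exactly how a printed top table
relates to its genome-wide FDR column, and the bundled
`smoking_dmps_reference()` table is used in the tests to verify the
arithmetic against an independently computed published FDR column.
`genomic_lambda()` uses the exact χ²₁ null median `qchisq(0.5, 1)` rather
than a rounded constant.

## Gene scores

A gene's score is the t-statistic of its proxy CpG — the probe with maximum
|t| anywhere in the gene's annotated region — because how methylation at a
particular gene sub-region maps to expression is not settled, and committing
to promoters (say) would silently discard gene-body signal. The max-|t| rule
is deliberately inclusive; its cost is that genes with many probes get
stochastically larger null scores (a maximum over more draws). The GSZ's
competitive permutation null absorbs this at the set level as long as probe
counts are not grossly confounded with set membership. Ties on |t| break by
smaller p, then probe id, so results are reproducible to the byte. Probes
annotated to several genes count once per distinct gene; repeated
transcript-level annotations of the same gene count once.

## Gene Set Z-score

For a ranked score vector `s(1) ≥ … ≥ s(N)` and a set of size `m`, let
`X_k` be the sum of member scores among the top `k`. Under uniformly random
membership (sampling without replacement),

    E[X_k] = (m/N) · S_k
    V[X_k] = p(1−p) · [ Q_k − (S_k² − Q_k)/(N−1) ],   p = m/N

with `S_k`, `Q_k` the running sums of scores and squared scores
(`running_moments()`, O(N), verified in the tests against exhaustive
enumeration of every placement for all N ≤ 8). The profile
`Z_k = (X_k − E[X_k]) / sqrt(Ṽ_k + ε σ²)` uses a variance `Ṽ_k` smoothed
along the list by an exponentially weighted moving average (weight
`lambda_var`, default 0.5) and floored by `ε = var_floor` (default 0.01)
times the pooled score variance σ². Both devices target the head of the
list, where raw `V_k` is near zero and an unstabilized ratio would reward
trivial one-gene excursions. The statistic is the maximum of `Z_k` over all
`k` and over both ranking directions, so coherent hyper- and hypomethylation
both register; the reported direction is the profile that attained the
maximum, with ties going to the high-scoring end. For a set that is extreme
overall, both profiles necessarily deviate (one near its head, the
complement near its tail), so the direction label is attribution, not a
hypothesis test of sidedness.

Significance uses gene-label permutations — the competitive question is
whether *these* genes outscore random genes in the same experiment — with
one shared stream of B permutations reused across all sets
(`analyze_collection()`): applying a random permutation to a fixed position
set yields a uniform random subset, so sharing is statistically free and
makes the cost B permutations total. The empirical p is
`(1 + #{null ≥ obs})/(B + 1)`. Because the GSZ is a maximum, its null is
well approximated by a Gumbel law; `evd_pvalue()` fits one by maximum
likelihood (method-of-moments start) and reads the observed statistic off
the upper tail, giving usable p-values far below the `1/(B+1)` floor at
B = 100. A Gumbel rather than the three-parameter generalized
extreme-value family is a deliberate economy: one fewer parameter is
markedly more stable at B = 100, and the tests validate the choice by
calibration (type-I error at nominal 0.05 within the binomial 99% band
under fully null data) and by rank-concordance of asymptotic and empirical
p-values rather than by distributional assertion. Degenerate nulls fall
back to the empirical p with a warning. FDR over sets is computed globally,
or within each category when a set → category map is supplied (collections
such as GO subdomains are conventionally adjusted separately); both modes
are exposed because published practice varies.

Defaults: analyzed size bounds 5–1000 after intersection with the scored
universe, B = 100, seeds explicit everywhere.

## Region analysis

`region_means()` averages β per sample within each gene-region group
(TSS200, TSS1500, 5'UTR, 1stExon, Body, 3'UTR — a probe annotated to
several groups contributes once to each) and each collapsed island relation
(N/S shores pool to Shore, N/S shelves to Shelf; Island and OpenSea are
carried as their own categories alongside the shore/shelf zones for
completeness). `region_analysis()` compares smokers and never smokers per
region with the two-sided Wilcoxon rank-sum test — two-sided as the
conservative default where sidedness is not pre-registered — exact when the
pooled sample is small and untied, otherwise normal approximation with
midranks, tie-corrected variance and continuity correction. The per-region
p-values are reported unadjusted (the convention for this small,
pre-specified family), with a clearly-labelled BH column alongside. The
region test is deliberately unadjusted for covariates; it is a descriptive
complement to the regression tier, not a replacement.

## The synthetic generator

`generate_dataset()` emulates, at desk scale, a normalized 450K whole-blood
dataset: default 20,000 probes × 125 samples with 21 active and 104 never
smokers, six leukocyte proportions per sample (Dirichlet-like around typical
blood composition), uniform age 40–49, balanced chip blocks of about 12
samples, and a configurable fraction (default 16/125) of samples missing
alcohol and socioeconomic status jointly, completely at random — exercising
the model-2 listwise drop. All signal is built additively on the M scale and
mapped to β by the logistic transform, so β is strictly inside (0, 1) and a
planted shift equals the regression coefficient it should produce.

Baseline β is drawn island-relation-dependently — Island β around 0.2,
Shore around 0.45, Shelf/OpenSea around 0.7, Beta-distributed jitter —
mimicking the bimodal 450K landscape so region averages differ by
construction. Covariate responses (age slopes, sex offsets, cell-type
signatures on subsets of probes) are linear in exactly the covariates the
models adjust for, which is what makes the null-calibration tests sharp: a
well-specified model must yield uniform p-values, and does. Batch structure
is two per-chip factors with per-probe loadings; the same factors drive the
control-probe matrix so `control_probe_pcs()` can recover them. The
methylation-probe loadings are centered at zero — normalized data retain
probe-specific batch residuals but no common per-chip shift (normalization
removes precisely that) — while control probes, standing in for raw
intensities, keep a common component. Planted truth is additive: selected
CpGs get `planted_cpg_delta_m` (default 0.5 M — a strong, replicated-hit
sized effect), all CpGs of one gene set's members get `planted_set_delta_m`
(default 0.15 M — individually sub-threshold, jointly detectable, the
regime threshold-free set testing exists for), and optionally every probe
of one island-relation zone gets a region-wide shift. Residual noise is
Gaussian on the M scale, default SD 0.3.

What the generator does **not** emulate: type I/II probe chemistry, SNPs
under probes, spatial chip artefacts, correlated neighbouring CpGs,
non-Gaussian heavy-tailed residuals, or any raw-intensity phenomena (IDAT,
dye bias, background). Passing tests therefore demonstrate the statistical
machinery is correct under a well-specified model of normalized data — not
that any particular real dataset satisfies those assumptions.

## Numerical and reproducibility choices

* Every stochastic function takes or derives an explicit seed; the pipeline
  derives per-stage seeds from one master seed and restores the caller's RNG
  state, and the test suite asserts byte-identical output files across
  repeated seeded runs.
* Problem sizes in the tests (up to 20,000 probes × 125 samples, 200 sets,
  B = 100) are chosen so the entire suite runs in well under a minute while
  preserving the multiplicity structure that matters for FDR arithmetic.
* The GSZ floor `ε σ²` makes the all-equal-scores case well-defined (GSZ 0
  with a warning) instead of 0/0.
* `m_to_beta()` uses the logistic form `1/(1 + 2^(−M))`, stable for large
  |M| in both directions.
* BH with NA p-values propagates NA rather than silently re-ranking.

## Known limitations

* The gene proxy score inherits a probe-count bias (max over more probes is
  stochastically larger); the competitive null absorbs it on average, but a
  gene set systematically composed of probe-dense genes would be
  anti-conservative. A size-matched null (stratified permutation) would be
  the extension point.
* The Gumbel tail is an approximation; far beyond the permutation range
  (p ≪ 1/B) the asymptotic p-values are extrapolations and should be read
  as ordering, not literal error rates.
* The region comparison is unadjusted by design and inherits whatever
  sample-level structure normalization left behind.
* Model 2's listwise deletion assumes covariates are missing completely at
  random, which the generator makes true and real cohorts may not.
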