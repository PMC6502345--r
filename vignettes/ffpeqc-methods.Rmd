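---
title: "Models and methods behind ffpeqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ffpeqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpeqc)
```

`ffpeqc` implements the quality-control side of RNA-Seq on archival FFPE
tissue: fragment-distribution metrics, a per-sample QC data model,
cohort-level correlation and stratification analyses, expression-level
concordance metrics, a go/no-go decision policy, and a synthetic-cohort
generator that makes every one of those steps testable with known ground
truth. This vignette explains the models, the parameters that matter, and
the choices made where the design was genuinely open.

## Fragment distribution values

The central quantity is mass-weighted, not molecule-count-weighted: DV~N~
is the percentage of total fluorescence area — a proxy for nucleic-acid
mass — carried by fragments *strictly longer* than N nucleotides. This
matches the established industry definition of DV200. Two consequences are
worth stating explicitly:

* **Strict inequality.** Mass exactly at the threshold counts as below;
  a point mass at 200 nt has DV200 = 0 and DV100 = 100. Instrument vendors
  do not document their convention; strictness here is a package decision,
  pinned in one place and covered by boundary tests.
* **Monotonicity.** DV50 ≥ DV100 ≥ DV200 holds for every computed profile,
  and the QC-table validator enforces it on input data.

From a discrete `FragmentSizeDistribution` the computation is an exact
mass ratio. From an `ElectropherogramTrace` it is a pipeline:

1. **Baseline subtraction** by an approximate rolling minimum. The default
   window spans the whole trace, which removes a constant offset exactly
   and — deliberately — does not bend around broad fragment humps; shrink
   the window (`baselineWindow`, in points) when a trace shows slow drift.
2. **Lower-marker detection.** RNA chips carry a spike-in marker near
   25 nt. Within a search window (default marker ± 10 nt) the signal is
   linearly detrended — sample density can slope steeply through the
   window — and the dominant local maximum exceeding the residual median
   by `k` MADs (default `k = 5`) is taken as the marker. Ties break toward
   the smaller size. No qualifying peak means the DV computation *fails*;
   failure is a value (`status = "failed"`), not an error, and propagates
   into QC tables as missing DV — mirroring how real cohorts acquire
   uncomputable samples. No upper marker is modelled.
3. **Excision by bridging.** The marker interval (extent at 5% of peak
   height) is replaced by linear interpolation between its shoulders, so
   genuine sample signal under the marker tails is approximated rather
   than discarded.
4. **Integration.** Negative residual signal is clipped to zero and the
   trace is integrated by the trapezoid rule above each threshold, with an
   interpolated node at the threshold.

On noiseless renderings of finely sampled densities (grid ≤ 1 nt) the
trace route agrees with the exact distribution route to within half a
percentage point; the residual gap is the half-bin difference between a
discrete strict-`>` sum and a continuous integral, so it is largest for
heavily degraded material whose density is still high at the threshold.

## The QC table and its conventions

Missing values are first-class and distinct from zero: DV is missing when
the marker was not found, RIN when the instrument could not fit its model,
storage time when the archive date is unknown (the packaged table encodes
this as `"no info"`, mapped to `NA` by a per-column alias). Replicate
pairs are ordinary rows — they were prepared and sequenced independently —
and the blank expression-cluster labels stay blank. Quartiles use the
linear-interpolation convention (`quantile(type = 7)`), recorded in the
summary output because 1.5 × IQR whisker rules depend on it.

The packaged fixture `table2_seer_ffpe.tsv` is a 67-row archival
ovarian-carcinoma cohort (three repositories, storage 7–32 years). Its
printed cohort statistics — median DV200 13 (n = 53), DV100 56, DV50 98,
RIN 2.4 (n = 61), 14 DV-missing samples, 8 samples with DV200 in
[30, 50], none above 50, median library size 405 bp, median yield
23.2 ng — are reproduced exactly by `summarizeColumn()`/`countWhere()`
(yield to the printed rounding).

## Correlations and cohort strata

`pearsonPairwise()` defaults to pairwise-complete deletion (each cell uses
every record complete on *its* two metrics, maximising n and recording it
per cell); listwise deletion is one switch away, because the two schemes
genuinely differ on tables with structured missingness and the original
study did not state which it used. Cells with fewer than 3 complete pairs
or a constant metric are `NA` with a recorded reason. Raw values are the
default scale; `log10Metrics` is available for yield-type columns that
span orders of magnitude.

Two caveats are built into the design rather than papered over:

* The published coefficients for this cohort (storage–DV200 ≈ −0.44,
  storage–DV100 ≈ −0.39, contamination–library-size ≈ 0.77) were computed
  on a richer per-sample matrix (read-mapping rates, sequencing yields,
  qPCR molarity) than the printed table, with an unstated inclusion rule.
  Recomputing from the printed table gives −0.28 / −0.24 / 0.59
  (pairwise; listwise is similar), and no defensible inclusion rule we
  tested recovers the printed values. The package reports both deletion
  schemes and does not force agreement; the corresponding acceptance
  check is intentionally allowed to stay red against the published band.
* The published storage-cohort means (DV200 20/14/8, DV100 53/46/34,
  yield 500/87/41 ng across the 7–12 / 13–22 / 23–32 year strata) are
  likewise not exactly recovered by direct re-averaging.
  `compareCohorts()` therefore always prints recomputed and published
  values side by side.

Storage time itself is `ceiling(elapsed years)` with a one-year floor — a
block is never stored zero years; the floor is a convention consistent
with the fixture containing no value below 7.

## Expression metrics

The noise rule — a gene fails in a sample when TPM < 1 **or** raw count
< 5 — is applied gene-wise by default (a gene is dropped only when it
fails everywhere) with a per-sample masking mode available. Genes
detected uses *strictly more than* 5 reads; the signature-gene cutoff
*at least* 5 reads. The two constants are deliberately separate
configuration values because the two rules arise in different contexts
and only one of them is strict.

All correlation, clustering and PCA default to log2(TPM + 1): raw TPM
spans four orders of magnitude and a handful of highly expressed genes
would otherwise dominate every Pearson coefficient. Raw-TPM modes remain
switchable because the original analyses did not document their scale.

Signature concordance subsets to signature genes with ≥ 5 reads somewhere,
correlates each sample with a reference profile, and clusters samples by
average linkage on 1 − Pearson distance, cutting at k = 3 (configurable).
Classes are labelled from "B" downward by decreasing median concordance —
the analogue of concordant / low-medium / near-empty quality tiers.
Samples whose signature counts are all below the cutoff carry no signal
to cluster and are excluded with a reason. Linkage and distance are
package decisions (the source names neither); average linkage on
correlation distance is the common choice for expression heatmaps.

Gene-body bias reduces a 100-bin 5′→3′ coverage profile to two ratios:
mean of bins 1–20 (5′) and 81–100 (3′), each over the mean of the middle
bins 41–60, flagged above 1.5. The windows and the 1.5 ratio are package
inventions — the source shows curves without a numeric score — and both
are configurable; the statistics are scale-invariant by construction.
GC anomaly flags work on a 100-bin GC histogram: fractions at ≤ 10% and
≥ 80% GC, flagged above 5% of reads, plus a check that the bulk sits in
the 40–60% band normal for human samples.

## The decision policy

The policy encodes the screening rules as pinned, auditable inequalities:

| rule | default | boundary |
|---|---|---|
| proceed | DV100 > 40 | 40 itself fails |
| higher input | DV100 < 60 | 60 itself proceeds normally |
| DV200 bands | 30 / 50 / 70 | 30 and 50 lower-inclusive, 70 exclusive |
| contamination | low > 1%, high > 5% | both strict |
| replicate pass | r ≥ 0.7 | inclusive |

Missing DV100 yields `indeterminate`, not failure — such samples have been
sequenced successfully; the policy reports rather than blocks, and all
other flags are still evaluated. A sample that is both highly contaminated
and below the gene-count floor collects an explicit exclusion reason.
The molarity floor (2 nM) and gene-count floor (1000) behind the side
flags are package decisions modelled on the failure pattern of near-empty
libraries, not published constants; they are parameters of
`policyThresholds()` and surfaced in every decision's reasons. Verdicts
are monotone in DV100 by construction, and the test suite checks this on
randomised records.

## The synthetic cohort generator

The generator's role is parameter recovery: every configured correlation,
tier proportion and planted anomaly must be recoverable by the package's
own analysis functions. Its defaults are the study conditions of a
long-stored archival cohort: n = 67, storage 7–32 years, 14/67 samples
with uncomputable DV, 6/67 with missing RIN, 1/67 with unknown storage
time, contamination present in 56/67 samples.

**Degradation.** Each sample's fragment-size distribution is lognormal
with median `250·exp(−0.08·years) + 40` nt and spread `sdlog = 0.65`, a
broad degraded smear. DV values are *computed from this distribution* via
`dvProfile()`, never sampled directly — so DV50 ≥ DV100 ≥ DV200 holds by
construction and the generator exercises the same code path as real data.
The per-sample lognormal noise on the median is not hand-set: it is
solved by bisection (on a fixed private random stream, so results are
reproducible and independent of the user's seed) so that the realised
(storage, DV100) Pearson correlation matches the configured target
(−0.4 by default). Targets too close to |1| are rejected as infeasible
before sampling. Library yield follows the squared degradation trend with
a damped contribution of the realised size deviation plus its own
calibrated lognormal noise (target −0.2); the DV200 correlation is not
separately calibrated — one latent degradation axis drives all DV values —
and is simply reported.

**Contamination** is a two-component mixture: a clean state concentrated
below 1% and a heavy-tailed Beta(1.2, 5) state scaled to percent,
matching the observed bimodal pattern. Mapped and mRNA fractions are
logistic in DV100 minus a contamination penalty; they live in the truth
table, not the QC schema.

**Expression.** Counts are Poisson draws around tier-dependent latent TPM
(`countScale` expected counts per TPM-kilobase, a depth proxy), and the
TPM assay is recomputed from the counts and the configured gene lengths,
so the two assays are always consistent. The three signature tiers share
a baseline gene profile plus *tier-level shared deviation profiles*: a
tier's samples cohere with one another more than with other tiers. This
is a deliberate modelling choice — mutually uncorrelated near-zero
profiles carry no recoverable planted structure for average-linkage
clustering, whereas real near-empty libraries do share their sparse
residual profile. Concordant replicate pairs share a latent profile with
independent per-member noise whose scale is again solved by bisection so
that `replicateCorrelation()` — including Poisson count noise, TPM
renormalisation and the noise filter — lands on the target r = 0.75.
Discordant partners have scrambled gene structure and correlate near
zero. Gene-body 3′ ramps are planted in low-mRNA samples and GC anomalies
in near-zero-tier samples.

**What the generator does not emulate.** No read-level data, no sequence
content, no batch structure, no inter-gene correlation beyond the tier
profiles, no distributional fit to the packaged table (forms and
magnitudes are hand-set to the reported scale). Passing the recovery
tests therefore shows the pipeline is internally consistent and correctly
implemented — not that real archival cohorts follow lognormal size
distributions or logistic mapping curves.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to make sampling noise small
relative to the tolerances while keeping a laptop run comfortable:
100 random distributions for trace-equivalence (0.5 nt grids, where the
discrete-sum/integral gap stays within the 0.5 pp band), 200 cohort
replicates at n = 67 for correlation recovery (tolerance ± 0.1), 50 seeds
at 24 samples × 2000 genes for tier recovery (≥ 90% agreement), 30 seeds
for the replicate regimes. Bisection calibrations run 25–40 iterations on
4000-draw fixed streams and are memoised per configuration. Degenerate
inputs are handled as values, not crashes: empty GC profiles report zero
fractions, zero-coverage gene-body profiles and signal-free samples are
excluded with reasons, constant metrics yield `NA` correlations with a
recorded cause.

## Known limitations

* The trace pipeline assumes a size-calibrated axis; ladder-based
  time-to-size calibration is out of scope, as is RIN computation
  (proprietary).
* DV from traces inherits the instrument's resolution; below ~0.5 nt
  grids the strict-threshold convention itself is the dominant
  uncertainty.
* The published correlation and cohort-mean values for the packaged table
  are not exactly recoverable from the table alone (see above); the
  package reports recomputed values next to published ones rather than
  asserting agreement.
* The decision policy encodes screening heuristics for degraded archival
  RNA; it is not a substitute for library-level QC, and its two floors
  (molarity, gene count) are tunable conventions.
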