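#' @import methods
#' @importFrom stats approx as.dist cor cutree dist hclust mad median prcomp
#'   quantile rbeta rnorm rpois runif sd setNames complete.cases plogis
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames
#' @importFrom S4Vectors DataFrame
NULL

# Numeric columns of the per-sample QC schema; used by validation, summaries
# and correlation analyses.
.QC_NUMERIC_COLUMNS <- c(
  "input_for_libprep", "rin", "dv200", "dv100", "dv50",
  "lib_size", "lib_yield", "lib_molarity", "storage_time",
  "contamination_pct", "genes_detected"
)

.QC_COLUMNS <- c(
  "sample_id", "input_for_libprep", "rin", "dv200", "dv100", "dv50",
  "lib_size", "lib_yield", "lib_molarity", "storage_time", "resequenced",
  "contamination_pct", "cluster_label", "genes_detected"
)

#' Per-sample QC table for an FFPE RNA-Seq cohort
#'
#' Holds one row per sample with the library-preparation and sequencing QC
#' schema used throughout the package: RNA input mass, RIN, the fragment
#' distribution values DV200/DV100/DV50 (percent of RNA mass in fragments
#' longer than 200/100/50 nt), library size/yield/molarity, specimen storage
#' time in years, resequencing status, percent contamination (non-human
#' reads), expression-cluster label and genes detected. Missing values are
#' first-class (`NA`), distinct from zero: DV values are missing whenever the
#' electropherogram lower marker could not be identified, and storage time is
#' missing when the archival date is unknown. An optional `site` column
#' (repository of origin) may be carried for synthetic cohorts.
#'
#' Validity enforces: percent fields in [0, 100]; positive masses, sizes and
#' molarities; `storage_time` an integer of at least 1 year when present;
#' non-negative gene counts; unique sample identifiers; and the fragment-mass
#' ordering DV50 >= DV100 >= DV200 whenever all three are present (more of
#' the mass always exceeds a smaller size cutoff).
#'
#' @slot records A `data.frame` with the schema columns above.
#' @seealso [readQCTable()], [summarizeColumn()], [countWhere()]
#' @export
setClass("QCTable", representation(records = "data.frame"))

setValidity("QCTable", function(object) {
  msg <- validateQCRecords(object@records)
  if (length(msg) == 0L) TRUE else msg
})

#' Fragment-size distribution of an RNA sample
#'
#' A mass-weighted (fluorescence-area-equivalent) distribution of fragment
#' lengths: `sizes` are fragment lengths in nucleotides, strictly increasing,
#' and `massWeights` the total nucleic-acid mass at each size. DV metrics are
#' mass fractions of this distribution above a size threshold.
#'
#' @slot sizes Numeric, fragment lengths (nt), positive, strictly increasing.
#' @slot massWeights Numeric, non-negative mass weights aligned to `sizes`;
#'   at least one must be positive.
#' @seealso [dvValue()], [dvProfile()]
#' @export
setClass("FragmentSizeDistribution",
  representation(sizes = "numeric", massWeights = "numeric"))

setValidity("FragmentSizeDistribution", function(object) {
  s <- object@sizes; w <- object@massWeights
  if (length(s) != length(w)) return("sizes and massWeights differ in length")
  if (length(s) == 0L) return("empty distribution")
  if (any(!is.finite(s)) || any(s <= 0)) return("sizes must be positive and finite")
  if (any(diff(s) <= 0)) return("sizes must be strictly increasing")
  if (any(!is.finite(w)) || any(w < 0)) return("massWeights must be finite and non-negative")
  if (sum(w) <= 0) return("at least one mass weight must be positive")
  TRUE
})

#' Size-calibrated electropherogram trace
#'
#' A fluorescence-versus-size trace from capillary electrophoresis of RNA.
#' The size axis is already ladder-calibrated to nucleotides. The signal may
#' carry baseline drift and noise and may be locally negative. RNA chips
#' inject a lower-marker spike-in (nominally 25 nt) whose peak must be
#' detected and excised before the trace can be integrated into DV values;
#' when the marker cannot be found the DV computation fails, which is how
#' uncomputable samples arise in real cohorts.
#'
#' @slot sizeNt Numeric, calibrated positions (nt), strictly increasing,
#'   at least 16 points.
#' @slot signal Numeric fluorescence values aligned to `sizeNt`.
#' @slot lowerMarkerNt Nominal lower-marker size in nt (default 25).
#' @seealso [detectLowerMarker()], [dvProfile()], [renderTrace()]
#' @export
setClass("ElectropherogramTrace",
  representation(sizeNt = "numeric", signal = "numeric",
                 lowerMarkerNt = "numeric"))

setValidity("ElectropherogramTrace", function(object) {
  s <- object@sizeNt
  if (length(s) != length(object@signal)) return("sizeNt and signal differ in length")
  if (length(s) < 16L) return("trace needs at least 16 points")
  if (any(!is.finite(s))) return("sizeNt must be finite")
  if (any(diff(s) <= 0)) return("sizeNt must be strictly increasing")
  if (length(object@lowerMarkerNt) != 1L || object@lowerMarkerNt <= 0)
    return("lowerMarkerNt must be a single positive value")
  TRUE
})

#' DV profile: fragment-mass percentages above size thresholds
#'
#' The result of a DV computation at one or more size thresholds. When
#' `status == "computed"`, `dv[i]` is the percentage of total fragment mass
#' strictly longer than `thresholds[i]` nt, so the profile is non-increasing
#' in the threshold. When the computation fails (no lower marker, no usable
#' signal) `status == "failed"` and `reason` says why; failed profiles carry
#' `NA` values and propagate into QC tables as missing DV.
#'
#' @slot thresholds Numeric size thresholds (nt), ascending.
#' @slot dv Numeric percentages in [0, 100] aligned to thresholds (NA when
#'   failed).
#' @slot status Either `"computed"` or `"failed"`.
#' @slot reason Failure reason, `NA_character_` when computed.
#' @export
setClass("DVProfile",
  representation(thresholds = "numeric", dv = "numeric",
                 status = "character", reason = "character"))

setValidity("DVProfile", function(object) {
  if (length(object@thresholds) != length(object@dv))
    return("thresholds and dv differ in length")
  if (!object@status %in% c("computed", "failed"))
    return("status must be 'computed' or 'failed'")
  if (object@status == "computed") {
    if (any(is.na(object@dv))) return("computed profile cannot contain NA")
    if (any(object@dv < -1e-9 | object@dv > 100 + 1e-9))
      return("dv values must lie in [0, 100]")
    if (any(diff(object@dv) > 1e-9))
      return("dv must be non-increasing as the threshold increases")
  }
  TRUE
})

#' Pairwise-complete Pearson correlation matrix over QC metrics
#'
#' @slot metrics Ordered metric names.
#' @slot r Square correlation matrix; `NA` where fewer than 3 complete pairs
#'   or a constant metric made the coefficient undefined.
#' @slot nPairs Square matrix of complete-pair counts per cell.
#' @slot method `"pairwise"` or `"listwise"` deletion.
#' @slot reasons Square character matrix with a reason for each `NA` cell.
#' @seealso [pearsonPairwise()]
#' @export
setClass("QCCorrelationMatrix",
  representation(metrics = "character", r = "matrix", nPairs = "matrix",
                 method = "character", reasons = "matrix"))

setValidity("QCCorrelationMatrix", function(object) {
  k <- length(object@metrics)
  if (!all(dim(object@r) == c(k, k))) return("r dimension mismatch")
  if (!all(dim(object@nPairs) == c(k, k))) return("nPairs dimension mismatch")
  if (any(abs(object@r) > 1 + 1e-12, na.rm = TRUE)) return("|r| must be <= 1")
  if (!isTRUE(all.equal(object@r, t(object@r)))) return("r must be symmetric")
  if (!identical(object@nPairs, t(object@nPairs))) return("nPairs must be symmetric")
  TRUE
})

#' Storage-time cohort summary
#'
#' Per-bin, per-metric sample counts, means and standard deviations for
#' closed integer storage-year intervals, plus an `"unknown"` bin for samples
#' whose archival time is not recorded. Quartile-free by design: the cohort
#' display in the source study reports mean and SD per bin.
#'
#' @slot bins Named list of length-2 integer vectors (closed intervals).
#' @slot summary `data.frame` with columns bin, metric, n, mean, sd.
#' @seealso [stratifyByStorage()], [compareCohorts()]
#' @export
setClass("CohortSummary",
  representation(bins = "list", summary = "data.frame"))

#' Decision thresholds for the FFPE sequencing go/no-go policy
#'
#' Encodes the screening rules: proceed when DV100 exceeds
#' `dv100ProceedMin` (default 40), use a higher RNA input when DV100 is below
#' `dv100HighInputBelow` (default 60); the DV200 input-recommendation bands at
#' 30/50/70 percent; contamination flag edges at 1 and 5 percent; the
#' replicate-concordance pass bar (default r >= 0.7); the mRNA-content
#' quality split at 10 percent; and the library-molarity and genes-detected
#' floors used for exclusion flags. Every inequality direction is pinned and
#' documented in the corresponding rule function.
#'
#' @slot dv100ProceedMin,dv100HighInputBelow DV100 rule edges (percent).
#' @slot dv200Bands DV200 band edges (percent), ascending, length 3.
#' @slot contaminationLow,contaminationHigh Contamination flag edges (percent).
#' @slot replicatePassR Replicate-concordance pass bar (Pearson r).
#' @slot mrnaQualityPct mRNA-content quality split (percent).
#' @slot molarityFloor Low-molarity flag floor (nM).
#' @slot genesFloor Low-gene-count flag floor (count).
#' @seealso [policyThresholds()], [assessSample()], [screenCohort()]
#' @export
setClass("PolicyThresholds",
  representation(dv100ProceedMin = "numeric", dv100HighInputBelow = "numeric",
                 dv200Bands = "numeric", contaminationLow = "numeric",
                 contaminationHigh = "numeric", replicatePassR = "numeric",
                 mrnaQualityPct = "numeric", molarityFloor = "numeric",
                 genesFloor = "numeric"))

setValidity("PolicyThresholds", function(object) {
  if (object@dv100ProceedMin >= object@dv100HighInputBelow)
    return("dv100ProceedMin must be below dv100HighInputBelow")
  if (length(object@dv200Bands) != 3L || any(diff(object@dv200Bands) <= 0))
    return("dv200Bands must be three increasing edges")
  if (object@contaminationLow >= object@contaminationHigh)
    return("contaminationLow must be below contaminationHigh")
  TRUE
})

#' Per-sample QC decision
#'
#' An auditable verdict for one sample: `proceed`, `proceed_high_input`,
#' `do_not_proceed` or `indeterminate` (DV100 unmeasured), together with
#' every fired rule (name, observed value, threshold) and side flags for
#' contamination level, low library molarity and low gene count.
#'
#' @slot sampleId Sample identifier.
#' @slot verdict One of proceed, proceed_high_input, do_not_proceed,
#'   indeterminate.
#' @slot reasons `data.frame` with columns rule, observed, threshold.
#' @slot flags Named list: contamination (none/low/high), lowMolarity,
#'   lowGeneCount, excludeContaminatedLowYield.
#' @seealso [assessSample()]
#' @export
setClass("QCDecision",
  representation(sampleId = "character", verdict = "character",
                 reasons = "data.frame", flags = "list"))

setValidity("QCDecision", function(object) {
  ok <- c("proceed", "proceed_high_input", "do_not_proceed", "indeterminate")
  if (!object@verdict %in% ok) return("unknown verdict")
  TRUE
})

#' Expression matrix for an FFPE cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with two assays:
#' `counts` (non-negative integers from the quantifier) and `tpm`
#' (transcripts per million). Replicate-pair annotations live in `colData`
#' (column `replicate_of`, `NA` for unpaired samples). On an unfiltered
#' matrix each TPM column sums to 1e6 within 0.1 percent; after gene
#' filtering the sums may drop, so validity only checks shapes and
#' non-negativity.
#'
#' @seealso [FFPEExpressionSet()], [filterLowExpression()],
#'   [replicateCorrelation()], [signatureConcordance()]
#' @export
setClass("FFPEExpressionSet", contains = "SummarizedExperiment")

setValidity("FFPEExpressionSet", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "tpm") %in% an))
    return("assays 'counts' and 'tpm' are required")
  cts <- SummarizedExperiment::assay(object, "counts")
  tpm <- SummarizedExperiment::assay(object, "tpm")
  if (any(cts < 0, na.rm = TRUE)) return("counts must be non-negative")
  if (any(tpm < 0, na.rm = TRUE)) return("tpm must be non-negative")
  TRUE
})

#' Synthetic-cohort configuration
#'
#' Parameters of the study-shaped generator. Degradation is expressed
#' through the fragment-size distribution: mean fragment size declines with
#' storage years as `a * exp(-b * years) + c` (defaults 250 nt, 0.08/yr,
#' 40 nt) with per-sample lognormal noise whose spread is calibrated so the
#' realised (storage, DV100) correlation matches `targetCorDV100`. Library
#' yield decays with degradation under its own calibrated lognormal noise;
#' contamination is a two-component mixture (near-zero mass plus a
#' heavy-tailed Beta for the contaminated state); mapped and mRNA fractions
#' are logistic in DV100 minus a contamination penalty; a configured fraction
#' of samples has missing DV (marker failure) and missing RIN.
#'
#' @slot nSamples Number of samples (default 67).
#' @slot storageRange Closed integer range of storage years (default 7..32).
#' @slot degradeA,degradeB,degradeC Mean-fragment-size decline parameters.
#' @slot sdlogSize Lognormal spread of the per-sample size distribution.
#' @slot targetCorDV100,targetCorDV200,targetCorYield Target Pearson
#'   correlations of storage time with DV100, DV200 and library yield
#'   (defaults -0.4, -0.45, -0.2; DV200's is reported, not calibrated,
#'   because one latent degradation axis drives both DV values).
#' @slot probContaminated Probability of the contaminated mixture state.
#' @slot contamShape1,contamShape2 Beta parameters of the contaminated tail.
#' @slot fracMissingDV,fracMissingRIN Fractions with missing DV / RIN.
#' @slot fracUnknownStorage Fraction with unknown storage time.
#' @seealso [cohortConfig()], [simulateCohort()]
#' @export
setClass("CohortConfig",
  representation(nSamples = "numeric", storageRange = "numeric",
                 degradeA = "numeric", degradeB = "numeric",
                 degradeC = "numeric", sdlogSize = "numeric",
                 targetCorDV100 = "numeric", targetCorDV200 = "numeric",
                 targetCorYield = "numeric", probContaminated = "numeric",
                 contamShape1 = "numeric", contamShape2 = "numeric",
                 fracMissingDV = "numeric", fracMissingRIN = "numeric",
                 fracUnknownStorage = "numeric"))

setValidity("CohortConfig", function(object) {
  if (object@nSamples < 2) return("nSamples must be at least 2")
  if (length(object@storageRange) != 2L ||
      object@storageRange[1] < 1 || diff(object@storageRange) < 0)
    return("storageRange must be an increasing interval of years >= 1")
  p <- c(object@probContaminated, object@fracMissingDV,
         object@fracMissingRIN, object@fracUnknownStorage)
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  if (abs(object@targetCorDV100) > 0.95)
    return("infeasible target correlation: |r| too close to 1 for a noisy degradation model")
  TRUE
})
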