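#' Percentage of fragment mass above a size threshold
#'
#' @param x A [FragmentSizeDistribution-class].
#' @param threshold Size threshold in nt (strictly-greater-than convention:
#'   mass exactly at the threshold counts as below).
#' @param ... Passed to methods.
#' @return A percentage in [0, 100].
#' @export
setGeneric("dvValue", function(x, threshold, ...) standardGeneric("dvValue"))

#' DV profile at a set of size thresholds
#'
#' @param x A [FragmentSizeDistribution-class] or
#'   [ElectropherogramTrace-class].
#' @param thresholds Ascending positive size thresholds in nt
#'   (default `c(50, 100, 200)`, i.e. DV50/DV100/DV200).
#' @param ... Passed to methods.
#' @return A [DVProfile-class].
#' @export
setGeneric("dvProfile", function(x, thresholds = c(50, 100, 200), ...)
  standardGeneric("dvProfile"))

#' QC records accessor
#'
#' @param x A [QCTable-class].
#' @return The underlying `data.frame`, one row per sample.
#' @export
setGeneric("qcRecords", function(x) standardGeneric("qcRecords"))

#' @describeIn qcRecords Records of a QCTable.
#' @export
setMethod("qcRecords", "QCTable", function(x) x@records)

#' Number of samples
#' @param x A [QCTable-class].
#' @export
setMethod("length", "QCTable", function(x) nrow(x@records))

setMethod("show", "QCTable", function(object) {
  r <- object@records
  cat("QCTable with", nrow(r), "samples\n")
  ndv <- sum(!is.na(r$dv200))
  cat("  DV measured:", ndv, "| DV missing:", nrow(r) - ndv, "\n")
  if ("storage_time" %in% names(r))
    cat("  storage years:",
        paste(range(r$storage_time, na.rm = TRUE), collapse = "-"),
        "(", sum(is.na(r$storage_time)), "unknown )\n")
})

setMethod("show", "FragmentSizeDistribution", function(object) {
  cat("FragmentSizeDistribution:", length(object@sizes), "points,",
      "sizes", min(object@sizes), "-", max(object@sizes), "nt\n")
})

setMethod("show", "ElectropherogramTrace", function(object) {
  cat("ElectropherogramTrace:", length(object@sizeNt), "points,",
      min(object@sizeNt), "-", max(object@sizeNt), "nt,",
      "lower marker at", object@lowerMarkerNt, "nt\n")
})

setMethod("show", "DVProfile", function(object) {
  if (object@status == "failed") {
    cat("DVProfile: failed (", object@reason, ")\n", sep = "")
  } else {
    cat("DVProfile:",
        paste(sprintf("DV%g=%.2f", object@thresholds, object@dv),
              collapse = "  "), "\n")
  }
})

setMethod("show", "QCCorrelationMatrix", function(object) {
  cat("QCCorrelationMatrix (", object@method, " deletion) over ",
      length(object@metrics), " metrics\n", sep = "")
  print(round(object@r, 3))
})

setMethod("show", "CohortSummary", function(object) {
  cat("CohortSummary over bins:",
      paste(names(object@bins), collapse = ", "), "\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "QCDecision", function(object) {
  cat("QCDecision[", object@sampleId, "]: ", object@verdict, "\n", sep = "")
  if (nrow(object@reasons)) print(object@reasons, row.names = FALSE)
  cat("  contamination:", object@flags$contamination, "\n")
})

setMethod("show", "PolicyThresholds", function(object) {
  cat("PolicyThresholds: proceed when DV100 >", object@dv100ProceedMin,
      "; high input when DV100 <", object@dv100HighInputBelow, "\n")
  cat("  DV200 bands at", paste(object@dv200Bands, collapse = "/"),
      "%; contamination edges", object@contaminationLow, "/",
      object@contaminationHigh, "%\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig: n =", object@nSamples, ", storage",
      paste(object@storageRange, collapse = "-"), "years, target",
      "r(storage, DV100) =", object@targetCorDV100, "\n")
})

#' Accessors for DVProfile
#' @param x A [DVProfile-class].
#' @return `dvValues`: named numeric vector of percentages; `dvStatus`: the
#'   status string.
#' @export
setGeneric("dvValues", function(x) standardGeneric("dvValues"))

#' @describeIn dvValues DV percentages named by threshold.
#' @export
setMethod("dvValues", "DVProfile", function(x)
  setNames(x@dv, paste0("DV", x@thresholds)))

#' @rdname dvValues
#' @export
setGeneric("dvStatus", function(x) standardGeneric("dvStatus"))

#' @describeIn dvValues Computation status ("computed" or "failed").
#' @export
setMethod("dvStatus", "DVProfile", function(x) x@status)

#' Accessors for QCCorrelationMatrix
#' @param x A [QCCorrelationMatrix-class].
#' @return `corValues`: the correlation matrix; `nPairs`: the complete-pair
#'   count matrix.
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @describeIn corValues Correlation matrix.
#' @export
setMethod("corValues", "QCCorrelationMatrix", function(x) x@r)

#' @rdname corValues
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @describeIn corValues Pairwise-complete sample counts.
#' @export
setMethod("nPairs", "QCCorrelationMatrix", function(x) x@nPairs)

#' Accessors for QCDecision
#' @param x A [QCDecision-class].
#' @return `verdict`: the verdict string; `decisionReasons`: a `data.frame`
#'   of fired rules with observed values and thresholds.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @describeIn verdict Verdict of a decision.
#' @export
setMethod("verdict", "QCDecision", function(x) x@verdict)

#' @rdname verdict
#' @export
setGeneric("decisionReasons", function(x) standardGeneric("decisionReasons"))

#' @describeIn verdict Fired rules with observed values and thresholds.
#' @export
setMethod("decisionReasons", "QCDecision", function(x) x@reasons)

#' @rdname verdict
#' @export
setGeneric("decisionFlags", function(x) standardGeneric("decisionFlags"))

#' @describeIn verdict Side flags (contamination level, low molarity, low
#'   gene count, exclusion).
#' @export
setMethod("decisionFlags", "QCDecision", function(x) x@flags)

#' Cohort summary table accessor
#' @param x A [CohortSummary-class].
#' @return `data.frame` with columns bin, metric, n, mean, sd.
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))

#' @describeIn cohortTable Summary table of a CohortSummary.
#' @export
setMethod("cohortTable", "CohortSummary", function(x) x@summary)
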