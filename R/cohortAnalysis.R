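#' Pairwise-complete Pearson correlation matrix over QC metrics
#'
#' Computes Pearson correlations between numeric QC columns. Under the
#' default `"pairwise"` deletion each cell uses the records where both of
#' its two metrics are non-missing, maximising the per-cell n; `"listwise"`
#' restricts every cell to records complete on all requested metrics. Cells
#' with fewer than 3 complete pairs, or with a constant metric in the
#' pair-set, are set to `NA` with the reason and the pair count recorded.
#' Yields and molarities in archival FFPE cohorts span orders of magnitude;
#' `log10Metrics` optionally log-transforms such columns first.
#'
#' @param x A [QCTable-class] or `data.frame`.
#' @param metrics Numeric schema columns (default: all of them).
#' @param method `"pairwise"` (default) or `"listwise"` deletion.
#' @param log10Metrics Columns to log10-transform before correlating.
#' @return A [QCCorrelationMatrix-class].
#' @export
pearsonPairwise <- function(x, metrics = .QC_NUMERIC_COLUMNS,
                            method = c("pairwise", "listwise"),
                            log10Metrics = character(0)) {
  method <- match.arg(method)
  r <- if (is(x, "QCTable")) qcRecords(x) else x
  if (nrow(r) < 2L) stop("need at least 2 records")
  bad <- setdiff(metrics, .QC_NUMERIC_COLUMNS)
  if (length(bad)) stop("not numeric QC columns: ", paste(bad, collapse = ", "))
  m <- as.matrix(r[, metrics, drop = FALSE])
  for (col in intersect(log10Metrics, metrics))
    m[, col] <- log10(m[, col])
  if (method == "listwise")
    m[!complete.cases(m), ] <- NA
  k <- length(metrics)
  rr <- matrix(NA_real_, k, k, dimnames = list(metrics, metrics))
  np <- matrix(0L, k, k, dimnames = list(metrics, metrics))
  why <- matrix(NA_character_, k, k, dimnames = list(metrics, metrics))
  for (i in seq_len(k)) for (j in seq_len(i)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    n <- sum(ok)
    np[i, j] <- np[j, i] <- n
    if (n < 3L) { why[i, j] <- why[j, i] <- "fewer than 3 complete pairs"; next }
    xi <- m[ok, i]; xj <- m[ok, j]
    if (sd(xi) == 0 || sd(xj) == 0) {
      why[i, j] <- why[j, i] <- "constant"
      next
    }
    v <- if (i == j) 1 else cor(xi, xj)
    rr[i, j] <- rr[j, i] <- v
  }
  new("QCCorrelationMatrix", metrics = metrics, r = rr, nPairs = np,
      method = method, reasons = why)
}

#' Storage time in whole years
#'
#' Elapsed time from diagnosis (block creation) to RNA extraction, rounded
#' up to the next whole year, with a minimum of one year: a block is never
#' recorded as stored for zero years.
#'
#' @param diagnosisYear,extractionYear Fractional calendar years (e.g.
#'   2003.25); extraction must not precede diagnosis.
#' @return Integer years (>= 1).
#' @export
storageTime <- function(diagnosisYear, extractionYear) {
  el <- extractionYear - diagnosisYear
  if (any(el < 0)) stop("extraction precedes diagnosis")
  as.integer(pmax(1, ceiling(el)))
}

.DEFAULT_BINS <- list(`7-12` = c(7L, 12L), `13-22` = c(13L, 22L),
                      `23-32` = c(23L, 32L))

#' Stratify QC metrics by storage-time cohort
#'
#' Assigns every record to one closed integer storage-year bin (defaults
#' 7-12, 13-22 and 23-32 years, the archival strata of long-stored FFPE
#' repositories) or to the `"unknown"` bin when storage time is missing, and
#' reports n, mean and SD per bin and metric over non-missing metric values.
#' A record with a storage time outside all bins is an error naming it.
#'
#' @param x A [QCTable-class] or `data.frame`.
#' @param bins Named list of length-2 closed integer intervals.
#' @param metrics Numeric schema columns to summarise.
#' @return A [CohortSummary-class].
#' @export
stratifyByStorage <- function(x, bins = .DEFAULT_BINS,
                              metrics = c("dv200", "dv100", "lib_yield")) {
  r <- if (is(x, "QCTable")) qcRecords(x) else x
  st <- r$storage_time
  lab <- rep(NA_character_, nrow(r))
  for (b in names(bins))
    lab[!is.na(st) & st >= bins[[b]][1] & st <= bins[[b]][2]] <- b
  lab[is.na(st)] <- "unknown"
  if (anyNA(lab))
    stop("storage time outside all bins for: ",
         paste(r$sample_id[is.na(lab)], collapse = ", "))
  out <- do.call(rbind, lapply(c(names(bins), "unknown"), function(b) {
    sel <- lab == b
    do.call(rbind, lapply(metrics, function(mt) {
      v <- r[[mt]][sel]
      v <- v[!is.na(v)]
      data.frame(bin = b, metric = mt, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_)
    }))
  }))
  new("CohortSummary", bins = bins, summary = out)
}

#' Published storage-cohort means for the 67-sample SEER FFPE study
#'
#' The cohort averages printed by the source study for its three archival
#' strata: DV200 20/14/8, DV100 53/46/34 and library yield 500/87/41 ng for
#' the 7-12, 13-22 and 23-32 year bins. Direct re-averaging of the printed
#' per-sample table does not exactly reproduce these (the study's inclusion
#' rule for replicates/resequenced rows is unstated), so these values are
#' provided for side-by-side display, never asserted as recomputable.
#'
#' @return `data.frame` with columns bin, metric, published.
#' @seealso [compareCohorts()]
#' @export
cohortReference <- function() {
  data.frame(
    bin = rep(c("7-12", "13-22", "23-32"), each = 3),
    metric = rep(c("dv200", "dv100", "lib_yield"), times = 3),
    published = c(20, 53, 500, 14, 46, 87, 8, 34, 41))
}

#' Recomputed versus published cohort means, side by side
#'
#' Joins a [CohortSummary-class] recomputed from a QC table with the
#' published cohort averages, for transparent comparison without forcing
#' agreement.
#'
#' @param summary A [CohortSummary-class] (e.g. from [stratifyByStorage()]).
#' @param reference A reference table as from [cohortReference()].
#' @return `data.frame` with columns bin, metric, n, recomputed, published.
#' @export
compareCohorts <- function(summary, reference = cohortReference()) {
  s <- cohortTable(summary)
  out <- merge(s[, c("bin", "metric", "n", "mean")], reference,
               by = c("bin", "metric"), all.x = TRUE, sort = FALSE)
  names(out)[names(out) == "mean"] <- "recomputed"
  out[order(match(out$bin, c(names(summary@bins), "unknown"))), ]
}
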