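#' Validate per-sample QC records
#'
#' Checks the row-level invariants of the QC schema and returns a character
#' vector of violations, each prefixed with the offending row number(s):
#' percent fields in [0, 100], positive masses/sizes/molarities, integer
#' storage years >= 1, non-negative gene counts, unique sample identifiers,
#' and DV50 >= DV100 >= DV200 wherever all three DV values are present.
#'
#' @param records A `data.frame` with the QC schema columns.
#' @return Character vector of violation messages; empty when valid.
#' @export
validateQCRecords <- function(records) {
  msg <- character(0)
  need <- setdiff(.QC_COLUMNS, names(records))
  if (length(need))
    return(paste("missing columns:", paste(need, collapse = ", ")))
  bad <- function(rows, what) {
    if (any(rows, na.rm = TRUE))
      sprintf("rows %s: %s", paste(which(rows), collapse = ","), what)
  }
  r <- records
  add <- function(x) if (!is.null(x)) msg <<- c(msg, x)
  dup <- duplicated(r$sample_id)
  if (any(dup))
    add(sprintf("duplicate sample_id: %s",
                paste(unique(r$sample_id[dup]), collapse = ", ")))
  for (col in c("rin")) # RIN score bounded 1-10
    add(bad(!is.na(r[[col]]) & (r[[col]] < 1 | r[[col]] > 10),
            "rin outside [1, 10]"))
  for (col in c("dv200", "dv100", "dv50", "contamination_pct"))
    add(bad(!is.na(r[[col]]) & (r[[col]] < 0 | r[[col]] > 100),
            paste(col, "outside [0, 100]")))
  for (col in c("input_for_libprep", "lib_size", "lib_yield", "lib_molarity"))
    add(bad(!is.na(r[[col]]) & r[[col]] <= 0, paste(col, "must be positive")))
  add(bad(!is.na(r$storage_time) &
            (r$storage_time < 1 | r$storage_time != round(r$storage_time)),
          "storage_time must be an integer of at least 1 year"))
  add(bad(!is.na(r$genes_detected) & r$genes_detected < 0,
          "genes_detected must be non-negative"))
  allDV <- !is.na(r$dv50) & !is.na(r$dv100) & !is.na(r$dv200)
  add(bad(allDV & !(r$dv50 >= r$dv100 & r$dv100 >= r$dv200),
          "DV ordering violated (need dv50 >= dv100 >= dv200)"))
  msg
}

#' Construct a QCTable from a data.frame
#'
#' @param records `data.frame` with the QC schema columns; validated on
#'   construction, with violations reported by row number.
#' @return A [QCTable-class].
#' @export
QCTable <- function(records) {
  records <- as.data.frame(records)
  new("QCTable", records = records)
}

#' Read a per-sample QC table from delimited text
#'
#' Reads a comma- or tab-delimited QC table with a mandatory header naming
#' the schema columns. Missing values are encoded by `naTokens`
#' (default `"NA"`); in addition, per-column aliases map free-text missing
#' markers to `NA` — by default `"no info"` in `storage_time`, the notation
#' used for unknown archival dates. A non-numeric value in a numeric column
#' that is not a recognised missing token is an error naming the row and
#' column, as are unknown columns and duplicate sample identifiers. Rows
#' that violate schema invariants abort the read with their row numbers.
#'
#' The packaged fixture `table2_seer_ffpe.tsv` (67 ovarian-carcinoma FFPE
#' samples from three SEER residual tissue repositories, storage times 7 to
#' 32 years) is read with the defaults:
#' `readQCTable(system.file("extdata", "table2_seer_ffpe.tsv", package = "ffpeqc"))`.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param naTokens Tokens read as missing in any column.
#' @param aliasMap Named list: per-column extra missing tokens.
#' @return A validated [QCTable-class]; zero data rows give an empty table.
#' @export
readQCTable <- function(path, sep = NULL, naTokens = "NA",
                        aliasMap = list(storage_time = "no info")) {
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0), fileEncoding = "UTF-8")
  extra <- setdiff(names(raw), c(.QC_COLUMNS, "site"))
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  need <- setdiff(.QC_COLUMNS, names(raw))
  if (length(need))
    stop("missing column(s): ", paste(need, collapse = ", "))
  for (col in names(raw)) {
    v <- trimws(raw[[col]])
    v[v %in% naTokens | v == ""] <- NA_character_
    if (!is.null(aliasMap[[col]]))
      v[v %in% aliasMap[[col]]] <- NA_character_
    raw[[col]] <- v
  }
  for (col in intersect(.QC_NUMERIC_COLUMNS, names(raw))) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    badRow <- which(!is.na(v) & is.na(num))
    if (length(badRow))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   v[badRow[1]], col, badRow[1]))
    raw[[col]] <- num
  }
  raw$storage_time <- as.integer(raw$storage_time)
  raw$genes_detected <- as.integer(raw$genes_detected)
  raw$resequenced <- toupper(raw$resequenced) %in% c("Y", "YES", "TRUE", "1")
  dup <- duplicated(raw$sample_id)
  if (any(dup))
    stop("duplicate sample_id: ", paste(unique(raw$sample_id[dup]), collapse = ", "))
  viol <- validateQCRecords(raw)
  if (length(viol))
    stop("invalid rows:\n  ", paste(viol, collapse = "\n  "))
  QCTable(raw)
}

#' Write a QC table to delimited text
#'
#' Inverse of [readQCTable()]: missing values are written as `NA` so that a
#' round trip is the identity on every field including missingness.
#'
#' @param x A [QCTable-class].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
writeQCTable <- function(x, path, sep = "\t") {
  r <- qcRecords(x)
  r$resequenced <- ifelse(r$resequenced, "Y", "N")
  write.table(r, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Descriptive statistics for one QC metric
#'
#' Five-number summary plus mean and SD over the non-missing values of one
#' numeric column. Quartiles use the linear-interpolation convention
#' (`quantile(type = 7)`), recorded in the output, since box-and-whisker
#' displays (1.5 x IQR whiskers) depend on it; the median of an even count
#' is the midpoint of the two central values.
#'
#' @param x A [QCTable-class] or `data.frame` of QC records.
#' @param metric Name of a numeric schema column.
#' @return One-row `data.frame`: metric, n, min, q1, median, mean, q3, max,
#'   sd; attribute `quartile_type` records the convention.
#' @export
summarizeColumn <- function(x, metric) {
  r <- if (is(x, "QCTable")) qcRecords(x) else x
  if (!metric %in% .QC_NUMERIC_COLUMNS)
    stop("not a numeric QC column: ", metric)
  v <- r[[metric]]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no data for metric '", metric, "'")
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- data.frame(metric = metric, n = length(v), min = min(v),
                    q1 = q[1], median = q[2], mean = mean(v), q3 = q[3],
                    max = max(v), sd = if (length(v) > 1) sd(v) else 0)
  attr(out, "quartile_type") <- "linear interpolation (quantile type 7)"
  out
}

#' Count records satisfying an interval or missingness predicate
#'
#' Counts records whose `metric` lies in the interval [lower, upper] (bound
#' inclusiveness configurable), or, with `missing = TRUE`, records whose
#' `metric` is missing. Missing values never satisfy an interval predicate,
#' so interval counts over a partition of the line plus one is-missing count
#' always sum to the number of records.
#'
#' @param x A [QCTable-class] or `data.frame`.
#' @param metric Numeric schema column.
#' @param lower,upper Interval bounds (defaults -Inf/Inf).
#' @param includeLower,includeUpper Closed (default) or open bounds.
#' @param missing If `TRUE`, count missing values instead.
#' @return Integer count.
#' @export
countWhere <- function(x, metric, lower = -Inf, upper = Inf,
                       includeLower = TRUE, includeUpper = TRUE,
                       missing = FALSE) {
  r <- if (is(x, "QCTable")) qcRecords(x) else x
  v <- r[[metric]]
  if (is.null(v)) stop("unknown column: ", metric)
  if (missing) return(sum(is.na(v)))
  lo <- if (includeLower) v >= lower else v > lower
  hi <- if (includeUpper) v <= upper else v < upper
  sum(lo & hi, na.rm = TRUE)
}
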