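#' Construct policy thresholds
#'
#' Defaults encode the screening framework for degraded archival RNA:
#' proceed when DV100 > 40 (strictly), start with higher RNA input when
#' DV100 < 60; DV200 input-recommendation bands at 30/50/70 percent
#' (above 70: input as low as 20 ng; 50-70: 20-50 ng; 30-50: 50-100 ng;
#' below 30: do not proceed); contamination flagged low above 1 percent and
#' high above 5 percent (strict at both edges); replicate concordance
#' passes at r >= 0.7; mRNA content above 10 percent marks the
#' higher-quality stratum. The molarity floor (2 nM) and the gene-count
#' floor (1000) used for exclusion flags are package decisions modelled on
#' the failure pattern of near-empty libraries, not published constants.
#'
#' @param dv100ProceedMin,dv100HighInputBelow DV100 rule edges.
#' @param dv200Bands DV200 band edges, ascending.
#' @param contaminationLow,contaminationHigh Contamination edges (percent).
#' @param replicatePassR Replicate pass bar (inclusive).
#' @param mrnaQualityPct mRNA stratum split (percent).
#' @param molarityFloor Low-molarity flag floor (nM).
#' @param genesFloor Low-gene-count flag floor.
#' @return A [PolicyThresholds-class].
#' @export
policyThresholds <- function(dv100ProceedMin = 40, dv100HighInputBelow = 60,
                             dv200Bands = c(30, 50, 70),
                             contaminationLow = 1, contaminationHigh = 5,
                             replicatePassR = 0.7, mrnaQualityPct = 10,
                             molarityFloor = 2, genesFloor = 1000) {
  new("PolicyThresholds", dv100ProceedMin = dv100ProceedMin,
      dv100HighInputBelow = dv100HighInputBelow, dv200Bands = dv200Bands,
      contaminationLow = contaminationLow,
      contaminationHigh = contaminationHigh,
      replicatePassR = replicatePassR, mrnaQualityPct = mrnaQualityPct,
      molarityFloor = molarityFloor, genesFloor = genesFloor)
}

#' Contamination level flag
#'
#' `none` when the contaminated-read percentage is at most the low edge
#' (default 1), `low` when strictly above it up to the high edge (default
#' 5), `high` when strictly above the high edge. Both edges are strict
#' ("greater than").
#'
#' @param pct Percent of reads mapping to contaminant genomes, in [0, 100].
#' @param t A [PolicyThresholds-class].
#' @return `"none"`, `"low"` or `"high"`.
#' @export
contaminationFlag <- function(pct, t = policyThresholds()) {
  if (is.na(pct)) return(NA_character_)
  if (pct > t@contaminationHigh) "high"
  else if (pct > t@contaminationLow) "low"
  else "none"
}

#' Replicate-concordance pass rule
#'
#' A replicate pair passes when its expression correlation reaches the bar
#' (inclusive, default r >= 0.7, the regime in which biological replicates
#' of usable archival samples reproduce).
#'
#' @param r Pearson correlation in [-1, 1].
#' @param t A [PolicyThresholds-class].
#' @return `"pass"` or `"fail"`.
#' @export
replicatePass <- function(r, t = policyThresholds()) {
  if (r >= t@replicatePassR) "pass" else "fail"
}

#' RNA input recommendation from DV200
#'
#' The exome-capture kit guidance keyed on DV200: above 70 percent input as
#' low as 20 ng suffices; 50-70 (upper-inclusive) needs 20-50 ng; 30-50
#' (lower edge inclusive, matching the printed "30-50%" band label) needs
#' 50-100 ng; below 30 percent the kit vendor does not recommend
#' proceeding. A missing DV200 yields a refusal with reason "unmeasured".
#'
#' @param dv200 DV200 percentage in [0, 100], or `NA`.
#' @param t A [PolicyThresholds-class].
#' @return List: `proceed` (logical), `inputNg` (length-2 ng range or
#'   `NULL`), `band` label, `reason` when refusing.
#' @export
recommendInput <- function(dv200, t = policyThresholds()) {
  e <- t@dv200Bands
  if (is.na(dv200))
    return(list(proceed = FALSE, inputNg = NULL, band = "unmeasured",
                reason = "unmeasured"))
  if (dv200 > e[3])
    list(proceed = TRUE, inputNg = c(20, 20), band = "high",
         reason = NA_character_)
  else if (dv200 > e[2])
    list(proceed = TRUE, inputNg = c(20, 50), band = "medium",
         reason = NA_character_)
  else if (dv200 >= e[1])
    list(proceed = TRUE, inputNg = c(50, 100), band = "low",
         reason = NA_character_)
  else
    list(proceed = FALSE, inputNg = NULL, band = "below_minimum",
         reason = sprintf("DV200 below %g%%", e[1]))
}

#' Assess a single sample against the sequencing policy
#'
#' The DV100 rule drives the verdict: missing DV100 gives `indeterminate`
#' (such samples can still be sequenced, but the fragment metrics could not
#' be computed and other QC must carry the decision); DV100 at or below the
#' proceed edge (default 40, strict ">" to proceed) gives `do_not_proceed`;
#' between the edges gives `proceed_high_input`; at or above the high-input
#' edge (default 60) gives `proceed`. Regardless of verdict, contamination
#' is flagged, and a sample that is both highly contaminated and below the
#' gene-count floor collects an exclusion reason (contaminated libraries
#' that yield no mRNA should be excluded from analysis). Low library
#' molarity is also flagged. Every fired rule appears in `reasons` with the
#' observed value and the threshold, so decisions are fully auditable.
#'
#' @param record One-row `data.frame` (QC schema) or a list with the schema
#'   fields.
#' @param t A [PolicyThresholds-class].
#' @return A [QCDecision-class].
#' @export
assessSample <- function(record, t = policyThresholds()) {
  g <- function(f) {
    v <- record[[f]]
    if (is.null(v) || length(v) == 0L) NA else v[1]
  }
  reasons <- data.frame(rule = character(0), observed = numeric(0),
                        threshold = numeric(0))
  addReason <- function(rule, observed, threshold)
    reasons <<- rbind(reasons,
                      data.frame(rule = rule, observed = observed,
                                 threshold = threshold))
  dv100 <- g("dv100")
  if (is.na(dv100)) {
    v <- "indeterminate"
    addReason("dv100_unmeasured", NA_real_, t@dv100ProceedMin)
  } else if (dv100 <= t@dv100ProceedMin) {
    v <- "do_not_proceed"
    addReason("dv100_at_or_below_proceed_min", dv100, t@dv100ProceedMin)
  } else if (dv100 < t@dv100HighInputBelow) {
    v <- "proceed_high_input"
    addReason("dv100_below_high_input_edge", dv100, t@dv100HighInputBelow)
  } else {
    v <- "proceed"
    addReason("dv100_at_or_above_high_input_edge", dv100,
              t@dv100HighInputBelow)
  }
  contam <- g("contamination_pct")
  cflag <- contaminationFlag(contam, t)
  if (!is.na(cflag) && cflag != "none")
    addReason(paste0("contamination_", cflag), contam,
              if (cflag == "high") t@contaminationHigh else t@contaminationLow)
  genes <- g("genes_detected")
  lowGenes <- !is.na(genes) && genes < t@genesFloor
  if (lowGenes) addReason("low_gene_count", genes, t@genesFloor)
  exclude <- identical(cflag, "high") && lowGenes
  if (exclude)
    addReason("exclude_contaminated_low_yield", contam, t@contaminationHigh)
  mol <- g("lib_molarity")
  lowMol <- !is.na(mol) && mol < t@molarityFloor
  if (lowMol) addReason("low_library_molarity", mol, t@molarityFloor)
  sid <- g("sample_id")
  new("QCDecision",
      sampleId = if (is.na(sid)) "<unnamed>" else as.character(sid),
      verdict = v, reasons = reasons,
      flags = list(contamination = cflag, lowMolarity = lowMol,
                   lowGeneCount = lowGenes,
                   excludeContaminatedLowYield = exclude))
}

#' Screen a whole cohort
#'
#' Applies [assessSample()] to every record and tabulates verdicts and
#' flags. Verdict counts always sum to the number of records: every record
#' yields a decision, never an error.
#'
#' @param x A [QCTable-class] or `data.frame`.
#' @param t A [PolicyThresholds-class].
#' @return List: `decisions` data.frame (sample_id, verdict, contamination,
#'   lowMolarity, lowGeneCount, exclude, reasons as a `;`-joined string),
#'   `verdictCounts`, `flagCounts`.
#' @export
screenCohort <- function(x, t = policyThresholds()) {
  r <- if (is(x, "QCTable")) qcRecords(x) else x
  dec <- lapply(seq_len(nrow(r)), function(i) assessSample(r[i, ], t))
  df <- data.frame(
    sample_id = vapply(dec, function(d) d@sampleId, ""),
    verdict = vapply(dec, function(d) d@verdict, ""),
    contamination = vapply(dec, function(d)
      as.character(d@flags$contamination), ""),
    lowMolarity = vapply(dec, function(d) d@flags$lowMolarity, NA),
    lowGeneCount = vapply(dec, function(d) d@flags$lowGeneCount, NA),
    exclude = vapply(dec, function(d)
      d@flags$excludeContaminatedLowYield, NA),
    reasons = vapply(dec, function(d)
      paste(d@reasons$rule, collapse = ";"), ""))
  vc <- table(factor(df$verdict, levels = c("proceed", "proceed_high_input",
                                            "do_not_proceed",
                                            "indeterminate")))
  fc <- c(contamination_low = sum(df$contamination == "low", na.rm = TRUE),
          contamination_high = sum(df$contamination == "high", na.rm = TRUE),
          low_molarity = sum(df$lowMolarity),
          low_gene_count = sum(df$lowGeneCount),
          exclude = sum(df$exclude))
  list(decisions = df, verdictCounts = vc, flagCounts = fc)
}
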