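#' Construct an expression set with counts and TPM assays
#'
#' @param counts Genes x samples matrix of non-negative raw counts.
#' @param tpm Genes x samples matrix of TPM values, same dimnames.
#' @param replicateOf Optional named character vector mapping a sample id to
#'   the id of its biological-replicate partner (stored in `colData`).
#' @return An [FFPEExpressionSet-class].
#' @export
FFPEExpressionSet <- function(counts, tpm, replicateOf = NULL) {
  counts <- as.matrix(counts); tpm <- as.matrix(tpm)
  if (!identical(dim(counts), dim(tpm)))
    stop("counts and tpm must have identical dimensions")
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  cd$replicate_of <- NA_character_
  if (!is.null(replicateOf))
    cd[names(replicateOf), "replicate_of"] <- unname(replicateOf)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm), colData = cd)
  new("FFPEExpressionSet", se)
}

#' TPM from raw counts and gene lengths
#'
#' Standard within-sample normalisation: counts are divided by gene length
#' in kilobases, then each column is scaled to sum to one million.
#'
#' @param counts Genes x samples count matrix.
#' @param lengths Gene lengths in bases, length `nrow(counts)`.
#' @return TPM matrix.
#' @export
computeTPM <- function(counts, lengths) {
  rate <- counts / (lengths / 1000)
  sweep(rate, 2, colSums(rate) / 1e6, "/", check.margin = FALSE)
}

.passesNoise <- function(m, tpmMin, countMin) {
  SummarizedExperiment::assay(m, "tpm") >= tpmMin &
    SummarizedExperiment::assay(m, "counts") >= countMin
}

#' Filter genes below the expression-noise threshold
#'
#' A gene fails the noise threshold in a sample when its TPM is below
#' `tpmMin` (default 1) or its raw count below `countMin` (default 5). In
#' `mode = "gene"` (default) a gene is removed only when it fails in every
#' sample, i.e. kept if any sample reaches both thresholds; `mode = "mask"`
#' instead zeroes the failing entries per sample and keeps all genes. Both
#' modes are idempotent.
#'
#' @param m An [FFPEExpressionSet-class].
#' @param tpmMin,countMin Noise thresholds (kept when TPM >= tpmMin AND
#'   count >= countMin; the thresholds are "below is noise").
#' @param mode `"gene"` or `"mask"`.
#' @return A filtered [FFPEExpressionSet-class].
#' @export
filterLowExpression <- function(m, tpmMin = 1, countMin = 5,
                                mode = c("gene", "mask")) {
  mode <- match.arg(mode)
  pass <- .passesNoise(m, tpmMin, countMin)
  if (mode == "gene") return(m[rowSums(pass) > 0L, ])
  a <- SummarizedExperiment::assays(m)
  a$counts[!pass] <- 0
  a$tpm[!pass] <- 0
  SummarizedExperiment::assays(m) <- a
  m
}

#' Genes detected in a sample
#'
#' Number of genes with strictly more than `minReads` mapped reads
#' (default 5), the detection rule used for cohort-level gene counting.
#'
#' @param counts Non-negative count vector for one sample, or an
#'   [FFPEExpressionSet-class] (then a named per-sample vector is returned).
#' @param minReads Strict lower bound on the read count.
#' @return Integer count, or a named vector for a whole expression set.
#' @export
genesDetected <- function(counts, minReads = 5) {
  if (is(counts, "SummarizedExperiment"))
    return(colSums(SummarizedExperiment::assay(counts, "counts") > minReads))
  sum(counts > minReads)
}

#' Expression correlation between replicate pairs
#'
#' For each pair of biological replicates, Pearson correlation over the
#' genes that survive the noise filter in either member of the pair,
#' computed by default on log2(TPM + 1) (the raw-TPM scale is available via
#' `transform`). The transform used is recorded on the result.
#'
#' @param m An [FFPEExpressionSet-class].
#' @param pairs Two-column matrix or `data.frame` of sample-id pairs.
#' @param transform `"log2tpm"` (default) or `"tpm"`.
#' @param tpmMin,countMin Noise thresholds for the per-pair gene filter.
#' @return Numeric vector of per-pair correlations, named `id1:id2`, with
#'   attribute `transform`.
#' @export
replicateCorrelation <- function(m, pairs, transform = c("log2tpm", "tpm"),
                                 tpmMin = 1, countMin = 5) {
  transform <- match.arg(transform)
  pairs <- as.matrix(pairs)
  absent <- setdiff(unique(c(pairs)), colnames(m))
  if (length(absent))
    stop("pair member(s) absent from the matrix: ",
         paste(absent, collapse = ", "))
  pass <- .passesNoise(m, tpmMin, countMin)
  tpm <- SummarizedExperiment::assay(m, "tpm")
  out <- apply(pairs, 1L, function(p) {
    keep <- pass[, p[1]] | pass[, p[2]]
    if (sum(keep) < 3L) return(NA_real_)
    a <- tpm[keep, p[1]]; b <- tpm[keep, p[2]]
    if (transform == "log2tpm") { a <- log2(a + 1); b <- log2(b + 1) }
    cor(a, b)
  })
  names(out) <- paste(pairs[, 1], pairs[, 2], sep = ":")
  attr(out, "transform") <- transform
  out
}

#' Result of signature-gene concordance clustering
#'
#' @slot concordance Named per-sample Pearson correlation with the
#'   reference profile over the usable signature genes.
#' @slot cluster Named per-sample class labels ordered by decreasing median
#'   concordance (so "B" is the most reference-like class, mirroring
#'   B > C > D quality tiers).
#' @slot excluded Named character vector of exclusion reasons for samples
#'   with no usable signature signal.
#' @slot tree The average-linkage `hclust` tree on 1 - Pearson distance.
#' @export
setClass("ConcordanceResult",
  representation(concordance = "numeric", cluster = "character",
                 excluded = "character", tree = "ANY"))

setMethod("show", "ConcordanceResult", function(object) {
  cat("ConcordanceResult:", length(object@cluster), "samples in",
      length(unique(object@cluster)), "classes;",
      length(object@excluded), "excluded\n")
  print(table(object@cluster))
})

#' @rdname ConcordanceResult-class
#' @param x A `ConcordanceResult`.
#' @return `concordance()`: named numeric vector; `clusterLabels()`: named
#'   character vector.
#' @export
setGeneric("concordance", function(x) standardGeneric("concordance"))

#' @describeIn ConcordanceResult-class Per-sample reference concordance.
#' @export
setMethod("concordance", "ConcordanceResult", function(x) x@concordance)

#' @rdname ConcordanceResult-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @describeIn ConcordanceResult-class Quality-class labels.
#' @export
setMethod("clusterLabels", "ConcordanceResult", function(x) x@cluster)

#' Signature-gene concordance clustering into quality classes
#'
#' Subsets the matrix to the signature genes reaching at least `minReads`
#' raw counts in at least one sample, transforms to log2(TPM + 1), computes
#' each sample's Pearson correlation with a reference expression profile,
#' and hierarchically clusters the samples (average linkage on 1 - Pearson
#' distance between sample profiles) into `k` classes. Classes are labelled
#' from `"B"` downward in order of decreasing median reference concordance,
#' the analogue of concordant / intermediate / near-empty quality tiers.
#' Samples whose signature counts are all below `minReads` carry no usable
#' signal and are excluded with a reason rather than clustered.
#'
#' @param m An [FFPEExpressionSet-class].
#' @param signature Character vector of signature gene ids (>= 3 must be
#'   usable, else an error "signature not represented").
#' @param reference Named numeric reference expression vector (TPM scale)
#'   over the signature genes.
#' @param k Number of quality classes (default 3).
#' @param minReads Per-gene minimum count cutoff (default 5, inclusive).
#' @return A [ConcordanceResult-class].
#' @export
signatureConcordance <- function(m, signature, reference, k = 3,
                                 minReads = 5) {
  sig <- intersect(signature, rownames(m))
  cts <- SummarizedExperiment::assay(m, "counts")[sig, , drop = FALSE]
  usable <- sig[apply(cts, 1L, max) >= minReads]
  if (length(usable) < 3L) stop("signature not represented")
  excluded <- setNames(character(0), character(0))
  dead <- colnames(m)[apply(cts[usable, , drop = FALSE], 2L,
                            function(v) all(v < minReads))]
  if (length(dead))
    excluded <- setNames(
      rep(sprintf("all signature genes below %d reads", minReads),
          length(dead)), dead)
  keep <- setdiff(colnames(m), dead)
  if (length(keep) < k)
    stop("fewer usable samples than classes")
  lx <- log2(SummarizedExperiment::assay(m, "tpm")[usable, keep,
                                                   drop = FALSE] + 1)
  ref <- log2(reference[usable] + 1)
  conc <- apply(lx, 2L, function(v)
    if (sd(v) == 0 || sd(ref) == 0) 0 else cor(v, ref))
  C <- suppressWarnings(cor(lx))
  C[is.na(C)] <- 0                 # constant profiles: treat as uncorrelated
  d <- as.dist(1 - C)
  tree <- hclust(d, method = "average")
  grp <- cutree(tree, k = k)
  med <- tapply(conc, grp, median)
  ord <- order(med, decreasing = TRUE)
  lab <- setNames(LETTERS[1 + seq_len(k)][match(grp, ord)], names(grp))
  new("ConcordanceResult", concordance = conc, cluster = lab,
      excluded = excluded, tree = tree)
}

#' Gene-body coverage bias
#'
#' Each 100-bin coverage profile (normalised transcript position 5' to 3')
#' is scaled to unit mean; the 5' bias statistic is the mean of bins 1-20
#' divided by the mean of the middle bins 41-60, and the 3' statistic the
#' mean of bins 81-100 over the same middle. A profile is flagged when its
#' statistic exceeds `flagRatio` (default 1.5). Profiles are also averaged
#' within the mRNA-content strata above/below `mrnaSplit` percent (default
#' 10), the split at which transcript-length bias largely disappears in
#' rRNA-depleted libraries. Zero-coverage profiles are excluded with a
#' reason. Both statistics are invariant to rescaling a profile.
#'
#' @param profiles Samples x 100 matrix of coverage values (rownames =
#'   sample ids), or a list of numeric length-100 vectors.
#' @param mrnaPct Named per-sample percent of bases in mRNA.
#' @param flagRatio Bias flag threshold (default 1.5).
#' @param mrnaSplit mRNA-content stratum split in percent (default 10).
#' @return List: `perSample` data.frame (sample, bias5, bias3, flag5,
#'   flag3), `curves` list of mean unit-mean curves `high`/`low`, and
#'   `excluded` named reasons.
#' @export
geneBodyBias <- function(profiles, mrnaPct, flagRatio = 1.5,
                         mrnaSplit = 10) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  if (ncol(profiles) != 100L) stop("profiles must have 100 bins")
  tot <- rowMeans(profiles)
  excluded <- setNames(rep("zero coverage", sum(tot <= 0)),
                       rownames(profiles)[tot <= 0])
  profiles <- profiles[tot > 0, , drop = FALSE]
  norm <- profiles / rowMeans(profiles)
  mid <- rowMeans(norm[, 41:60, drop = FALSE])
  b5 <- rowMeans(norm[, 1:20, drop = FALSE]) / mid
  b3 <- rowMeans(norm[, 81:100, drop = FALSE]) / mid
  perSample <- data.frame(sample = rownames(norm), bias5 = b5, bias3 = b3,
                          flag5 = b5 > flagRatio, flag3 = b3 > flagRatio,
                          row.names = NULL)
  mp <- mrnaPct[rownames(norm)]
  curves <- list(
    high = if (any(mp > mrnaSplit, na.rm = TRUE))
      colMeans(norm[which(mp > mrnaSplit), , drop = FALSE]) else NULL,
    low = if (any(mp <= mrnaSplit, na.rm = TRUE))
      colMeans(norm[which(mp <= mrnaSplit), , drop = FALSE]) else NULL)
  list(perSample = perSample, curves = curves, excluded = excluded)
}

#' GC-profile anomaly flags
#'
#' From a 100-bin read-count histogram over GC percent, computes the
#' fraction of reads at very low (<= 10 percent) and very high (>= 80
#' percent) GC, flags either fraction above `flagFrac` (default 0.05), and
#' reports whether the bulk of the reads sits in the 40-60 percent band
#' normal for human samples. An all-zero profile yields an error-free
#' report with zero fractions and no flags.
#'
#' @param gcBins Numeric length-100 read counts over GC bins 1..100 percent.
#' @param flagFrac Flag threshold on either tail fraction.
#' @return List: fracLow, fracHigh, fracNormalBand, flagLowGC, flagHighGC,
#'   bulkNormal (fracNormalBand > 0.5).
#' @export
gcAnomalyFlags <- function(gcBins, flagFrac = 0.05) {
  if (length(gcBins) != 100L) stop("gcBins must have 100 bins")
  tot <- sum(gcBins)
  frac <- function(idx) if (tot > 0) sum(gcBins[idx]) / tot else 0
  lo <- frac(1:10); hi <- frac(80:100); midBand <- frac(40:60)
  list(fracLow = lo, fracHigh = hi, fracNormalBand = midBand,
       flagLowGC = lo > flagFrac, flagHighGC = hi > flagFrac,
       bulkNormal = midBand > 0.5)
}

#' Principal-component projection of samples
#'
#' Projects samples onto the first two principal components of the
#' log2(TPM + 1) noise-filtered matrix. Signs are made deterministic by the
#' convention that each component's largest-magnitude gene loading is
#' positive.
#'
#' @param m An [FFPEExpressionSet-class] with at least 3 samples.
#' @param tpmMin,countMin Noise-filter thresholds applied first.
#' @return Samples x 2 matrix of projections (columns PC1, PC2), with the
#'   proportion of variance explained in attribute `varExplained`.
#' @export
replicatePCA <- function(m, tpmMin = 1, countMin = 5) {
  if (ncol(m) < 3L) stop("need at least 3 samples")
  mf <- filterLowExpression(m, tpmMin, countMin)
  lx <- log2(SummarizedExperiment::assay(mf, "tpm") + 1)
  lx <- lx[apply(lx, 1L, sd) > 0, , drop = FALSE]
  pc <- prcomp(t(lx), center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  proj <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) { rot[, j] <- -rot[, j]; proj[, j] <- -proj[, j] }
  }
  colnames(proj) <- c("PC1", "PC2")
  attr(proj, "varExplained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  proj
}
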