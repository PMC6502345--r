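#' Construct a synthetic-cohort configuration
#'
#' Defaults reproduce the shape of a long-stored archival FFPE cohort:
#' 67 samples stored 7-32 years; mean fragment size declining with storage
#' as `250 * exp(-0.08 * years) + 40` nt; per-sample lognormal size spread
#' `sdlogSize = 0.65` (a broad degraded smear); target storage-time
#' correlations -0.4 (DV100) and -0.2 (library yield), achieved by
#' calibrating the degradation / yield noise; contamination as a
#' two-component mixture (clean near-zero state, heavy-tailed Beta state
#' with probability 56/67); 14/67 of samples with uncomputable DV, 6/67
#' with missing RIN and 1/67 with unknown storage time, matching the
#' observed missingness.
#'
#' @param nSamples,storageRange,degradeA,degradeB,degradeC,sdlogSize See
#'   [CohortConfig-class].
#' @param targetCorDV100,targetCorDV200,targetCorYield Target correlations.
#' @param probContaminated,contamShape1,contamShape2 Contamination mixture.
#' @param fracMissingDV,fracMissingRIN,fracUnknownStorage Missingness.
#' @return A [CohortConfig-class].
#' @export
cohortConfig <- function(nSamples = 67, storageRange = c(7, 32),
                         degradeA = 250, degradeB = 0.08, degradeC = 40,
                         sdlogSize = 0.65, targetCorDV100 = -0.4,
                         targetCorDV200 = -0.45, targetCorYield = -0.2,
                         probContaminated = 56 / 67, contamShape1 = 1.2,
                         contamShape2 = 5, fracMissingDV = 14 / 67,
                         fracMissingRIN = 6 / 67,
                         fracUnknownStorage = 1 / 67) {
  new("CohortConfig", nSamples = nSamples, storageRange = storageRange,
      degradeA = degradeA, degradeB = degradeB, degradeC = degradeC,
      sdlogSize = sdlogSize, targetCorDV100 = targetCorDV100,
      targetCorDV200 = targetCorDV200, targetCorYield = targetCorYield,
      probContaminated = probContaminated, contamShape1 = contamShape1,
      contamShape2 = contamShape2, fracMissingDV = fracMissingDV,
      fracMissingRIN = fracMissingRIN,
      fracUnknownStorage = fracUnknownStorage)
}

.meanSize <- function(config, years)
  config@degradeA * exp(-config@degradeB * years) + config@degradeC

# DV of a lognormal mass distribution with median m: closed form used only
# for noise calibration; emitted records go through dvProfile() on an
# explicit FragmentSizeDistribution.
.dvLognormal <- function(m, sdlog, threshold)
  100 * (1 - stats::plnorm(threshold, meanlog = log(m), sdlog = sdlog))

# Run fn() under a private RNG stream so calibration is deterministic and
# leaves the caller's stream untouched.
.withPrivateSeed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

# Solve for the lognormal noise sd that makes cor(storage, DV100) hit the
# configured target (bisection on fixed large calibration draws). The
# deterministic decline alone gives |r| near 1; noise attenuates it.
# Memoised per configuration.
.calibrateSizeNoise <- function(config) {
  key <- paste("size", paste(c(config@storageRange, config@degradeA,
                               config@degradeB, config@degradeC,
                               config@sdlogSize, config@targetCorDV100),
                             collapse = "|"))
  if (!is.null(.calibrationCache[[key]])) return(.calibrationCache[[key]])
  .calibrationCache[[key]] <- .calibrateSizeNoiseImpl(config)
  .calibrationCache[[key]]
}

.calibrateSizeNoiseImpl <- function(config) {
  .withPrivateSeed(20240101L, function() {
    nCal <- 4000L
    yrs <- runif(nCal, config@storageRange[1], config@storageRange[2])
    yrs <- ceiling(yrs)
    eps <- rnorm(nCal)
    corAt <- function(s) {
      m <- .meanSize(config, yrs) * exp(s * eps)
      cor(yrs, .dvLognormal(m, config@sdlogSize, 100))
    }
    target <- config@targetCorDV100
    lo <- 1e-3; hi <- 3
    if (corAt(lo) > target)   # even noiseless decline too weak
      stop("infeasible target correlation for this degradation model")
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (corAt(mid) <= target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}

# Same idea for library yield: yield declines with the realised fragment
# size (degraded samples amplify poorly), multiplicative lognormal noise
# calibrated so cor(storage, raw yield) hits its target.
# Library yield declines with the degradation trend; the realised
# per-sample size deviation contributes damped (raw-scale Pearson is
# destroyed by undamped lognormal tails), plus its own lognormal noise.
.yieldModel <- function(config, yrs, eps, sizeNoise, logNoise) {
  mDet <- .meanSize(config, yrs)
  pmax(1, 100 * (mDet / 250)^2 * exp(0.4 * sizeNoise * eps + logNoise))
}

.calibrateYieldNoise <- function(config, sizeNoise) {
  key <- paste("yield", paste(c(config@storageRange, config@degradeA,
                                config@degradeB, config@degradeC,
                                config@targetCorYield, sizeNoise),
                              collapse = "|"))
  if (!is.null(.calibrationCache[[key]])) return(.calibrationCache[[key]])
  .calibrationCache[[key]] <- .calibrateYieldNoiseImpl(config, sizeNoise)
  .calibrationCache[[key]]
}

.calibrateYieldNoiseImpl <- function(config, sizeNoise) {
  .withPrivateSeed(20240102L, function() {
    nCal <- 4000L
    yrs <- ceiling(runif(nCal, config@storageRange[1],
                         config@storageRange[2]))
    eps <- rnorm(nCal); eta <- rnorm(nCal)
    corAt <- function(s) {
      yld <- .yieldModel(config, yrs, eps, sizeNoise, s * eta)
      cor(yrs, yld)
    }
    target <- config@targetCorYield
    lo <- 1e-2; hi <- 4
    if (corAt(lo) > target)
      stop("infeasible target yield correlation")
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (corAt(mid) <= target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}

#' Simulate a study-shaped QC cohort with known ground truth
#'
#' Draws storage times, degrades each sample's fragment-size distribution
#' (lognormal with a median that declines with storage years plus
#' calibrated per-sample noise), computes DV values from the explicit
#' distribution via [dvProfile()] (so DV50 >= DV100 >= DV200 holds by
#' construction), and derives library yield, size, molarity, contamination
#' (two-component mixture), mapped/mRNA fractions (logistic in DV100 minus
#' a contamination penalty), genes detected, RIN, and replicate/missingness
#' structure. A configured fraction of samples loses its DV values
#' (emulating lower-marker failure) and RIN; one sample in 67 has unknown
#' storage time. The returned truth table keeps every latent value.
#'
#' @param config A [CohortConfig-class].
#' @param seed Integer seed; the run is fully reproducible per seed.
#' @param sizeNoise,yieldNoise Optional explicit noise scales bypassing the
#'   target-correlation calibration (0 gives the strictly monotone
#'   degradation limit).
#' @return List: `qc` (a validated [QCTable-class]) and `truth`
#'   (`data.frame` of latent values: true storage years, mean fragment
#'   size, true DV values, contamination state, mapped/mRNA percent,
#'   quality tier, missingness indicators).
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L,
                           sizeNoise = NULL, yieldNoise = NULL) {
  if (is.null(sizeNoise)) sizeNoise <- .calibrateSizeNoise(config)
  if (is.null(yieldNoise))
    yieldNoise <- .calibrateYieldNoise(config, sizeNoise)
  set.seed(seed)
  n <- as.integer(config@nSamples)
  yrs <- sample(seq(config@storageRange[1], config@storageRange[2]), n,
                replace = TRUE)
  eps <- rnorm(n)
  m <- .meanSize(config, yrs) * exp(sizeNoise * eps)
  grid <- seq(1, 2000, by = 2)
  dv <- t(vapply(m, function(mi) {
    d <- FragmentSizeDistribution(grid, stats::dlnorm(grid, log(mi),
                                                      config@sdlogSize))
    dvValues(dvProfile(d))
  }, numeric(3)))
  colnames(dv) <- c("dv50", "dv100", "dv200")
  yld <- .yieldModel(config, yrs, eps, sizeNoise, yieldNoise * rnorm(n))
  contamState <- runif(n) < config@probContaminated
  contam <- ifelse(contamState,
                   100 * rbeta(n, config@contamShape1, config@contamShape2),
                   100 * rbeta(n, 0.4, 40))
  contam <- round(pmin(contam, 99), 2)
  libSize <- round(pmin(pmax(360 + 2.2 * contam + rnorm(n, 0, 45), 250),
                        620))
  molarity <- yld / (0.008 * libSize)
  mapped <- pmin(pmax(100 * plogis((dv[, "dv100"] - 45) / 12) -
                        0.6 * contam + rnorm(n, 0, 6), 2), 95)
  mrna <- pmin(pmax(34 * plogis((dv[, "dv100"] - 50) / 15) *
                      (1 - 0.008 * contam) + rnorm(n, 0, 1.5), 0.3), 34)
  genes <- as.integer(round(pmin(pmax(
    30000 * plogis((mrna - 8) / 3) + rnorm(n, 0, 1200), 5), 31500)))
  rin <- round(pmin(pmax(rnorm(n, 2.35, 0.35), 1), 2.8), 1)
  input <- ifelse(runif(n) < 0.55, 1000, round(runif(n, 90, 1000), 1))
  tier <- ifelse(mrna > 10, "B", ifelse(mrna > 3, "C", "D"))
  missDV <- seq_len(n) %in% sample.int(n, round(config@fracMissingDV * n))
  missRIN <- seq_len(n) %in% sample.int(n, round(config@fracMissingRIN * n))
  missST <- seq_len(n) %in%
    sample.int(n, round(config@fracUnknownStorage * n))
  sid <- sprintf("SYN_%03d", seq_len(n))
  rec <- data.frame(
    sample_id = sid, input_for_libprep = input,
    rin = ifelse(missRIN, NA_real_, rin),
    dv200 = ifelse(missDV, NA_real_, round(dv[, "dv200"], 1)),
    dv100 = ifelse(missDV, NA_real_, round(dv[, "dv100"], 1)),
    dv50 = ifelse(missDV, NA_real_, round(dv[, "dv50"], 1)),
    lib_size = libSize, lib_yield = round(yld, 2),
    lib_molarity = round(molarity, 3),
    storage_time = ifelse(missST, NA_integer_, as.integer(yrs)),
    resequenced = runif(n) < 0.37,
    contamination_pct = contam, cluster_label = tier,
    genes_detected = genes,
    site = sample(paste0("site", 1:3), n, replace = TRUE))
  truth <- data.frame(
    sample_id = sid, storage_years = yrs, mean_size = m,
    dv50 = dv[, "dv50"], dv100 = dv[, "dv100"], dv200 = dv[, "dv200"],
    contaminated = contamState, mapped_pct = mapped, mrna_pct = mrna,
    tier = tier, dv_missing = missDV, rin_missing = missRIN,
    storage_unknown = missST)
  list(qc = QCTable(rec), truth = truth,
       calibration = c(sizeNoise = sizeNoise, yieldNoise = yieldNoise))
}

#' Render a fragment-size distribution as an electropherogram trace
#'
#' Discretises the distribution's mass density onto a regular size grid
#' (linear interpolation when the input is already finely sampled, Gaussian
#' kernel smoothing of coarse atoms otherwise), optionally injects the
#' lower-marker peak at 25 nt, and adds Gaussian noise and a constant
#' baseline offset. The ground-truth DV profile of the generating
#' distribution is returned alongside so trace-based DV recovery can be
#' checked against it.
#'
#' @param dist A [FragmentSizeDistribution-class].
#' @param noiseSd Additive Gaussian noise SD (signal units).
#' @param marker Inject the lower-marker peak? (`TRUE` by default; a trace
#'   without it is the designed failure mode of [dvProfile()].)
#' @param gridStep Grid step in nt (> 0, default 1).
#' @param markerNt,markerSd Marker position and width (nt).
#' @param baselineOffset Constant non-negative baseline added to the trace.
#' @return List: `trace` ([ElectropherogramTrace-class]) and `truth`
#'   ([DVProfile-class] of the generating distribution).
#' @export
renderTrace <- function(dist, noiseSd = 0, marker = TRUE, gridStep = 1,
                        markerNt = 25, markerSd = 1.5,
                        baselineOffset = 0) {
  if (gridStep <= 0) stop("grid step must be positive")
  s <- dist@sizes; w <- dist@massWeights
  grid <- seq(1, max(s) * 1.05 + 40, by = gridStep)
  fine <- length(s) >= 50 && median(diff(s)) <= 2 * gridStep
  if (fine) {
    sig <- approx(s, w, xout = grid, yleft = 0, yright = 0)$y
  } else {            # coarse atoms: smooth with a narrow Gaussian kernel
    sig <- rowSums(vapply(seq_along(s), function(i)
      w[i] * stats::dnorm(grid, s[i], 2), numeric(length(grid))))
  }
  if (marker) {
    h <- max(sig)
    if (h <= 0) h <- 1
    sig <- sig + 0.9 * h * exp(-0.5 * ((grid - markerNt) / markerSd)^2)
  }
  sig <- sig + baselineOffset
  if (noiseSd > 0) sig <- sig + rnorm(length(grid), 0, noiseSd)
  list(trace = ElectropherogramTrace(grid, sig, markerNt),
       truth = dvProfile(dist))
}

.calibrationCache <- new.env(parent = emptyenv())

# Calibrate the within-pair noise scale so that replicateCorrelation on
# simulated counts (Poisson count noise + noise filtering included) hits
# the target r. Fixed private stream; a few averaged internal replicates
# per bisection step. Memoised: the result depends only on the arguments.
.calibratePairNoise <- function(targetR, nGenes, lengths, countScale) {
  key <- paste(targetR, nGenes, countScale, round(sum(lengths)), sep = "|")
  if (!is.null(.calibrationCache[[key]])) return(.calibrationCache[[key]])
  .calibrationCache[[key]] <- .calibratePairNoiseImpl(targetR, nGenes,
                                                      lengths, countScale)
  .calibrationCache[[key]]
}

.calibratePairNoiseImpl <- function(targetR, nGenes, lengths, countScale) {
  .withPrivateSeed(20240103L, function() {
    rAt <- function(a) {
      mean(vapply(1:4, function(rep) {
        mu <- rnorm(nGenes, 3, 1.5)
        l1 <- pmax(mu + a * rnorm(nGenes), 0)
        l2 <- pmax(mu + a * rnorm(nGenes), 0)
        tpm <- cbind(2^l1 - 1, 2^l2 - 1)
        cts <- matrix(rpois(2L * nGenes,
                            tpm * lengths / 1000 * countScale),
                      ncol = 2)
        dimnames(cts) <- list(paste0("g", seq_len(nGenes)), c("a", "b"))
        tpmObs <- computeTPM(cts, lengths)
        m <- FFPEExpressionSet(cts, tpmObs)
        unname(replicateCorrelation(m, cbind("a", "b")))
      }, numeric(1)))
    }
    lo <- 0.05; hi <- 4
    for (i in 1:25) {
      mid <- (lo + hi) / 2
      if (rAt(mid) >= targetR) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}

#' Simulate an expression matrix with planted tiers, replicate pairs and
#' coverage/GC profiles
#'
#' Generates a genes x samples cohort with three planted quality tiers on a
#' signature gene subset (high / intermediate / near-zero signature
#' expression, the analogues of concordant, low-medium and near-empty
#' sample classes), negative-binomial-like counts (Poisson draws around
#' tier-dependent TPM), TPM recomputed consistently from the counts and the
#' configured gene lengths, concordant replicate pairs calibrated to a
#' target expression correlation and discordant pairs with no shared gene
#' structure, 100-bin gene-body profiles with 3' ramps planted in low-mRNA
#' samples, and 100-bin GC profiles with low/high-GC anomalies planted in
#' the near-zero tier.
#'
#' Each tier carries a shared tier-level deviation profile in addition to
#' the per-sample noise, so samples of a tier cohere with one another more
#' than with other tiers — the structure that makes the planted partition
#' recoverable by average-linkage clustering.
#'
#' @param nSamples Samples before replicate augmentation (default 24).
#' @param nGenes Total genes (default 2000).
#' @param nSignature Signature genes (default 193).
#' @param tierProbs Tier proportions, names B/C/D (default 26:13:28).
#' @param concordantPairs,discordantPairs Number of replicate pairs of each
#'   regime (defaults 4 and 3).
#' @param targetR Target concordant-pair correlation (default 0.75).
#' @param countScale Expected counts per TPM-kilobase unit (sequencing
#'   depth proxy, default 5).
#' @param seed Integer seed.
#' @return List: `expr` ([FFPEExpressionSet-class]), `signature` gene ids,
#'   `reference` named TPM reference vector, `pairs` data.frame (id1, id2,
#'   regime), `geneBody` samples x 100 matrix, `gc` samples x 100 matrix,
#'   `truth` data.frame (sample, tier, mrna_pct, bias_planted,
#'   gc_anomaly_planted).
#' @export
simulateExpression <- function(nSamples = 24, nGenes = 2000,
                               nSignature = 193,
                               tierProbs = c(B = 26, C = 13, D = 28) / 67,
                               concordantPairs = 4, discordantPairs = 3,
                               targetR = 0.75, countScale = 5, seed = 1L) {
  if (abs(sum(tierProbs) - 1) > 1e-8)
    stop("tier proportions must sum to 1")
  lengths <- .withPrivateSeed(20240104L,
                              function() runif(nGenes, 500, 3000))
  pairNoise <- if (concordantPairs > 0)
    .calibratePairNoise(targetR, nGenes, lengths, countScale) else NA_real_
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  sig <- genes[seq_len(nSignature)]
  tiers <- sample(names(tierProbs), nSamples, replace = TRUE,
                  prob = tierProbs)
  mu <- rnorm(nGenes, 3, 1.5)              # baseline log2 TPM profile
  names(mu) <- genes
  devB <- rnorm(nSignature); devC <- rnorm(nSignature)
  devD <- rnorm(nSignature)
  sampleLog <- function(tier) {
    l <- pmax(mu + 0.35 * rnorm(nGenes), 0)   # non-signature backbone
    si <- seq_len(nSignature)
    if (tier == "D")                       # near-empty library overall
      l <- l * 0.25
    l[si] <- switch(tier,
      B = pmax(mu[si] + 0.35 * devB + rnorm(nSignature, 0, 0.45), 0),
      C = pmax(0.5 * mu[si] + 1.5 * devC + rnorm(nSignature, 0, 0.5), 0),
      D = pmax(0.2 * mu[si] + 1.6 * devD + rnorm(nSignature, 0, 0.25)
               - 0.6, 0))
    l
  }
  ids <- sprintf("S%02d", seq_len(nSamples))
  logm <- vapply(tiers, sampleLog, numeric(nGenes))
  colnames(logm) <- ids
  # replicate pairs: concordant partners share the member's profile with
  # calibrated independent noise; discordant partners have scrambled gene
  # structure (independent of every other sample).
  pairRows <- list(); k <- 0L
  for (i in seq_len(concordantPairs)) {
    k <- k + 1L
    repId <- sprintf("R%02dc", i)
    base <- pmax(mu + 0.3 * rnorm(nGenes), 0)
    l1 <- pmax(base + pairNoise * rnorm(nGenes), 0)
    l2 <- pmax(base + pairNoise * rnorm(nGenes), 0)
    logm <- cbind(logm, l1, l2)
    colnames(logm)[ncol(logm) - 1:0] <- c(paste0(repId, "1"),
                                          paste0(repId, "2"))
    tiers <- c(tiers, "B", "B")
    pairRows[[k]] <- data.frame(id1 = paste0(repId, "1"),
                                id2 = paste0(repId, "2"),
                                regime = "concordant")
  }
  for (i in seq_len(discordantPairs)) {
    k <- k + 1L
    repId <- sprintf("R%02dd", i)
    l1 <- pmax(mu + 0.35 * rnorm(nGenes), 0)
    l2 <- pmax(rnorm(nGenes, 3, 1.5), 0)   # no shared gene structure
    logm <- cbind(logm, l1, l2)
    colnames(logm)[ncol(logm) - 1:0] <- c(paste0(repId, "1"),
                                          paste0(repId, "2"))
    tiers <- c(tiers, "B", "D")
    pairRows[[k]] <- data.frame(id1 = paste0(repId, "1"),
                                id2 = paste0(repId, "2"),
                                regime = "discordant")
  }
  pairs <- do.call(rbind, pairRows)
  allIds <- colnames(logm)
  tpmLatent <- 2^logm - 1
  cts <- matrix(rpois(length(tpmLatent),
                      tpmLatent * lengths / 1000 * countScale),
                nrow = nGenes, dimnames = list(genes, allIds))
  tpm <- computeTPM(cts, lengths)
  tpm[, colSums(cts) == 0] <- 0
  repOf <- setNames(pairs$id1, pairs$id2)
  expr <- FFPEExpressionSet(cts, tpm, replicateOf = repOf)
  # per-sample mRNA content tied to tier; gene-body 3' ramp planted in the
  # low-mRNA stratum, GC anomalies planted in near-zero-tier samples
  nAll <- length(allIds)
  mrna <- vapply(tiers, function(t) switch(t, B = runif(1, 12, 30),
                                           C = runif(1, 5, 15),
                                           D = runif(1, 0.5, 4)),
                 numeric(1))
  names(mrna) <- allIds
  biasPlanted <- mrna <= 10
  bins <- seq_len(100)
  gb <- t(vapply(seq_len(nAll), function(i) {
    strength <- if (biasPlanted[i]) runif(1, 1.5, 3) else runif(1, 0, 0.25)
    pmax(1 + strength * exp((bins - 100) / 15) +
           rnorm(100, 0, 0.02), 0)
  }, numeric(100)))
  rownames(gb) <- allIds
  gcAnom <- tiers == "D"
  gc <- t(vapply(seq_len(nAll), function(i) {
    base <- stats::dnorm(bins, 50, 8)
    base <- base / sum(base) * 1e6
    if (gcAnom[i]) {
      side <- sample(c("low", "high"), 1)
      extra <- 0.2 * sum(base)
      if (side == "low") base[1:8] <- base[1:8] + extra / 8
      else base[85:95] <- base[85:95] + extra / 11
    }
    base * exp(rnorm(1, 0, 0.1))
  }, numeric(100)))
  rownames(gc) <- allIds
  truth <- data.frame(sample = allIds, tier = tiers, mrna_pct = mrna,
                      bias_planted = biasPlanted,
                      gc_anomaly_planted = gcAnom, row.names = NULL)
  list(expr = expr, signature = sig,
       reference = setNames(2^mu[seq_len(nSignature)] - 1, sig),
       pairs = pairs, geneBody = gb, gc = gc, truth = truth,
       calibration = c(pairNoise = pairNoise))
}
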