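# Shared helpers: fixture access, independent oracles, random generators.

fixturePath <- function() {
  system.file("extdata", "table2_seer_ffpe.tsv", package = "ffpeqc")
}

fixtureTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- readQCTable(fixturePath())
    cache
  }
})

# Independent sort-based median: no quantile() machinery.
sortMedian <- function(v) {
  v <- sort(v[!is.na(v)])
  n <- length(v)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
}

# Independent two-pass covariance Pearson oracle on complete vectors.
twoPassPearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Trapezoid integration oracle for continuous mass densities.
trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

# Random smooth fragment-mass density on a fine grid (lognormal mixture
# with medians comfortably above the marker region). Half-nt grid so the
# discrete mass sum and continuous integrals agree tightly.
randomFineDistribution <- function() {
  grid <- seq(1, 1500, by = 0.5)
  k <- sample(1:3, 1)
  med <- runif(k, 80, 500)
  sdl <- runif(k, 0.25, 0.6)
  wt <- runif(k, 0.2, 1)
  dens <- Reduce(`+`, lapply(seq_len(k), function(i)
    wt[i] * dlnorm(grid, log(med[i]), sdl[i])))
  FragmentSizeDistribution(grid, dens)
}

# Minimal expression set built from explicit matrices.
toyExpression <- function(counts, tpm = NULL, lengths = NULL) {
  if (is.null(tpm)) {
    if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
    tpm <- computeTPM(counts, lengths)
    tpm[, colSums(counts) == 0] <- 0
  }
  FFPEExpressionSet(counts, tpm)
}
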