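test_that("noise filtering keeps a gene iff some sample clears both thresholds", {
  cts <- rbind(g1 = c(0, 3), g2 = c(5, 0), g3 = c(10, 2))
  tpm <- rbind(g1 = c(0.2, 0.8), g2 = c(1.0, 0), g3 = c(0.5, 0.9))
  colnames(cts) <- colnames(tpm) <- c("a", "b")
  m <- FFPEExpressionSet(cts, tpm)
  kept <- rownames(filterLowExpression(m))
  expect_false("g1" %in% kept)      # below both thresholds everywhere
  expect_true("g2" %in% kept)       # boundary kept: thresholds are "<"
  expect_false("g3" %in% kept)      # count ok but TPM < 1 everywhere
})

test_that("filtering matches a hand-enumerated oracle on a 10-gene toy", {
  set.seed(21)
  cts <- matrix(rpois(30, 6), nrow = 10,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  tpm <- matrix(runif(30, 0, 3), nrow = 10, dimnames = dimnames(cts))
  keepOracle <- character(0)
  for (g in rownames(cts)) {
    pass <- FALSE
    for (s in colnames(cts))
      if (tpm[g, s] >= 1 && cts[g, s] >= 5) pass <- TRUE
    if (pass) keepOracle <- c(keepOracle, g)
  }
  m <- FFPEExpressionSet(cts, tpm)
  expect_equal(rownames(filterLowExpression(m)), keepOracle)
})

test_that("filtering is idempotent in both modes", {
  se <- simulateExpression(nSamples = 6, nGenes = 300,
                           concordantPairs = 0, discordantPairs = 0,
                           seed = 3)
  f1 <- filterLowExpression(se$expr)
  expect_equal(dim(filterLowExpression(f1)), dim(f1))
  m1 <- filterLowExpression(se$expr, mode = "mask")
  m2 <- filterLowExpression(m1, mode = "mask")
  expect_equal(SummarizedExperiment::assay(m1, "counts"),
               SummarizedExperiment::assay(m2, "counts"))
})

test_that("genes detected uses a strict read-count bound", {
  expect_equal(genesDetected(c(6, 5, 0, 100)), 2)
  expect_equal(genesDetected(rep(0, 50)), 0)
  # monotone non-increasing in the bound
  set.seed(9)
  v <- rpois(200, 8)
  counts <- vapply(0:20, function(k) genesDetected(v, k), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("replicate correlation is 1 for identical columns and errors on absentees", {
  cts <- matrix(rpois(200, 20), nrow = 100,
                dimnames = list(paste0("g", 1:100), c("a", "b")))
  cts[, "b"] <- cts[, "a"]
  m <- toyExpression(cts)
  r <- replicateCorrelation(m, cbind("a", "b"))
  expect_equal(as.numeric(r), 1)
  expect_equal(attr(r, "transform"), "log2tpm")
  expect_error(replicateCorrelation(m, cbind("a", "zz")), "zz")
})

test_that("concordant pairs land near their target and discordant pairs near zero", {
  se <- simulateExpression(nSamples = 4, concordantPairs = 2,
                           discordantPairs = 2, seed = 17)
  rc <- replicateCorrelation(se$expr, se$pairs[, 1:2])
  conc <- rc[se$pairs$regime == "concordant"]
  disc <- rc[se$pairs$regime == "discordant"]
  expect_true(all(abs(conc - 0.75) < 0.08))
  expect_true(all(disc < 0.22))
})

test_that("a sample equal to the reference is fully concordant and top class", {
  set.seed(31)
  nG <- 60
  genes <- paste0("g", seq_len(nG))
  ref <- setNames(2^rnorm(nG, 4, 1.5) - 1, genes)
  ref[ref < 0] <- 0
  tpm <- cbind(ideal = ref,
               noisy = pmax(ref * 2^rnorm(nG, 0, 0.6), 0),
               mid = pmax(ref^0.4 * 2^rnorm(nG, 0, 1.5), 0),
               dead1 = pmax(2^rnorm(nG, -1, 1) - 1, 0),
               dead2 = pmax(2^rnorm(nG, -1, 1) - 1, 0))
  rownames(tpm) <- genes
  cts <- round(tpm * 2) ; cts[, "dead1"] <- pmin(cts[, "dead1"], 20)
  m <- FFPEExpressionSet(cts, tpm)
  res <- signatureConcordance(m, genes, ref, k = 3)
  expect_equal(unname(concordance(res)["ideal"]), 1)
  expect_equal(unname(clusterLabels(res)["ideal"]), "B")
})

test_that("samples with no usable signature counts are excluded with a reason", {
  cts <- matrix(10, nrow = 5, ncol = 3,
                dimnames = list(paste0("g", 1:5), c("a", "b", "dead")))
  cts[, "dead"] <- c(4, 4, 0, 1, 2)      # all below the 5-read cutoff
  cts[1, "a"] <- 40
  m <- toyExpression(cts)
  res <- signatureConcordance(m, rownames(cts),
                              setNames(rep(10, 5), rownames(cts)), k = 2)
  expect_true("dead" %in% names(res@excluded))
  expect_match(unname(res@excluded["dead"]), "below 5 reads")
  expect_false("dead" %in% names(clusterLabels(res)))
})

test_that("an unrepresented signature is an error", {
  cts <- matrix(10, nrow = 4, ncol = 3,
                dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
  m <- toyExpression(cts)
  expect_error(
    signatureConcordance(m, c("x1", "x2", "x3"),
                         setNames(rep(1, 3), c("x1", "x2", "x3"))),
    "signature not represented")
})

test_that("planted quality tiers are recovered by concordance clustering", {
  se <- simulateExpression(nSamples = 24, concordantPairs = 0,
                           discordantPairs = 0, seed = 8)
  res <- signatureConcordance(se$expr, se$signature, se$reference)
  tt <- se$truth; rownames(tt) <- tt$sample
  lab <- clusterLabels(res)
  expect_gte(mean(lab == tt[names(lab), "tier"]), 0.9)
  # class ordering follows median concordance: B most reference-like
  med <- tapply(concordance(res), lab, median)
  expect_true(all(diff(med[order(names(med))]) < 0))
})

test_that("gene-body bias statistics flag planted 3' ramps and nothing else", {
  flat <- rep(1, 100)
  ramp <- 1 + 2.5 * exp((1:100 - 100) / 15)
  profiles <- rbind(flat = flat, ramp = ramp)
  mrna <- c(flat = 20, ramp = 4)
  res <- geneBodyBias(profiles, mrna)
  ps <- res$perSample
  expect_equal(ps$bias5[ps$sample == "flat"], 1)
  expect_equal(ps$bias3[ps$sample == "flat"], 1)
  expect_false(ps$flag3[ps$sample == "flat"])
  expect_true(ps$flag3[ps$sample == "ramp"])
  expect_false(ps$flag5[ps$sample == "ramp"])
})

test_that("bias statistics are invariant to rescaling a profile", {
  set.seed(13)
  p <- matrix(runif(100, 0.5, 2), nrow = 1,
              dimnames = list("s1", NULL))
  r1 <- geneBodyBias(p, c(s1 = 15))$perSample
  r2 <- geneBodyBias(p * 37, c(s1 = 15))$perSample
  expect_equal(r1$bias3, r2$bias3)
  expect_equal(r1$bias5, r2$bias5)
})

test_that("high-mRNA stratum curves are flatter when bias is planted low", {
  se <- simulateExpression(nSamples = 20, concordantPairs = 0,
                           discordantPairs = 0, seed = 5)
  tt <- se$truth
  res <- geneBodyBias(se$geneBody, setNames(tt$mrna_pct, tt$sample))
  skewness <- function(v) max(v) / min(v)
  expect_lt(skewness(res$curves$high), skewness(res$curves$low))
})

test_that("zero-coverage profiles are excluded with a reason", {
  p <- rbind(ok = rep(1, 100), dead = rep(0, 100))
  res <- geneBodyBias(p, c(ok = 15, dead = 15))
  expect_equal(names(res$excluded), "dead")
  expect_equal(nrow(res$perSample), 1L)
})

test_that("GC anomaly flags fire on tail-heavy profiles only", {
  centred <- dnorm(1:100, 50, 8); centred <- centred / sum(centred) * 1e6
  res <- gcAnomalyFlags(centred)
  expect_false(res$flagLowGC)
  expect_false(res$flagHighGC)
  expect_true(res$bulkNormal)

  highHeavy <- centred
  highHeavy[85:95] <- highHeavy[85:95] + 0.25 * sum(centred) / 11
  res2 <- gcAnomalyFlags(highHeavy)
  expect_true(res2$flagHighGC)
  expect_gt(res2$fracHigh, 0.05)

  res3 <- gcAnomalyFlags(rep(0, 100))     # empty profile: quiet zeros
  expect_equal(res3$fracLow, 0)
  expect_false(res3$flagLowGC || res3$flagHighGC)
})

test_that("PCA projections are deterministic and identify planted outliers", {
  se <- simulateExpression(nSamples = 10, concordantPairs = 1,
                           discordantPairs = 1, seed = 19)
  pr <- replicatePCA(se$expr)
  expect_equal(colnames(pr), c("PC1", "PC2"))
  # the structureless discordant partner is the farthest from the centroid
  d <- sqrt(rowSums(scale(pr, scale = FALSE)^2))
  expect_equal(names(which.max(d)), "R01d2")
  # gene order must not matter
  perm <- sample(nrow(se$expr))
  pr2 <- replicatePCA(se$expr[perm, ])
  expect_equal(pr2, pr, tolerance = 1e-8)
  expect_error(replicatePCA(se$expr[, 1:2]), "at least 3")
})

test_that("identical samples project to identical coordinates", {
  cts <- matrix(rpois(300, 30), nrow = 100,
                dimnames = list(paste0("g", 1:100), c("a", "b", "c")))
  cts[, "b"] <- cts[, "a"]
  pr <- replicatePCA(toyExpression(cts))
  expect_equal(pr["a", ], pr["b", ])
})
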