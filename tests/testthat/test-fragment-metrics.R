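test_that("DV of simple discrete distributions is the exact mass fraction", {
  expect_equal(dvValue(FragmentSizeDistribution(300, 1), 200), 100)
  expect_equal(dvValue(FragmentSizeDistribution(40, 1), 50), 0)
  # boundary: mass exactly at the threshold counts as below (strict ">")
  d <- FragmentSizeDistribution(c(100, 200), c(1, 1))
  expect_equal(dvValue(d, 200), 0)
  expect_equal(dvValue(d, 100), 50)
})

test_that("DV of an exponential-decay density matches a trapezoid oracle", {
  s <- seq(1, 2000, by = 1)
  w <- exp(-s / 100)
  d <- FragmentSizeDistribution(s, w)
  oracle <- 100 * trapezoid(s[s > 100], w[s > 100]) / trapezoid(s, w)
  expect_equal(dvValue(d, 100), oracle, tolerance = 0.01)
  expect_equal(dvValue(d, 100), 100 * exp(-1), tolerance = 0.02)
})

test_that("three equal masses give the hand-enumerated profile", {
  d <- FragmentSizeDistribution(c(60, 150, 250), c(1, 1, 1))
  p <- dvProfile(d)
  expect_equal(unname(dvValues(p)), c(100, 200 / 3, 100 / 3))
  # point mass at 200: strictly-greater convention
  p2 <- dvProfile(FragmentSizeDistribution(200, 1), c(100, 200))
  expect_equal(unname(dvValues(p2)), c(100, 0))
})

test_that("DV profiles are monotone in threshold and scale invariant", {
  set.seed(41)
  for (i in 1:25) {
    d <- randomFineDistribution()
    dv <- dvValues(dvProfile(d, c(50, 100, 200, 400)))
    expect_true(all(diff(dv) <= 1e-9))
    dScaled <- FragmentSizeDistribution(d@sizes, d@massWeights * runif(1, 0.1, 50))
    expect_equal(dvValues(dvProfile(dScaled, c(50, 100, 200, 400))), dv)
  }
})

test_that("adding mass above the largest threshold weakly increases all DVs", {
  set.seed(42)
  for (i in 1:10) {
    d <- randomFineDistribution()
    th <- c(50, 100, 200)
    before <- dvValues(dvProfile(d, th))
    w2 <- d@massWeights
    w2[d@sizes > 300] <- w2[d@sizes > 300] + runif(1, 0.1, 1)
    after <- dvValues(dvProfile(FragmentSizeDistribution(d@sizes, w2), th))
    expect_true(all(after >= before - 1e-9))
  }
})

test_that("empty or invalid distributions raise informative errors", {
  expect_error(FragmentSizeDistribution(c(10, 20), c(0, 0)), "positive")
  expect_error(FragmentSizeDistribution(c(20, 10), c(1, 1)), "increasing")
  expect_error(dvValue(FragmentSizeDistribution(10, 1), -5), "positive")
})

test_that("the lower marker is found in a rendered trace and excisable", {
  grid <- seq(1, 600, by = 1)
  sig <- dlnorm(grid, log(150), 0.4) +
    0.05 * exp(-0.5 * ((grid - 25) / 1.5)^2)
  tr <- ElectropherogramTrace(grid, sig)
  mk <- detectLowerMarker(tr)
  expect_true(mk$found)
  expect_true(mk$interval[1] <= 25 && 25 <= mk$interval[2])
})

test_that("a flat noise-only trace yields marker failure, not an error", {
  set.seed(7)
  tr <- ElectropherogramTrace(1:200, rnorm(200, 1, 0.05))
  mk <- detectLowerMarker(tr)
  expect_false(mk$found)
  expect_match(mk$reason, "no marker")
})

test_that("of two candidate marker peaks the taller wins; ties go small", {
  grid <- seq(1, 100, by = 0.5)
  two <- function(h1, h2)
    ElectropherogramTrace(grid,
      h1 * exp(-0.5 * ((grid - 20) / 1)^2) +
      h2 * exp(-0.5 * ((grid - 30) / 1)^2))
  expect_equal(detectLowerMarker(two(1, 2))$peakNt, 30)
  expect_equal(detectLowerMarker(two(2, 1))$peakNt, 20)
  expect_equal(detectLowerMarker(two(1, 1))$peakNt, 20)  # tie -> smaller
})

test_that("trace DV agrees with the distribution oracle on noiseless renderings", {
  set.seed(11)
  worst <- 0
  for (i in 1:30) {
    d <- randomFineDistribution()
    rt <- renderTrace(d, gridStep = 0.5)
    p <- dvProfile(rt$trace)
    expect_equal(dvStatus(p), "computed")
    dev <- max(abs(dvValues(p) - dvValues(rt$truth)))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 0.5)
})

test_that("a trace without the marker peak fails and propagates as missing DV", {
  set.seed(12)
  d <- randomFineDistribution()
  rt <- renderTrace(d, marker = FALSE)
  p <- dvProfile(rt$trace)
  expect_equal(dvStatus(p), "failed")
  expect_true(all(is.na(dvValues(p))))
})

test_that("a heavily degraded rendering shows the expected DV ordering", {
  grid <- seq(1, 800, by = 1)
  d <- FragmentSizeDistribution(grid, dexp(grid, 1 / 60))
  rt <- renderTrace(d, gridStep = 0.5)
  dv <- dvValues(dvProfile(rt$trace))
  expect_true(dv["DV200"] < dv["DV100"])
  expect_true(dv["DV100"] < dv["DV50"])
  expect_lt(dv["DV200"], 10)
})

test_that("malformed traces are rejected", {
  expect_error(ElectropherogramTrace(c(1:10, 10:1), rep(1, 20)),
               "increasing")
  expect_error(ElectropherogramTrace(1:10, 1:10), "16 points")
})

test_that("size files round-trip through the two-column reader", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("# synthetic distribution", "size_nt,mass",
               paste(c(60, 150, 250), c(1, 2, 1), sep = ",")), tf)
  d <- readSizeFile(tf)
  expect_s4_class(d, "FragmentSizeDistribution")
  expect_equal(d@sizes, c(60, 150, 250))
  expect_equal(dvValue(d, 100), 75)
})
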