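rec <- function(dv100 = NA, contam = 0, genes = 20000, mol = 10,
                id = "s1") {
  list(sample_id = id, dv100 = dv100, contamination_pct = contam,
       genes_detected = genes, lib_molarity = mol)
}

test_that("the DV100 rule drives the verdict with pinned boundaries", {
  expect_equal(verdict(assessSample(rec(75))), "proceed")
  expect_equal(verdict(assessSample(rec(60))), "proceed")
  expect_equal(verdict(assessSample(rec(50))), "proceed_high_input")
  expect_equal(verdict(assessSample(rec(40))), "do_not_proceed")  # strict ">"
  expect_equal(verdict(assessSample(rec(41))), "proceed_high_input")
  expect_equal(verdict(assessSample(rec())), "indeterminate")
})

test_that("every fired rule is auditable with observed value and threshold", {
  d <- assessSample(rec(50, contam = 22.61, genes = 500, mol = 1))
  rs <- decisionReasons(d)
  expect_true("dv100_below_high_input_edge" %in% rs$rule)
  expect_true("contamination_high" %in% rs$rule)
  expect_true("low_gene_count" %in% rs$rule)
  expect_true("low_library_molarity" %in% rs$rule)
  expect_true("exclude_contaminated_low_yield" %in% rs$rule)
  expect_equal(rs$observed[rs$rule == "contamination_high"], 22.61)
  expect_equal(rs$threshold[rs$rule == "contamination_high"], 5)
  expect_true(decisionFlags(d)$excludeContaminatedLowYield)
})

test_that("contamination flags use strict edges at 1 and 5 percent", {
  expect_equal(contaminationFlag(0.38), "none")
  expect_equal(contaminationFlag(1.0), "none")
  expect_equal(contaminationFlag(5.0), "low")
  expect_equal(contaminationFlag(5.01), "high")
  expect_equal(contaminationFlag(22.61), "high")
})

test_that("input recommendations follow the DV200 bands", {
  expect_equal(recommendInput(75)$inputNg, c(20, 20))
  expect_equal(recommendInput(60)$inputNg, c(20, 50))
  expect_equal(recommendInput(50)$inputNg, c(50, 100))  # upper-inclusive
  expect_equal(recommendInput(30)$inputNg, c(50, 100))  # lower-inclusive
  expect_false(recommendInput(29)$proceed)
  expect_equal(recommendInput(NA)$reason, "unmeasured")
})

test_that("replicate concordance passes at the inclusive 0.7 bar", {
  expect_equal(replicatePass(0.75), "pass")
  expect_equal(replicatePass(0.7), "pass")
  expect_equal(replicatePass(0.22), "fail")
})

test_that("cohort screening counts match a brute-force scan of the fixture", {
  qc <- fixtureTable()
  r <- qcRecords(qc)
  sc <- screenCohort(qc)
  nProceedable <- 0L
  for (i in seq_len(nrow(r)))
    if (!is.na(r$dv100[i]) && r$dv100[i] > 40) nProceedable <- nProceedable + 1L
  got <- sum(sc$decisions$verdict %in% c("proceed", "proceed_high_input"))
  expect_equal(got, nProceedable)
  expect_equal(sum(sc$verdictCounts), nrow(r))
  expect_equal(sum(sc$decisions$verdict == "indeterminate"),
               sum(is.na(r$dv100)))
})

test_that("an all-missing-DV table is wholly indeterminate", {
  r <- qcRecords(fixtureTable())
  r$dv100 <- NA_real_
  sc <- screenCohort(r)
  expect_true(all(sc$decisions$verdict == "indeterminate"))
})

test_that("raising DV100 never downgrades the verdict", {
  rank <- c(do_not_proceed = 1, proceed_high_input = 2, proceed = 3)
  set.seed(23)
  for (i in 1:50) {
    base <- rec(runif(1, 0, 100), contam = runif(1, 0, 50),
                genes = sample(10:30000, 1), mol = runif(1, 0.1, 50))
    higher <- base
    higher$dv100 <- min(100, base$dv100 + runif(1, 0, 60))
    v1 <- rank[verdict(assessSample(base))]
    v2 <- rank[verdict(assessSample(higher))]
    expect_gte(v2, v1)
  }
})

test_that("screening a planted synthetic cohort recovers verdict structure", {
  sim <- simulateCohort(seed = 3)
  sc <- screenCohort(sim$qc)
  r <- qcRecords(sim$qc)
  expect_equal(sum(sc$verdictCounts), nrow(r))
  expect_equal(unname(sc$verdictCounts["indeterminate"]),
               sum(is.na(r$dv100)))
  # verdicts agree with a direct reading of the dv100 column
  v <- sc$decisions$verdict[!is.na(r$dv100)]
  dv <- r$dv100[!is.na(r$dv100)]
  expect_true(all(v[dv > 60] == "proceed" | dv[v == "proceed"] >= 60))
  expect_true(all(v[dv <= 40] == "do_not_proceed"))
})

test_that("threshold objects validate their ordering", {
  expect_error(policyThresholds(dv100ProceedMin = 70,
                                dv100HighInputBelow = 60),
               "below")
  expect_error(policyThresholds(contaminationLow = 6), "below")
})
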