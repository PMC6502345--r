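test_that("pairwise cells agree with a two-pass covariance oracle", {
  r <- qcRecords(fixtureTable())
  cm <- pearsonPairwise(r, c("storage_time", "dv200", "dv100", "lib_yield"))
  for (a in c("storage_time", "dv200")) for (b in c("dv100", "lib_yield")) {
    ok <- !is.na(r[[a]]) & !is.na(r[[b]])
    expect_equal(corValues(cm)[a, b], twoPassPearson(r[[a]][ok], r[[b]][ok]),
                 tolerance = 1e-12)
    expect_equal(nPairs(cm)[a, b], sum(ok))
  }
})

test_that("pair counts match a brute-force scan of the fixture", {
  r <- qcRecords(fixtureTable())
  cm <- pearsonPairwise(r, c("storage_time", "dv200"))
  # brute force: walk rows, count those with both fields present
  n <- 0L
  for (i in seq_len(nrow(r)))
    if (!is.na(r$storage_time[i]) && !is.na(r$dv200[i])) n <- n + 1L
  expect_equal(nPairs(cm)["storage_time", "dv200"], n)
  expect_equal(corValues(cm)["storage_time", "storage_time"], 1)
})

test_that("sparse or constant pairs are missing with a recorded reason", {
  r <- data.frame(sample_id = paste0("s", 1:5),
                  input_for_libprep = c(1, 2, NA, NA, NA),
                  rin = c(2, 3, NA, NA, NA),
                  dv200 = c(5, 5, 5, 5, 5),
                  dv100 = c(10, 20, 30, 40, 50),
                  dv50 = c(90, 91, 92, 93, 94),
                  lib_size = 400, lib_yield = 10, lib_molarity = 3,
                  storage_time = 7L, resequenced = FALSE,
                  contamination_pct = 1, cluster_label = "B",
                  genes_detected = 100L)
  cm <- pearsonPairwise(r, c("input_for_libprep", "rin", "dv200", "dv100"))
  expect_true(is.na(corValues(cm)["input_for_libprep", "rin"]))   # n = 2
  expect_equal(nPairs(cm)["input_for_libprep", "rin"], 2L)
  expect_equal(cm@reasons["input_for_libprep", "rin"],
               "fewer than 3 complete pairs")
  expect_true(is.na(corValues(cm)["dv200", "dv100"]))
  expect_equal(cm@reasons["dv200", "dv100"], "constant")
})

test_that("record order does not change the correlation matrix", {
  r <- qcRecords(fixtureTable())
  m <- c("storage_time", "dv200", "dv100", "contamination_pct")
  set.seed(5)
  perm <- sample(nrow(r))
  expect_equal(corValues(pearsonPairwise(r[perm, ], m)),
               corValues(pearsonPairwise(r, m)))
})

test_that("listwise deletion restricts every cell to complete records", {
  r <- qcRecords(fixtureTable())
  m <- c("storage_time", "rin", "dv200")
  cm <- pearsonPairwise(r, m, method = "listwise")
  cc <- !is.na(r$storage_time) & !is.na(r$rin) & !is.na(r$dv200)
  expect_true(all(nPairs(cm) == sum(cc)))
  expect_equal(corValues(cm)["storage_time", "dv200"],
               twoPassPearson(r$storage_time[cc], r$dv200[cc]),
               tolerance = 1e-12)
})

test_that("storage time rounds up to whole years with a one-year floor", {
  expect_equal(storageTime(2000.0, 2006.1), 7L)
  expect_equal(storageTime(2000.0, 2007.0), 7L)
  expect_equal(storageTime(2000.0, 2000.2), 1L)
  expect_error(storageTime(2005, 2004), "precedes")
})

test_that("storage strata counts match a brute-force scan of the fixture", {
  r <- qcRecords(fixtureTable())
  s <- stratifyByStorage(fixtureTable())
  tab <- cohortTable(s)
  n712 <- 0L
  for (i in seq_len(nrow(r))) {
    st <- r$storage_time[i]
    if (!is.na(st) && st >= 7L && st <= 12L) n712 <- n712 + 1L
  }
  got <- tab[tab$bin == "7-12" & tab$metric == "lib_yield", ]
  expect_equal(got$n, n712)   # lib_yield never missing in the fixture
  unknown <- tab[tab$bin == "unknown" & tab$metric == "lib_yield", ]
  expect_equal(unknown$n, sum(is.na(r$storage_time)))
})

test_that("empty bins carry n = 0 and missing summaries", {
  r <- qcRecords(fixtureTable())[1:2, ]       # both stored 7 years
  s <- stratifyByStorage(r, bins = list(`7-12` = c(7L, 12L),
                                        `13-22` = c(13L, 22L),
                                        `23-32` = c(23L, 32L)))
  tab <- cohortTable(s)
  empty <- tab[tab$bin == "23-32" & tab$metric == "dv100", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("a storage time outside all bins is an error naming the record", {
  r <- qcRecords(fixtureTable())
  r$storage_time[1] <- 40L
  expect_error(stratifyByStorage(r), r$sample_id[1])
})

test_that("synthetic cohorts show declining DV100 means across strata", {
  sim <- simulateCohort(seed = 71)
  s <- stratifyByStorage(sim$qc)
  tab <- cohortTable(s)
  m <- tab$mean[tab$metric == "dv100" & tab$bin != "unknown"]
  expect_true(all(diff(m) < 0))
})

test_that("recomputed and published cohort means are reported side by side", {
  cmp <- compareCohorts(stratifyByStorage(fixtureTable()))
  expect_true(all(c("recomputed", "published") %in% names(cmp)))
  core <- cmp[cmp$bin %in% c("7-12", "13-22", "23-32"), ]
  expect_equal(nrow(core), 9L)
  expect_true(all(!is.na(core$recomputed)))
  expect_true(all(!is.na(core$published)))
})
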