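test_that("configuration validation rejects out-of-range parameters", {
  expect_error(srsSimConfig(exposureLevels = c(300000, -1)), "exposure")
  expect_error(srsSimConfig(incidenceLevels = c(0.5, 1.5)), "incidence")
  expect_error(
    srsSimConfig(prTable = data.frame(duration = 1, serious = TRUE, pr = 0)),
    "pr")
  expect_error(srsSimConfig(signalFraction = 1), "signalFraction")
  expect_error(
    srsSimConfig(prTable = defaultPrTable()[-1, ]), "stratum")
})

test_that("profiles carry exactly balanced strata at the defaults", {
  p <- buildProfiles(srsSimConfig())
  expect_equal(nrow(p$drugs), 60)
  expect_equal(nrow(p$ades), 40)
  expect_equal(unname(table(p$drugs$exposure)), c(30L, 30L),
               ignore_attr = TRUE)
  # durations balanced within each exposure stratum
  tab <- table(p$drugs$exposure, p$drugs$duration)
  expect_true(all(tab == 10L))
  expect_equal(sum(p$ades$incidence == 1 / 200), 20)
  expect_equal(sum(p$ades$serious), 20)
  expect_true(all(table(p$ades$incidence, p$ades$serious) == 10L))
})

test_that("indivisible strata are rejected, single-stratum grids allowed", {
  expect_error(buildProfiles(srsSimConfig(nDrugs = 41)), "equal strata")
  expect_error(buildProfiles(srsSimConfig(nAdes = 7)), "equal strata")
  p <- buildProfiles(srsSimConfig(
    nDrugs = 2, nAdes = 2, exposureLevels = 1000, incidenceLevels = 0.01,
    durationLevels = 1,
    prTable = data.frame(duration = 1, serious = c(TRUE, FALSE),
                         pr = c(0.1, 0.1))))
  expect_equal(unique(p$drugs$exposure), 1000)
  expect_equal(unique(p$ades$incidence), 0.01)
})

test_that("expected report rate is e * i * RR * pr and rejects non-positive input", {
  expect_equal(expectedReportRate(300000, 1 / 200, 10, 0.095), 1425)
  expect_equal(expectedReportRate(30000, 1 / 500, 1.2, 0.010), 0.72)
  expect_equal(expectedReportRate(100, 0.1, 1, 0.1), 1)
  expect_error(expectedReportRate(0, 0.1, 1, 0.1), "positive")
  expect_error(expectedReportRate(10, 0.1, -1, 0.1), "positive")
})

test_that("signal assignment plants the configured number of cells and RR shares", {
  cfg <- srsSimConfig()
  ds <- simulateSrs(cfg, seed = 3)
  tr <- signalTruth(ds)
  expect_equal(sum(tr$isSignal), 240)
  expect_equal(unname(table(tr$rr[tr$isSignal])),
               rep(60L, 4), ignore_attr = TRUE)
  expect_true(all(tr$rr[!tr$isSignal] == 1))
  # signalFraction 0: every cell at the null RR
  ds0 <- simulateSrs(srsSimConfig(signalFraction = 0), seed = 3)
  expect_equal(sum(signalTruth(ds0)$isSignal), 0)
  expect_true(all(signalTruth(ds0)$rr == 1))
})

test_that("the same seed reproduces a dataset bit-identically", {
  cfg <- tinyConfig()
  d1 <- simulateSrs(cfg, seed = 11)
  d2 <- simulateSrs(cfg, seed = 11)
  expect_identical(counts(d1), counts(d2))
  expect_identical(signalTruth(d1), signalTruth(d2))
  d3 <- simulateSrs(cfg, seed = 12)
  expect_false(identical(counts(d1), counts(d3)))
  # strata sizes identical across seeds even though placement differs
  expect_equal(table(signalTruth(d3)$rr), table(signalTruth(d1)$rr))
})

test_that("total reports always equals the sum of the count matrix", {
  for (s in 1:5) {
    ds <- simulateSrs(tinyConfig(), seed = s)
    expect_identical(totalReports(ds), sum(counts(ds)))
  }
})

test_that("cell counts have Poisson mean and variance", {
  # single-stratum grid: all 2000 cells share lambda = e*i*pr = 142.5
  cfg <- srsSimConfig(
    nDrugs = 50, nAdes = 40, exposureLevels = 300000,
    incidenceLevels = 1 / 200, durationLevels = 1,
    prTable = data.frame(duration = 1, serious = c(TRUE, FALSE),
                         pr = c(0.095, 0.095)),
    signalFraction = 0)
  lam <- 300000 * (1 / 200) * 0.095
  x <- as.vector(counts(simulateSrs(cfg, seed = 21)))
  m <- length(x)
  expect_lt(abs(mean(x) - lam), 4 * sqrt(lam / m))
  expect_lt(abs(var(x) - lam), 4 * lam * sqrt(2 / (m - 1)))
})

test_that("batch mean total matches the analytic Poisson mean", {
  cfg <- srsSimConfig()
  p <- buildProfiles(cfg)
  prKey <- setNames(defaultPrTable()$pr,
                    paste(defaultPrTable()$duration, defaultPrTable()$serious))
  lamBase <- outer(p$drugs$exposure, p$ades$incidence) *
    outer(p$drugs$duration, p$ades$serious,
          function(d, s) prKey[paste(d, s)])
  meanRR <- 0.9 * 1 + 0.1 * mean(c(10, 4.9, 1.5, 1.2))
  analytic <- sum(lamBase) * meanRR
  batch <- simulateSrsBatch(cfg, 100, masterSeed = 31)
  tot <- vapply(batch, totalReports, numeric(1))
  # placement of signal cells dominates the dataset-to-dataset variance
  expect_lt(abs(mean(tot) - analytic), 4 * sd(tot) / sqrt(length(tot)))
})

test_that("batches are reproducible and built from documented substreams", {
  cfg <- tinyConfig()
  b1 <- simulateSrsBatch(cfg, 3, masterSeed = 99)
  b2 <- simulateSrsBatch(cfg, 3, masterSeed = 99)
  expect_identical(lapply(b1, counts), lapply(b2, counts))
  one <- simulateSrsBatch(cfg, 1, masterSeed = 99)
  expect_identical(counts(one[[1]]),
                   counts(simulateSrs(cfg, seed = datasetSeeds(99, 1))))
  # calling the simulator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulateSrs(cfg, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})
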