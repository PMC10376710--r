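test_that("periodogram equals per-frequency least-squares fit power", {
  set.seed(41)
  days <- gridDays(missionGrid())
  freqs <- spectralGrid(days)$frequencies
  for (r in 1:20) {
    y <- rnorm(8)
    expect_equal(lombScarglePeriodogram(y, days, freqs),
                 oracleLsPower(y, days, freqs), tolerance = 1e-8)
  }
  # with missing bins, the fit runs on the observed subset only
  y <- rnorm(8); y[c(3, 6)] <- NA
  expect_equal(lombScarglePeriodogram(y, days, freqs),
               oracleLsPower(y, days, freqs), tolerance = 1e-8)
})

test_that("periodogram power is nonnegative and peaks at a planted frequency", {
  t <- 0:31
  y <- cos(2 * pi * t * 4 / 32)
  freqs <- (1:16) / 32
  p <- lombScarglePeriodogram(y, t, freqs)
  expect_true(all(p >= 0))
  expect_equal(which.max(p), 4L)
  expect_error(lombScarglePeriodogram(c(1, 2, NA, NA, NA), 1:5), "3 present")
})

test_that("inverse-transform autocorrelations match direct lagged products", {
  # on a complete even grid with the natural frequencies the pairing with
  # the circular lagged-product estimator is exact
  set.seed(7)
  for (n in c(8, 12)) {
    t <- seq_len(n) - 1
    sg <- spectralGrid(t, oversampling = NULL)
    for (r in 1:10) {
      y <- rnorm(n)
      p <- lombScarglePeriodogram(y, t, sg$frequencies)
      rho <- autocorrelations(p, sg$frequencies, sg$lagStep, sg$nLags)
      expect_equal(rho, oracleCircularRho(y, sg$nLags), tolerance = 1e-6)
    }
  }
})

test_that("autocorrelations are normalized and bounded", {
  set.seed(8)
  days <- gridDays(missionGrid())
  sg <- spectralGrid(0:7)
  for (r in 1:20) {
    p <- lombScarglePeriodogram(rnorm(8), 0:7, sg$frequencies)
    rho <- autocorrelations(p, sg$frequencies, sg$lagStep, sg$nLags)
    expect_equal(rho[1], 1, tolerance = 1e-9)
    expect_true(all(abs(rho) <= 1 + 1e-9))
  }
  expect_error(autocorrelations(rep(0, 4), (1:4) / 8, 1), "degenerate")
})

test_that("white noise has small autocorrelations on a long window", {
  set.seed(9)
  n <- 128
  t <- seq_len(n) - 1
  sg <- spectralGrid(t, oversampling = NULL)
  y <- rnorm(n)
  p <- lombScarglePeriodogram(y, t, sg$frequencies)
  rho <- autocorrelations(p, sg$frequencies, sg$lagStep, sg$nLags)
  expect_true(all(abs(rho[-1]) <= 3 / sqrt(n)))
})

test_that("bootstrap nulls are reproducible and quantile-monotone", {
  set.seed(10)
  pool <- rnorm(300)
  t <- 0:7
  a <- buildNull(pool, t, nBoot = 2000, seed = 5)
  b <- buildNull(pool, t, nBoot = 2000, seed = 5)
  expect_equal(rhoThresholds(a), rhoThresholds(b))
  expect_equal(spikeThresholds(a), spikeThresholds(b))
  mid <- buildNull(pool, t, nBoot = 2000, level = 0.5, seed = 5)
  expect_true(all(rhoThresholds(a) >= rhoThresholds(mid)))
  expect_error(buildNull(numeric(0), t), "empty")
})

test_that("held-out null series fall below the lag-1 threshold at the stated rate", {
  set.seed(11)
  pool <- as.vector(vapply(1:60, function(i) normalizeSeries(rnorm(8)),
                           numeric(8)))
  t <- 0:7
  null <- buildNull(pool, t, nBoot = 20000, seed = 13)
  held <- bootstrapAutocorrelations(pool, t, n = 5000, seed = 77)
  frac <- mean(held[, 2] < rhoThresholds(null)[1])
  expect_gt(frac, 0.93)
  expect_lt(frac, 0.97)
})

test_that("the lag rule takes the smallest significant lag", {
  null <- new("SpectralNull", rhoQ = c(0.5, 0.5, 0.5, 0.5), maxQ = 1,
              minQ = -1, level = 0.95, nBoot = 100L, seed = 1,
              nullMaxRho = seq(0, 1, length.out = 100),
              nullMaxima = seq(0, 1, length.out = 100),
              nullMinima = seq(-1, 0, length.out = 100))
  res <- classifySeries(c(1, 0.6, 0.7, 0.1, 0.1), rep(0, 8), null)
  expect_equal(res$kind, "Lag1")
  expect_equal(res$M, 1L)
  # equality with the threshold counts as exceedance
  expect_equal(classifySeries(c(1, 0.2, 0.5, 0.1, 0.1), rep(0, 8),
                              null)$kind, "Lag2")
})

test_that("spike tests apply only to series failing the lag rule", {
  null <- new("SpectralNull", rhoQ = rep(0.5, 4), maxQ = 0.8, minQ = -0.8,
              level = 0.95, nBoot = 100L, seed = 1,
              nullMaxRho = seq(0, 1, length.out = 100),
              nullMaxima = seq(0, 1, length.out = 100),
              nullMinima = seq(-1, 0, length.out = 100))
  spiky <- c(0, 0, 0, 0, 0, 0.95, 0, 0)
  # lag fires -> Lag even with an extreme value
  expect_equal(classifySeries(c(1, 0.9, 0, 0, 0), spiky, null)$kind, "Lag1")
  # lag fails -> spikes are tested
  expect_equal(classifySeries(c(1, 0.1, 0, 0, 0), spiky, null)$kind,
               "SpikeMax")
  expect_equal(classifySeries(c(1, 0.1, 0, 0, 0), -spiky, null)$kind,
               "SpikeMin")
  expect_equal(classifySeries(c(1, 0.1, 0, 0, 0), spiky * 0.5, null)$kind,
               "NoTrend")
})

test_that("planted archetypes are classified into their expected classes", {
  # one subject, a diverse panel, low noise
  sim <- simulateCohort(nSubjects = 1, nMeasurements = 60, nBlocks = 1,
                        plantedFraction = 0.1, amplitude = 15, noiseSd = 1,
                        archetypes = c("flight_rise_persist",
                                       "landing_spike", "landing_dip"),
                        seed = 31)
  me <- classifyCohort(preprocessCohort(sim$records), nBoot = 5000, seed = 7)
  tc <- trendClasses(me)
  tr <- merge(tc, sim$truth$assignments,
              by = c("subject_id", "measurement_id"))
  lag <- tr[tr$expectedClass == "Lag", ]
  expect_true(all(grepl("^Lag", lag$trendClass)))
  expect_true(all(tr$trendClass[tr$expectedClass == "SpikeMax"] == "SpikeMax"))
  expect_true(all(tr$trendClass[tr$expectedClass == "SpikeMin"] == "SpikeMin"))
})

test_that("every classified series gets exactly one class and classes are exhaustive", {
  sim <- simulateCohort(nSubjects = 3, nMeasurements = 12, seed = 17)
  me <- classifyCohort(preprocessCohort(sim$records), nBoot = 2000, seed = 3)
  tc <- trendClasses(me)
  expect_true(all(tc$trendClass %in%
                    c(paste0("Lag", 1:4), "SpikeMax", "SpikeMin", "NoTrend")))
  expect_true(all(!is.na(tc$trendClass)))
  expect_true(all(is.na(tc$lagM[!grepl("^Lag", tc$trendClass)])))
  expect_true(all(tc$lagM[grepl("^Lag", tc$trendClass)] %in% 1:4))
})

test_that("classification is reproducible for a fixed seed", {
  sim <- simulateCohort(nSubjects = 2, nMeasurements = 8, seed = 4)
  me <- preprocessCohort(sim$records)
  a <- trendClasses(classifyCohort(me, nBoot = 1000, seed = 9))
  b <- trendClasses(classifyCohort(me, nBoot = 1000, seed = 9))
  expect_identical(a, b)
})

test_that("Benjamini-Hochberg selection matches the stated arithmetic", {
  expect_equal(significanceAdjust(rep(1, 5)), rep(FALSE, 5))
  expect_equal(significanceAdjust(c(0.001, 0.02, 0.8)),
               c(TRUE, TRUE, FALSE))
  # appending a large p never removes a selected item
  set.seed(12)
  for (r in 1:20) {
    p <- runif(6)^2
    before <- significanceAdjust(p)
    after <- significanceAdjust(c(p, 0.9))[seq_along(p)]
    expect_true(all(after[before]))
  }
})
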