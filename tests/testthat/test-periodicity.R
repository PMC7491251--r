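test_that("lombScargle recovers a planted cosine, with and without gaps", {
  lag <- setdiff(seq(-200000, 200000, by = 500), 0)
  y <- cos(2 * pi * lag / 40000)
  cfg <- scanConfig()
  pg <- lombScargle(mkProfile(lag, y), cfg)
  step <- periodGridStep(40000, 200000 - cfg$minLag)
  expect_lt(abs(pg@peakPeriod - 40000), step + 1e-9)
  expect_gt(pg@pnmax, 3)

  # 30% of lags deleted at random: still the same peak
  set.seed(21)
  keep <- sort(sample(length(lag), round(0.7 * length(lag))))
  pg2 <- lombScargle(mkProfile(lag[keep], y[keep]), cfg)
  expect_lt(abs(pg2@peakPeriod - 40000), step + 1e-9)

  # constant profile: no power anywhere, p ~ 1, smallest period by tie rule
  pgc <- lombScargle(mkProfile(lag, rep(0.25, length(lag))), cfg)
  expect_true(all(pgc@power == 0))
  expect_equal(pgc@pValue, 1)
  expect_equal(pgc@pnmax, 0)
  expect_equal(pgc@peakPeriod, min(pgc@period))

  expect_error(lombScargle(mkProfile(c(-1000, 1000) * 10, c(0.1, 0.2)), cfg),
               "non-missing points")
})

test_that("periodogram matches a DFT oracle on complete uniform profiles", {
  set.seed(22)
  n <- 128L
  dt <- 500
  t <- (0:(n - 1)) * dt                       # one-sided uniform lag grid
  y <- runif(n, -0.95, 0.95)
  kset <- 2:12                                # Fourier indices, 2k < n
  freqs <- kset / (n * dt)
  cfg <- scanConfig(minLag = 0, fold = FALSE)
  pg <- lombScargle(mkProfile(t, y), cfg, frequencies = freqs)
  oracle <- dftPeriodogram(y, dt, kset)
  expect_equal(pg@power, oracle, tolerance = 1e-6)
})

test_that("peak significance reproduces the PNmax threshold arithmetic", {
  # z = 10, M = 50: p = 1 - (1 - e^-10)^50, evaluated directly
  sig <- peakSignificance(10, nFreqs = 200, oversampling = 4,
                          method = "horne")
  expect_equal(sig$pValue, 1 - (1 - exp(-10))^50, tolerance = 1e-12)
  expect_equal(sig$pnmax, -log(sig$pValue))
  expect_equal(sig$pnmax, 6.089, tolerance = 1e-3)

  # p = 1 maps to pnmax = 0
  expect_equal(peakSignificance(0, 100, 4, method = "horne")$pnmax, 0)
  expect_equal(peakSignificance(0, 100, 4, method = "baluev",
                                bandwidth = 1e-4, teff = 2e5)$pnmax, 0)

  # strictly decreasing p in peak power, for both methods
  z <- seq(0.5, 30, by = 0.5)
  for (m in c("horne", "baluev")) {
    p <- vapply(z, function(zz)
      peakSignificance(zz, 100, 4, method = m,
                       bandwidth = 1e-4, teff = 2e5)$pValue, numeric(1))
    expect_true(all(diff(p) < 0))
  }

  # pnmax at p = 0.05 is -ln(0.05) ~ 2.996 regardless of method
  # (solve horne for the z giving p = 0.05, then check the log arithmetic)
  f <- function(z) peakSignificance(z, 100, 4, method = "horne")$pValue - 0.05
  zstar <- uniroot(f, c(1, 20))$root
  pn <- peakSignificance(zstar, 100, 4, method = "horne")$pnmax
  expect_gt(pn, 2.9); expect_lt(pn, 3.1)

  # extreme power: p clipped, pnmax finite
  expect_lte(peakSignificance(1e4, 100, 4)$pnmax, -log(1e-300) + 1)
})

test_that("scanGenome maps a planted period at window centres", {
  set.seed(23)
  truth <- makeTruth(400000, 1, 30000, seed = 23)
  b <- simulateExpression(truth, noiseSd = 0.15, seed = 123)
  x <- bundleExpression(b)
  band <- correlationBand(x, 100000)
  cfg <- scanConfig(window = 200000, slide = 25000, periodMax = 50000,
                    maxLag = 100000)
  sc <- scanGenome(band, cfg)
  expect_equal(nrow(sc), 16L)                        # 400k/25k circular
  expect_equal(diff(sc$center)[1], 25000)
  step <- periodGridStep(30000, 100000 - cfg$minLag)
  expect_gt(mean(abs(sc$peakPeriod - 30000) < step * 1.5), 0.85)
  expect_true(all(sc$pnmax >= 0))

  # all-masked input: every window skipped
  V <- fpmValues(x); V[] <- NA_real_
  xm <- makeExpr(matrix(rnorm(800 * 5), 800, 5), mask = rep(TRUE, 800))
  bandm <- suppressWarnings(correlationBand(xm, 100000))
  scm <- scanGenome(bandm, cfg)
  expect_equal(nrow(scm), 0L)
  expect_gt(nrow(attr(scm, "skipped")), 0L)
})

test_that("randomizationNull permutes positions and pools window PNmax", {
  set.seed(24)
  V <- matrix(rnorm(400 * 5), 400, 5)
  x <- makeExpr(V)
  cfg <- scanConfig(window = 100000, slide = 50000, periodMax = 40000,
                    maxLag = 50000, seed = 5)
  null <- randomizationNull(x, cfg, nRandomizations = 3)
  expect_s3_class(null, "PNmaxNull")
  expect_equal(length(null$windowsPerReplicate), 3L)
  expect_equal(length(null$pnmax), sum(null$windowsPerReplicate))
  expect_true(all(null$pnmax >= 0))

  # deterministic under the same seed
  null2 <- randomizationNull(x, cfg, nRandomizations = 3)
  expect_identical(null$pnmax, null2$pnmax)

  # quantile helpers are consistent
  q95 <- nullQuantile(null, 0.95)
  expect_gte(nullExceedance(null, q95 + 1), 0.95)

  expect_error(randomizationNull(x, scanConfig(seed = NULL)), "seed")
})
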