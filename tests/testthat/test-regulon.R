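test_that("betweenSites places circular midpoints toward the clockwise successor", {
  expect_equal(sort(betweenSites(c(1000, 3000), 10000)), c(2000, 7000))

  # equally spaced sites: mocks equally spaced, offset by half the spacing
  sites <- seq(0, 9000, by = 1000)
  mocks <- betweenSites(sites, 10000)
  expect_equal(sort(mocks), sites + 500)

  # cardinality always preserved
  set.seed(41)
  s <- sort(sample(0:99999, 17))
  expect_equal(length(betweenSites(s, 100000)), 17L)

  # rotation equivariance (mod genome length)
  d <- 12345
  m1 <- sort((betweenSites(s, 100000) + d) %% 100000)
  m2 <- sort(betweenSites((s + d) %% 100000, 100000))
  expect_equal(m1, m2)

  expect_error(betweenSites(5, 1000), ">= 2 sites")
})

test_that("parseTargets applies the > 20 at-bin retention threshold", {
  g <- binGrid(200000, 500)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "targets.tsv")
  # widely spaced targets at bin midpoints: each claims exactly 3 bins
  pos7 <- (0:6) * 10000 + 5250      # 7 x 3 = 21 bins -> retained
  pos6 <- (0:5) * 10000 + 105250    # 6 x 3 = 18 bins
  pos6 <- c(pos6, 105300)           # overlapping window: union unchanged
  df <- rbind(data.frame(regulator = "keep", target_position = pos7),
              data.frame(regulator = "drop", target_position = pos6))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  regs <- suppressMessages(parseTargets(f, g))
  expect_named(regs, "keep")
  expect_equal(length(regs$keep$atBins), 21L)

  # overlapping flanks: union of bins counted once
  expect_equal(targetBins(c(5250, 5350), g, flank = 500),
               targetBins(5250, g, flank = 500 + 100))
})

test_that("gene-name targets resolve through the annotation 5' start", {
  g <- binGrid(50000, 500)
  ann <- c(makeGenes(c(1000, 30000), c(2000, 31000), c("+", "-"),
                     name = c("araC", "lacZ")))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "tf.tsv")
  write.table(data.frame(TF = rep("crp", 25),
                         gene = rep(c("araC", "lacZ", "ghost"),
                                    length.out = 25)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  regs <- suppressMessages(parseTargets(f, g, ann, minBins = 2))
  expect_equal(regs$crp$positions, c(1000, 30999))   # 5' ends
  expect_error(suppressMessages(
    parseTargets(f, g, NULL)), "annotation required")
})

test_that("subset distributions partition the band pairs", {
  set.seed(42)
  V <- matrix(rnorm(100 * 5), 100, 5)
  x <- makeExpr(V)
  band <- correlationBand(x, 10000)
  targets <- structure(list(regulator = "tf", flank = 500,
                            positions = c(10250, 20250, 30250),
                            atBins = targetBins(c(10250, 20250, 30250),
                                                binGrid(x), 500)),
                       class = "RegulatorTargets")
  sd_ <- subsetDistributions(band, targets, nRandom = 5, seed = 9)
  expect_setequal(names(sd_$distributions),
                  c("At", "Between", "Random", "Without"))

  # At + pairs-touching partition: |Without| + |touching| = all band pairs
  r <- bandValues(band)
  pos <- band@offsets > 0
  total <- sum(is.finite(r[, pos]))
  touch <- logical(100); touch[targets$atBins] <- TRUE
  n_touch <- 0
  for (o in band@offsets[pos]) {
    j <- ((seq_len(100) - 1 + o) %% 100) + 1
    n_touch <- n_touch + sum((touch | touch[j]) &
                             is.finite(r[, as.character(o * 500)]))
  }
  expect_equal(length(sd_$distributions$Without), total - n_touch)

  # Random draws are size-exact per replicate and seed-deterministic
  sd2 <- subsetDistributions(band, targets, nRandom = 5, seed = 9)
  expect_identical(sd_$distributions$Random, sd2$distributions$Random)
  expect_equal(length(sd_$randomMeans), 5L)

  expect_error(subsetDistributions(band, structure(list(
    regulator = "x", flank = 500, positions = 1,
    atBins = integer(0)), class = "RegulatorTargets")), "at-bins")
})

test_that("exclusion re-profiling is identity for an empty set and errors when too few bins survive", {
  set.seed(43)
  V <- matrix(rnorm(200 * 5), 200, 5)
  x <- makeExpr(V)
  band <- correlationBand(x, 20000)
  cfg <- scanConfig(window = 50000, periodMin = 5000, periodMax = 20000,
                    maxLag = 20000, minLag = 2000)
  ex <- exclusionReprofile(band, c(0, 100000), integer(0), cfg)
  expect_equal(ex$full$profile@meanR, ex$excluded$profile@meanR)
  expect_equal(ex$deltaPeriod, 0)
  expect_equal(ex$deltaPNmax, 0)

  expect_error(exclusionReprofile(band, c(0, 5000), 1:100, cfg),
               "survive")
})
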