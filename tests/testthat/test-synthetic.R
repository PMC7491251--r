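test_that("makeTruth constructs a deterministic, well-formed world", {
  t1 <- makeTruth(1e6, 1, 40000, seed = 7)
  expect_equal(nrow(t1@regions), 1L)
  expect_equal(t1@regions$period, 40000)
  expect_equal(t1@regions$start, 0)
  expect_equal(t1@regions$end, 1e6)

  # identical call, identical truth
  t2 <- makeTruth(1e6, 1, 40000, seed = 7)
  expect_identical(t1@operons, t2@operons)
  expect_identical(t1@regulators, t2@regulators)

  # sizing error: 100 kbp cannot hold 4 x 70 kbp
  expect_error(makeTruth(100000, 1, 70000, seed = 1), "4 periods")

  # intervals inside the genome; regions non-overlapping
  t3 <- makeTruth(1.2e6, 3, c(24000, 42000), seed = 9)
  expect_equal(t3@regions$period, c(24000, 42000, 24000))
  expect_true(all(t3@operons$start >= 0 & t3@operons$end <= 1.2e6))
  expect_true(all(t3@regions$start[-1] >= t3@regions$end[-3]))
  expect_true(validObject(t3))

  # anchors are spaced by the planted period inside the region
  a <- anchorPositions(t3, 2)
  expect_equal(unique(diff(a)), 42000)
  expect_true(all(a >= t3@regions$start[2] & a < t3@regions$end[2]))
})

test_that("zero-noise expression is rank-1 in log space at anchor bins", {
  truth <- makeTruth(100000, 1, 20000, seed = 3, withRegulators = FALSE,
                     operonMeanGap = 1e9)   # no operons: per-bin groups
  b <- simulateExpression(truth, nPhases = 5, nReplicates = 1, noiseSd = 0,
                          countModel = "expected", seed = 5)
  x <- bundleExpression(b)
  V <- fpmValues(x)
  # bins one anchor apart carry identical kernel weight: r exactly 1
  i <- 3; j <- i + 40    # 20000 / 500 bins apart, same in-anchor phase
  expect_equal(cor(V[i, ], V[j, ]), 1, tolerance = 1e-10)

  # opposite-sign coupling: strong anti-correlation in log space (the
  # per-sample library total is itself a nonlinear function of the shared
  # factor, so -1 is approached, not attained, after FPM normalisation)
  ba <- simulateExpression(truth, nPhases = 5, nReplicates = 1, noiseSd = 0,
                           countModel = "expected", alternateSign = TRUE,
                           seed = 5)
  Va <- fpmValues(bundleExpression(ba))
  expect_lt(cor(log(Va[i, ]), log(Va[j, ])), -0.95)

  expect_error(simulateExpression(truth, nPhases = 2), "nPhases")
  expect_error(simulateExpression(truth, noiseSd = -1), "noiseSd")
})

test_that("simulated counts honour the design and the structural-RNA inflation", {
  truth <- makeTruth(200000, 1, 25000, seed = 4)
  b <- simulateExpression(truth, nPhases = 4, nReplicates = 2, seed = 8)
  expect_equal(ncol(rawCounts(b)), 8L)
  expect_equal(nrow(sampleDesign(b)), 8L)
  expect_equal(length(unique(sampleDesign(b)$phase)), 4L)
  expect_true(all(rawCounts(b) >= 0))

  # seed determinism
  b2 <- simulateExpression(truth, nPhases = 4, nReplicates = 2, seed = 8)
  expect_identical(rawCounts(b), rawCounts(b2))

  # structural-RNA bins are conspicuously inflated before masking
  sr <- truth@structuralRNA
  g <- binGrid(b)
  centers <- binStarts(g) + 250
  hot <- which(centers >= sr$start[1] & centers < sr$end[1])
  cold <- setdiff(seq_len(nBins(g)), hot)
  expect_gt(mean(rawCounts(b)[hot, 1]), 10 * mean(rawCounts(b)[cold, 1]))

  # ... and masked by the pipeline
  x <- bundleExpression(b)
  expect_true(all(maskedBins(x)[hot]))
})

test_that("simulated contacts decay with distance, stay symmetric, and boost anchors", {
  truth <- makeTruth(200000, 1, 25000, seed = 5)
  cm <- simulateContacts(truth, binWidth = 5000, decayExponent = 1,
                         couplingBoost = 1, seed = 6)
  f <- contactValues(cm)
  expect_equal(f, t(f))
  expect_true(all(f >= 0))
  expect_true(all(diag(f) == 0))
  # monotone-ish decay: mean at 10 kbp exceeds mean at 50 kbp
  g <- binGrid(cm)
  n <- nBins(g)
  d <- abs(outer(binStarts(g), binStarts(g), "-"))
  d <- pmin(d, 200000 - d)
  expect_gt(mean(f[d == 10000]), mean(f[d == 50000]))

  # seed determinism and boost effect on anchor pairs
  cm2 <- simulateContacts(truth, binWidth = 5000, decayExponent = 1,
                          couplingBoost = 1, seed = 6)
  expect_identical(contactValues(cm2), f)
  cmb <- simulateContacts(truth, binWidth = 5000, couplingBoost = 5, seed = 6)
  ab <- unique(floor(anchorPositions(truth, 1) / 5000) + 1)
  expect_equal(contactValues(cmb)[ab[1], ab[2]] / f[ab[1], ab[2]], 5)

  expect_error(simulateContacts(truth, decayExponent = 0), "positive")
})

test_that("fixtures round-trip bit-identically through the readers", {
  truth <- makeTruth(100000, 1, 20000, seed = 11)
  b <- simulateExpression(truth, nPhases = 3, nReplicates = 2, seed = 12)
  b <- setContacts(b, simulateContacts(truth, binWidth = 5000, seed = 13))
  dir <- withr::local_tempdir()
  paths <- writeFixtures(b, dir, bedGraph = TRUE)

  # counts
  m <- readCountsTSV(paths$counts)
  expect_equal(as.vector(m), as.vector(rawCounts(b)))
  expect_equal(colnames(m), sampleDesign(b)$sample)
  expect_equal(attr(m, "binStart"), binStarts(binGrid(b)))

  # design
  expect_equal(readDesignTSV(paths$design), sampleDesign(b))

  # annotation strands match the truth operons
  ann <- rtracklayer::import(paths$annotation)
  genes <- ann[ann$type == "gene"]
  expect_equal(as.character(GenomicRanges::strand(genes)),
               b@truth@operons$strand)
  expect_equal(GenomicRanges::start(genes), b@truth@operons$start + 1)

  # regulator TSV row count equals the total number of targets
  rt <- read.delim(paths$regulators)
  expect_equal(nrow(rt), sum(lengths(b@truth@regulators)))

  # contacts round-trip
  cm <- readContactsTSV(paths$contacts, binGrid(b@contacts))
  expect_equal(contactValues(cm), contactValues(b@contacts))

  # bedGraph round-trips through countBins
  s1 <- sampleDesign(b)$sample[1]
  counts1 <- countBins(paths[[paste0("bedgraph_", s1)]], binGrid(b),
                       format = "bedgraph")
  expect_equal(counts1, unname(rawCounts(b)[, 1]))

  # byte-identical rewrite under the same seed
  dir2 <- withr::local_tempdir()
  b3 <- simulateExpression(truth, nPhases = 3, nReplicates = 2, seed = 12)
  b3 <- setContacts(b3, simulateContacts(truth, binWidth = 5000, seed = 13))
  paths2 <- writeFixtures(b3, dir2, bedGraph = TRUE)
  expect_equal(unname(tools::md5sum(paths$counts)),
               unname(tools::md5sum(paths2$counts)))
  expect_equal(unname(tools::md5sum(paths$annotation)),
               unname(tools::md5sum(paths2$annotation)))
})
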