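test_that("binGrid tiles the genome and does circular lag arithmetic", {
  g <- binGrid(10000, 500)
  expect_equal(nBins(g), 20L)
  expect_equal(binStarts(g)[1:3], c(0, 500, 1000))

  # sliding grid: 1000 bp bins every 500 bp
  gs <- binGrid(10000, 1000, 500)
  expect_equal(nBins(gs), 20L)
  expect_equal(gs@binWidth, 1000)

  # signed wrap minimality: bin 1 -> bin 20 is -500, not +9500
  expect_equal(binLag(g, 1, 20), -500)
  expect_equal(binLag(g, 20, 1), 500)

  # antisymmetry and wrap bound over random pairs
  set.seed(1)
  i <- sample(20, 50, TRUE); j <- sample(20, 50, TRUE)
  lag <- binLag(g, i, j)
  half <- abs(lag) == 5000      # antipodal bins: +L/2 by convention
  expect_equal(lag[!half], -binLag(g, j, i)[!half])
  expect_true(all(abs(lag) <= 5000))

  # linear grid: plain difference
  gl <- binGrid(10000, 500, circular = FALSE)
  expect_equal(binLag(gl, 1, 20), 9500)

  expect_error(binGrid(10000, -1), "positive")
  expect_error(binGrid(10000, 500, 600), "step")
  expect_error(binGrid(100, 500), "genome length")
})

test_that("countBins assigns fragments by midpoint from BAM and bedGraph", {
  skip_if_not_installed("Rsamtools")
  g <- binGrid(10000, 500)
  dir <- withr::local_tempdir()

  # single-end reads of length 100: midpoint = pos0 + 50
  sam <- file.path(dir, "toy.sam")
  reads <- data.frame(pos1 = c(701, 701, 2951))  # mids 750, 750, 3000
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             "@SQ\tSN:genome\tLN:10000",
             sprintf("r%d\t0\tgenome\t%d\t60\t100M\t*\t0\t0\t%s\t*",
                     seq_len(nrow(reads)), reads$pos1,
                     strrep("A", 100)))
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE)
  counts <- countBins(bam, g)
  expect_equal(sum(counts), 3L)
  expect_equal(counts[2], 2L)   # bin [500, 1000) holds the two mids at 750
  expect_equal(counts[7], 1L)   # bin [3000, 3500) holds the mid at 3000

  # genome-length mismatch is named
  expect_error(countBins(bam, binGrid(9000, 500)), "9000")

  # bedGraph path with per-base midpoint counts reproduces the BAM counts
  bg <- file.path(dir, "toy.bedgraph")
  df <- data.frame(chrom = "genome", start = (0:19) * 500,
                   end = (1:20) * 500, value = counts / 500)
  write.table(df, bg, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_equal(countBins(bg, g, format = "bedgraph"), counts)

  # empty input -> zeros
  empty_sam <- file.path(dir, "empty.sam")
  writeLines(lines[1:2], empty_sam)
  empty_bam <- Rsamtools::asBam(empty_sam, file.path(dir, "empty"),
                                overwrite = TRUE)
  expect_equal(countBins(empty_bam, g), integer(20))
})

test_that("paired-end fragments are counted once, by fragment midpoint", {
  g <- binGrid(10000, 500)
  dir <- withr::local_tempdir()
  # one proper pair: fragment [1001, 1400] -> midpoint 1200 -> bin 3
  sam <- file.path(dir, "pe.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:genome\tLN:10000",
    sprintf("p1\t99\tgenome\t1001\t60\t100M\t=\t1301\t400\t%s\t*", strrep("A", 100)),
    sprintf("p1\t147\tgenome\t1301\t60\t100M\t=\t1001\t-400\t%s\t*", strrep("A", 100))
  ), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "pe"), overwrite = TRUE)
  counts <- countBins(bam, g)
  expect_equal(sum(counts), 1L)
  expect_equal(counts[3], 1L)
})

test_that("structural-RNA masking follows the >= 1 bp overlap rule", {
  g <- binGrid(10000, 500)
  # tRNA on [600, 680): only bin 2
  ann <- makeGenes(600, 680, "+", type = "tRNA")
  expect_equal(which(maskStructuralRNA(ann, g)), 2L)
  # rRNA spanning [400, 1100): bins 1-3
  ann <- makeGenes(400, 1100, "+", type = "rRNA")
  expect_equal(which(maskStructuralRNA(ann, g)), 1:3)
  # CDS only: nothing masked, with a warning
  ann <- makeGenes(400, 1100, "+", type = "CDS")
  expect_warning(m <- maskStructuralRNA(ann, g), "no features")
  expect_false(any(m))
  # record order does not matter
  ann2 <- c(makeGenes(5000, 5100, "+", type = "tRNA"),
            makeGenes(400, 1100, "+", type = "rRNA"))
  expect_equal(maskStructuralRNA(ann2, g),
               maskStructuralRNA(rev(ann2), g))
})

test_that("FPM normalisation and replicate averaging follow the scale rules", {
  g <- binGrid(1000, 500)
  design1 <- data.frame(sample = "s1", phase = "P1", replicate = 1L)
  x <- normalizeAndAverage(matrix(c(2, 8), 2, 1), c(FALSE, FALSE), design1, g)
  expect_equal(as.numeric(fpmValues(x)), c(200000, 800000))

  # replicates [100, 300] FPM -> 200 (two samples engineered to those FPM)
  design2 <- data.frame(sample = c("a", "b"), phase = "P1", replicate = 1:2)
  x <- normalizeAndAverage(matrix(c(1, 9, 3, 7), 2, 2), c(FALSE, FALSE),
                           design2, g)
  expect_equal(unname(fpmValues(x)[1, 1]), (1e5 + 3e5) / 2)

  # masked bin excluded from the per-million denominator
  g3 <- binGrid(1500, 500)
  design1b <- data.frame(sample = "s1", phase = "P1", replicate = 1L)
  x <- normalizeAndAverage(matrix(c(90, 2, 8), 3, 1), c(TRUE, FALSE, FALSE),
                           design1b, g3)
  expect_equal(as.numeric(fpmValues(x)), c(NA, 200000, 800000))
  # ... and included when asked
  xi <- normalizeAndAverage(matrix(c(90, 2, 8), 3, 1), c(TRUE, FALSE, FALSE),
                            design1b, g3, maskDenominator = "include")
  expect_equal(as.numeric(fpmValues(xi)), c(NA, 20000, 80000))

  # zero unmasked counts is an error
  expect_error(normalizeAndAverage(matrix(c(5, 0), 2, 1), c(TRUE, FALSE),
                                   design1, g), "zero counts")

  # property: unmasked FPM sums to 1e6 per condition
  set.seed(2)
  g20 <- binGrid(10000, 500)
  counts <- matrix(rpois(20 * 4, 50), 20, 4)
  mask <- rep(c(TRUE, FALSE), c(3, 17))
  design <- data.frame(sample = letters[1:4],
                       phase = rep(c("P1", "P2"), each = 2),
                       replicate = rep(1:2, 2))
  x <- normalizeAndAverage(counts, mask, design, g20)
  sums <- colSums(fpmValues(x), na.rm = TRUE)
  expect_equal(unname(sums), rep(1e6, 2), tolerance = 1e-9)
})

test_that("rebinExpression sums raw counts and propagates the mask", {
  g <- binGrid(10000, 500)
  counts <- matrix(1, 20, 3)
  mask <- rep(FALSE, 20); mask[4] <- TRUE
  design <- data.frame(sample = paste0("s", 1:3), phase = paste0("P", 1:3),
                       replicate = 1L)
  x <- normalizeAndAverage(counts, mask, design, g)
  x5k <- rebinExpression(x, 5000)
  expect_equal(nBins(binGrid(x5k)), 2L)
  expect_equal(as.numeric(rawCounts(x5k)[1, ]), rep(10, 3)) # ten 1-count bins
  expect_true(maskedBins(x5k)[1])                       # mask propagates
  expect_false(maskedBins(x5k)[2])

  # identity re-bin
  expect_equal(fpmValues(rebinExpression(x, 500)), fpmValues(x))
  expect_error(rebinExpression(x, 750), "multiple")
})

test_that("the expression matrix serialises with mask and phase columns", {
  g <- binGrid(2000, 500)
  design <- data.frame(sample = c("a", "b"), phase = c("P1", "P2"),
                       replicate = 1L)
  x <- normalizeAndAverage(matrix(1:8, 4, 2), c(TRUE, FALSE, FALSE, FALSE),
                           design, g)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTSV(x, path)
  df <- read.delim(path)
  expect_equal(names(df), c("bin_start", "bin_end", "mask", "P1", "P2"))
  expect_true(df$mask[1] && is.na(df$P1[1]))
  expect_equal(df$P1[-1], unname(fpmValues(x)[-1, "P1"]))
})
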