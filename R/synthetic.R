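#' Construct the ground truth of a synthetic genome
#'
#' Divides a circular genome of `genomeLength` bp into `nRegions` equal
#' contiguous regions, each coupled to one latent expression factor whose
#' anchors are spaced `period` bp apart (periods drawn in order from
#' `periodChoices`, recycled). Operon blocks with strands, structural-RNA
#' intervals and regulator target maps are laid down alongside. All
#' draws are governed by `seed`; identical calls yield identical truths.
#'
#' @param genomeLength genome length in bp; each region must hold at
#'   least four periods (sizing error otherwise).
#' @param nRegions number of coupled regions (default 1: a single
#'   genome-wide period).
#' @param periodChoices planted period(s) in bp, recycled over regions.
#' @param seed integer seed.
#' @param amplitude coupling amplitude(s), recycled over regions
#'   (default 1; 0 plants pure noise).
#' @param operonMeanLength,operonMeanGap mean operon length / intergenic
#'   gap in bp (defaults 3,000 and 2,000 — E. coli-like operon cover).
#' @param nStructuralRNA number of structural-RNA intervals (default
#'   scales as one per 700 kbp, the E. coli rRNA-operon density).
#' @param structuralWidth width of each structural-RNA interval
#'   (default 5,000 bp, an rRNA operon).
#' @param withRegulators also generate regulator target maps: `regA`
#'   (targets at region-1 anchors: genuinely co-expressed), `regB`
#'   (uniform targets: null), `regC` (5 targets: below the 20-bin
#'   analysis threshold).
#' @return a [SyntheticTruth-class].
#' @export
makeTruth <- function(genomeLength, nRegions = 1, periodChoices, seed,
                      amplitude = 1,
                      operonMeanLength = 3000, operonMeanGap = 2000,
                      nStructuralRNA = max(1L, round(genomeLength / 7e5)),
                      structuralWidth = 5000, withRegulators = TRUE) {
  stopifnot(length(periodChoices) >= 1, nRegions >= 1)
  segL <- floor(genomeLength / nRegions)
  periods <- rep_len(periodChoices, nRegions)
  amps <- rep_len(amplitude, nRegions)
  if (any(segL < 4 * periods))
    stop("genome too short: each of ", nRegions, " regions spans ", segL,
         " bp but must hold >= 4 periods (max requested ", max(periods), " bp)")
  truth <- NULL
  .withSeed(seed, {
    regions <- data.frame(
      start = (seq_len(nRegions) - 1) * segL,
      end = c((seq_len(nRegions - 1)) * segL, genomeLength)[seq_len(nRegions)],
      period = periods, amplitude = amps)
    if (nRegions == 1) regions$end <- genomeLength

    # operons: alternating gap/block walk along the genome
    op_start <- numeric(0); op_end <- numeric(0)
    pos <- rexp(1, 1 / operonMeanGap)
    while (TRUE) {
      len <- min(max(500, rgamma(1, shape = 2, scale = operonMeanLength / 2)),
                 15000)
      if (pos + len >= genomeLength) break
      op_start <- c(op_start, round(pos))
      op_end <- c(op_end, round(pos + len))
      pos <- pos + len + rexp(1, 1 / operonMeanGap)
    }
    operons <- data.frame(start = op_start, end = op_end,
                          strand = sample(c("+", "-"), length(op_start),
                                          replace = TRUE))

    # structural RNA: non-overlapping intervals by rejection
    srna <- numeric(0)
    tries <- 0
    while (length(srna) < nStructuralRNA && tries < 1000) {
      cand <- round(runif(1, 0, genomeLength - structuralWidth))
      if (!length(srna) ||
          all(abs(cand - srna) >= 2 * structuralWidth)) srna <- c(srna, cand)
      tries <- tries + 1
    }
    structuralRNA <- data.frame(start = sort(srna),
                                end = sort(srna) + structuralWidth)

    regulators <- list()
    if (withRegulators) {
      anchors1 <- .anchorPositions(regions$start[1], regions$end[1],
                                   regions$period[1])
      regulators$regA <- sort(sample(anchors1, min(30, length(anchors1)),
                                     replace = length(anchors1) < 30))
      regulators$regB <- sort(round(runif(30, 0, genomeLength - 1)))
      regulators$regC <- sort(round(runif(5, 0, genomeLength - 1)))
    }
    truth <- new("SyntheticTruth", genomeLength = as.numeric(genomeLength),
                 regions = regions, operons = operons,
                 structuralRNA = structuralRNA, regulators = regulators,
                 seed = as.integer(seed))
  })
  truth
}

.anchorPositions <- function(start, end, period) {
  seq(start, end - 1, by = period)
}

#' Anchor positions of a region's factor family
#' @param truth a [SyntheticTruth-class].
#' @param region region index (row of `truth@regions`).
#' @return anchor positions in bp.
#' @export
anchorPositions <- function(truth, region = 1) {
  stopifnot(is(truth, "SyntheticTruth"), region <= nrow(truth@regions))
  rg <- truth@regions[region, ]
  .anchorPositions(rg$start, rg$end, rg$period)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %s bp, %d region(s) with period(s) %s bp, ",
                     "%d operons, %d structural-RNA intervals, %d regulators\n"),
              format(object@genomeLength, big.mark = ","),
              nrow(object@regions),
              paste(unique(object@regions$period), collapse = "/"),
              nrow(object@operons), nrow(object@structuralRNA),
              length(object@regulators)))
})

#' Simulate binned expression from a synthetic truth
#'
#' Generative model, per bin `b` and sample `(phase p, replicate)`:
#' `log mu = baseline_g + a_k * w(b, k) * f(k, p) + eps`, where `g` is
#' the bin's signal group (all bins of an operon share one group, hence
#' one signal), `w(b, k)` is a triangular kernel of the distance from the
#' bin centre to the nearest anchor of region `k`'s factor family
#' (half-width `kernelHalfWidth`, default `period/2`, so the averaged
#' correlation-vs-lag profile is a smooth wave with the planted period),
#' `f(k, p) ~ N(0, 1)` is the phase-varying factor shared between
#' replicates, and `eps ~ N(0, noiseSd)` is drawn per (bin, phase,
#' replicate) — operon members share the deterministic signal, not the
#' noise. Structural-RNA bins get 100x inflated intensity (so a
#' masking failure is loud), intensities are scaled to `librarySize`
#' per sample, and counts are Poisson (`countModel = "expected"` returns
#' the continuous intensities, for analytic oracles).
#'
#' @param truth a [SyntheticTruth-class].
#' @param nPhases number of growth phases (>= 3; default 5).
#' @param nReplicates replicates per phase (default 2).
#' @param noiseSd sd of the per-(group, phase, replicate) log-normal
#'   noise (default 0.2).
#' @param librarySize expected fragments per sample (default 2e6).
#' @param binWidth simulation bin width in bp (default 500).
#' @param kernelHalfWidth triangular kernel half-width in bp; default
#'   `period/2` per region (a value of `binWidth` restricts the signal
#'   to anchor bins only).
#' @param countModel `"poisson"` (default) or `"expected"`.
#' @param alternateSign if `TRUE`, successive anchors of a family couple
#'   with alternating sign (yields correlation -1 between odd/even
#'   anchor bins at zero noise).
#' @param seed integer seed (default `truth@seed + 1`).
#' @return a [SyntheticBundle-class].
#' @export
simulateExpression <- function(truth, nPhases = 5, nReplicates = 2,
                               noiseSd = 0.2, librarySize = 2e6,
                               binWidth = 500, kernelHalfWidth = NULL,
                               countModel = c("poisson", "expected"),
                               alternateSign = FALSE,
                               seed = truth@seed + 1L) {
  countModel <- match.arg(countModel)
  stopifnot(is(truth, "SyntheticTruth"))
  if (nPhases < 3)
    stop("nPhases must be >= 3 (correlation over phases needs >= 3 points)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  L <- truth@genomeLength
  grid <- binGrid(L, binWidth, binWidth, circular = TRUE)
  n <- grid@nBins
  centers <- binStarts(grid) + binWidth / 2
  rg <- truth@regions
  nFam <- nrow(rg)

  # signal groups: operon membership by bin centre
  group <- seq_len(n)
  if (nrow(truth@operons)) {
    for (i in seq_len(nrow(truth@operons))) {
      inside <- centers >= truth@operons$start[i] &
                centers < truth@operons$end[i]
      group[inside] <- n + i
    }
  }
  ugroup <- match(group, unique(group))
  nGroups <- max(ugroup)
  # group representative centre (operon midpoint for operon groups)
  repCenter <- tapply(centers, ugroup, mean)[seq_len(nGroups)]

  # triangular anchor-distance weights per family, at group representatives
  W <- matrix(0, nGroups, nFam)
  SGN <- matrix(1, nGroups, nFam)
  for (k in seq_len(nFam)) {
    P <- rg$period[k]
    h <- if (is.null(kernelHalfWidth)) P / 2 else kernelHalfWidth
    inside <- repCenter >= rg$start[k] & repCenter < rg$end[k]
    phase <- (repCenter - rg$start[k]) %% P
    d <- pmin(phase, P - phase)
    w <- pmax(0, 1 - d / h)
    w[!inside] <- 0
    W[, k] <- w
    if (alternateSign)
      SGN[, k] <- (-1)^(round((repCenter - rg$start[k]) / P))
  }

  design <- data.frame(
    sample = paste0("P", rep(seq_len(nPhases), each = nReplicates),
                    "R", rep(seq_len(nReplicates), nPhases)),
    phase = paste0("P", rep(seq_len(nPhases), each = nReplicates)),
    replicate = rep(seq_len(nReplicates), nPhases),
    stringsAsFactors = FALSE)
  nSamples <- nrow(design)

  counts <- NULL
  .withSeed(seed, {
    baseline <- rnorm(nGroups, 0, 0.5)
    f <- matrix(rnorm(nFam * nPhases), nFam, nPhases)
    # shared *signal* per group (operon co-transcription); noise is per bin
    logmu_g <- matrix(baseline, nGroups, nSamples)
    for (s in seq_len(nSamples)) {
      p <- rep(seq_len(nPhases), each = nReplicates)[s]
      coupling <- as.vector((W * SGN) %*% (rg$amplitude * f[, p]))
      logmu_g[, s] <- logmu_g[, s] + coupling
    }
    logmu <- logmu_g[ugroup, , drop = FALSE]
    if (noiseSd > 0)
      logmu <- logmu + matrix(rnorm(length(logmu), 0, noiseSd),
                              nrow(logmu), ncol(logmu))
    mu <- exp(logmu)
    if (nrow(truth@structuralRNA)) {
      for (i in seq_len(nrow(truth@structuralRNA))) {
        hit <- centers >= truth@structuralRNA$start[i] &
               centers < truth@structuralRNA$end[i]
        mu[hit, ] <- mu[hit, ] * 100
      }
    }
    lambda <- sweep(mu, 2, colSums(mu), "/") * librarySize
    counts <- if (countModel == "poisson")
      matrix(rpois(length(lambda), lambda), n, nSamples)
    else lambda
  })
  colnames(counts) <- design$sample

  annotation <- .truthAnnotation(truth)
  new("SyntheticBundle", truth = truth, grid = grid,
      counts = counts, design = design, annotation = annotation,
      contacts = NULL)
}

.truthAnnotation <- function(truth) {
  parts <- list()
  if (nrow(truth@operons)) {
    op <- truth@operons
    parts$genes <- GenomicRanges::GRanges("genome",
      IRanges::IRanges(start = op$start + 1, end = op$end),
      strand = op$strand, type = "gene",
      Name = paste0("op", seq_len(nrow(op))))
  }
  if (nrow(truth@structuralRNA)) {
    sr <- truth@structuralRNA
    parts$rrna <- GenomicRanges::GRanges("genome",
      IRanges::IRanges(start = sr$start + 1, end = sr$end),
      strand = "+", type = "rRNA",
      Name = paste0("rrn", seq_len(nrow(sr))))
  }
  gr <- if (length(parts)) suppressWarnings(do.call(c, unname(parts)))
        else GenomicRanges::GRanges()
  GenomeInfoDb::seqlengths(gr) <- c(genome = truth@genomeLength)
  gr
}

#' Simulate a distance-decay contact matrix coupled to the truth
#'
#' Baseline contact between coarse bins decays as a power law of their
#' circular distance, `(d / binWidth)^(-decayExponent)`; pairs of bins
#' that each contain an anchor of the same factor family have their
#' contact multiplied by `couplingBoost` (so that spatially "close"
#' pairs are exactly the co-expressed ones); symmetric multiplicative
#' log-normal noise is applied on top.
#'
#' @param truth a [SyntheticTruth-class].
#' @param binWidth contact bin width in bp (default 5,000).
#' @param decayExponent positive power-law exponent (default 1, the
#'   short-range decay regime of bacterial 3C maps).
#' @param couplingBoost multiplier for same-family anchor pairs
#'   (default 1 = null case: contacts depend on distance only).
#' @param noiseSd sd of the log-normal contact noise (default 0.1).
#' @param seed integer seed (default `truth@seed + 2`).
#' @return a [ContactMatrix-class].
#' @export
simulateContacts <- function(truth, binWidth = 5000, decayExponent = 1,
                             couplingBoost = 1, noiseSd = 0.1,
                             seed = truth@seed + 2L) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (decayExponent <= 0) stop("decayExponent must be positive")
  L <- truth@genomeLength
  grid <- binGrid(L, binWidth, binWidth, circular = TRUE)
  n <- grid@nBins
  s <- binStarts(grid)
  D <- abs(outer(s, s, "-"))
  D <- pmin(D, L - D)
  base <- (pmax(D, binWidth) / binWidth)^(-decayExponent)
  diag(base) <- 0
  if (couplingBoost != 1) {
    for (k in seq_len(nrow(truth@regions))) {
      if (truth@regions$amplitude[k] == 0) next  # no co-expression, no boost
      ab <- unique(floor(anchorPositions(truth, k) / binWidth) + 1)
      ab <- ab[ab >= 1 & ab <= n]
      if (length(ab) >= 2) {
        pairs <- t(combn(ab, 2))
        base[pairs] <- base[pairs] * couplingBoost
        base[pairs[, 2:1, drop = FALSE]] <-
          base[pairs[, 2:1, drop = FALSE]] * couplingBoost
      }
    }
  }
  freq <- NULL
  .withSeed(seed, {
    E <- matrix(1, n, n)
    up <- upper.tri(E)
    E[up] <- exp(rnorm(sum(up), 0, noiseSd))
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
    freq <- base * E
  })
  contactMatrix(freq, grid, normalization = "synthetic")
}

#' @rdname syntheticTruth
#' @export
setMethod("syntheticTruth", "SyntheticBundle", function(x) x@truth)

#' @rdname rawCounts
#' @export
setMethod("rawCounts", "SyntheticBundle", function(x) x@counts)

#' @rdname sampleDesign
#' @export
setMethod("sampleDesign", "SyntheticBundle", function(x) x@design)

#' @rdname binGrid
#' @export
setMethod("binGrid", "SyntheticBundle", function(x, ...) x@grid)

setMethod("show", "SyntheticBundle", function(object) {
  cat(sprintf("SyntheticBundle: %d bins x %d samples (%d phases), contacts: %s\n",
              nrow(object@counts), ncol(object@counts),
              length(unique(object@design$phase)),
              if (is.null(object@contacts)) "none" else "yes"))
})

#' Binned expression of a synthetic bundle through the real pipeline
#'
#' Masks structural-RNA bins from the bundle's annotation and runs
#' [normalizeAndAverage()] — the same code path real data take.
#'
#' @param bundle a [SyntheticBundle-class].
#' @param ... passed to [normalizeAndAverage()].
#' @return a [BinnedExpression-class].
#' @export
bundleExpression <- function(bundle, ...) {
  stopifnot(is(bundle, "SyntheticBundle"))
  mask <- suppressWarnings(
    maskStructuralRNA(bundle@annotation, bundle@grid))
  normalizeAndAverage(bundle@counts, mask, bundle@design, bundle@grid, ...)
}

#' Write a synthetic bundle as plain-text fixtures
#'
#' Emits `counts.tsv` (bin_start, bin_end, one column per sample),
#' `design.tsv`, `annotation.gff3`, `regulators.tsv`
#' (regulator, target_position), `contacts.tsv` (COO, written when the
#' bundle carries contacts) and optionally one bedGraph per sample
#' (per-base midpoint-count scale, i.e. value = count / binWidth, so the
#' bedGraph reader reproduces the counts exactly). All files round-trip
#' through the package readers bit-identically.
#'
#' @param bundle a [SyntheticBundle-class].
#' @param dir output directory (created if needed).
#' @param bedGraph also write per-sample bedGraph tracks.
#' @return invisibly, a named list of file paths.
#' @export
writeFixtures <- function(bundle, dir, bedGraph = FALSE) {
  stopifnot(is(bundle, "SyntheticBundle"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  g <- bundle@grid
  paths <- list()

  cdf <- data.frame(bin_start = binStarts(g),
                    bin_end = binStarts(g) + g@binWidth)
  cdf <- cbind(cdf, as.data.frame(bundle@counts))
  paths$counts <- file.path(dir, "counts.tsv")
  write.table(cdf, paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)

  paths$design <- file.path(dir, "design.tsv")
  write.table(bundle@design, paths$design, sep = "\t", quote = FALSE,
              row.names = FALSE)

  paths$annotation <- file.path(dir, "annotation.gff3")
  rtracklayer::export(bundle@annotation, paths$annotation, format = "gff3")

  regs <- bundle@truth@regulators
  if (length(regs)) {
    rdf <- data.frame(
      regulator = rep(names(regs), lengths(regs)),
      target_position = unlist(regs, use.names = FALSE))
    paths$regulators <- file.path(dir, "regulators.tsv")
    write.table(rdf, paths$regulators, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if (!is.null(bundle@contacts)) {
    f <- contactValues(bundle@contacts)
    idx <- which(upper.tri(f, diag = TRUE) & f != 0, arr.ind = TRUE)
    codf <- data.frame(bin_i = idx[, 1], bin_j = idx[, 2],
                       frequency = f[idx])
    paths$contacts <- file.path(dir, "contacts.tsv")
    write.table(codf, paths$contacts, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if (bedGraph) {
    for (s in seq_len(ncol(bundle@counts))) {
      bg <- data.frame(chrom = "genome",
                       start = format(binStarts(g), scientific = FALSE,
                                      trim = TRUE),
                       end = format(pmin(binStarts(g) + g@binWidth,
                                         g@genomeLength),
                                    scientific = FALSE, trim = TRUE),
                       value = bundle@counts[, s] / g@binWidth)
      p <- file.path(dir, paste0(bundle@design$sample[s], ".bedgraph"))
      write.table(bg, p, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
      paths[[paste0("bedgraph_", bundle@design$sample[s])]] <- p
    }
  }
  invisible(paths)
}

#' Read a counts TSV written by [writeFixtures()]
#' @param path TSV path.
#' @return counts matrix with attributes `binStart` and `binEnd`.
#' @export
readCountsTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  attr(m, "binStart") <- df$bin_start
  attr(m, "binEnd") <- df$bin_end
  m
}

#' Read a design TSV written by [writeFixtures()]
#' @param path TSV path.
#' @return data.frame `(sample, phase, replicate)`.
#' @export
readDesignTSV <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Attach a contact matrix to a bundle
#' @param bundle a [SyntheticBundle-class].
#' @param contacts a [ContactMatrix-class].
#' @return the updated bundle.
#' @export
setContacts <- function(bundle, contacts) {
  stopifnot(is(bundle, "SyntheticBundle"), is(contacts, "ContactMatrix"))
  initialize(bundle, contacts = contacts)
}
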