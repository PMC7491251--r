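#' Count fragments per bin from a BAM/SAM file or a bedGraph track
#'
#' The default assignment rule is by fragment midpoint: a properly paired
#' fragment contributes one count to every bin covering its midpoint (for
#' a non-overlapping grid that is exactly one bin); single-end reads use
#' the read midpoint. `mode = "coverage"` instead sums per-base coverage
#' over the bin, the natural rule for overlapping sliding bins.
#'
#' For bedGraph input the bin value is always
#' `sum(value * overlap width)`; with a track that encodes per-base
#' fragment-midpoint counts this reproduces the BAM midpoint counts
#' exactly, with an ordinary coverage track it is the coverage sum.
#'
#' @param file path to a coordinate-sorted BAM (or SAM) file, or a
#'   bedGraph file.
#' @param grid a [BinGrid-class]; its `genomeLength` must match the
#'   reference length of the input.
#' @param format `"auto"` (by file extension), `"bam"` or `"bedgraph"`.
#' @param mode `"midpoint"` (default) or `"coverage"`; BAM only.
#' @return integer vector of per-bin counts (length `nBins(grid)`).
#' @export
countBins <- function(file, grid, format = c("auto", "bam", "bedgraph"),
                      mode = c("midpoint", "coverage")) {
  stopifnot(is(grid, "BinGrid"))
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (format == "auto") {
    format <- if (grepl("\\.(bam|sam)$", file, ignore.case = TRUE)) "bam"
              else "bedgraph"
  }
  if (format == "bam") .countBinsBam(file, grid, mode)
  else .countBinsBedGraph(file, grid)
}

.countBinsBam <- function(file, grid, mode) {
  hdr <- Rsamtools::scanBamHeader(file)[[1]]$targets
  if (length(hdr) < 1) stop("BAM header has no reference sequences: ", file)
  reflen <- as.numeric(hdr[1])
  if (reflen != grid@genomeLength)
    stop("reference length in ", basename(file), " (", reflen,
         ") does not match grid genome length (", grid@genomeLength, ")")
  ga <- GenomicAlignments::readGAlignments(file,
          param = Rsamtools::ScanBamParam(
            what = c("flag", "isize"),
            flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  if (length(ga) == 0) return(integer(grid@nBins))
  isize <- S4Vectors::mcols(ga)$isize
  paired <- !is.na(isize) & isize != 0
  if (any(paired)) {
    # leftmost mate of each pair carries isize > 0; count the fragment once
    keep <- paired & isize > 0
    frag_start <- GenomicAlignments::start(ga)[keep]
    frag_width <- isize[keep]
  } else {
    frag_start <- GenomicAlignments::start(ga)
    frag_width <- GenomicAlignments::qwidth(ga)
  }
  if (mode == "midpoint") {
    mid0 <- (frag_start - 1) + floor(frag_width / 2)   # 0-based midpoint
    if (grid@circular) mid0 <- mid0 %% grid@genomeLength
    mid0 <- mid0[mid0 >= 0 & mid0 < grid@genomeLength]
    mp <- GenomicRanges::GRanges("genome",
            IRanges::IRanges(start = mid0 + 1, width = 1))
    hits <- GenomicRanges::findOverlaps(binRanges(grid), mp)
    tab <- tabulate(S4Vectors::mcols(binRanges(grid))$bin[
             S4Vectors::queryHits(hits)], nbins = grid@nBins)
    as.integer(tab)
  } else {
    frags <- GenomicRanges::GRanges("genome",
              IRanges::IRanges(start = frag_start,
                               end = pmin(frag_start + frag_width - 1,
                                          grid@genomeLength)))
    .sumScoreOverBins(frags, rep(1, length(frags)), grid)
  }
}

.countBinsBedGraph <- function(file, grid) {
  bg <- rtracklayer::import(file, format = "bedGraph")
  if (length(bg) == 0) return(integer(grid@nBins))
  if (max(GenomicRanges::end(bg)) > grid@genomeLength)
    stop("bedGraph intervals in ", basename(file), " extend to ",
         max(GenomicRanges::end(bg)), " bp, beyond the grid genome length (",
         grid@genomeLength, ")")
  v <- .sumScoreOverBins(bg, S4Vectors::mcols(bg)$score, grid)
  as.integer(round(v))
}

## sum(value * overlap width) per bin, honouring wrapped bins
.sumScoreOverBins <- function(gr, value, grid) {
  br <- binRanges(grid)
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(br)
  hits <- GenomicRanges::findOverlaps(br, gr)
  if (length(hits) == 0) return(numeric(grid@nBins))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
          GenomicRanges::ranges(br)[q], GenomicRanges::ranges(gr)[s]))
  contrib <- value[s] * ov
  out <- numeric(grid@nBins)
  agg <- tapply(contrib, S4Vectors::mcols(br)$bin[q], sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Mask bins overlapping structural RNA (rRNA/tRNA/tmRNA)
#'
#' A bin is masked iff it overlaps (by at least 1 bp) any feature of one
#' of the structural-RNA types. Masked bins are nulled throughout the
#' analysis: rRNA-depletion efficiency differs between libraries, so these
#' bins would otherwise bias the per-million normalisation and flood the
#' correlation structure.
#'
#' @param annotation a `GRanges` with a `type` metadata column, or a path
#'   to a GFF3 file (imported with [rtracklayer::import()]).
#' @param grid a [BinGrid-class].
#' @param types feature types to mask (default rRNA, tRNA, tmRNA).
#' @return logical vector, `TRUE` = masked.
#' @export
maskStructuralRNA <- function(annotation, grid,
                              types = c("rRNA", "tRNA", "tmRNA")) {
  stopifnot(is(grid, "BinGrid"))
  gr <- .asAnnotation(annotation)
  sel <- as.character(S4Vectors::mcols(gr)$type) %in% types
  mask <- logical(grid@nBins)
  if (!any(sel)) {
    warning("no features of type ", paste(types, collapse = "/"),
            " found; empty mask")
    return(mask)
  }
  feats <- gr[sel]
  br <- binRanges(grid)
  GenomeInfoDb::seqlevels(feats) <- GenomeInfoDb::seqlevels(br)
  hits <- GenomicRanges::findOverlaps(br, feats, minoverlap = 1L)
  mask[unique(S4Vectors::mcols(br)$bin[S4Vectors::queryHits(hits)])] <- TRUE
  mask
}

.asAnnotation <- function(annotation) {
  if (is.character(annotation)) {
    gr <- rtracklayer::import(annotation)
  } else gr <- annotation
  stopifnot(is(gr, "GRanges"))
  gr
}

#' Normalise counts to fragments per million and average replicates
#'
#' Per sample, counts are scaled by `1e6 / library size`; by default the
#' library size is the sum over *unmasked* bins, so that the variable
#' structural-RNA content of each library does not distort the scale
#' (`maskDenominator = "include"` reproduces the naive total). Masked
#' bins are set to `NA` before scaling. Replicates of the same phase are
#' then arithmetically averaged.
#'
#' @param counts bins x samples matrix of raw counts.
#' @param mask logical per bin, `TRUE` = structural RNA.
#' @param design data.frame with columns `sample`, `phase`, `replicate`;
#'   rows parallel to `counts` columns.
#' @param grid the [BinGrid-class] of the rows.
#' @param maskDenominator `"exclude"` (default) or `"include"`.
#' @return a [BinnedExpression-class].
#' @export
normalizeAndAverage <- function(counts, mask, design, grid,
                                maskDenominator = c("exclude", "include")) {
  maskDenominator <- match.arg(maskDenominator)
  stopifnot(is(grid, "BinGrid"))
  counts <- as.matrix(counts)
  if (nrow(counts) != grid@nBins)
    stop("counts has ", nrow(counts), " rows but grid has ", grid@nBins, " bins")
  if (length(mask) != nrow(counts)) stop("mask length must match counts rows")
  if (ncol(counts) != nrow(design)) stop("one design row per sample required")
  phases <- unique(design$phase)
  if (any(!phases %in% design$phase)) stop("every phase needs >= 1 sample")

  fpm_samples <- matrix(NA_real_, nrow(counts), ncol(counts))
  for (s in seq_len(ncol(counts))) {
    denom_bins <- if (maskDenominator == "exclude") !mask else rep(TRUE, nrow(counts))
    total <- sum(counts[denom_bins, s])
    if (total <= 0)
      stop("sample ", design$sample[s], " has zero counts over unmasked bins")
    fpm_samples[, s] <- counts[, s] / total * 1e6
  }
  fpm_samples[mask, ] <- NA_real_

  fpm <- sapply(phases, function(p) {
    cols <- which(design$phase == p)
    if (length(cols) == 1) fpm_samples[, cols]
    else rowMeans(fpm_samples[, cols, drop = FALSE])
  })
  fpm <- matrix(fpm, nrow = nrow(counts),
                dimnames = list(NULL, as.character(phases)))
  new("BinnedExpression", grid = grid, counts = counts,
      design = as.data.frame(design), fpm = fpm, mask = as.logical(mask),
      maskDenominator = maskDenominator)
}

#' One-call binned expression from coverage files
#'
#' Convenience wrapper: [countBins()] per sample, [maskStructuralRNA()],
#' then [normalizeAndAverage()].
#'
#' @param files character vector of BAM/bedGraph paths, one per sample.
#' @param grid a [BinGrid-class].
#' @param annotation GFF3 path or `GRanges` for structural-RNA masking.
#' @param design data.frame `(sample, phase, replicate)` parallel to `files`.
#' @param ... passed to [normalizeAndAverage()].
#' @return a [BinnedExpression-class].
#' @export
binExpression <- function(files, grid, annotation, design, ...) {
  counts <- vapply(files, countBins, numeric(grid@nBins), grid = grid)
  counts <- matrix(as.numeric(counts), nrow = grid@nBins)
  mask <- maskStructuralRNA(annotation, grid)
  normalizeAndAverage(counts, mask, design, grid, ...)
}

#' Re-bin expression at a coarser width
#'
#' Raw counts are summed into the coarser bins *before* re-normalisation
#' (FPM is not additive), the mask propagates (a coarse bin is masked if
#' any constituent fine bin was), and the FPM/averaging rules are
#' reapplied. Used to match expression to 5 kbp contact matrices.
#'
#' @param x a [BinnedExpression-class] on a non-overlapping grid.
#' @param targetWidth new bin width in bp; a multiple of the source step.
#' @return a [BinnedExpression-class] on the coarser grid.
#' @export
rebinExpression <- function(x, targetWidth) {
  stopifnot(is(x, "BinnedExpression"))
  g <- x@grid
  if (g@step != g@binWidth)
    stop("re-binning requires a non-overlapping source grid")
  if (targetWidth %% g@step != 0)
    stop("targetWidth (", targetWidth, ") must be a multiple of the source step (",
         g@step, ")")
  if (targetWidth == g@binWidth) return(x)
  coarse <- binGrid(g@genomeLength, targetWidth, targetWidth, g@circular)
  grp <- floor(binStarts(g) / targetWidth) + 1   # coarse index per fine bin
  cc <- rowsum(x@counts, grp)
  counts <- matrix(0, coarse@nBins, ncol(x@counts))
  counts[as.integer(rownames(cc)), ] <- cc
  mask <- as.logical(tapply(x@mask, grp, any))[seq_len(coarse@nBins)]
  mask[is.na(mask)] <- FALSE
  normalizeAndAverage(counts, mask, x@design, coarse,
                      maskDenominator = x@maskDenominator)
}

#' @rdname fpmValues
#' @export
setMethod("fpmValues", "BinnedExpression", function(x) x@fpm)

#' @rdname rawCounts
#' @export
setMethod("rawCounts", "BinnedExpression", function(x) x@counts)

#' @rdname maskedBins
#' @export
setMethod("maskedBins", "BinnedExpression", function(x) x@mask)

#' @rdname conditionNames
#' @export
setMethod("conditionNames", "BinnedExpression", function(x) colnames(x@fpm))

#' @rdname sampleDesign
#' @export
setMethod("sampleDesign", "BinnedExpression", function(x) x@design)

#' @rdname binGrid
#' @export
setMethod("binGrid", "BinnedExpression", function(x, ...) x@grid)

setMethod("show", "BinnedExpression", function(object) {
  cat(sprintf(paste0("BinnedExpression: %d bins x %d phases (%d samples), ",
                     "%d masked bins, denominator=%s\n"),
              nrow(object@fpm), ncol(object@fpm), ncol(object@counts),
              sum(object@mask), object@maskDenominator))
})

#' Coerce to SummarizedExperiment
#'
#' The phase-averaged FPM matrix as a single assay with bin ranges as
#' `rowRanges` and the mask as a row metadata column.
#'
#' @param x a [BinnedExpression-class].
#' @return a `RangedSummarizedExperiment` (requires SummarizedExperiment).
#' @export
asSummarizedExperiment <- function(x) {
  stopifnot(is(x, "BinnedExpression"))
  if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
    stop("SummarizedExperiment is not installed")
  g <- x@grid
  rr <- GenomicRanges::GRanges("genome",
        IRanges::IRanges(start = binStarts(g) + 1,
                         width = pmin(g@binWidth, g@genomeLength - binStarts(g))))
  S4Vectors::mcols(rr)$mask <- x@mask
  SummarizedExperiment::SummarizedExperiment(
    assays = list(fpm = x@fpm), rowRanges = rr,
    colData = S4Vectors::DataFrame(phase = colnames(x@fpm)))
}

#' Write the phase-averaged expression matrix as TSV
#'
#' Columns: `bin_start`, `bin_end`, `mask`, then one column per phase
#' with the FPM values (`NA` at masked bins).
#'
#' @param x a [BinnedExpression-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeExpressionTSV <- function(x, path) {
  stopifnot(is(x, "BinnedExpression"))
  g <- x@grid
  df <- data.frame(bin_start = binStarts(g),
                   bin_end = binStarts(g) + g@binWidth,
                   mask = x@mask)
  df <- cbind(df, as.data.frame(x@fpm))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
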