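#' Create a bin grid over a (circular) genome
#'
#' Tiles a genome of length `genomeLength` with bins of width `binWidth`
#' whose starts are `step` bp apart. `step == binWidth` (the default)
#' yields the canonical non-overlapping 500 bp tiling; `step < binWidth`
#' yields sliding, overlapping bins (e.g. 1,000 bp bins sliding at 500 bp).
#'
#' @param x genome length in bp.
#' @param binWidth bin width in bp (default 500).
#' @param step distance between bin starts in bp (default `binWidth`).
#' @param circular logical; circular chromosome (default `TRUE`).
#' @param ... unused.
#' @return a [BinGrid-class].
#' @examples
#' g <- binGrid(10000, 500)
#' nBins(g)            # 20
#' binLag(g, 1, 20)    # -500: minimal circular wrap, not +9500
#' @export
setMethod("binGrid", "numeric", function(x, binWidth = 500, step = binWidth,
                                         circular = TRUE, ...) {
  if (length(x) != 1 || !is.finite(x) || x <= 0)
    stop("genome length must be a single positive number")
  if (binWidth <= 0 || step <= 0)
    stop("binWidth and step must be positive")
  if (step > binWidth)
    stop("step (", step, ") must not exceed binWidth (", binWidth, ")")
  if (binWidth > x)
    stop("binWidth (", binWidth, ") must not exceed genome length (", x, ")")
  new("BinGrid", genomeLength = as.numeric(x), binWidth = as.numeric(binWidth),
      step = as.numeric(step), circular = isTRUE(circular),
      nBins = as.integer(ceiling(x / step)))
})

#' @rdname nBins
#' @export
setMethod("nBins", "BinGrid", function(x) x@nBins)

#' @rdname genomeLength
#' @export
setMethod("genomeLength", "BinGrid", function(x) x@genomeLength)

#' @rdname binStarts
#' @export
setMethod("binStarts", "BinGrid", function(x) (seq_len(x@nBins) - 1) * x@step)

setMethod("show", "BinGrid", function(object) {
  cat(sprintf("BinGrid: %s bp %s genome, %d bins of %g bp every %g bp\n",
              format(object@genomeLength, big.mark = ","),
              if (object@circular) "circular" else "linear",
              object@nBins, object@binWidth, object@step))
})

#' Signed genomic lag between two bins
#'
#' For a circular grid the lag from bin `i` to bin `j` is the signed
#' minimal wrap distance between their starts, so `|lag| <=
#' genomeLength/2` and `binLag(g, i, j) == -binLag(g, j, i)`.
#'
#' @param grid a [BinGrid-class].
#' @param i,j 1-based bin indices (vectorised).
#' @return signed lag(s) in bp.
#' @export
binLag <- function(grid, i, j) {
  stopifnot(is(grid, "BinGrid"))
  d <- (j - i) * grid@step
  if (!grid@circular) return(d)
  L <- grid@genomeLength
  d <- d %% L
  ifelse(d > L / 2, d - L, d)
}

#' Bins as GRanges (wrapped bins split into two ranges)
#'
#' Converts the 0-based half-open bins to 1-based closed `GRanges` on a
#' single sequence named `"genome"`, for overlap queries against
#' annotation. A bin extending past the end of a circular genome
#' contributes two ranges; the `bin` metadata column maps ranges back to
#' bin indices.
#'
#' @param grid a [BinGrid-class].
#' @return a `GRanges` with metadata column `bin`.
#' @export
binRanges <- function(grid) {
  stopifnot(is(grid, "BinGrid"))
  L <- grid@genomeLength
  s0 <- binStarts(grid)                      # 0-based starts
  e0 <- s0 + grid@binWidth                   # 0-based half-open ends
  main_end <- pmin(e0, L)
  gr <- GenomicRanges::GRanges("genome",
        IRanges::IRanges(start = s0 + 1, end = main_end),
        bin = seq_len(grid@nBins))
  over <- which(e0 > L)
  if (length(over) && grid@circular) {
    wrap <- GenomicRanges::GRanges("genome",
        IRanges::IRanges(start = 1, end = e0[over] - L),
        bin = over)
    gr <- c(gr, wrap)
  }
  GenomeInfoDb::seqlengths(gr) <- c(genome = L)
  gr
}

## 1-based indices of bins whose *start* lies in the 0-based half-open
## region [start, end); start > end wraps through the origin (circular).
.binsInRegion <- function(grid, region) {
  start <- region[1]; end <- region[2]
  s0 <- binStarts(grid)
  if (start <= end) which(s0 >= start & s0 < end)
  else if (grid@circular) which(s0 >= start | s0 < end)
  else stop("region start > end on a linear grid")
}

## circular (or linear) successor index at signed offset o (in steps)
.shiftIndex <- function(grid, o) {
  n <- grid@nBins
  idx <- seq_len(n) + o
  if (grid@circular) ((idx - 1) %% n) + 1L
  else ifelse(idx >= 1 & idx <= n, idx, NA_integer_)
}
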