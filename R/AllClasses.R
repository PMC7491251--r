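#' @import methods
#' @importFrom stats cor var sd quantile rnorm rpois runif wilcox.test p.adjust
#' @importFrom utils read.delim write.table
NULL

#' BinGrid: a fixed-width tiling of a (circular) genome
#'
#' A `BinGrid` owns all coordinate arithmetic for the analysis: bin starts,
#' circular signed lags, and conversion to `GRanges` for overlap queries.
#' Bin `i` (1-based) covers the 0-based half-open interval
#' `[(i-1)*step, (i-1)*step + binWidth)`, wrapped at the genome end when
#' `circular`, truncated otherwise.
#'
#' @slot genomeLength genome length in bp.
#' @slot binWidth bin width in bp (default 500).
#' @slot step distance between successive bin starts in bp; equal to
#'   `binWidth` for non-overlapping tilings, smaller for sliding bins.
#' @slot circular logical; whether the chromosome is circular.
#' @slot nBins number of bins, `ceiling(genomeLength / step)`.
#' @export
setClass("BinGrid",
  representation(
    genomeLength = "numeric",
    binWidth     = "numeric",
    step         = "numeric",
    circular     = "logical",
    nBins        = "integer"
  )
)

setValidity("BinGrid", function(object) {
  msg <- NULL
  if (length(object@genomeLength) != 1 || !is.finite(object@genomeLength) ||
      object@genomeLength <= 0)
    msg <- c(msg, "genomeLength must be a single positive number")
  if (object@step <= 0 || object@binWidth <= 0)
    msg <- c(msg, "binWidth and step must be positive")
  if (object@step > object@binWidth)
    msg <- c(msg, "step must not exceed binWidth")
  if (object@binWidth > object@genomeLength)
    msg <- c(msg, "binWidth must not exceed genomeLength")
  if (object@nBins != as.integer(ceiling(object@genomeLength / object@step)))
    msg <- c(msg, "nBins must equal ceiling(genomeLength / step)")
  if (is.null(msg)) TRUE else msg
})

#' Binned, normalised, replicate-averaged expression
#'
#' Holds the raw per-sample fragment counts alongside the phase-averaged
#' fragments-per-million (FPM) matrix and the structural-RNA mask. Masked
#' bins carry `NA` in the FPM matrix. Raw counts are retained so the matrix
#' can be re-binned at a coarser width (counts are summed before
#' re-normalisation).
#'
#' @slot grid the [BinGrid-class] the rows refer to.
#' @slot counts raw fragment counts, bins x samples.
#' @slot design data.frame with columns `sample`, `phase`, `replicate`.
#' @slot fpm bins x phases matrix of replicate-averaged FPM; `NA` at mask.
#' @slot mask logical per bin; `TRUE` = structural-RNA, nulled.
#' @slot maskDenominator `"exclude"` or `"include"`: whether masked bins
#'   enter the per-million library-size denominator.
#' @export
setClass("BinnedExpression",
  representation(
    grid            = "BinGrid",
    counts          = "matrix",
    design          = "data.frame",
    fpm             = "matrix",
    mask            = "logical",
    maskDenominator = "character"
  )
)

setValidity("BinnedExpression", function(object) {
  msg <- NULL
  n <- object@grid@nBins
  if (nrow(object@counts) != n) msg <- c(msg, "counts rows must match grid nBins")
  if (nrow(object@fpm) != n)    msg <- c(msg, "fpm rows must match grid nBins")
  if (length(object@mask) != n) msg <- c(msg, "mask length must match grid nBins")
  if (ncol(object@counts) != nrow(object@design))
    msg <- c(msg, "counts columns must match design rows")
  if (!all(c("sample", "phase", "replicate") %in% names(object@design)))
    msg <- c(msg, "design needs columns sample, phase, replicate")
  if (any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' Banded pairwise-correlation structure
#'
#' For every bin and every signed lag in `[-maxLag, +maxLag]` (in steps of
#' `grid@step`, lag 0 excluded), the Pearson correlation of expression
#' change with the bin at that circular lag. Entries touching a masked bin
#' are `NA`. The band, not the full n^2 matrix, is the primary structure:
#' it is all the profile analyses need.
#'
#' @slot grid the [BinGrid-class].
#' @slot maxLag maximum |lag| in bp.
#' @slot offsets signed lag offsets in units of `grid@step` (no 0).
#' @slot r bins x offsets matrix of Pearson coefficients.
#' @slot nConditions number of conditions the correlations were computed over.
#' @export
setClass("CorrelationBand",
  representation(
    grid        = "BinGrid",
    maxLag      = "numeric",
    offsets     = "integer",
    r           = "matrix",
    nConditions = "integer"
  )
)

setValidity("CorrelationBand", function(object) {
  msg <- NULL
  if (nrow(object@r) != object@grid@nBins)
    msg <- c(msg, "r rows must match grid nBins")
  if (ncol(object@r) != length(object@offsets))
    msg <- c(msg, "r columns must match offsets")
  if (any(object@offsets == 0L))
    msg <- c(msg, "offsets must not contain 0 (self-correlation excluded)")
  rng <- range(object@r, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < -1 - 1e-8 || rng[2] > 1 + 1e-8))
    msg <- c(msg, "correlation values must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Region-averaged CPED profile
#'
#' Mean correlation per signed lag over the unmasked bins of a genomic
#' region, with per-lag 95% confidence half-widths (`1.96 * sd / sqrt(n)`)
#' and the number of contributing bins.
#'
#' @slot region numeric of length 2, `(start, end)` in bp (0-based,
#'   half-open; `start > end` denotes a region wrapping the origin).
#' @slot lag signed lags in bp.
#' @slot meanR mean Pearson coefficient per lag.
#' @slot ci95 95% CI half-width per lag.
#' @slot n contributing (non-missing) bin count per lag.
#' @export
setClass("AveragedProfile",
  representation(
    region = "numeric",
    lag    = "numeric",
    meanR  = "numeric",
    ci95   = "numeric",
    n      = "integer"
  )
)

setValidity("AveragedProfile", function(object) {
  k <- length(object@lag)
  if (length(object@meanR) != k || length(object@ci95) != k ||
      length(object@n) != k)
    return("lag, meanR, ci95 and n must have equal length")
  if (any(abs(object@meanR) > 1 + 1e-8, na.rm = TRUE))
    return("meanR must lie in [-1, 1]")
  TRUE
})

#' Lomb-Scargle periodogram of an averaged profile
#'
#' Classical normalised Lomb-Scargle power over a period grid, the peak
#' period, and its false-alarm significance: `p = 1 - (1 - exp(-z))^M`
#' with `M` the effective number of independent frequencies and
#' `PNmax = -ln(p)` (so PNmax > 3 corresponds to p < 0.05).
#'
#' @slot period period grid in bp (descending as frequency ascends).
#' @slot power normalised power per period.
#' @slot peakPeriod period at maximum power (ties resolve to the smaller
#'   period).
#' @slot peakPower power at the peak.
#' @slot mIndep effective independent frequency count used for the
#'   false-alarm probability.
#' @slot pValue false-alarm probability of the peak, clipped to
#'   `[1e-300, 1]`.
#' @slot pnmax `-ln(pValue)`.
#' @slot nPoints number of non-missing profile points used.
#' @export
setClass("PeriodogramResult",
  representation(
    period     = "numeric",
    power      = "numeric",
    peakPeriod = "numeric",
    peakPower  = "numeric",
    mIndep     = "numeric",
    pValue     = "numeric",
    pnmax      = "numeric",
    nPoints    = "integer"
  )
)

setValidity("PeriodogramResult", function(object) {
  if (length(object@period) != length(object@power))
    return("period and power must have equal length")
  if (any(object@power < -1e-10, na.rm = TRUE))
    return("power must be nonnegative")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  TRUE
})

#' Contact-frequency matrix at fixed bin width
#'
#' Symmetric nonnegative matrix of 3C/Hi-C contact frequencies on a
#' [BinGrid-class] (5 kbp bins in the canonical analysis). The diagonal is
#' ignored by all downstream operations.
#'
#' @slot grid the [BinGrid-class].
#' @slot freq symmetric nonnegative matrix, nBins x nBins.
#' @slot normalization free-text provenance tag for the processing applied
#'   upstream (no balancing is performed here).
#' @export
setClass("ContactMatrix",
  representation(
    grid          = "BinGrid",
    freq          = "matrix",
    normalization = "character"
  )
)

setValidity("ContactMatrix", function(object) {
  msg <- NULL
  n <- object@grid@nBins
  if (!all(dim(object@freq) == c(n, n)))
    msg <- c(msg, "freq must be nBins x nBins")
  if (any(object@freq < 0, na.rm = TRUE))
    msg <- c(msg, "contact frequencies must be nonnegative")
  if (!isTRUE(all.equal(object@freq, t(object@freq), tolerance = 1e-8,
                        check.attributes = FALSE)))
    msg <- c(msg, "freq must be symmetric")
  if (is.null(msg)) TRUE else msg
})

#' Ground truth of a synthetic genome
#'
#' The stated world of the generator: coupled regions with planted
#' co-expression periods, operon blocks with strands, structural-RNA
#' intervals (inflated counts, to exercise masking), and regulator target
#' maps. All coordinates are 0-based half-open bp.
#'
#' @slot genomeLength genome length in bp.
#' @slot regions data.frame `(start, end, period, amplitude)`; one latent
#'   factor family per region with anchors spaced `period` apart.
#' @slot operons data.frame `(start, end, strand)`.
#' @slot structuralRNA data.frame `(start, end)`.
#' @slot regulators named list mapping regulator name to target positions.
#' @slot seed the integer seed the truth was built from.
#' @export
setClass("SyntheticTruth",
  representation(
    genomeLength  = "numeric",
    regions       = "data.frame",
    operons       = "data.frame",
    structuralRNA = "data.frame",
    regulators    = "list",
    seed          = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- NULL
  L <- object@genomeLength
  rg <- object@regions
  if (nrow(rg)) {
    if (any(rg$start < 0 | rg$end > L | rg$start >= rg$end))
      msg <- c(msg, "regions must lie within [0, genomeLength)")
    o <- order(rg$start)
    if (nrow(rg) > 1 && any(rg$start[o][-1] < rg$end[o][-nrow(rg)]))
      msg <- c(msg, "regions must be non-overlapping")
  }
  for (df in list(object@operons, object@structuralRNA)) {
    if (nrow(df) && any(df$start < 0 | df$end > L))
      msg <- c(msg, "intervals must lie within [0, genomeLength)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Simulated dataset bundle
#'
#' Everything a pipeline run consumes, generated from one
#' [SyntheticTruth-class]: raw counts with their design, a stranded
#' annotation, and (optionally) a coupled contact matrix.
#'
#' @slot truth the generating [SyntheticTruth-class].
#' @slot grid the fine [BinGrid-class] of the counts.
#' @slot counts bins x samples nonnegative counts.
#' @slot design data.frame `(sample, phase, replicate)`.
#' @slot annotation `GRanges` with gene and structural-RNA records.
#' @slot contacts a [ContactMatrix-class], or a 0-bin placeholder when
#'   contacts were not simulated.
#' @export
setClass("SyntheticBundle",
  representation(
    truth      = "SyntheticTruth",
    grid       = "BinGrid",
    counts     = "matrix",
    design     = "data.frame",
    annotation = "ANY",
    contacts   = "ANY"
  )
)

setValidity("SyntheticBundle", function(object) {
  msg <- NULL
  if (nrow(object@counts) != object@grid@nBins)
    msg <- c(msg, "counts rows must match grid nBins")
  if (ncol(object@counts) != nrow(object@design))
    msg <- c(msg, "sample count must equal design rows (phases x replicates)")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and nonnegative")
  if (is.null(msg)) TRUE else msg
})
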