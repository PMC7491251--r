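#' @rdname binGrid
#' @export
setGeneric("binGrid", function(x, ...) standardGeneric("binGrid"))

#' Number of bins of an object's grid
#' @param x an object carrying a [BinGrid-class].
#' @return integer bin count.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' Genome length (bp) of an object's grid
#' @param x an object carrying a [BinGrid-class].
#' @return genome length in bp.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' 0-based start coordinates of all bins
#' @param x an object carrying a [BinGrid-class].
#' @return numeric vector of bin starts in bp.
#' @export
setGeneric("binStarts", function(x) standardGeneric("binStarts"))

#' Phase-averaged FPM values
#' @param x a [BinnedExpression-class].
#' @return bins x phases matrix (NA at masked bins).
#' @export
setGeneric("fpmValues", function(x) standardGeneric("fpmValues"))

#' Raw per-sample counts
#' @param x a [BinnedExpression-class] or [SyntheticBundle-class].
#' @return bins x samples count matrix.
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' Structural-RNA mask
#' @param x a [BinnedExpression-class].
#' @return logical vector, TRUE = masked.
#' @export
setGeneric("maskedBins", function(x) standardGeneric("maskedBins"))

#' Condition (phase) labels
#' @param x a [BinnedExpression-class].
#' @return character vector of phase labels.
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' Sample design table
#' @param x an object with a sample design.
#' @return data.frame with columns sample, phase, replicate.
#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))

#' Signed lags (bp) of a correlation band
#' @param x a [CorrelationBand-class].
#' @return numeric vector of signed lags in bp.
#' @export
setGeneric("bandLags", function(x) standardGeneric("bandLags"))

#' Correlation values
#' @param x a [CorrelationBand-class].
#' @return bins x lags matrix of Pearson coefficients.
#' @export
setGeneric("bandValues", function(x) standardGeneric("bandValues"))

#' Contact frequencies
#' @param x a [ContactMatrix-class].
#' @return symmetric matrix of contact frequencies.
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))

#' Generating truth of a synthetic bundle
#' @param x a [SyntheticBundle-class].
#' @return the [SyntheticTruth-class].
#' @export
setGeneric("syntheticTruth", function(x) standardGeneric("syntheticTruth"))
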