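#' Pearson correlation with complete-case filtering
#'
#' Standard Pearson r over the paired values where both observations are
#' present (the `use = "complete.obs"` convention). Returns `NA` when
#' fewer than 3 complete pairs remain or either vector is constant.
#'
#' @param x,y numeric vectors of equal length (condition values).
#' @return the coefficient, or `NA`.
#' @examples
#' pearsonR(1:5, c(1, 3, 2, 5, 4))   # 0.8
#' @export
pearsonR <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}

#' Banded pairwise correlations of expression change
#'
#' For every bin and every signed circular lag up to `maxLag` (step =
#' `grid@step`, lag 0 excluded), the Pearson correlation across phases
#' with the bin at that lag. Any pair touching a masked bin is `NA`.
#' Complete-case filtering is applied per pair, so partially missing
#' condition values are tolerated.
#'
#' @param x a [BinnedExpression-class] with >= 3 conditions.
#' @param maxLag maximum |lag| in bp (default 200,000); must not exceed
#'   half the genome length on a circular grid.
#' @return a [CorrelationBand-class].
#' @export
correlationBand <- function(x, maxLag = 200000) {
  stopifnot(is(x, "BinnedExpression"))
  g <- x@grid
  if (ncol(x@fpm) < 3)
    stop("need >= 3 conditions to correlate (have ", ncol(x@fpm), ")")
  if (g@circular && maxLag > g@genomeLength / 2)
    stop("maxLag (", maxLag, ") exceeds genomeLength/2 (", g@genomeLength / 2, ")")
  K <- as.integer(floor(maxLag / g@step))
  if (K < 1) stop("maxLag smaller than one grid step")
  n <- g@nBins
  if (g@circular && 2L * K >= n)
    stop("maxLag too large for the number of bins")
  offsets <- c(-(K:1), 1:K)
  V <- x@fpm
  V[x@mask, ] <- NA_real_
  r <- matrix(NA_real_, n, 2L * K)
  pos_cols <- matrix(NA_real_, n, K)   # r at offsets +1..+K
  for (o in seq_len(K)) {
    j <- .shiftIndex(g, o)
    keep <- !is.na(j)
    Y <- matrix(NA_real_, n, ncol(V))
    Y[keep, ] <- V[j[keep], ]
    pos_cols[, o] <- .rowPearson(V, Y)
  }
  # column layout: offsets -K..-1, +1..+K
  for (o in seq_len(K)) {
    r[, K + o] <- pos_cols[, o]
    # r(i, -o) = r(i - o, +o) at the shifted row
    jm <- .shiftIndex(g, -o)
    keep <- !is.na(jm)
    col <- rep(NA_real_, n)
    col[keep] <- pos_cols[jm[keep], o]
    r[, K - o + 1L] <- col
  }
  colnames(r) <- as.character(offsets * g@step)
  new("CorrelationBand", grid = g, maxLag = as.numeric(K * g@step),
      offsets = as.integer(offsets), r = r,
      nConditions = ncol(x@fpm))
}

## row-wise Pearson between matrices X and Y with pairwise-complete columns
.rowPearson <- function(X, Y) {
  M <- is.finite(X) & is.finite(Y)
  Xz <- ifelse(M, X, 0); Yz <- ifelse(M, Y, 0)
  n  <- rowSums(M)
  sx <- rowSums(Xz); sy <- rowSums(Yz)
  sxx <- rowSums(Xz * Xz); syy <- rowSums(Yz * Yz); sxy <- rowSums(Xz * Yz)
  cov <- sxy - sx * sy / n
  vx  <- sxx - sx^2 / n
  vy  <- syy - sy^2 / n
  r <- cov / sqrt(vx * vy)
  # guard degenerate cases: < 3 pairs or zero variance
  bad <- n < 3 | vx <= 1e-10 * pmax(sxx, 1e-300) |
         vy <= 1e-10 * pmax(syy, 1e-300)
  r[bad] <- NA_real_
  pmin(1, pmax(-1, r))
}

#' @rdname bandLags
#' @export
setMethod("bandLags", "CorrelationBand",
          function(x) as.numeric(x@offsets) * x@grid@step)

#' @rdname bandValues
#' @export
setMethod("bandValues", "CorrelationBand", function(x) x@r)

#' @rdname binGrid
#' @export
setMethod("binGrid", "CorrelationBand", function(x, ...) x@grid)

setMethod("show", "CorrelationBand", function(object) {
  cat(sprintf("CorrelationBand: %d bins x %d lags (|lag| <= %s bp, %d conditions)\n",
              nrow(object@r), ncol(object@r),
              format(object@maxLag, big.mark = ","), object@nConditions))
})

#' Region-averaged CPED profile
#'
#' Per-lag arithmetic mean of the individual bin profiles over all
#' unmasked bins whose start lies in the region, ignoring missing
#' entries, with a 95% CI half-width (`1.96 * sd / sqrt(n)`) and the
#' contributing bin count per lag.
#'
#' @param band a [CorrelationBand-class].
#' @param region numeric `(start, end)` in bp, 0-based half-open;
#'   `start > end` wraps through the origin on a circular grid.
#' @return an [AveragedProfile-class].
#' @export
averageProfiles <- function(band, region) {
  stopifnot(is(band, "CorrelationBand"), length(region) == 2)
  idx <- .binsInRegion(band@grid, region)
  if (length(idx) == 0) stop("region contains no bins")
  sub <- band@r[idx, , drop = FALSE]
  n <- colSums(is.finite(sub))
  if (all(n == 0))
    stop("region [", region[1], ", ", region[2], ") contains no unmasked data")
  .profileFromSub(sub, region, bandLags(band))
}

.profileFromSub <- function(sub, region, lags) {
  n <- colSums(is.finite(sub))
  meanR <- suppressWarnings(colMeans(sub, na.rm = TRUE))
  meanR[n == 0] <- NA_real_
  sdv <- apply(sub, 2, sd, na.rm = TRUE)
  ci <- ifelse(n > 1, 1.96 * sdv / sqrt(n), NA_real_)
  new("AveragedProfile", region = as.numeric(region), lag = lags,
      meanR = as.numeric(meanR), ci95 = as.numeric(ci), n = as.integer(n))
}

#' @describeIn averageProfiles lags (bp) of an averaged profile
#' @param x an [AveragedProfile-class].
#' @export
profileLags <- function(x) x@lag

#' @describeIn averageProfiles mean correlation per lag
#' @export
profileMeans <- function(x) x@meanR

#' @describeIn averageProfiles 95% CI half-width per lag
#' @export
profileCI <- function(x) x@ci95

setMethod("show", "AveragedProfile", function(object) {
  cat(sprintf("AveragedProfile: region [%s, %s) bp, %d lags, max |meanR| = %.3f\n",
              format(object@region[1], big.mark = ","),
              format(object@region[2], big.mark = ","),
              length(object@lag), max(abs(object@meanR), na.rm = TRUE)))
})

#' Serialize a band or profile as a tidy TSV
#'
#' @param x a [CorrelationBand-class] or [AveragedProfile-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeBandTSV <- function(x, path) {
  if (is(x, "CorrelationBand")) {
    df <- data.frame(bin = rep(seq_len(nrow(x@r)), times = ncol(x@r)),
                     lag = rep(bandLags(x), each = nrow(x@r)),
                     r = as.vector(x@r))
    df <- df[is.finite(df$r), ]
  } else if (is(x, "AveragedProfile")) {
    df <- data.frame(lag = x@lag, mean_r = x@meanR, ci95 = x@ci95, n = x@n)
  } else stop("unsupported object")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
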