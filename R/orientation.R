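#' Assign a transcription orientation to each bin
#'
#' A bin is called `CW` (clockwise = forward strand of the reference, the
#' flippable convention) if every gene overlapping it by at least
#' `minOverlap` bp is on the forward strand, `CCW` if every such gene is
#' on the reverse strand, `ambiguous` when both strands overlap, and
#' `none` when no gene does. Ambiguous and orientation-free bins are
#' excluded from oriented analyses; the discarded fraction is reported
#' (about two thirds of bins on a real genome).
#'
#' @param annotation `GRanges` (or GFF3 path) with stranded gene records.
#' @param grid a [BinGrid-class].
#' @param featureType annotation `type` value(s) to use (default
#'   `"gene"`; falls back to all stranded records if absent).
#' @param minOverlap minimum overlap in bp (default 1).
#' @param convention `"forward-cw"` (default) or `"forward-ccw"`.
#' @return data.frame `(bin, call, nFwd, nRev)` with `call` a factor in
#'   `CW, CCW, ambiguous, none`; attribute `"discardFraction"`.
#' @export
assignOrientation <- function(annotation, grid, featureType = "gene",
                              minOverlap = 1L,
                              convention = c("forward-cw", "forward-ccw")) {
  convention <- match.arg(convention)
  stopifnot(is(grid, "BinGrid"))
  gr <- .asAnnotation(annotation)
  sel <- as.character(S4Vectors::mcols(gr)$type) %in% featureType
  if (!any(sel)) sel <- rep(TRUE, length(gr))
  genes <- gr[sel]
  stranded <- as.character(GenomicRanges::strand(genes)) %in% c("+", "-")
  if (any(!stranded))
    message(sum(!stranded), " unstranded records ignored for orientation")
  genes <- genes[stranded]
  br <- binRanges(grid)
  GenomeInfoDb::seqlevels(genes) <- GenomeInfoDb::seqlevels(br)
  hits <- GenomicRanges::findOverlaps(br, genes, minoverlap = minOverlap)
  bin_of <- S4Vectors::mcols(br)$bin[S4Vectors::queryHits(hits)]
  fwd <- as.character(GenomicRanges::strand(genes))[S4Vectors::subjectHits(hits)] == "+"
  nFwd <- tabulate(bin_of[fwd], nbins = grid@nBins)
  nRev <- tabulate(bin_of[!fwd], nbins = grid@nBins)
  call <- rep("none", grid@nBins)
  call[nFwd > 0 & nRev == 0] <- "CW"
  call[nRev > 0 & nFwd == 0] <- "CCW"
  call[nFwd > 0 & nRev > 0] <- "ambiguous"
  if (convention == "forward-ccw") {
    call[call == "CW"] <- "tmp"; call[call == "CCW"] <- "CW"; call[call == "tmp"] <- "CCW"
  }
  out <- data.frame(bin = seq_len(grid@nBins),
                    call = factor(call, levels = c("CW", "CCW", "ambiguous", "none")),
                    nFwd = nFwd, nRev = nRev)
  attr(out, "discardFraction") <- mean(call %in% c("ambiguous", "none"))
  out
}

#' Mirror CPED profiles onto the transcription-direction axis
#'
#' Bins transcribed counter-clockwise have their lag axis negated, so
#' that after averaging, positive lags mean "downstream of transcription"
#' for every retained bin. Ambiguous and orientation-free bins are
#' dropped (all-`NA`). Mirroring twice is the identity.
#'
#' @param band a [CorrelationBand-class].
#' @param orientation output of [assignOrientation()] on the same grid.
#' @return a [CorrelationBand-class] on the oriented lag axis.
#' @export
mirrorProfiles <- function(band, orientation) {
  stopifnot(is(band, "CorrelationBand"),
            nrow(orientation) == band@grid@nBins)
  r <- band@r
  ccw <- which(orientation$call == "CCW")
  drop <- which(orientation$call %in% c("ambiguous", "none"))
  if (length(ccw)) r[ccw, ] <- r[ccw, rev(seq_len(ncol(r))), drop = FALSE]
  if (length(drop)) r[drop, ] <- NA_real_
  initialize(band, r = r)
}

#' Stratify bins by expression strength
#'
#' Unmasked bins are split into `nStrata` near-equal groups (sizes differ
#' by at most 1) by their mean FPM over the phase-averaged conditions,
#' with deterministic tie-breaking by bin index. Stratum 1 is weakest.
#'
#' @param x a [BinnedExpression-class] with at least `nStrata` unmasked
#'   bins.
#' @param nStrata number of strata (default 5, i.e. quintiles).
#' @param summary `"mean"` (default) or `"max"` across conditions.
#' @return list (`"StrengthStrata"`): `stratum` (integer per bin, `NA`
#'   at masked bins), `boundaries` (upper FPM cut of each stratum but
#'   the last), `strength` (per-bin summary).
#' @export
strengthStrata <- function(x, nStrata = 5, summary = c("mean", "max")) {
  summary <- match.arg(summary)
  stopifnot(is(x, "BinnedExpression"))
  keep <- which(!x@mask)
  if (length(keep) < nStrata)
    stop("need at least ", nStrata, " unmasked bins")
  strength <- rep(NA_real_, x@grid@nBins)
  strength[keep] <- if (summary == "mean")
    rowMeans(x@fpm[keep, , drop = FALSE], na.rm = TRUE)
  else apply(x@fpm[keep, , drop = FALSE], 1, max, na.rm = TRUE)
  ord <- keep[order(strength[keep], keep)]
  m <- length(ord)
  sizes <- rep(m %/% nStrata, nStrata)
  extra <- m %% nStrata
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stratum <- rep(NA_integer_, x@grid@nBins)
  stratum[ord] <- rep(seq_len(nStrata), times = sizes)
  boundaries <- vapply(seq_len(nStrata - 1), function(k)
    max(strength[ord][stratum[ord] == k]), numeric(1))
  structure(list(stratum = stratum, boundaries = boundaries,
                 strength = strength),
            class = "StrengthStrata")
}

#' Oriented-vs-unoriented profile contrast
#'
#' Per-lag difference of the two mean profiles with a combined 95% CI
#' (`sqrt(ci_o^2 + ci_u^2)`), plus a summary asymmetry statistic: the
#' mean over positive lags of `meanR(+L) - meanR(-L)` on the *oriented*
#' profile. A supercoiling-gradient signature would make downstream
#' (positive oriented) lags systematically more correlated than upstream
#' ones, i.e. a positive asymmetry beyond its CI.
#'
#' @param oriented,unoriented [AveragedProfile-class] objects on the
#'   same lag grid.
#' @return list: `lag`, `difference`, `ci95`, `asymmetry`,
#'   `asymmetryCI`.
#' @export
supercoilingContrast <- function(oriented, unoriented) {
  stopifnot(is(oriented, "AveragedProfile"), is(unoriented, "AveragedProfile"))
  if (length(oriented@lag) != length(unoriented@lag) ||
      any(oriented@lag != unoriented@lag))
    stop("profiles are on different lag grids")
  diff <- oriented@meanR - unoriented@meanR
  ci <- sqrt(oriented@ci95^2 + unoriented@ci95^2)
  pos <- which(oriented@lag > 0)
  neg_match <- match(-oriented@lag[pos], oriented@lag)
  d <- oriented@meanR[pos] - oriented@meanR[neg_match]
  dci2 <- oriented@ci95[pos]^2 + oriented@ci95[neg_match]^2
  ok <- is.finite(d)
  asym <- mean(d[ok])
  asymCI <- sqrt(sum(dci2[ok], na.rm = TRUE)) / sum(ok)
  list(lag = oriented@lag, difference = diff, ci95 = ci,
       asymmetry = asym, asymmetryCI = asymCI)
}
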