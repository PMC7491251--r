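# Shared fixture builders. Everything is generated in code at test time.

# A BinnedExpression directly from a values matrix (bypasses counting, for
# tests of the correlation/periodicity machinery).
makeExpr <- function(values, binWidth = 500, mask = NULL,
                     genomeLength = nrow(values) * binWidth) {
  g <- binGrid(genomeLength, binWidth)
  if (is.null(mask)) mask <- rep(FALSE, nrow(values))
  values[mask, ] <- NA_real_
  new("BinnedExpression", grid = g,
      counts = matrix(1, nrow(values), ncol(values)),
      design = data.frame(sample = paste0("s", seq_len(ncol(values))),
                          phase = paste0("P", seq_len(ncol(values))),
                          replicate = 1L),
      fpm = values, mask = mask, maskDenominator = "exclude")
}

# Stranded gene annotation from 0-based half-open intervals.
makeGenes <- function(start, end, strand, type = "gene",
                      name = paste0("g", seq_along(start)),
                      genomeLength = NULL) {
  gr <- GenomicRanges::GRanges("genome",
        IRanges::IRanges(start = start + 1, end = end),
        strand = strand, type = type, Name = name)
  if (!is.null(genomeLength))
    GenomeInfoDb::seqlengths(gr) <- c(genome = genomeLength)
  gr
}

# Exact two-sided rank-sum p-value by enumeration of all rank assignments
# (independent oracle for the Wilcoxon implementation; no ties assumed).
enumRankSumP <- function(x, y) {
  all <- c(x, y)
  n <- length(all); nx <- length(x)
  r <- rank(all)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- combn(n, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  pLess <- mean(ws <= wObs)
  pGreater <- mean(ws >= wObs)
  min(1, 2 * min(pLess, pGreater))
}

# Schuster/DFT periodogram at exact Fourier frequencies of an evenly
# sampled complete profile, normalised the classical Lomb-Scargle way
# (independent oracle; uses fft only).
dftPeriodogram <- function(y, dt, kset) {
  n <- length(y)
  yc <- y - mean(y)
  F <- stats::fft(yc)
  vapply(kset, function(k) Mod(F[k + 1])^2 / (n * stats::var(y)), numeric(1))
}

# small helper: period-domain width of one frequency-grid step at period P
periodGridStep <- function(P, span, oversampling = 4) {
  P^2 / (oversampling * span)
}

# AveragedProfile from bare vectors (periodicity tests)
mkProfile <- function(lag, y, n = 100L) {
  new("AveragedProfile", region = c(0, 1), lag = lag, meanR = y,
      ci95 = rep(0.01, length(lag)), n = rep(as.integer(n), length(lag)))
}
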