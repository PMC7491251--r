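#' Construct a contact matrix
#'
#' @param freq symmetric nonnegative matrix (nBins x nBins), or a
#'   3-column COO data.frame `(bin_i, bin_j, frequency)` with 1-based
#'   indices.
#' @param grid the [BinGrid-class] of the rows (5 kbp bins canonically).
#' @param normalization free-text provenance tag (default `"processed"`:
#'   matrices are consumed as published, no balancing applied here).
#' @return a [ContactMatrix-class].
#' @export
contactMatrix <- function(freq, grid, normalization = "processed") {
  stopifnot(is(grid, "BinGrid"))
  if (is.data.frame(freq)) {
    m <- matrix(0, grid@nBins, grid@nBins)
    i <- as.integer(freq[[1]]); j <- as.integer(freq[[2]])
    v <- as.numeric(freq[[3]])
    if (any(i < 1 | i > grid@nBins | j < 1 | j > grid@nBins))
      stop("COO indices outside 1..", grid@nBins)
    m[cbind(i, j)] <- v
    m[cbind(j, i)] <- v
    freq <- m
  }
  new("ContactMatrix", grid = grid, freq = as.matrix(freq),
      normalization = normalization)
}

#' @rdname contactValues
#' @export
setMethod("contactValues", "ContactMatrix", function(x) x@freq)

#' @rdname binGrid
#' @export
setMethod("binGrid", "ContactMatrix", function(x, ...) x@grid)

setMethod("show", "ContactMatrix", function(object) {
  nz <- sum(object@freq[upper.tri(object@freq)] > 0)
  cat(sprintf("ContactMatrix: %d x %d bins (%g bp), %d nonzero pairs, %s\n",
              nrow(object@freq), ncol(object@freq), object@grid@binWidth,
              nz, object@normalization))
})

#' Read a COO contact TSV
#'
#' Expects a header and three columns: 1-based `bin_i`, `bin_j`,
#' `frequency` (each unordered pair once; symmetrised on read).
#'
#' @param path TSV path.
#' @param grid the [BinGrid-class].
#' @param ... passed to [contactMatrix()].
#' @return a [ContactMatrix-class].
#' @export
readContactsTSV <- function(path, grid, ...) {
  df <- read.delim(path)
  if (ncol(df) < 3) stop("contact TSV needs 3 columns: ", path)
  contactMatrix(df[, 1:3], grid, ...)
}

#' Join contact frequencies to pairwise expression correlations
#'
#' All unordered pairs of unmasked bins whose circular linear distance
#' strictly exceeds `minLinearDistance` (20 kbp by default, removing
#' operon- and supercoiling-gradient-driven co-expression), with the
#' Pearson correlation of their expression across conditions and their
#' contact frequency. Pairs with missing (NA or zero) contact are
#' dropped and counted.
#'
#' @param expr a [BinnedExpression-class] on the contact grid (use
#'   [rebinExpression()] to match widths).
#' @param contacts a [ContactMatrix-class] on the same grid.
#' @param minLinearDistance exclusion radius in bp (default 20,000,
#'   strict inequality).
#' @return data.frame `(binI, binJ, distance, contact, r)`; attributes
#'   `"nDroppedContact"` (pairs without usable contact) and `"nPairs"`
#'   (distance-eligible pairs).
#' @export
buildPairs <- function(expr, contacts, minLinearDistance = 20000) {
  stopifnot(is(expr, "BinnedExpression"), is(contacts, "ContactMatrix"))
  g <- expr@grid
  cg <- contacts@grid
  if (g@nBins != cg@nBins || g@genomeLength != cg@genomeLength ||
      g@binWidth != cg@binWidth)
    stop("expression grid (", g@nBins, " bins of ", g@binWidth,
         " bp) does not match contact grid (", cg@nBins, " bins of ",
         cg@binWidth, " bp)")
  keep <- which(!expr@mask)
  V <- expr@fpm[keep, , drop = FALSE]
  C <- suppressWarnings(cor(t(V), use = "pairwise.complete.obs"))
  idx <- which(upper.tri(C), arr.ind = TRUE)
  bi <- keep[idx[, 1]]; bj <- keep[idx[, 2]]
  dist <- abs(binLag(g, bi, bj))
  ok <- dist > minLinearDistance
  bi <- bi[ok]; bj <- bj[ok]; dist <- dist[ok]
  r <- C[idx][ok]
  contact <- contacts@freq[cbind(bi, bj)]
  usable <- is.finite(contact) & contact > 0 & is.finite(r)
  out <- data.frame(binI = bi[usable], binJ = bj[usable],
                    distance = dist[usable], contact = contact[usable],
                    r = r[usable])
  attr(out, "nPairs") <- length(bi)
  attr(out, "nDroppedContact") <- sum(!usable)
  out
}

#' Group pairs by contact frequency and rank-test against the lowest group
#'
#' Groups are equal-width intervals on `log10(contact frequency)` over
#' the observed range (hence unequal memberships), or contact-frequency
#' quantiles with `method = "quantile"`. Per group: mean correlation,
#' 95% CI of the mean, n. Each group is compared with the lowest-contact
#' group by a two-sided Wilcoxon rank-sum test; p-values are
#' Bonferroni-multiplied by the number of comparisons and capped at 1.
#' Empty groups are merged into their lower neighbour with a warning.
#'
#' @param pairs output of [buildPairs()].
#' @param nGroups number of groups (8 and 21 canonically).
#' @param method `"logwidth"` (default) or `"quantile"`.
#' @return list (`"PairAssociation"`): `pairs` (with a `group` column),
#'   `summary` data.frame `(group, n, meanR, ci95, lo, hi)`, `tests`
#'   data.frame `(group, pRaw, pBonferroni)`, `method`, `breaks`.
#' @export
groupAndTest <- function(pairs, nGroups = 8,
                         method = c("logwidth", "quantile")) {
  method <- match.arg(method)
  stopifnot(nrow(pairs) >= 2)
  lc <- log10(pairs$contact)
  if (diff(range(lc)) == 0) {
    pairs$group <- 1L
    warning("all contact frequencies equal; single group, no tests")
    sm <- data.frame(group = 1L, n = nrow(pairs), meanR = mean(pairs$r),
                     ci95 = 1.96 * sd(pairs$r) / sqrt(nrow(pairs)))
    return(structure(list(pairs = pairs, summary = sm,
                          tests = data.frame(group = integer(0),
                                             pRaw = numeric(0),
                                             pBonferroni = numeric(0)),
                          method = method, breaks = range(lc)),
                     class = "PairAssociation"))
  }
  breaks <- if (method == "logwidth")
    seq(min(lc), max(lc), length.out = nGroups + 1)
  else unique(quantile(lc, probs = seq(0, 1, length.out = nGroups + 1)))
  grp <- cut(lc, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  # merge empty groups into the lower neighbour by renumbering occupied ones
  occupied <- sort(unique(grp))
  if (length(occupied) < nGroups)
    warning(nGroups - length(occupied),
            " empty contact group(s) merged into neighbours")
  grp <- match(grp, occupied)
  pairs$group <- grp
  ng <- length(occupied)
  sm <- do.call(rbind, lapply(seq_len(ng), function(k) {
    v <- pairs$r[grp == k]
    data.frame(group = k, n = length(v), meanR = mean(v),
               ci95 = if (length(v) > 1) 1.96 * sd(v) / sqrt(length(v)) else NA)
  }))
  tests <- if (ng >= 2) {
    ref <- pairs$r[grp == 1]
    do.call(rbind, lapply(2:ng, function(k) {
      v <- pairs$r[grp == k]
      p <- if (length(v) >= 1 && length(ref) >= 1)
        suppressWarnings(wilcox.test(v, ref)$p.value) else NA_real_
      data.frame(group = k, pRaw = p,
                 pBonferroni = min(p * (ng - 1), 1))
    }))
  } else data.frame(group = integer(0), pRaw = numeric(0),
                    pBonferroni = numeric(0))
  structure(list(pairs = pairs, summary = sm, tests = tests,
                 method = method, breaks = breaks),
            class = "PairAssociation")
}

#' @export
print.PairAssociation <- function(x, ...) {
  cat(sprintf("PairAssociation: %d pairs in %d contact groups (%s)\n",
              nrow(x$pairs), nrow(x$summary), x$method))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
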