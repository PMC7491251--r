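#' Parse a RegulonDB-style regulator-target table
#'
#' Accepts two-or-more-column TSVs in the "TF - gene interactions" /
#' "Sigma - gene interactions" layouts (first column regulator, second
#' column target gene; extra columns ignored, `#` comments skipped). If
#' the second column is numeric it is taken as a genomic position
#' directly; otherwise gene names are resolved against the annotation and
#' the target position is the gene's annotated start (5' end on its
#' strand; `positionMode = "midpoint"` for the alternative). Regulators
#' associated with 20 or fewer distinct bins within `flank` bp of their
#' targets are dropped.
#'
#' @param file path to the TSV.
#' @param grid a [BinGrid-class].
#' @param annotation `GRanges` or GFF3 path for gene-name resolution
#'   (may be omitted when the table already carries positions).
#' @param flank half-width in bp of the window around each target whose
#'   bins count as "at" the target (default 500).
#' @param minBins retention threshold: keep regulators with strictly
#'   more than this many at-bins (default 20).
#' @param positionMode `"start"` (default) or `"midpoint"`.
#' @return named list of `RegulatorTargets` lists, each with elements
#'   `regulator`, `positions` (sorted bp), `flank`, `atBins` (sorted bin
#'   indices).
#' @export
parseTargets <- function(file, grid, annotation = NULL, flank = 500,
                         minBins = 20, positionMode = c("start", "midpoint")) {
  positionMode <- match.arg(positionMode)
  stopifnot(is(grid, "BinGrid"))
  tab <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("target table needs >= 2 columns: ", file)
  reg <- as.character(tab[[1]])
  tgt <- tab[[2]]
  if (is.numeric(tgt)) {
    pos <- as.numeric(tgt)
  } else {
    if (is.null(annotation))
      stop("annotation required to resolve gene-name targets")
    gr <- .asAnnotation(annotation)
    nm <- .geneNames(gr)
    hit <- match(as.character(tgt), nm)
    if (all(is.na(hit)))
      stop("no target gene names could be resolved against the annotation")
    if (any(is.na(hit)))
      message(sum(is.na(hit)), " unresolvable target genes skipped")
    reg <- reg[!is.na(hit)]
    g <- gr[hit[!is.na(hit)]]
    pos <- if (positionMode == "midpoint")
      (GenomicRanges::start(g) + GenomicRanges::end(g)) / 2 - 1
    else ifelse(as.character(GenomicRanges::strand(g)) == "-",
                GenomicRanges::end(g) - 1, GenomicRanges::start(g) - 1)
  }
  out <- list()
  for (r in unique(reg)) {
    p <- sort(unique(pos[reg == r]))
    at <- targetBins(p, grid, flank)
    if (length(at) > minBins) {
      out[[r]] <- structure(list(regulator = r, positions = p,
                                 flank = flank, atBins = at),
                            class = "RegulatorTargets")
    } else {
      message("regulator ", r, " dropped: ", length(at),
              " at-bins (<= ", minBins, ")")
    }
  }
  out
}

.geneNames <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  for (col in c("Name", "gene", "locus_tag", "ID")) {
    if (col %in% names(mc) && !all(is.na(mc[[col]])))
      return(as.character(mc[[col]]))
  }
  rep(NA_character_, length(gr))
}

#' Bins within a flank of target positions
#'
#' Union of all bins overlapping `[target - flank, target + flank]`
#' (counted once; overlapping windows do not double-count).
#'
#' @param positions target positions, 0-based bp.
#' @param grid a [BinGrid-class].
#' @param flank half-width in bp (default 500).
#' @return sorted unique 1-based bin indices.
#' @export
targetBins <- function(positions, grid, flank = 500) {
  stopifnot(is(grid, "BinGrid"))
  if (length(positions) == 0) return(integer(0))
  L <- grid@genomeLength
  positions <- if (grid@circular) positions %% L
               else pmin(pmax(positions, 0), L - 1)
  s <- pmax(positions - flank, if (grid@circular) -Inf else 0)
  e <- pmin(positions + flank, if (grid@circular) Inf else L - 1)
  # represent circular windows as up to two linear pieces
  pieces_s <- c(pmax(s, 0), ifelse(s < 0, s + L, NA), ifelse(e >= L, 0, NA))
  pieces_e <- c(pmin(e, L - 1), ifelse(s < 0, L - 1, NA), ifelse(e >= L, e - L, NA))
  ok <- !is.na(pieces_s)
  win <- GenomicRanges::GRanges("genome",
          IRanges::IRanges(start = pieces_s[ok] + 1, end = pieces_e[ok] + 1))
  br <- binRanges(grid)
  hits <- GenomicRanges::findOverlaps(br, win)
  sort(unique(S4Vectors::mcols(br)$bin[S4Vectors::queryHits(hits)]))
}

#' Mock "between" binding sites at circular midpoints
#'
#' One mock site per real site: the circular midpoint between the site
#' and its clockwise successor. Shifting all sites by a constant shifts
#' all mocks by the same constant (mod genome length), and the mock set
#' always has the cardinality of the real set.
#'
#' @param positions real site positions in bp.
#' @param genomeLength genome length in bp.
#' @return mock positions in bp (same length as `positions`).
#' @examples
#' betweenSites(c(1000, 3000), 10000)   # 2000 and 7000
#' @export
betweenSites <- function(positions, genomeLength) {
  if (length(positions) < 2) stop("need >= 2 sites to place mocks between them")
  p <- sort(positions %% genomeLength)
  succ <- c(p[-1], p[1])
  gap <- (succ - p) %% genomeLength
  (p + gap / 2) %% genomeLength
}

## r values of all unordered within-set band pairs (positive offsets only,
## so each pair is counted once)
.setPairR <- function(band, bins) {
  g <- band@grid
  pos <- band@offsets > 0
  inset <- logical(g@nBins)
  inset[bins] <- TRUE
  vals <- numeric(0)
  for (col in which(pos)) {
    o <- band@offsets[col]
    j <- .shiftIndex(g, o)
    i_ok <- which(inset & !is.na(j) & inset[pmax(j, 1)])
    if (length(i_ok)) vals <- c(vals, band@r[cbind(i_ok, col)])
  }
  vals[is.finite(vals)]
}

## r values of all band pairs not touching the given bins
.withoutPairR <- function(band, bins) {
  g <- band@grid
  touch <- logical(g@nBins)
  touch[bins] <- TRUE
  vals <- numeric(0)
  for (col in which(band@offsets > 0)) {
    o <- band@offsets[col]
    j <- .shiftIndex(g, o)
    i_ok <- which(!touch & !is.na(j) & !touch[pmax(j, 1)])
    if (length(i_ok)) vals <- c(vals, band@r[cbind(i_ok, col)])
  }
  vals[is.finite(vals)]
}

#' At/Between/Random/Without correlation subsets for a regulator
#'
#' Partitions the banded pairwise correlations into the four diagnostic
#' subsets: `At` (both bins within `flank` of a real target), `Between`
#' (same rule at the circular-midpoint mock sites), `Random` (pooled over
#' `nRandom` uniformly drawn unmasked bin sets of size `|At bins|`) and
#' `Without` (every band pair not touching an at-bin). Regulator-driven
#' co-expression shows up as a higher mean in `At` than in every other
#' subset; each comparison is made operational with a two-sided
#' rank-sum test.
#'
#' @param band a [CorrelationBand-class].
#' @param targets a `RegulatorTargets` (from [parseTargets()]) or a
#'   numeric vector of target positions.
#' @param nRandom random replicate sets (default 100).
#' @param seed integer seed for the random draws.
#' @param mask optional logical mask; random draws avoid masked bins
#'   (defaults to the bins that are all-`NA` in the band).
#' @return list (`"SubsetCorrelations"`): `regulator`, `distributions`
#'   (list of numeric vectors), `means`, `tests` (p-values of At vs each
#'   other subset), `randomMeans` (per-replicate Random means), `nRandom`.
#' @export
subsetDistributions <- function(band, targets, nRandom = 100, seed = 1,
                                mask = NULL) {
  stopifnot(is(band, "CorrelationBand"))
  if (is.numeric(targets))
    targets <- structure(list(regulator = "regulator", positions = targets,
                              flank = 500,
                              atBins = targetBins(targets, band@grid, 500)),
                         class = "RegulatorTargets")
  at <- targets$atBins
  if (length(at) < 2) stop("fewer than 2 at-bins")
  g <- band@grid
  if (is.null(mask)) mask <- rowSums(is.finite(band@r)) == 0
  mock <- betweenSites(targets$positions, g@genomeLength)
  mockBins <- targetBins(mock, g, targets$flank)

  atR <- .setPairR(band, at)
  betweenR <- .setPairR(band, mockBins)
  withoutR <- .withoutPairR(band, at)
  candidates <- which(!mask)
  randomR <- NULL
  randomMeans <- numeric(nRandom)
  .withSeed(seed, {
    randomR <- lapply(seq_len(nRandom), function(k) {
      draw <- sample(candidates, length(at))
      .setPairR(band, draw)
    })
  })
  randomMeans <- vapply(randomR, function(v) mean(v), numeric(1))
  randomAll <- unlist(randomR)
  dists <- list(At = atR, Between = betweenR, Random = randomAll,
                Without = withoutR)
  means <- vapply(dists, mean, numeric(1))
  tests <- vapply(c("Between", "Random", "Without"), function(nm) {
    if (length(atR) < 2 || length(dists[[nm]]) < 2) return(NA_real_)
    suppressWarnings(wilcox.test(atR, dists[[nm]])$p.value)
  }, numeric(1))
  structure(list(regulator = targets$regulator, distributions = dists,
                 means = means, tests = tests, randomMeans = randomMeans,
                 nRandom = nRandom),
            class = "SubsetCorrelations")
}

#' @export
print.SubsetCorrelations <- function(x, ...) {
  cat("Subset correlations for", x$regulator, "\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Averaged profile and periodogram with and without regulator bins
#'
#' Removes every correlation involving an at-bin (both the bins' own
#' profiles and their appearance as partners in other bins' profiles),
#' then re-averages the region profile and re-runs the periodogram. A
#' periodicity carried by the excluded bins collapses; one independent of
#' them survives with its peak period intact.
#'
#' @param band a [CorrelationBand-class].
#' @param region numeric `(start, end)` region in bp.
#' @param atBins bin indices to exclude.
#' @param config a [scanConfig()].
#' @return list: `full` and `excluded`, each `(profile, periodogram)`,
#'   plus `deltaPeriod` and `deltaPNmax` (excluded minus full).
#' @export
exclusionReprofile <- function(band, region, atBins, config = scanConfig()) {
  stopifnot(is(band, "CorrelationBand"))
  full_prof <- averageProfiles(band, region)
  full_pg <- lombScargle(full_prof, config, nConditions = band@nConditions)

  g <- band@grid
  r <- band@r
  r[atBins, ] <- NA_real_
  touch <- logical(g@nBins)
  touch[atBins] <- TRUE
  for (col in seq_along(band@offsets)) {
    j <- .shiftIndex(g, band@offsets[col])
    bad <- which(!is.na(j) & touch[pmax(j, 1)])
    if (length(bad)) r[bad, col] <- NA_real_
  }
  band2 <- initialize(band, r = r)
  idx <- .binsInRegion(g, region)
  surviving <- sum(rowSums(is.finite(r[idx, , drop = FALSE])) > 0)
  if (surviving < 8)
    stop("only ", surviving, " bins with data survive the exclusion in the region")
  excl_prof <- averageProfiles(band2, region)
  excl_pg <- lombScargle(excl_prof, config, nConditions = band@nConditions)
  list(full = list(profile = full_prof, periodogram = full_pg),
       excluded = list(profile = excl_prof, periodogram = excl_pg),
       deltaPeriod = excl_pg@peakPeriod - full_pg@peakPeriod,
       deltaPNmax = excl_pg@pnmax - full_pg@pnmax)
}
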