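#' Assemble a full-run configuration
#'
#' One serializable list holding every constant of the canonical
#' analysis: 500 bp bins, a +/-200 kbp correlation band, 400 kbp windows
#' sliding at 5 kbp over a 10-70 kbp period range, +/-500 bp regulator
#' flanks, a 20 kbp contact-pair exclusion, 100 random regulator subsets
#' and 5 expression-strength strata. A single `seed` expands into
#' per-stage seeds by fixed offsets (simulation +1, contacts +2,
#' regulator subsets +3, randomization null +4), so any stage can be
#' reproduced in isolation.
#'
#' @param genomeLength genome length in bp (synthetic mode).
#' @param binWidth,step,circular bin grid parameters.
#' @param maxLag correlation band half-width in bp.
#' @param window,slide,periodMin,periodMax,oversampling scan parameters,
#'   see [scanConfig()].
#' @param nRandomizations shuffled-genome replicates (0 skips the null).
#' @param flank regulator target flank in bp.
#' @param minLinearDistance contact-pair exclusion radius in bp.
#' @param nRandomSubsets random regulator subsets.
#' @param nStrata expression-strength strata.
#' @param contactGroups contact-frequency group count.
#' @param maskDenominator `"exclude"` or `"include"`, see
#'   [normalizeAndAverage()].
#' @param seed master integer seed.
#' @param ... extra fields stored verbatim (e.g. synthetic-truth
#'   parameters `nRegions`, `periodChoices`, `noiseSd`, `couplingBoost`).
#' @return classed list (`"RunConfig"`).
#' @export
runConfig <- function(genomeLength = 1e6, binWidth = 500, step = binWidth,
                      circular = TRUE, maxLag = 200000,
                      window = 400000, slide = 5000,
                      periodMin = 10000, periodMax = 70000,
                      oversampling = 4, nRandomizations = 0,
                      flank = 500, minLinearDistance = 20000,
                      nRandomSubsets = 100, nStrata = 5,
                      contactGroups = 8,
                      maskDenominator = "exclude", seed = 1, ...) {
  structure(list(genomeLength = genomeLength, binWidth = binWidth,
                 step = step, circular = circular, maxLag = maxLag,
                 window = window, slide = slide, periodMin = periodMin,
                 periodMax = periodMax, oversampling = oversampling,
                 nRandomizations = nRandomizations, flank = flank,
                 minLinearDistance = minLinearDistance,
                 nRandomSubsets = nRandomSubsets, nStrata = nStrata,
                 contactGroups = contactGroups,
                 maskDenominator = maskDenominator, seed = seed, ...),
            class = "RunConfig")
}

#' Run the full analysis on a synthetic bundle or files
#'
#' Executes binning, the correlation band, the sliding-window
#' periodicity scan (plus the shuffled-genome null when
#' `nRandomizations > 0`), the orientation analysis, the regulator
#' subset analysis and the 3C association, in order. Deterministic for
#' a given config; the config is attached to the result.
#'
#' @param config a [runConfig()].
#' @param bundle optional [SyntheticBundle-class]; when omitted, a
#'   bundle is simulated from the config's synthetic-truth fields
#'   (`periodChoices` etc.).
#' @param targetsFile optional regulator TSV path; defaults to the
#'   bundle's truth regulators.
#' @return list of stage outputs (`expression`, `band`, `scan`, `null`,
#'   `orientation`, `contrast`, `regulon`, `hic`) with the config as
#'   attribute `"config"`.
#' @export
runAll <- function(config, bundle = NULL, targetsFile = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(bundle)) {
    bundle <- stage("simulate", {
      truth <- makeTruth(config$genomeLength,
                         nRegions = config$nRegions %||% 1,
                         periodChoices = config$periodChoices %||% 40000,
                         seed = config$seed,
                         amplitude = config$amplitude %||% 1)
      b <- simulateExpression(truth, noiseSd = config$noiseSd %||% 0.2,
                              binWidth = config$binWidth,
                              seed = config$seed + 1L)
      setContacts(b, simulateContacts(truth,
                    couplingBoost = config$couplingBoost %||% 1,
                    seed = config$seed + 2L))
    })
  }
  expr <- stage("binning",
    bundleExpression(bundle, maskDenominator = config$maskDenominator))
  band <- stage("cped", correlationBand(expr, maxLag = config$maxLag))
  sc <- scanConfig(window = config$window, slide = config$slide,
                   periodMin = config$periodMin,
                   periodMax = config$periodMax,
                   oversampling = config$oversampling,
                   nRandomizations = config$nRandomizations,
                   maxLag = config$maxLag, seed = config$seed + 4L)
  scan <- stage("periodicity", scanGenome(band, sc))
  null <- if (config$nRandomizations > 0)
    stage("null", randomizationNull(expr, sc)) else NULL

  orientation <- stage("orientation",
    assignOrientation(bundle@annotation, expr@grid))
  oband <- stage("orientation", mirrorProfiles(band, orientation))
  region <- c(0, expr@grid@genomeLength)
  contrast <- stage("orientation", supercoilingContrast(
    averageProfiles(oband, region), averageProfiles(band, region)))

  regulon <- stage("regulon", {
    regs <- if (!is.null(targetsFile))
      parseTargets(targetsFile, expr@grid, bundle@annotation,
                   flank = config$flank)
    else {
      raw <- bundle@truth@regulators
      out <- list()
      for (nm in names(raw)) {
        at <- targetBins(raw[[nm]], expr@grid, config$flank)
        if (length(at) > 20)
          out[[nm]] <- structure(list(regulator = nm, positions = raw[[nm]],
                                      flank = config$flank, atBins = at),
                                 class = "RegulatorTargets")
      }
      out
    }
    lapply(regs, function(tg)
      subsetDistributions(band, tg, nRandom = config$nRandomSubsets,
                          seed = config$seed + 3L))
  })

  hic <- if (!is.null(bundle@contacts)) stage("hic", {
    expr5k <- rebinExpression(expr, binGrid(bundle@contacts)@binWidth)
    pairs <- buildPairs(expr5k, bundle@contacts,
                        minLinearDistance = config$minLinearDistance)
    groupAndTest(pairs, nGroups = config$contactGroups)
  }) else NULL

  out <- list(bundle = bundle, expression = expr, band = band, scan = scan,
              null = null, orientation = orientation, contrast = contrast,
              regulon = regulon, hic = hic)
  attr(out, "config") <- config
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
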