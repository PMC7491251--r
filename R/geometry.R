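#' DNA contour-length geometry
#'
#' Desk arithmetic relating genomic lengths to physical dimensions at
#' 3.4 Angstrom (0.34 nm) per base pair: the contour length of a
#' stretch of B-DNA, and the circumference and diameter of a circle
#' formed by it. A 20 kbp loop is ~6.8 um around — ~2.1 um across,
#' the width of an exponential-phase E. coli cell — while the full
#' 4.6 Mbp chromosome is ~1,564 um of DNA, which is why plectonemic
#' substructure rather than one open ring is the only geometrically
#' plausible arrangement.
#'
#' @param bp length in base pairs.
#' @param risePerBp axial rise per base pair in micrometres
#'   (default 3.4e-4, i.e. 3.4 Angstrom).
#' @return `dnaContourLength`: contour length in micrometres.
#' @examples
#' dnaContourLength(20000)       # 6.8 um
#' loopGeometry(20000)$diameter  # ~2.16 um
#' @export
dnaContourLength <- function(bp, risePerBp = 3.4e-4) {
  bp * risePerBp
}

#' @rdname dnaContourLength
#' @return `loopGeometry`: list with `circumference` and `diameter` of a
#'   circular loop of `bp` base pairs, in micrometres.
#' @export
loopGeometry <- function(bp, risePerBp = 3.4e-4) {
  circ <- dnaContourLength(bp, risePerBp)
  list(circumference = circ, diameter = circ / pi)
}
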