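#' EightCMMatch: a located eight-cysteine motif
#'
#' Records the positions of the eight backbone cysteines of an 8CM match and
#' the five variable inter-cysteine gaps. Positions are 1-based indices into
#' the scanned sequence. The CC dyad (cysteines 3 and 4 adjacent) and the
#' CXC triplet (cysteines 5 and 6 separated by one residue) are structural
#' constants of the motif and are enforced by the validity method; only the
#' five variable gaps (C1-C2, C2-C3, C4-C5, C6-C7, C7-C8) are stored, each
#' counting the residues strictly between the two flanking cysteines.
#'
#' @slot positions integer(8), strictly increasing 1-based cysteine indices.
#' @slot gaps integer(5), the variable spacings (g1, g2, g4, g6, g7).
#'
#' @seealso [findEightCM()], [spacingSignature()]
#' @export
setClass("EightCMMatch",
  representation(positions = "integer", gaps = "integer"))

setValidity("EightCMMatch", function(object) {
  p <- object@positions
  g <- object@gaps
  msg <- character()
  if (length(p) != 8L) msg <- c(msg, "positions must have length 8")
  if (length(g) != 5L) msg <- c(msg, "gaps must have length 5")
  if (length(p) == 8L) {
    if (any(diff(p) <= 0L)) msg <- c(msg, "positions must be strictly increasing")
    if (p[4L] != p[3L] + 1L) msg <- c(msg, "cysteines 3 and 4 must be adjacent (CC dyad)")
    if (p[6L] != p[5L] + 2L) msg <- c(msg, "cysteines 5 and 6 must flank one residue (CXC triplet)")
    if (length(g) == 5L) {
      expect <- c(p[2L] - p[1L], p[3L] - p[2L], p[5L] - p[4L],
                  p[7L] - p[6L], p[8L] - p[7L]) - 1L
      if (!identical(as.integer(expect), g))
        msg <- c(msg, "gaps inconsistent with positions")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn EightCMMatch Cysteine positions (1-based).
#' @param object,x An `EightCMMatch`.
#' @export
setGeneric("motifPositions", function(x) standardGeneric("motifPositions"))

#' @rdname EightCMMatch-class
#' @export
setMethod("motifPositions", "EightCMMatch", function(x) x@positions)

setMethod("show", "EightCMMatch", function(object) {
  cat("EightCMMatch: C1..C8 at",
      paste(object@positions, collapse = ", "), "\n")
  cat("  spacing signature (g1,g2,g4,g6,g7):",
      paste(object@gaps, collapse = ","), "\n")
})

.EightCMMatch <- function(positions) {
  p <- as.integer(positions)
  g <- as.integer(c(p[2L] - p[1L], p[3L] - p[2L], p[5L] - p[4L],
                    p[7L] - p[6L], p[8L] - p[7L]) - 1L)
  new("EightCMMatch", positions = p, gaps = g)
}
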