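#' Detect the eight-cysteine motif in a protein sequence
#'
#' Searches for eight cysteines forming the nsLTP backbone
#' C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C: cysteines 3 and 4 adjacent (CC dyad),
#' cysteines 5 and 6 separated by exactly one residue (CXC triplet), and the
#' five variable gaps (C1-C2, C2-C3, C4-C5, C6-C7, C7-C8) each within
#' `[minGap, maxGap]` residues. Gaps count residues strictly between the two
#' flanking cysteines. Extra cysteines outside the matched backbone are
#' permitted (type G proteins carry cysteine-free long C-terminal
#' extensions, but user data need not).
#'
#' When several eight-cysteine assignments are valid, the
#' lexicographically smallest position vector is returned
#' (leftmost-then-most-compact), which makes the result deterministic and
#' favours an N-terminal mature domain.
#'
#' @param sequence Protein sequence (character or [Biostrings::AAString]).
#' @param minGap,maxGap Bounds for the five variable gaps. The defaults
#'   (2, 40) bracket every spacing observed in the family types (5-29) with
#'   margin.
#' @return An [EightCMMatch-class] or `NULL` when no assignment exists.
#' @examples
#' # minimal backbone with every variable gap equal to 2
#' findEightCM("MCAACAACCAACACAACAAC")
#' @export
findEightCM <- function(sequence, minGap = 2L, maxGap = 40L) {
  sequence <- .seqChar(sequence)
  stopifnot(minGap >= 1L, minGap <= maxGap)
  res <- strsplit(sequence, "")[[1]]
  cs <- which(res == "C")
  if (length(cs) < 8L) return(NULL)
  minGap <- as.integer(minGap); maxGap <- as.integer(maxGap)
  # required gap range between consecutive backbone cysteines k and k+1
  # (difference of positions minus one); slots 3 and 5 are structural
  lo <- c(minGap, minGap, 0L, minGap, 1L, minGap, minGap)
  hi <- c(maxGap, maxGap, 0L, maxGap, 1L, maxGap, maxGap)
  n <- length(cs)
  # depth-first search in ascending position order: the first complete
  # assignment found is the lexicographically smallest position vector
  found <- NULL
  chosen <- integer(8L)
  recurse <- function(level, fromIdx) {
    for (i in fromIdx:n) {
      p <- cs[i]
      if (level > 1L) {
        gap <- p - chosen[level - 1L] - 1L
        if (gap < lo[level - 1L]) next
        if (gap > hi[level - 1L]) break  # positions ascend; no later fit
      }
      chosen[level] <<- p
      if (level == 8L) { found <<- chosen; return(TRUE) }
      if (i < n && recurse(level + 1L, i + 1L)) return(TRUE)
    }
    FALSE
  }
  if (n >= 8L) recurse(1L, 1L)
  if (is.null(found)) NULL else .EightCMMatch(found)
}

#' Scan a set of proteins for the eight-cysteine motif
#'
#' @param proteins Named [Biostrings::AAStringSet] or named character vector.
#' @inheritParams findEightCM
#' @return A [S4Vectors::DataFrame] with one row per protein: `id`,
#'   `has_8cm`, the eight cysteine positions `c1`..`c8` (NA when absent) and
#'   the spacing signature `g1,g2,g4,g6,g7`.
#' @export
scanEightCM <- function(proteins, minGap = 2L, maxGap = 40L) {
  seqs <- .seqChar(proteins)
  ids <- names(seqs)
  if (is.null(ids)) stop("proteins must be named")
  hits <- lapply(seqs, findEightCM, minGap = minGap, maxGap = maxGap)
  pos <- t(vapply(hits, function(h)
    if (is.null(h)) rep(NA_integer_, 8L) else motifPositions(h), integer(8L)))
  gaps <- t(vapply(hits, function(h)
    if (is.null(h)) rep(NA_integer_, 5L) else h@gaps, integer(5L)))
  colnames(pos) <- paste0("c", 1:8)
  colnames(gaps) <- c("g1", "g2", "g4", "g6", "g7")
  S4Vectors::DataFrame(id = ids, has_8cm = !vapply(hits, is.null, logical(1)),
                       pos, gaps, row.names = NULL)
}

#' Spacing signature of an 8CM match
#'
#' @param match An [EightCMMatch-class].
#' @return Integer vector of the five variable gaps (g1, g2, g4, g6, g7).
#' @export
spacingSignature <- function(match) {
  stopifnot(is(match, "EightCMMatch"))
  setNames(match@gaps, c("g1", "g2", "g4", "g6", "g7"))
}

#' Load the packaged per-type spacing grammars
#'
#' One grammar per nsLTP type (1, 2, C, D, E, G), each listing the allowed
#' values of the five variable 8CM gaps and whether the type is
#' GPI-anchored. The values mirror the spacings observed in the cabbage
#' family; pass a custom YAML file to generalise them (e.g. to ranges).
#'
#' @param path Optional path to a YAML grammar file with the same layout as
#'   the packaged default.
#' @return Named list of grammars; each grammar is a list with elements
#'   `gpi` (logical) and `g1`, `g2`, `g4`, `g6`, `g7` (integer vectors).
#' @export
ltpGrammars <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "spacing_grammars.yaml",
                        package = "nsLTPscan", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  lapply(raw, function(g) {
    out <- list(gpi = isTRUE(g$gpi))
    for (slot in c("g1", "g2", "g4", "g6", "g7")) {
      v <- as.integer(g[[slot]])
      if (!length(v) || any(v <= 0L))
        stop("grammar slot ", slot, " must be a non-empty set of positive integers")
      out[[slot]] <- v
    }
    out
  })
}

#' Test a spacing signature against a type grammar
#'
#' @param signature Integer vector of length 5 (g1, g2, g4, g6, g7).
#' @param grammar One element of [ltpGrammars()].
#' @return `TRUE` iff every gap is a member of the grammar's allowed set for
#'   that slot.
#' @export
matchesGrammar <- function(signature, grammar) {
  stopifnot(length(signature) == 5L)
  slots <- c("g1", "g2", "g4", "g6", "g7")
  all(vapply(seq_len(5L), function(i)
    signature[[i]] %in% grammar[[slots[i]]], logical(1)))
}

#' Predict the disulfide pairing of an 8CM
#'
#' The cysteine pairing of the four disulfide bridges follows the
#' hydrophobicity of the central residue of the CXC triplet: a hydrophilic
#' centre gives the pairing C1-C6, C2-C3, C4-C7, C5-C8 (type 1 pattern); a
#' hydrophobic centre gives C1-C5, C2-C3, C4-C7, C6-C8 (type 2/D pattern).
#' Hydrophilicity is judged on the Kyte-Doolittle scale with threshold 0.
#'
#' @param sequence The scanned protein sequence.
#' @param match The [EightCMMatch-class] located in `sequence`.
#' @param scale Named numeric hydropathy scale (default Kyte-Doolittle).
#' @return A 4x2 integer matrix of 1-based cysteine indices, one bridge per
#'   row.
#' @export
predictDisulfidePairing <- function(sequence, match, scale = KD_SCALE) {
  sequence <- .seqChar(sequence)
  stopifnot(is(match, "EightCMMatch"))
  centre <- substr(sequence, match@positions[5L] + 1L, match@positions[5L] + 1L)
  h <- unname(scale[centre])
  if (is.na(h)) stop("CXC centre residue ", centre, " not in hydropathy scale")
  pairs <- if (h <= 0)
    matrix(c(1L, 6L, 2L, 3L, 4L, 7L, 5L, 8L), ncol = 2L, byrow = TRUE)
  else
    matrix(c(1L, 5L, 2L, 3L, 4L, 7L, 6L, 8L), ncol = 2L, byrow = TRUE)
  colnames(pairs) <- c("from", "to")
  pairs
}
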