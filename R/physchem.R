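# Average residue masses (Da); a peptide adds one water (18.01524 Da).
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# pKa sets for the isoelectric-point computation. The Bjellqvist set (the
# default) uses residue-specific N-terminal pKa values; side chains cover
# D, E, C, Y (acidic) and H, K, R (basic).
PKA_SETS <- list(
  bjellqvist = list(
    nterm = c(default = 7.5, A = 7.59, M = 7.0, S = 6.93, P = 8.36,
              T = 6.82, V = 7.44, E = 7.7),
    cterm = c(default = 3.55, D = 4.55, E = 4.75),
    side = c(C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0,
             R = 12.0, Y = 10.0)
  ),
  emboss = list(
    nterm = c(default = 8.6),
    cterm = c(default = 3.6),
    side = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8,
             R = 12.5, Y = 10.1)
  ),
  ipc_protein = list(
    nterm = c(default = 9.094),
    cterm = c(default = 2.869),
    side = c(C = 7.555, D = 3.872, E = 4.412, H = 5.637, K = 9.052,
             R = 11.84, Y = 10.85)
  )
)

#' Mature sequence after signal-peptide cleavage
#'
#' Removes the N-terminal signal peptide from a precursor. GPI-anchored
#' proteins keep their C-terminal anchor signal: the downstream tail is not
#' trimmed, so type-G mature lengths include it.
#'
#' @param precursor Precursor sequence.
#' @param spCall A signal-peptide call as returned by
#'   [predictSignalPeptide()] (or a bare positive integer cleavage length).
#' @return The mature sequence (character).
#' @export
matureSequence <- function(precursor, spCall) {
  precursor <- .seqChar(precursor)
  if (is.numeric(spCall)) spCall <- list(present = spCall > 0,
                                         cleavage_len = as.integer(spCall))
  if (!isTRUE(spCall$present) || is.na(spCall$cleavage_len) ||
      spCall$cleavage_len < 1L)
    stop("cannot derive a mature sequence without a signal-peptide call")
  if (spCall$cleavage_len >= nchar(precursor))
    stop("cleavage length ", spCall$cleavage_len,
         " leaves no mature sequence")
  substr(precursor, spCall$cleavage_len + 1L, nchar(precursor))
}

#' Average molecular mass of a peptide
#'
#' Sum of the residue average masses plus one water (18.01524 Da), the
#' convention used by standard pI/Mw calculators.
#'
#' @param sequence Peptide sequence (canonical residues only).
#' @return Mass in Da.
#' @examples
#' averageMass("G") # glycine residue + water = 75.07 Da
#' @export
averageMass <- function(sequence) {
  sequence <- .seqChar(sequence)
  if (!nchar(sequence)) stop("empty sequence has no defined mass")
  res <- .assertCanonical(sequence, "peptide")
  sum(RESIDUE_MASS[res]) + WATER_MASS
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups: the N-terminus plus
#' H, K, R side chains (positive) and the C-terminus plus D, E, C, Y side
#' chains (negative).
#'
#' @param sequence Peptide sequence.
#' @param pH pH value(s).
#' @param pkaSet One of `"bjellqvist"` (default), `"emboss"`,
#'   `"ipc_protein"`, or a list with elements `nterm`, `cterm`, `side`.
#' @return Net charge, vectorized over `pH`.
#' @export
peptideCharge <- function(sequence, pH, pkaSet = "bjellqvist") {
  sequence <- .seqChar(sequence)
  res <- .assertCanonical(sequence, "peptide")
  pka <- if (is.character(pkaSet)) PKA_SETS[[match.arg(pkaSet, names(PKA_SETS))]]
         else pkaSet
  term <- function(tab, residue) {
    if (residue %in% names(tab)) tab[[residue]] else tab[["default"]]
  }
  posPka <- c(term(pka$nterm, res[1]),
              rep(pka$side["H"], sum(res == "H")),
              rep(pka$side["K"], sum(res == "K")),
              rep(pka$side["R"], sum(res == "R")))
  negPka <- c(term(pka$cterm, res[length(res)]),
              rep(pka$side["D"], sum(res == "D")),
              rep(pka$side["E"], sum(res == "E")),
              rep(pka$side["C"], sum(res == "C")),
              rep(pka$side["Y"], sum(res == "Y")))
  vapply(pH, function(p)
    sum(1 / (1 + 10^(p - posPka))) - sum(1 / (1 + 10^(negPka - p))),
    numeric(1))
}

#' Theoretical isoelectric point
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge of the
#' peptide is zero, by bisection on [0, 14]. The charge is strictly
#' decreasing in pH, so the root is unique; iteration stops when
#' |charge| < `tol`.
#'
#' @inheritParams peptideCharge
#' @param tol Charge tolerance at the root (default 1e-4).
#' @param maxIter Maximum bisection iterations (default 100).
#' @return The pI (numeric).
#' @export
isoelectricPoint <- function(sequence, pkaSet = "bjellqvist",
                             tol = 1e-4, maxIter = 100L) {
  sequence <- .seqChar(sequence)
  lo <- 0; hi <- 14
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    q <- peptideCharge(sequence, mid, pkaSet)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical characterization of mature proteins
#'
#' Convenience wrapper: cleaves each precursor at its signal-peptide call
#' and computes mature length, average mass and theoretical pI.
#'
#' @param precursors Named [Biostrings::AAStringSet] or named character
#'   vector.
#' @param spLens Named integer vector of signal-peptide lengths (names
#'   matching `precursors`); by default [predictSignalPeptide()] is run on
#'   each precursor.
#' @param pkaSet Passed to [isoelectricPoint()].
#' @return A `data.frame` with columns id, sp_len, mature_len, mass_da, pi.
#' @export
physchemTable <- function(precursors, spLens = NULL, pkaSet = "bjellqvist") {
  seqs <- .seqChar(precursors)
  ids <- names(seqs)
  if (is.null(ids)) stop("precursors must be named")
  rows <- lapply(ids, function(id) {
    sl <- if (!is.null(spLens)) unname(spLens[id])
          else predictSignalPeptide(seqs[[id]])$cleavage_len
    if (is.na(sl)) return(data.frame(id = id, sp_len = NA_integer_,
                                     mature_len = NA_integer_,
                                     mass_da = NA_real_, pi = NA_real_))
    mat <- matureSequence(seqs[[id]], sl)
    data.frame(id = id, sp_len = as.integer(sl), mature_len = nchar(mat),
               mass_da = averageMass(mat),
               pi = isoelectricPoint(mat, pkaSet))
  })
  do.call(rbind, rows)
}
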