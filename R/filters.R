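SMALL_CLEAVAGE <- c("A", "G", "S", "C", "T")   # (-3,-1) rule residues
SMALL_OMEGA <- c("A", "G", "S", "N", "D", "C") # GPI attachment residues

#' Predict an N-terminal signal peptide
#'
#' A documented heuristic standing in for a full secretory-signal
#' predictor. A signal peptide is called when, within the first 45
#' residues, there is (i) a hydrophobic core: a window of at least
#' `coreLen` consecutive residues with mean Kyte-Doolittle hydropathy >=
#' `coreHydro`, starting within the first 12 residues after an optional
#' positively charged N-region (a leading stretch of M/K/R), and (ii) a
#' cleavage site 3-12 residues after the core end whose -3 and -1 residues
#' are both small (A, G, S, C, T). The cleavage length is the index of the
#' -1 residue (the mature protein starts immediately after it); among
#' feasible sites the most N-terminal is reported. External predictor
#' output can be substituted via the `externalCalls` argument of
#' [runFilterCascade()].
#'
#' @param sequence Precursor sequence of length >= 30.
#' @param coreLen Minimum hydrophobic-core length (default 8).
#' @param coreHydro Minimum mean core hydropathy (default 1.6).
#' @return A list with elements `present` (logical), `cleavage_len`
#'   (integer, NA when absent) and `score` (min(1, core hydropathy / 3), 0
#'   when absent).
#' @export
predictSignalPeptide <- function(sequence, coreLen = 8L, coreHydro = 1.6) {
  sequence <- .seqChar(sequence)
  res <- .assertCanonical(sequence, "precursor")
  if (length(res) < 30L)
    stop("sequence shorter than 30 residues; cannot evaluate a signal peptide")
  lim <- min(45L, length(res))
  kd <- unname(KD_SCALE[res[seq_len(lim)]])
  nRegion <- 0L
  while (nRegion < lim && res[nRegion + 1L] %in% c("M", "K", "R"))
    nRegion <- nRegion + 1L
  maxStart <- min(nRegion + 12L, lim - coreLen + 1L)
  cum <- c(0, cumsum(kd))
  winMean <- function(s, e) (cum[e + 1L] - cum[s]) / (e - s + 1L)
  # feasible core ends, and the best attainable core mean for each end
  coreEnds <- integer(0)
  endMean <- numeric(0)
  for (e in seq.int(coreLen, lim)) {
    starts <- seq_len(min(maxStart, e - coreLen + 1L))
    if (!length(starts)) next
    means <- vapply(starts, function(s) winMean(s, e), numeric(1))
    if (any(means >= coreHydro)) {
      coreEnds <- c(coreEnds, e)
      endMean <- c(endMean, max(means))
    }
  }
  absent <- list(present = FALSE, cleavage_len = NA_integer_, score = 0)
  if (!length(coreEnds)) return(absent)
  for (cl in seq.int(min(coreEnds) + 3L, lim)) {
    if (cl - 2L < 1L) next
    if (!(res[cl] %in% SMALL_CLEAVAGE && res[cl - 2L] %in% SMALL_CLEAVAGE))
      next
    ok <- coreEnds[cl - coreEnds >= 3L & cl - coreEnds <= 12L]
    if (length(ok)) {
      best <- max(endMean[match(ok, coreEnds)])
      return(list(present = TRUE, cleavage_len = cl,
                  score = min(1, best / 3)))
    }
  }
  absent
}

#' Predict a C-terminal GPI-anchor signal
#'
#' Heuristic GPI call: present when the final 25 residues contain a
#' hydrophobic stretch of at least 8 residues (mean Kyte-Doolittle
#' hydropathy >= 1.5) preceded, 8-12 residues upstream of the stretch
#' start, by a small residue (A, G, S, N, D, C) designated the omega
#' (attachment) site. The earliest qualifying stretch is used and the
#' qualifying omega closest to it is reported.
#'
#' @param sequence Mature or precursor sequence of length >= 40.
#' @return A list with `present` (logical) and `omega_pos` (1-based index,
#'   NA when absent).
#' @export
predictGpiAnchor <- function(sequence) {
  sequence <- .seqChar(sequence)
  res <- .assertCanonical(sequence, "sequence")
  n <- length(res)
  if (n < 40L) stop("sequence shorter than 40 residues; cannot evaluate GPI signal")
  kd <- unname(KD_SCALE[res])
  cum <- c(0, cumsum(kd))
  first <- max(n - 24L, 1L)
  for (t in seq.int(first, n - 7L)) {
    if ((cum[t + 8L] - cum[t]) / 8 < 1.5) next
    omega <- seq.int(max(t - 12L, 1L), t - 8L)
    omega <- omega[omega >= 1L & res[omega] %in% SMALL_OMEGA]
    if (length(omega)) {
      w <- max(omega)
      if (n - w >= 10L)
        return(list(present = TRUE, omega_pos = w))
    }
  }
  list(present = FALSE, omega_pos = NA_integer_)
}

#' Test whether a candidate is a hybrid proline-rich protein
#'
#' HyPRPs carry the 8CM but are excluded from the nsLTP family. The rule
#' used here: the region between the signal peptide and the first 8CM
#' cysteine is at least 20 residues long and at least 25% proline.
#'
#' @param sequence Precursor sequence.
#' @param spLen Signal-peptide length (residues).
#' @param motifStart 1-based position of the first backbone cysteine;
#'   defaults to the first cysteine in the sequence.
#' @param minLen,minPro Rule thresholds (defaults 20 aa, 0.25).
#' @return Logical.
#' @export
isHyprp <- function(sequence, spLen, motifStart = NULL,
                    minLen = 20L, minPro = 0.25) {
  sequence <- .seqChar(sequence)
  res <- strsplit(sequence, "")[[1]]
  if (is.null(motifStart)) {
    motifStart <- which(res == "C")[1]
    if (is.na(motifStart)) return(FALSE)
  }
  region <- res[seq_len(length(res)) > spLen &
                seq_len(length(res)) < motifStart]
  length(region) >= minLen && mean(region == "P") >= minPro
}

#' Exclude a candidate by similarity to reference proteins
#'
#' Flags candidates that align to any member of a user-supplied exclusion
#' set (known protease inhibitors / seed storage proteins, which share the
#' nsLTP Pfam domain) with global-alignment identity >= `minIdentity` and
#' coverage of the shorter sequence >= `minCoverage`.
#'
#' @param candidate Candidate sequence.
#' @param exclusionRefs [Biostrings::AAStringSet] (or named character) of
#'   reference sequences; when empty every candidate is kept and a warning
#'   is raised once.
#' @param minIdentity Identity floor (default 0.40).
#' @param minCoverage Coverage floor on the shorter sequence (default 0.75).
#' @return Logical: `TRUE` when the candidate should be excluded.
#' @export
excludeBySimilarity <- function(candidate, exclusionRefs,
                                minIdentity = 0.40, minCoverage = 0.75) {
  if (length(exclusionRefs) == 0L) {
    warning("empty exclusion reference set; no candidates excluded")
    return(FALSE)
  }
  refs <- .seqChar(exclusionRefs)
  candidate <- .seqChar(candidate)
  for (ref in refs) {
    al <- .alignPair(candidate, ref)
    if (al$identity >= minIdentity && al$coverage >= minCoverage)
      return(TRUE)
  }
  FALSE
}

FILTER_STAGES <- c("no_8cm", "no_signal_peptide", "similar_to_exclusion",
                   "hyprp")

#' Run the candidate filter cascade
#'
#' Applies, in order: the essential-cysteine (8CM) check, the N-terminal
#' signal-sequence check, the similarity exclusion against protease
#' inhibitor / storage protein references, and the hybrid proline-rich
#' protein check. Every rejected protein carries exactly one reason — the
#' first failing stage — and the kept and rejected sets partition the
#' input.
#'
#' @param candidates Named [Biostrings::AAStringSet] or named character
#'   vector of precursor sequences.
#' @param exclusionRefs Optional exclusion reference set (see
#'   [excludeBySimilarity()]); `NULL` disables the similarity stage.
#' @param config Named list of knobs: `minGap`, `maxGap` (8CM scan),
#'   `minIdentity`, `minCoverage` (similarity stage), `hyprpMinLen`,
#'   `hyprpMinPro`. Defaults as in the stage functions.
#' @param externalCalls Optional `data.frame` of precomputed predictor
#'   output with columns `id`, `sp_present`, `sp_len`, `gpi_present`,
#'   `omega_pos`, substituting for the built-in signal-peptide and GPI
#'   heuristics.
#' @return A list: `kept` ([S4Vectors::DataFrame] with id, motif columns,
#'   sp_len, gpi_present, omega_pos), `rejected` (`data.frame` of id and
#'   reason), and `stage_counts` (named integer vector of rejections per
#'   stage, plus `input` and `kept`).
#' @export
runFilterCascade <- function(candidates, exclusionRefs = NULL,
                             config = list(), externalCalls = NULL) {
  seqs <- .seqChar(candidates)
  ids <- names(seqs)
  if (length(seqs) && is.null(ids)) stop("candidates must be named")
  cfg <- modifyList(list(minGap = 2L, maxGap = 40L, minIdentity = 0.40,
                         minCoverage = 0.75, hyprpMinLen = 20L,
                         hyprpMinPro = 0.25), config)
  keptRows <- list()
  rejected <- data.frame(id = character(), reason = character())
  counts <- setNames(integer(length(FILTER_STAGES)), FILTER_STAGES)
  doSim <- !is.null(exclusionRefs)
  if (doSim && length(exclusionRefs) == 0L) {
    warning("empty exclusion reference set; similarity stage skipped")
    doSim <- FALSE
  }
  ext <- NULL
  if (!is.null(externalCalls)) {
    ext <- externalCalls
    rownames(ext) <- ext$id
  }
  for (id in ids) {
    s <- seqs[[id]]
    m <- findEightCM(s, cfg$minGap, cfg$maxGap)
    if (is.null(m)) {
      rejected <- rbind(rejected, data.frame(id = id, reason = "no_8cm"))
      counts["no_8cm"] <- counts["no_8cm"] + 1L
      next
    }
    if (!is.null(ext) && id %in% rownames(ext)) {
      sp <- list(present = isTRUE(ext[id, "sp_present"]),
                 cleavage_len = as.integer(ext[id, "sp_len"]), score = NA_real_)
      gpi <- list(present = isTRUE(ext[id, "gpi_present"]),
                  omega_pos = as.integer(ext[id, "omega_pos"]))
    } else {
      sp <- predictSignalPeptide(s)
      gpi <- if (nchar(s) >= 40L) predictGpiAnchor(s)
             else list(present = FALSE, omega_pos = NA_integer_)
    }
    if (!sp$present) {
      rejected <- rbind(rejected,
                        data.frame(id = id, reason = "no_signal_peptide"))
      counts["no_signal_peptide"] <- counts["no_signal_peptide"] + 1L
      next
    }
    if (doSim && excludeBySimilarity(s, exclusionRefs,
                                     cfg$minIdentity, cfg$minCoverage)) {
      rejected <- rbind(rejected,
                        data.frame(id = id, reason = "similar_to_exclusion"))
      counts["similar_to_exclusion"] <- counts["similar_to_exclusion"] + 1L
      next
    }
    if (isHyprp(s, sp$cleavage_len, motifStart = motifPositions(m)[1],
                minLen = cfg$hyprpMinLen, minPro = cfg$hyprpMinPro)) {
      rejected <- rbind(rejected, data.frame(id = id, reason = "hyprp"))
      counts["hyprp"] <- counts["hyprp"] + 1L
      next
    }
    keptRows[[id]] <- S4Vectors::DataFrame(
      id = id, sp_len = sp$cleavage_len, sp_score = sp$score,
      gpi_present = gpi$present, omega_pos = gpi$omega_pos,
      t(setNames(motifPositions(m), paste0("c", 1:8))),
      t(spacingSignature(m)))
  }
  kept <- if (length(keptRows)) do.call(rbind, unname(keptRows))
          else S4Vectors::DataFrame(id = character(0))
  stageCounts <- c(input = length(seqs), counts, kept = nrow(kept))
  stopifnot(nrow(kept) + nrow(rejected) == length(seqs))
  list(kept = kept, rejected = rejected, stage_counts = stageCounts)
}
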