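# Needleman-Wunsch global alignment of two protein sequences.
# Returns identity (matches / aligned columns excluding terminal gap
# columns), coverage (fraction of the shorter sequence inside the
# non-terminal columns) and the alignment score.
.alignPair <- function(a, b, gapOpening = 10, gapExtension = 0.5) {
  if (!nchar(a) || !nchar(b)) stop("cannot align an empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpening, gapExtension = gapExtension, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  n <- length(pa)
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
  keep <- seq.int(lead + 1L, n - trail)
  matches <- sum(pa[keep] == sa[keep] & pa[keep] != "-")
  cols <- length(keep)
  shorter <- min(nchar(a), nchar(b))
  shorterAligned <- if (nchar(a) <= nchar(b)) sum(pa[keep] != "-")
                    else sum(sa[keep] != "-")
  list(identity = matches / cols,
       coverage = shorterAligned / shorter,
       score = Biostrings::score(al))
}

#' Pairwise global-alignment identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5); identity is matches divided by aligned columns,
#' excluding terminal gap columns so that short sequences are not
#' penalized for length differences.
#'
#' @param a,b Protein sequences (character or [Biostrings::AAString]).
#' @param gapOpening,gapExtension Gap penalties.
#' @return Identity fraction in [0, 1]; symmetric in its arguments.
#' @export
pairwiseIdentity <- function(a, b, gapOpening = 10, gapExtension = 0.5) {
  .alignPair(.seqChar(a), .seqChar(b), gapOpening, gapExtension)$identity
}

#' All-against-all identity matrix
#'
#' @param proteins Named [Biostrings::AAStringSet] or named character
#'   vector of (mature) sequences.
#' @return Symmetric numeric matrix with unit diagonal, dimnames = protein
#'   ids.
#' @export
identityMatrix <- function(proteins) {
  seqs <- .seqChar(proteins)
  ids <- names(seqs)
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- pairwiseIdentity(seqs[[i]], seqs[[j]])
    }
  m
}

#' Assign an nsLTP type
#'
#' Two-round rule: a protein with a GPI-anchor call is type G regardless of
#' its spacing; otherwise the protein is compared against typed exemplar
#' sets (types 1, 2, C, D, E) by pairwise identity. Types whose best
#' exemplar identity reaches `minIdentity` are candidates; among candidates
#' the type with the highest mean identity wins, ties broken first by
#' spacing-grammar compatibility of the protein's 8CM signature, then
#' lexicographically. When no type reaches the floor the protein is listed
#' individually as type X.
#'
#' @param mature Mature protein sequence.
#' @param gpiCall A [predictGpiAnchor()]-style list (or logical).
#' @param exemplars Named list (names = type labels) of named character
#'   vectors / AAStringSets of typed mature exemplar sequences.
#' @param signature Optional 5-gap spacing signature of the protein's 8CM
#'   (used for grammar tie-breaks and the `grammar_ok` flag).
#' @param grammars Grammar list from [ltpGrammars()].
#' @param minIdentity Identity floor below which the protein is type X
#'   (default 0.30).
#' @return A list: `type`, `best_identity` (max identity over all
#'   exemplars), `grammar_ok` (signature compatible with the assigned
#'   type's grammar; NA for type X or missing signature).
#' @export
assignType <- function(mature, gpiCall, exemplars, signature = NULL,
                       grammars = ltpGrammars(), minIdentity = 0.30) {
  mature <- .seqChar(mature)
  gpi <- if (is.logical(gpiCall)) gpiCall else isTRUE(gpiCall$present)
  grammarOk <- function(type) {
    if (is.null(signature) || !type %in% names(grammars)) return(NA)
    matchesGrammar(signature, grammars[[type]])
  }
  if (gpi) {
    return(list(type = "G", best_identity = NA_real_,
                grammar_ok = grammarOk("G")))
  }
  if (!length(exemplars) || !any(lengths(exemplars) > 0L))
    stop("no typed exemplars supplied")
  stats <- lapply(exemplars, function(ex) {
    ids <- vapply(.seqChar(ex), function(e) pairwiseIdentity(mature, e),
                  numeric(1))
    list(top = max(ids), mean = mean(ids))
  })
  tops <- vapply(stats, `[[`, numeric(1), "top")
  means <- vapply(stats, `[[`, numeric(1), "mean")
  bestIdentity <- max(tops)
  cand <- names(stats)[tops >= minIdentity]
  if (!length(cand))
    return(list(type = "X", best_identity = bestIdentity, grammar_ok = NA))
  best <- cand[means[cand] == max(means[cand])]
  if (length(best) > 1L) {
    gOk <- vapply(best, function(t) isTRUE(grammarOk(t)), logical(1))
    if (any(gOk)) best <- best[gOk]
    best <- sort(best)[1]
  }
  list(type = best, best_identity = bestIdentity,
       grammar_ok = grammarOk(best))
}

#' Synthetic typed exemplars
#'
#' Mature exemplar sequences for the non-GPI types (1, 2, C, D and E),
#' assembled deterministically from the per-type family templates
#' ([typeTemplates()]) with every variable gap at the type's maximum
#' allowed value. These are synthetic grammar-conforming sequences, not
#' real plant proteins; supply curated Arabidopsis/rice references for
#' production use.
#'
#' @param types Type labels to include (default the five non-GPI types;
#'   GPI-anchored proteins are assigned type G before any identity
#'   comparison).
#' @return Named list of named character vectors, one element per type.
#' @export
defaultExemplars <- function(types = c("1", "2", "C", "D", "E")) {
  tpls <- typeTemplates()[types]
  out <- lapply(names(tpls), function(type) {
    tpl <- tpls[[type]]
    gaps <- nchar(c(tpl$g1, tpl$g2, tpl$g4, tpl$g6, tpl$g7))
    setNames(.assembleMature(tpl, gaps),
             paste0("exemplar_", type))
  })
  setNames(out, names(tpls))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (as implemented in the ape package) for a
#' quick clustering view of an identity matrix; use `1 - identity` as the
#' distance.
#'
#' @param d Symmetric numeric distance matrix with zero diagonal and
#'   dimnames, n >= 3.
#' @return Newick string with branch lengths.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(d))
  ape::write.tree(tree)
}
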