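#' Chromosome distribution of family genes
#'
#' @param geneIds Character vector of family gene identifiers (e.g. catalog
#'   names).
#' @param loci [GenomicRanges::GRanges] with a `gene_id` column (see
#'   [readGeneLoci()]); genes without a locus are counted as unanchored.
#' @return Named integer vector of per-chromosome counts plus an
#'   `unanchored` bucket; the counts sum to `length(geneIds)`.
#' @export
chromosomeDistribution <- function(geneIds, loci) {
  hit <- match(geneIds, loci$gene_id)
  if (anyDuplicated(loci$gene_id[loci$gene_id %in% geneIds]))
    stop("duplicate locus for gene(s): ",
         paste(unique(loci$gene_id[duplicated(loci$gene_id)]), collapse = ", "))
  chrom <- as.character(seqnames(loci))[hit]
  counts <- table(chrom[!is.na(hit)])
  out <- c(setNames(as.integer(counts), names(counts)),
           unanchored = sum(is.na(hit)))
  stopifnot(sum(out) == length(geneIds))
  out
}

#' Detect tandem duplicate arrays
#'
#' A tandem array is a maximal run of two or more family genes on one
#' chromosome in which consecutive family members are separated by at most
#' `maxIntervening` non-family genes and at most `maxDistance` base pairs
#' (start-to-start). Arrays are maximal and disjoint.
#'
#' @param familyIds Character vector of family gene identifiers.
#' @param loci [GenomicRanges::GRanges] of all annotated genes with a
#'   `gene_id` column.
#' @param maxIntervening Maximum number of intervening non-family genes
#'   between consecutive array members (default 1).
#' @param maxDistance Maximum start-to-start distance in bp (default 1e5).
#' @return A list of arrays, each a list with `chrom` and `members`
#'   (ordered gene ids).
#' @export
detectTandemArrays <- function(familyIds, loci, maxIntervening = 1L,
                               maxDistance = 1e5) {
  arrays <- list()
  for (chr in unique(as.character(seqnames(loci)))) {
    g <- loci[as.character(seqnames(loci)) == chr]
    g <- g[order(start(g))]
    fam <- which(g$gene_id %in% familyIds)
    if (length(fam) < 2L) next
    current <- fam[1]
    for (k in seq_along(fam)[-1]) {
      i <- fam[k]
      prev <- current[length(current)]
      intervening <- i - prev - 1L
      dist <- start(g)[i] - start(g)[prev]
      if (intervening <= maxIntervening && dist <= maxDistance) {
        current <- c(current, i)
      } else {
        if (length(current) >= 2L)
          arrays[[length(arrays) + 1L]] <-
            list(chrom = chr, members = g$gene_id[current])
        current <- i
      }
    }
    if (length(current) >= 2L)
      arrays[[length(arrays) + 1L]] <-
        list(chrom = chr, members = g$gene_id[current])
  }
  arrays
}

# best-hit table: for every query in a, the best-scoring subject in b
.bestHits <- function(a, b) {
  out <- vector("list", length(a))
  names(out) <- names(a)
  for (qa in names(a)) {
    best <- NULL
    for (sb in names(b)) {
      al <- .alignPair(a[[qa]], b[[sb]])
      if (is.null(best) || al$score > best$score ||
          (al$score == best$score &&
           (al$identity > best$identity ||
            (al$identity == best$identity && sb < best$subject)))) {
        best <- c(al, list(subject = sb))
      }
    }
    out[[qa]] <- best
  }
  out
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is emitted when b is a's best-scoring global-alignment hit
#' in proteome B and a is b's best hit in proteome A, and the pair passes
#' the coverage and identity floors. Score ties are broken by higher
#' identity and then lexicographic subject identifier. The output is a
#' partial matching: no gene appears twice.
#'
#' @param proteomeA,proteomeB Named [Biostrings::AAStringSet] or named
#'   character vectors.
#' @param minCoverage Coverage floor on the shorter sequence (default
#'   0.75).
#' @param minIdentity Identity floor (default 0.30).
#' @return A `data.frame` with columns query_id, subject_id, identity,
#'   coverage.
#' @export
reciprocalBestHits <- function(proteomeA, proteomeB,
                               minCoverage = 0.75, minIdentity = 0.30) {
  a <- .seqChar(proteomeA); b <- .seqChar(proteomeB)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      identity = numeric(), coverage = numeric())
  if (!length(a) || !length(b)) return(empty)
  ab <- .bestHits(a, b)
  ba <- .bestHits(b, a)
  rows <- list()
  for (qa in names(ab)) {
    hit <- ab[[qa]]
    if (ba[[hit$subject]]$subject != qa) next
    if (hit$coverage < minCoverage || hit$identity < minIdentity) next
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = qa, subject_id = hit$subject,
      identity = hit$identity, coverage = hit$coverage)
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Collinearity (synteny) filter on ortholog pairs
#'
#' A pair is called syntenic when at least `minAnchors - 1` other pairs lie
#' within `window` gene-order ranks of it on both genomes, on the same
#' chromosome pair, with a consistent relative order (a fully inverted
#' block also counts).
#'
#' @param pairs Ortholog pairs as from [reciprocalBestHits()].
#' @param geneOrderA,geneOrderB `data.frame`s with columns gene_id, chrom,
#'   rank (per-chromosome gene-order rank).
#' @param window Rank window (default 10).
#' @param minAnchors Minimum pairs per collinear block, including the pair
#'   itself (default 3).
#' @return The syntenic subset of `pairs`.
#' @export
collinearOrthologs <- function(pairs, geneOrderA, geneOrderB,
                               window = 10L, minAnchors = 3L) {
  if (!nrow(pairs)) return(pairs)
  ia <- match(pairs$query_id, geneOrderA$gene_id)
  ib <- match(pairs$subject_id, geneOrderB$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("pair references a gene absent from the gene order tables")
  ca <- geneOrderA$chrom[ia]; ra <- geneOrderA$rank[ia]
  cb <- geneOrderB$chrom[ib]; rb <- geneOrderB$rank[ib]
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    near <- which(ca == ca[i] & cb == cb[i] &
                  abs(ra - ra[i]) <= window & abs(rb - rb[i]) <= window)
    near <- setdiff(near, i)
    if (length(near) < minAnchors - 1L) next
    da <- sign(ra[near] - ra[i]); db <- sign(rb[near] - rb[i])
    same <- sum(da != 0 & da == db)
    inv <- sum(da != 0 & da == -db)
    keep[i] <- max(same, inv) >= minAnchors - 1L
  }
  pairs[keep, , drop = FALSE]
}
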