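IUPAC_DNA <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

.iupacToRegex <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_DNA))
  if (length(bad))
    stop("pattern contains non-IUPAC letter(s): ", paste(bad, collapse = ", "))
  paste0(IUPAC_DNA[letters], collapse = "")
}

.revcompDna <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

#' Default stress-related cis-element dictionary
#'
#' A small dictionary of stress-associated promoter elements (ABRE, MBS,
#' LTR, TC-rich, WUN-motif, ARE, GC-motif) with IUPAC patterns and stress
#' categories, shipped as a TSV config. Replace it with an export from a
#' curated plant cis-element database for production scans.
#'
#' @param path Optional path to a custom TSV (columns name, pattern,
#'   category).
#' @return `data.frame` with columns name, pattern, category.
#' @export
defaultCisMotifs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cis_elements.tsv",
                        package = "nsLTPscan", mustWork = TRUE)
  motifs <- read.delim(path, sep = "\t", colClasses = "character")
  stopifnot(all(c("name", "pattern", "category") %in% names(motifs)))
  invisible(lapply(motifs$pattern, .iupacToRegex)) # validate alphabet
  motifs
}

#' Scan a promoter for cis-element motifs
#'
#' Exact IUPAC matching of every motif at every position, on the forward
#' strand and (by default) the reverse strand. An N in the promoter
#' sequence matches nothing. Reverse-strand hits are reported in forward
#' coordinates at the leftmost base of the matched window.
#'
#' @param sequence Promoter DNA sequence (A/C/G/T/N).
#' @param motifs Motif dictionary (see [defaultCisMotifs()]).
#' @param bothStrands Scan the reverse strand too (default TRUE).
#' @return `data.frame` with columns motif_name, position (1-based start on
#'   the forward strand), strand.
#' @export
scanPromoter <- function(sequence, motifs = defaultCisMotifs(),
                         bothStrands = TRUE) {
  sequence <- toupper(.seqChar(sequence))
  if (grepl("[^ACGTN]", sequence))
    stop("promoter sequence contains non-DNA characters")
  hits <- list()
  scan1 <- function(pattern) {
    rx <- paste0("(?=", .iupacToRegex(pattern), ")")
    m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  for (i in seq_len(nrow(motifs))) {
    fw <- scan1(motifs$pattern[i])
    if (length(fw))
      hits[[length(hits) + 1L]] <- data.frame(
        motif_name = motifs$name[i], position = fw, strand = "+")
    if (bothStrands) {
      rv <- scan1(.revcompDna(motifs$pattern[i]))
      if (length(rv))
        hits[[length(hits) + 1L]] <- data.frame(
          motif_name = motifs$name[i], position = rv, strand = "-")
    }
  }
  if (!length(hits))
    return(data.frame(motif_name = character(), position = integer(),
                      strand = character()))
  out <- do.call(rbind, hits)
  out[order(out$position, out$motif_name, out$strand), , drop = FALSE]
}

#' Scan a set of promoters
#'
#' @param promoters Named [Biostrings::DNAStringSet] or named character
#'   vector of promoter sequences.
#' @inheritParams scanPromoter
#' @return `data.frame` with gene_id, motif_name, position, strand.
#' @export
scanPromoters <- function(promoters, motifs = defaultCisMotifs(),
                          bothStrands = TRUE) {
  seqs <- if (is(promoters, "DNAStringSet")) as.character(promoters)
          else promoters
  ids <- names(seqs)
  if (is.null(ids)) stop("promoters must be named")
  rows <- lapply(ids, function(id) {
    h <- scanPromoter(seqs[[id]], motifs, bothStrands)
    if (nrow(h)) cbind(gene_id = id, h) else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(gene_id = character(), motif_name = character(),
                      position = integer(), strand = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-gene stress cis-element summary
#'
#' @param hits Hit table from [scanPromoters()].
#' @param genes All gene identifiers to report (genes without hits get an
#'   all-zero row).
#' @param motifs Motif dictionary used for the scan (supplies the
#'   motif-to-category map).
#' @return `data.frame` with one row per gene: counts per category and a
#'   logical `any_stress` flag.
#' @export
stressElementSummary <- function(hits, genes, motifs = defaultCisMotifs()) {
  cats <- unique(motifs$category)
  m <- matrix(0L, nrow = length(genes), ncol = length(cats),
              dimnames = list(genes, cats))
  if (nrow(hits)) {
    hitCat <- motifs$category[match(hits$motif_name, motifs$name)]
    tab <- table(factor(hits$gene_id, levels = genes),
                 factor(hitCat, levels = cats))
    m[] <- as.integer(tab)
  }
  out <- data.frame(gene_id = genes, m, check.names = FALSE,
                    row.names = NULL)
  out$any_stress <- rowSums(m) > 0L
  out
}
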