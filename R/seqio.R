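#' Read a protein FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] that upper-cases the
#' sequences, trims FASTA descriptions to the first whitespace-delimited
#' token for the sequence names, and enforces the package's residue policy:
#' only the 20 canonical amino-acid letters are accepted by default.
#'
#' @param path Path to a FASTA file.
#' @param nonCanonical Policy for residues outside the canonical 20
#'   (B, J, O, U, X, Z and anything else): `"error"` (default) aborts naming
#'   the offending record; `"mask"` replaces them with `X` and flags the
#'   record in `metadata(x)$masked` (such proteins cannot be scanned for the
#'   8CM reliably and are excluded by downstream scanning).
#' @return An [Biostrings::AAStringSet] named by record identifier, in file
#'   order. An empty file yields an empty set.
#' @export
readProteinFasta <- function(path, nonCanonical = c("error", "mask")) {
  nonCanonical <- match.arg(nonCanonical)
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA identifier(s): ", paste(dup, collapse = ", "))
  if (any(width(aa) == 0L)) {
    empty <- ids[width(aa) == 0L]
    stop("empty sequence for record(s): ", paste(empty, collapse = ", "))
  }
  aa <- Biostrings::AAStringSet(toupper(as.character(aa)))
  names(aa) <- ids
  seqs <- as.character(aa)
  ok <- !grepl(paste0("[^", paste(CANONICAL_AA, collapse = ""), "]"), seqs)
  if (!all(ok)) {
    if (nonCanonical == "error")
      stop("non-canonical residues in record(s): ",
           paste(ids[!ok], collapse = ", "))
    seqs[!ok] <- gsub(paste0("[^", paste(CANONICAL_AA, collapse = ""), "]"),
                      "X", seqs[!ok])
    aa <- Biostrings::AAStringSet(seqs)
    names(aa) <- ids
    S4Vectors::metadata(aa)$masked <- ids[!ok]
  }
  aa
}

#' Write protein sequences to FASTA
#'
#' @param x Named [Biostrings::AAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read gene loci from a GFF3 file
#'
#' Imports the annotation with [rtracklayer::import()] and keeps `gene`
#' features only. Coordinates stay 1-based inclusive as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A [GenomicRanges::GRanges] with a `gene_id` metadata column (taken
#'   from the `ID` attribute), one range per gene feature.
#' @export
readGeneLoci <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("gene feature without an ID attribute in ", path)
  mcols(gr) <- S4Vectors::DataFrame(gene_id = as.character(ids))
  gr
}

CATALOG_COLUMNS <- c("name", "type", "sp_len", "target", "mature_len",
                     "mass_da", "pi", "intron_count", "intron_positions",
                     "ortholog")

.validateCatalog <- function(cat) {
  miss <- setdiff(CATALOG_COLUMNS, names(cat))
  if (length(miss))
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!cat$type %in% c("1", "2", "C", "D", "E", "G", "X")))
    stop("unknown type label in catalog")
  if (any(cat$mature_len <= 0)) stop("mature_len must be positive")
  if (any(cat$mass_da <= 0)) stop("mass_da must be positive")
  if (any(cat$pi <= 0 | cat$pi >= 14)) stop("pi must lie in (0, 14)")
  if (any(cat$intron_count < 0)) stop("intron_count must be >= 0")
  # name prefix must agree with the type label (BoLTP1.*, BoLTPg*, ...)
  pref <- c(`1` = "1", `2` = "2", C = "c", D = "d", E = "e", G = "g", X = "x")
  tag <- substr(sub("^BoLTP", "", cat$name), 1L, 1L)
  if (any(tag != pref[cat$type]))
    stop("catalog name prefix inconsistent with type for: ",
         paste(cat$name[tag != pref[cat$type]], collapse = ", "))
  invisible(cat)
}

#' Read a catalog TSV
#'
#' @param path Path to a TSV with the fixed catalog columns (name, type,
#'   sp_len, target, mature_len, mass_da, pi, intron_count,
#'   intron_positions, ortholog). `intron_positions` is a comma-separated
#'   list of signed integers (bases from the codon of the eighth 8CM
#'   cysteine); `ortholog` is empty when no Arabidopsis ortholog is known.
#' @return A `data.frame`, one row per family member.
#' @export
readCatalog <- function(path) {
  cat <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", na.strings = NULL)
  for (col in c("sp_len", "mature_len", "intron_count"))
    cat[[col]] <- as.integer(cat[[col]])
  for (col in c("mass_da", "pi"))
    cat[[col]] <- as.numeric(cat[[col]])
  if (anyNA(cat$sp_len) || anyNA(cat$mass_da) || anyNA(cat$pi) ||
      anyNA(cat$intron_count))
    stop("unparsable numeric field in catalog ", path)
  .validateCatalog(cat)
  cat
}

#' Write a catalog TSV
#'
#' Serializes a catalog with the fixed column order so that
#' [readCatalog()] recovers it exactly.
#'
#' @param catalog A catalog `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  .validateCatalog(catalog)
  write.table(catalog[, CATALOG_COLUMNS], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the packaged cabbage nsLTP reference catalog
#'
#' Returns the transcription of the published 89-member Brassica oleracea
#' nsLTP catalog (name, type, signal-peptide length, subcellular target,
#' mature length, average mass, theoretical pI, intron count and positions,
#' and the Arabidopsis ortholog where one was reported). Intron positions
#' are given as bases from the codon encoding the eighth 8CM cysteine and
#' may be negative.
#'
#' @return A `data.frame` with 89 rows.
#' @export
loadReferenceCatalog <- function() {
  path <- system.file("extdata", "boltp_table1.tsv", package = "nsLTPscan",
                      mustWork = TRUE)
  cat <- readCatalog(path)
  if (nrow(cat) != 89L)
    stop("reference catalog integrity failure: expected 89 rows, found ",
         nrow(cat))
  cat
}

#' Summarize a catalog
#'
#' Computes the family-level aggregates used to describe the catalog: entry
#' and per-type counts, basic/acidic pI split, pI and signal-length
#' extremes, ortholog coverage, and the type-G mature-mass range.
#'
#' @param catalog A catalog `data.frame` (see [readCatalog()]).
#' @param basicPi pH above which a protein is counted as basic (default 7).
#' @return A named list of scalar summaries.
#' @export
summarizeCatalog <- function(catalog, basicPi = 7) {
  .validateCatalog(catalog)
  types <- c("1", "2", "C", "D", "E", "G", "X")
  typeCounts <- vapply(types, function(t) sum(catalog$type == t), integer(1))
  orth <- catalog$ortholog[!is.na(catalog$ortholog) & catalog$ortholog != ""]
  gMass <- catalog$mass_da[catalog$type == "G"]
  list(
    n_entries = nrow(catalog),
    type_counts = typeCounts,
    n_basic_pi = sum(catalog$pi > basicPi),
    n_acidic_pi = sum(catalog$pi <= basicPi),
    pi_min = min(catalog$pi),
    pi_max = max(catalog$pi),
    sp_len_min = min(catalog$sp_len),
    sp_len_max = max(catalog$sp_len),
    n_with_ortholog = length(orth),
    n_distinct_orthologs = length(unique(orth)),
    type_g_mass_max = if (length(gMass)) max(gMass) else NA_real_,
    type_g_mass_min = if (length(gMass)) min(gMass) else NA_real_
  )
}
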