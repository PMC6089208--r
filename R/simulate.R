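# Filler alphabet for simulated family members: cysteine-free so that a
# planted 8CM backbone is the unique eight-cysteine assignment, and free of
# strongly hydrophobic residues so that fillers never mimic a
# signal-peptide core or a GPI tail.
FILLER_AA <- c("A", "D", "E", "G", "H", "K", "N", "Q", "R", "S", "T", "Y")
# Planted type-X outliers draw their fillers from a disjoint alphabet, so
# their identity to every typed family stays far below the typing floor.
OUTLIER_AA <- c("H", "R", "Y", "W")
# CXC centre residue per type: hydrophilic in type 1 (and C/E/G),
# hydrophobic in types 2 and D, driving the two disulfide-pairing modes.
CXC_CENTRE <- c(`1` = "D", `2` = "L", C = "S", D = "L", E = "S", G = "S")

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.fill <- function(n, alphabet = FILLER_AA)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

.pkgEnv <- new.env(parent = emptyenv())

#' Per-type family template sequences
#'
#' Deterministic mature-sequence templates, one per type, generated from
#' the spacing grammars under a fixed internal seed: a 7-residue
#' pre-motif linker, the 8CM backbone with every variable gap at the
#' type's maximum allowed value, a type-specific CXC centre, and a
#' 5-residue tail. Simulated family members are derived from these
#' templates by point substitution, emulating within-family sequence
#' identity; the templates themselves double as the typing exemplars
#' ([defaultExemplars()]).
#'
#' @return Named list (type -> list of region strings: linker, g1, g2, g4,
#'   centre, g6, g7, tail).
#' @export
typeTemplates <- function() {
  if (!is.null(.pkgEnv$templates)) return(.pkgEnv$templates)
  grammars <- ltpGrammars()
  .pkgEnv$templates <- .withSeed(8L, {
    lapply(setNames(nm = names(grammars)), function(type) {
      g <- grammars[[type]]
      list(linker = .fill(7L),
           g1 = .fill(max(g$g1)), g2 = .fill(max(g$g2)),
           g4 = .fill(max(g$g4)), centre = CXC_CENTRE[[type]],
           g6 = .fill(max(g$g6)), g7 = .fill(max(g$g7)),
           tail = .fill(5L))
    })
  })
  .pkgEnv$templates
}

.assembleMature <- function(tpl, gaps, mutate = function(x) x) {
  take <- function(region, n) mutate(substr(region, 1L, n))
  paste0(mutate(tpl$linker),
         "C", take(tpl$g1, gaps[1]), "C", take(tpl$g2, gaps[2]), "CC",
         take(tpl$g4, gaps[3]), "C", tpl$centre, "C",
         take(tpl$g6, gaps[4]), "C", take(tpl$g7, gaps[5]), "C",
         mutate(tpl$tail))
}

.mutateFactory <- function(pSub, alphabet = FILLER_AA) {
  function(x) {
    if (!nchar(x)) return(x)
    res <- strsplit(x, "")[[1]]
    hit <- runif(length(res)) < pSub
    if (any(hit)) res[hit] <- sample(alphabet, sum(hit), replace = TRUE)
    paste(res, collapse = "")
  }
}

# Signal peptide engineered to satisfy the package's own heuristic with a
# deterministic cleavage length: M + hydrophobic core + A Q A, cleaved
# after the final A.
.makeSignal <- function(len = sample(17:34, 1L)) {
  stopifnot(len >= 13L)
  core <- .fill(len - 4L, c("L", "I", "V", "F"))
  list(seq = paste0("M", core, "A", "Q", "A"), len = len)
}

#' Generate one synthetic nsLTP precursor
#'
#' Builds a precursor of the requested type: an engineered signal peptide
#' (length uniform on 17-34), a short pre-motif linker, an 8CM backbone
#' with gaps drawn uniformly from the type's grammar and template-derived
#' fillers mutated at rate `pSub`, and — for type G only — a C-terminal
#' extension with an omega site and a hydrophobic tail that satisfies the
#' GPI heuristic. In strict mode (default) the corresponding detectors are
#' run on the product and any disagreement with the planted truth is an
#' error.
#'
#' @param type One of "1", "2", "C", "D", "E", "G".
#' @param grammars Grammar list from [ltpGrammars()].
#' @param pSub Per-residue substitution rate applied to template fillers
#'   (default 0.12).
#' @param strict Verify generator/detector consistency (default TRUE).
#' @return A list: `sequence` (precursor string) and `truth` (list with
#'   class, sp_len, gpi, omega_pos, signature, linker_len, tail_len).
#' @export
makePrecursor <- function(type, grammars = ltpGrammars(), pSub = 0.12,
                          strict = TRUE) {
  if (!type %in% names(grammars)) stop("unknown type: ", type)
  g <- grammars[[type]]
  tpl <- typeTemplates()[[type]]
  gaps <- vapply(c("g1", "g2", "g4", "g6", "g7"),
                 function(s) as.integer(sample(as.list(g[[s]]), 1L)[[1]]),
                 integer(1))
  mut <- .mutateFactory(pSub)
  linkerLen <- sample(3:7, 1L)
  tailLen <- sample(2:5, 1L)
  tpl2 <- tpl
  tpl2$linker <- substr(tpl$linker, 1L, linkerLen)
  tpl2$tail <- substr(tpl$tail, 1L, tailLen)
  mature <- .assembleMature(tpl2, gaps, mut)
  omegaMat <- NA_integer_
  if (isTRUE(g$gpi)) {
    ext <- .fill(sample(40:60, 1L))
    omegaMat <- nchar(mature) + nchar(ext) + 1L
    mature <- paste0(mature, ext, "G", .fill(10L, c("Q", "E")),
                     .fill(10L, c("L", "I", "V", "F")))
  }
  sig <- .makeSignal()
  sequence <- paste0(sig$seq, mature)
  truth <- list(class = type, sp_len = sig$len, gpi = isTRUE(g$gpi),
                omega_pos = if (isTRUE(g$gpi)) sig$len + omegaMat
                            else NA_integer_,
                signature = unname(gaps),
                linker_len = linkerLen, tail_len = tailLen)
  if (strict) .checkPrecursor(sequence, truth)
  list(sequence = sequence, truth = truth)
}

.checkPrecursor <- function(sequence, truth) {
  m <- findEightCM(sequence)
  if (is.null(m) || !identical(unname(spacingSignature(m)), truth$signature))
    stop("generator/detector inconsistency: 8CM signature mismatch")
  sp <- predictSignalPeptide(sequence)
  if (!sp$present || sp$cleavage_len != truth$sp_len)
    stop("generator/detector inconsistency: signal peptide")
  gpi <- predictGpiAnchor(sequence)
  if (gpi$present != truth$gpi)
    stop("generator/detector inconsistency: GPI call")
  if (truth$gpi && gpi$omega_pos != truth$omega_pos)
    stop("generator/detector inconsistency: omega position")
  if (isHyprp(sequence, truth$sp_len))
    stop("generator/detector inconsistency: HyPRP")
  invisible(TRUE)
}

#' Generate a synthetic type-X outlier
#'
#' A precursor with a valid 8CM (gaps uniform on [5, 29]) whose fillers
#' are drawn from a residue alphabet disjoint from the family templates,
#' so its identity to every typed exemplar falls below the typing floor.
#'
#' @inheritParams makePrecursor
#' @return As [makePrecursor()], with class "X".
#' @export
makeOutlier <- function(strict = TRUE) {
  gaps <- sample(5:29, 5L, replace = TRUE)
  tpl <- list(linker = .fill(5L, OUTLIER_AA),
              g1 = .fill(gaps[1], OUTLIER_AA), g2 = .fill(gaps[2], OUTLIER_AA),
              g4 = .fill(gaps[3], OUTLIER_AA),
              centre = sample(OUTLIER_AA, 1L),
              g6 = .fill(gaps[4], OUTLIER_AA), g7 = .fill(gaps[5], OUTLIER_AA),
              tail = .fill(3L, OUTLIER_AA))
  mature <- .assembleMature(tpl, gaps)
  sig <- .makeSignal()
  sequence <- paste0(sig$seq, mature)
  truth <- list(class = "X", sp_len = sig$len, gpi = FALSE,
                omega_pos = NA_integer_, signature = unname(gaps),
                linker_len = 5L, tail_len = 3L)
  if (strict) .checkPrecursor(sequence, truth)
  list(sequence = sequence, truth = truth)
}

#' Generate synthetic exclusion-reference proteins
#'
#' Protease-inhibitor / storage-protein stand-ins: precursors that carry a
#' signal peptide and an 8CM (the shared Pfam domain) but whose fillers
#' are random rather than family-template derived, so genuine family
#' members do not resemble them.
#'
#' @param n Number of references.
#' @return Named character vector of sequences (synthetic references).
#' @export
makeExclusionRefs <- function(n = 3L) {
  out <- vapply(seq_len(n), function(i) {
    gaps <- sample(5:25, 5L, replace = TRUE)
    tpl <- list(linker = .fill(5L), g1 = .fill(gaps[1]), g2 = .fill(gaps[2]),
                g4 = .fill(gaps[3]), centre = sample(FILLER_AA, 1L),
                g6 = .fill(gaps[4]), g7 = .fill(gaps[5]), tail = .fill(4L))
    paste0(.makeSignal()$seq, .assembleMature(tpl, gaps))
  }, character(1))
  setNames(out, paste0("excl", seq_len(n)))
}

#' Generate a decoy protein
#'
#' Decoys are engineered to fail exactly one stage of the filter cascade:
#' `nocys` mutates one backbone cysteine of an otherwise valid precursor
#' to serine (no eight-cysteine assignment remains); `nosp` places a valid
#' 8CM behind a charged/polar N-terminus with no hydrophobic core; `hyprp`
#' inserts a 30-residue, one-third-proline region between a valid signal
#' peptide and the motif; `inhibitor` is a point-mutated near-copy
#' (~85% identity) of an exclusion reference.
#'
#' @param kind One of "nocys", "nosp", "hyprp", "inhibitor".
#' @param refs Exclusion references (required for kind "inhibitor").
#' @param strict Verify the decoy fails at its intended stage.
#' @return A list: `sequence`, `truth` (class = paste0("decoy_", kind)).
#' @export
makeDecoy <- function(kind = c("nocys", "nosp", "hyprp", "inhibitor"),
                      refs = NULL, strict = TRUE) {
  kind <- match.arg(kind)
  if (kind == "nocys") {
    base <- makePrecursor(sample(c("1", "2", "C", "D", "E"), 1L),
                          strict = strict)
    m <- findEightCM(base$sequence)
    pos <- motifPositions(m)[sample.int(8L, 1L)]
    seqv <- strsplit(base$sequence, "")[[1]]
    seqv[pos] <- "S"
    sequence <- paste(seqv, collapse = "")
    if (strict && !is.null(findEightCM(sequence)))
      stop("nocys decoy still matches an 8CM")
  } else if (kind == "nosp") {
    base <- makePrecursor(sample(c("1", "2", "C", "D", "E"), 1L),
                          strict = strict)
    mature <- substr(base$sequence, base$truth$sp_len + 1L,
                     nchar(base$sequence))
    sequence <- paste0("M", .fill(sample(20:30, 1L),
                                  c("D", "E", "K", "N", "Q", "R")), mature)
    if (strict) {
      if (is.null(findEightCM(sequence))) stop("nosp decoy lost its 8CM")
      if (predictSignalPeptide(sequence)$present)
        stop("nosp decoy carries a signal peptide")
    }
  } else if (kind == "hyprp") {
    type <- sample(c("1", "2", "C", "D", "E"), 1L)
    tpl <- typeTemplates()[[type]]
    g <- ltpGrammars()[[type]]
    gaps <- vapply(c("g1", "g2", "g4", "g6", "g7"),
                   function(s) as.integer(sample(as.list(g[[s]]), 1L)[[1]]),
                   integer(1))
    proRegion <- paste(sample(c(rep("P", 10L), sample(FILLER_AA, 20L,
                                                      replace = TRUE))),
                      collapse = "")
    tpl$linker <- proRegion
    mature <- .assembleMature(tpl, gaps, .mutateFactory(0.12))
    # rebuild with the proline region un-mutated so its composition holds
    mature <- paste0(proRegion,
                     substr(mature, nchar(proRegion) + 1L, nchar(mature)))
    sig <- .makeSignal()
    sequence <- paste0(sig$seq, mature)
    if (strict) {
      sp <- predictSignalPeptide(sequence)
      if (!sp$present || sp$cleavage_len != sig$len)
        stop("hyprp decoy signal peptide failed")
      if (is.null(findEightCM(sequence))) stop("hyprp decoy lost its 8CM")
      if (!isHyprp(sequence, sig$len)) stop("hyprp decoy not proline-rich")
    }
  } else {
    if (is.null(refs) || !length(refs))
      stop("inhibitor decoys need exclusion references")
    ref <- refs[[sample.int(length(refs), 1L)]]
    res <- strsplit(ref, "")[[1]]
    hit <- which(runif(length(res)) < 0.15 & res != "C")
    # keep the engineered signal-peptide block intact so the decoy reaches
    # the similarity stage
    hit <- hit[hit > 40L]
    if (length(hit)) res[hit] <- sample(FILLER_AA, length(hit), replace = TRUE)
    sequence <- paste(res, collapse = "")
    if (strict && pairwiseIdentity(sequence, ref) < 0.5)
      stop("inhibitor decoy drifted too far from its reference")
  }
  list(sequence = sequence,
       truth = list(class = paste0("decoy_", kind), sp_len = NA_integer_,
                    gpi = FALSE, omega_pos = NA_integer_,
                    signature = rep(NA_integer_, 5L)))
}

#' Simulate a proteome with planted truth
#'
#' Generates family members per type, type-X outliers and decoys, shuffles
#' them, and returns the sequences with a truth table keyed by protein
#' identifier.
#'
#' @param nPerType Named integer vector: family members per type (names
#'   from "1", "2", "C", "D", "E", "G").
#' @param nOutliers Number of planted type-X outliers.
#' @param decoyCounts Named integer vector over "nocys", "nosp", "hyprp",
#'   "inhibitor".
#' @param exclusionRefs References for inhibitor decoys; generated with
#'   [makeExclusionRefs()] when needed and not supplied.
#' @param seed Optional seed applied locally for reproducibility.
#' @param strict Verify generator/detector consistency per protein.
#' @return A list: `proteins` (named [Biostrings::AAStringSet]), `truth`
#'   (`data.frame`: id, class, sp_len, gpi, omega_pos, g1..g7), and
#'   `exclusion_refs`.
#' @export
simulateProteome <- function(nPerType = c(`1` = 10, `2` = 10, C = 5, D = 10,
                                          E = 5, G = 10),
                             nOutliers = 0L,
                             decoyCounts = c(nocys = 0L, nosp = 0L,
                                             hyprp = 0L, inhibitor = 0L),
                             exclusionRefs = NULL, seed = NULL,
                             strict = TRUE) {
  .withSeed(seed, {
    grammars <- ltpGrammars()
    entries <- list()
    for (type in names(nPerType)) {
      for (k in seq_len(nPerType[[type]]))
        entries[[length(entries) + 1L]] <-
          makePrecursor(type, grammars, strict = strict)
    }
    for (k in seq_len(nOutliers))
      entries[[length(entries) + 1L]] <- makeOutlier(strict = strict)
    needRefs <- !is.null(decoyCounts) &&
      "inhibitor" %in% names(decoyCounts) && decoyCounts[["inhibitor"]] > 0L
    if (needRefs && is.null(exclusionRefs))
      exclusionRefs <- makeExclusionRefs(3L)
    for (kind in names(decoyCounts)) {
      for (k in seq_len(decoyCounts[[kind]]))
        entries[[length(entries) + 1L]] <-
          makeDecoy(kind, refs = exclusionRefs, strict = strict)
    }
    if (!length(entries))
      return(list(proteins = Biostrings::AAStringSet(),
                  truth = data.frame(), exclusion_refs = exclusionRefs))
    ord <- sample.int(length(entries))
    entries <- entries[ord]
    ids <- sprintf("prot%03d", seq_along(entries))
    seqs <- setNames(vapply(entries, `[[`, character(1), "sequence"), ids)
    truth <- do.call(rbind, lapply(seq_along(entries), function(i) {
      tr <- entries[[i]]$truth
      data.frame(id = ids[i], class = tr$class, sp_len = tr$sp_len,
                 gpi = tr$gpi, omega_pos = tr$omega_pos,
                 g1 = tr$signature[1], g2 = tr$signature[2],
                 g4 = tr$signature[3], g6 = tr$signature[4],
                 g7 = tr$signature[5])
    }))
    list(proteins = Biostrings::AAStringSet(seqs), truth = truth,
         exclusion_refs = exclusionRefs)
  })
}

#' Family-mirroring tandem array specification
#'
#' The default layout used by the genome simulator: five two-gene arrays
#' and two three-gene arrays (16 member genes in seven arrays), matching
#' the tandem structure reported for the cabbage family.
#'
#' @return `data.frame` with columns chrom and size.
#' @export
ltpArraysSpec <- function() {
  data.frame(chrom = c("C01", "C03", "C04", "C09", "Scaffold000118",
                       "C02", "C08"),
             size = c(2L, 2L, 2L, 2L, 2L, 3L, 3L))
}

#' Simulate a genome layout with planted tandem arrays
#'
#' Lays out family and background genes on chromosomes: array members are
#' adjacent (0-1 intervening background genes, < 100 kb apart) and
#' scattered family genes are isolated by several distant background
#' genes.
#'
#' @param arraysSpec `data.frame(chrom, size)`; default [ltpArraysSpec()].
#' @param nScattered Number of non-tandem family genes.
#' @param nBackgroundPerChrom Background genes appended per chromosome.
#' @param seed Optional local seed.
#' @return A list: `loci` ([GenomicRanges::GRanges] of all genes with
#'   `gene_id`), `family_ids`, and `truth` (`data.frame`: gene_id,
#'   array_id; array_id NA for scattered genes).
#' @export
simulateGenomeLayout <- function(arraysSpec = ltpArraysSpec(),
                                 nScattered = 10L,
                                 nBackgroundPerChrom = 8L, seed = NULL) {
  .withSeed(seed, {
    chroms <- unique(c(arraysSpec$chrom,
                       paste0("C0", seq_len(5L))))
    famCounter <- 0L; bgCounter <- 0L
    rows <- list()
    newFam <- function() {
      famCounter <<- famCounter + 1L
      sprintf("LTP%03d", famCounter)
    }
    newBg <- function() {
      bgCounter <<- bgCounter + 1L
      sprintf("BG%04d", bgCounter)
    }
    truth <- list()
    for (chr in chroms) {
      items <- list()  # list of c(id, is_family, array_id)
      for (ai in which(arraysSpec$chrom == chr)) {
        arrayId <- sprintf("array%02d", ai)
        for (k in seq_len(arraysSpec$size[ai])) {
          id <- newFam()
          items[[length(items) + 1L]] <- list(id = id, fam = TRUE,
                                              array = arrayId)
          # 0 or 1 intervening background gene inside the array; it shares
          # the array block so the spacing stays tight
          if (k < arraysSpec$size[ai] && runif(1) < 0.5)
            items[[length(items) + 1L]] <- list(id = newBg(), fam = FALSE,
                                                array = arrayId)
        }
        for (k in seq_len(4L))  # isolate the array
          items[[length(items) + 1L]] <- list(id = newBg(), fam = FALSE,
                                              array = NA)
      }
      for (k in seq_len(nBackgroundPerChrom))
        items[[length(items) + 1L]] <- list(id = newBg(), fam = FALSE,
                                            array = NA)
      rows[[chr]] <- items
    }
    # scatter remaining family genes between isolation blocks
    for (k in seq_len(nScattered)) {
      chr <- sample(chroms, 1L)
      items <- rows[[chr]]
      pos <- length(items)  # append at the end, after >= 4 background genes
      items[[pos + 1L]] <- list(id = newFam(), fam = TRUE, array = NA)
      for (j in seq_len(4L))
        items[[pos + 1L + j]] <- list(id = newBg(), fam = FALSE, array = NA)
      rows[[chr]] <- items
    }
    grs <- list()
    for (chr in names(rows)) {
      items <- rows[[chr]]
      if (!length(items)) next
      n <- length(items)
      arr <- vapply(items, function(it)
        if (is.na(it$array[1])) NA_character_ else it$array, character(1))
      # adjacent genes 20 kb apart inside an array block, 120 kb otherwise:
      # consecutive array members with one intervening background gene stay
      # within 40 kb; isolation blocks push everything else > 100 kb apart
      sameBlock <- !is.na(arr[-n]) & !is.na(arr[-1L]) & arr[-n] == arr[-1L]
      gapAfter <- ifelse(sameBlock, 20e3, 120e3)
      starts <- cumsum(c(1e4, gapAfter))
      grs[[chr]] <- GenomicRanges::GRanges(
        seqnames = chr,
        ranges = IRanges::IRanges(start = starts, width = 1000L),
        strand = sample(c("+", "-"), n, replace = TRUE),
        gene_id = vapply(items, `[[`, character(1), "id"))
      for (it in items)
        if (it$fam)
          truth[[length(truth) + 1L]] <-
            data.frame(gene_id = it$id, array_id = it$array)
    }
    loci <- suppressWarnings(do.call(c, unname(grs)))
    truthDf <- do.call(rbind, truth)
    list(loci = loci, family_ids = truthDf$gene_id, truth = truthDf)
  })
}

#' Simulate an expression count matrix with planted truth
#'
#' Draws negative-binomial counts for `nGenes` genes across sample groups
#' (organs or conditions) with `nReps` replicates each. Non-planted genes
#' share a common baseline FPKM; `specific` genes are high in exactly one
#' group and near-zero elsewhere; `de` genes carry a fold effect in the
#' second contrast group relative to the first.
#'
#' @param nGenes Number of genes.
#' @param groups Character vector of group (organ/condition) labels.
#' @param nReps Replicates per group.
#' @param specific Named character vector: gene index/name -> group in
#'   which the gene is exclusively expressed.
#' @param de Named numeric vector: gene -> linear fold change (> 1)
#'   applied in `groups[2]` relative to `groups[1]`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param baselineFpkm,highFpkm,lowFpkm Target FPKM of baseline genes,
#'   of specific genes in their group, and of specific genes elsewhere.
#' @param libSize Library size per sample.
#' @param seed Optional local seed.
#' @return A list: `se` (a `SummarizedExperiment` with organ and condition
#'   columns), `truth` (`data.frame`: gene_id, specific_group, de_fold).
#' @export
simulateCounts <- function(nGenes = 100L, groups = c("A", "B"), nReps = 3L,
                           specific = NULL, de = NULL, dispersion = 0.1,
                           baselineFpkm = 20, highFpkm = 50, lowFpkm = 0.1,
                           libSize = 2e7, seed = NULL) {
  if (!is.null(de) && any(de <= 1))
    stop("planted differential effects must have fold > 1")
  .withSeed(seed, {
    genes <- sprintf("gene%03d", seq_len(nGenes))
    lens <- sample(500:2000, nGenes, replace = TRUE)
    names(lens) <- genes
    samples <- data.frame(
      sample = paste(rep(groups, each = nReps),
                     rep(seq_len(nReps), length(groups)), sep = "_r"),
      organ = rep(groups, each = nReps),
      condition = rep(groups, each = nReps),
      library_size = libSize)
    target <- matrix(baselineFpkm, nGenes, length(groups),
                     dimnames = list(genes, groups))
    for (g in names(specific)) {
      target[g, ] <- lowFpkm
      target[g, specific[[g]]] <- highFpkm
    }
    for (g in names(de))
      target[g, groups[2]] <- target[g, groups[1]] * de[[g]]
    mu <- target[, samples$organ, drop = FALSE] * lens * libSize / 1e9
    counts <- matrix(0L, nGenes, nrow(samples),
                     dimnames = list(genes, samples$sample))
    for (j in seq_len(ncol(counts))) {
      counts[, j] <- if (dispersion > 0)
        rnbinom(nGenes, mu = mu[, j], size = 1 / dispersion)
      else stats::rpois(nGenes, mu[, j])
    }
    truth <- data.frame(
      gene_id = genes,
      specific_group = ifelse(genes %in% names(specific),
                              specific[genes], NA_character_),
      de_fold = ifelse(genes %in% names(de), de[genes], NA_real_))
    list(se = makeExpressionSet(counts, lens, samples), truth = truth)
  })
}

.instantiateIupac <- function(pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(toupper(pattern), "")[[1]],
               function(l) sample(sets[[l]], 1L), character(1)),
        collapse = "")
}

#' Simulate promoters with planted cis-element instances
#'
#' Random background DNA with concrete motif instances written at the
#' requested positions (reverse-complemented for minus-strand plants).
#' Background sequence may of course contain additional chance hits; the
#' truth table marks the planted instances only.
#'
#' @param genes Gene identifiers (one promoter each).
#' @param plants `data.frame` with columns gene, motif, position (1-based),
#'   strand; motif names are looked up in `motifs`.
#' @param length Promoter length in bp (default 1500).
#' @param motifs Motif dictionary (see [defaultCisMotifs()]).
#' @param seed Optional local seed.
#' @return A list: `promoters` (named character vector) and `truth`
#'   (the `plants` table).
#' @export
simulatePromoters <- function(genes, plants = NULL, length = 1500L,
                              motifs = defaultCisMotifs(), seed = NULL) {
  .withSeed(seed, {
    proms <- setNames(vapply(genes, function(g)
      .fill(length, c("A", "C", "G", "T")), character(1)), genes)
    if (!is.null(plants) && nrow(plants)) {
      for (g in unique(plants$gene)) {
        sub <- plants[plants$gene == g, , drop = FALSE]
        pat <- motifs$pattern[match(sub$motif, motifs$name)]
        if (anyNA(pat)) stop("unknown motif in plants for gene ", g)
        w <- nchar(pat)
        iv <- cbind(sub$position, sub$position + w - 1L)
        if (any(iv[, 2L] > length)) stop("plant extends past promoter end")
        if (nrow(iv) > 1L) {
          o <- order(iv[, 1L])
          if (any(iv[o, 1L][-1L] <= iv[o, 2L][-nrow(iv)]))
            stop("overlapping plants for gene ", g)
        }
        s <- proms[[g]]
        for (k in seq_len(nrow(sub))) {
          inst <- .instantiateIupac(pat[k])
          if (sub$strand[k] == "-") inst <- .revcompDna(inst)
          substr(s, sub$position[k], sub$position[k] + w[k] - 1L) <- inst
        }
        proms[[g]] <- s
      }
    }
    list(promoters = proms,
         truth = if (is.null(plants)) data.frame() else plants)
  })
}
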