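#' Pipeline configuration
#'
#' Single source of the workflow thresholds. Unknown keys are rejected so
#' that typos do not silently fall back to defaults.
#'
#' @param ... Overrides for any of: `minGap`, `maxGap` (8CM scan bounds),
#'   `minIdentity` (similarity exclusion floor), `minCoverage`,
#'   `typeMinIdentity` (typing floor, 0.30), `fpkmThreshold` (1.0),
#'   `fdr` (0.05), `foldChange` (2.0, strict), `maxIntervening`,
#'   `maxDistance` (tandem rule), `rbhMinCoverage` (0.75),
#'   `rbhMinIdentity`, `syntenyWindow`, `syntenyMinAnchors`,
#'   `promoterLength`, `hyprpMinLen`, `hyprpMinPro`, `pkaSet`, `seed`.
#' @return Named list of effective settings.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    minGap = 2L, maxGap = 40L,
    minIdentity = 0.40, minCoverage = 0.75,
    typeMinIdentity = 0.30,
    fpkmThreshold = 1.0, fdr = 0.05, foldChange = 2.0,
    maxIntervening = 1L, maxDistance = 1e5,
    rbhMinCoverage = 0.75, rbhMinIdentity = 0.30,
    syntenyWindow = 10L, syntenyMinAnchors = 3L,
    promoterLength = 1500L,
    hyprpMinLen = 20L, hyprpMinPro = 0.25,
    pkaSet = "bjellqvist", seed = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  stopifnot(defaults$minGap >= 1L)
  cfg <- modifyList(defaults, over)
  if (cfg$fpkmThreshold < 0 || cfg$fdr <= 0 || cfg$fdr >= 1 ||
      cfg$foldChange <= 1 || cfg$typeMinIdentity < 0 ||
      cfg$typeMinIdentity > 1)
    stop("configuration value out of range")
  cfg
}

#' Identify and characterize a family from a proteome
#'
#' End-to-end identification: 8CM scan and filter cascade, signal-peptide
#' cleavage, GPI calling, mature-protein mass and pI, and type assignment.
#'
#' @param proteome Named [Biostrings::AAStringSet] or named character
#'   vector of precursor proteins.
#' @param exemplars Typed exemplars for the identity round of
#'   classification (default [defaultExemplars()]).
#' @param exclusionRefs Optional protease-inhibitor / storage-protein
#'   references for the similarity stage.
#' @param config A [pipelineConfig()] list.
#' @return A list: `catalog` (`data.frame`: id, type, sp_len, mature_len,
#'   mass_da, pi, gpi, best_identity, grammar_ok, g1..g7), `rejected`,
#'   and `stage_counts`.
#' @export
runIdentification <- function(proteome, exemplars = defaultExemplars(),
                              exclusionRefs = NULL,
                              config = pipelineConfig()) {
  casc <- runFilterCascade(
    proteome, exclusionRefs = exclusionRefs,
    config = list(minGap = config$minGap, maxGap = config$maxGap,
                  minIdentity = config$minIdentity,
                  minCoverage = config$minCoverage,
                  hyprpMinLen = config$hyprpMinLen,
                  hyprpMinPro = config$hyprpMinPro))
  kept <- casc$kept
  if (!nrow(kept))
    return(list(catalog = data.frame(), rejected = casc$rejected,
                stage_counts = casc$stage_counts))
  seqs <- .seqChar(proteome)
  grammars <- ltpGrammars()
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    id <- kept$id[i]
    mature <- matureSequence(seqs[[id]], kept$sp_len[i])
    sig <- unlist(kept[i, c("g1", "g2", "g4", "g6", "g7")])
    ty <- assignType(mature,
                     gpiCall = list(present = kept$gpi_present[i]),
                     exemplars = exemplars, signature = sig,
                     grammars = grammars,
                     minIdentity = config$typeMinIdentity)
    data.frame(id = id, type = ty$type, sp_len = kept$sp_len[i],
               mature_len = nchar(mature),
               mass_da = averageMass(mature),
               pi = isoelectricPoint(mature, config$pkaSet),
               gpi = kept$gpi_present[i],
               best_identity = ty$best_identity,
               grammar_ok = if (is.na(ty$grammar_ok)) NA else ty$grammar_ok,
               g1 = sig[1], g2 = sig[2], g4 = sig[3], g6 = sig[4],
               g7 = sig[5], row.names = NULL)
  })
  list(catalog = do.call(rbind, rows), rejected = casc$rejected,
       stage_counts = casc$stage_counts)
}

#' Run the full analysis on a simulated or user-supplied workspace
#'
#' Orchestrates identification, genome context, expression classification,
#' differential expression and promoter scanning, and reports a single
#' machine-readable summary. Any stage whose inputs are absent is
#' skipped and listed in `missing_stages`.
#'
#' @param proteome Named precursor sequences (required).
#' @param loci Optional [GenomicRanges::GRanges] of all annotated genes
#'   (with `gene_id`); enables chromosome distribution and tandem arrays
#'   for the family members present in it.
#' @param familyIds Optional family gene identifiers for the genome
#'   stages; defaults to catalog ids found in `loci`.
#' @param orthoProteome Optional second proteome for reciprocal-best-hit
#'   orthology.
#' @param expressionSet Optional `SummarizedExperiment` (see
#'   [makeExpressionSet()]) with `organ` and/or `condition` columns.
#' @param contrast Optional length-2 character vector of condition labels
#'   for the differential-expression stage.
#' @param promoters Optional named promoter sequences.
#' @param exemplars,exclusionRefs,config As in [runIdentification()].
#' @return A list with the stage outputs (`identification`, `genome`,
#'   `expression`, `promoters`), a `summary` list of counts, and
#'   `missing_stages`.
#' @export
runFull <- function(proteome, loci = NULL, familyIds = NULL,
                    orthoProteome = NULL, expressionSet = NULL,
                    contrast = NULL, promoters = NULL,
                    exemplars = defaultExemplars(), exclusionRefs = NULL,
                    config = pipelineConfig()) {
  missing <- character()
  ident <- runIdentification(proteome, exemplars, exclusionRefs, config)
  summary <- list(
    n_input = unname(ident$stage_counts["input"]),
    n_kept = unname(ident$stage_counts["kept"]),
    n_rejected = nrow(ident$rejected),
    type_counts = if (nrow(ident$catalog))
      table(factor(ident$catalog$type,
                   levels = c("1", "2", "C", "D", "E", "G", "X")))
      else NULL)
  genome <- NULL
  if (!is.null(loci)) {
    if (is.null(familyIds))
      familyIds <- intersect(ident$catalog$id, loci$gene_id)
    dist <- chromosomeDistribution(familyIds, loci)
    arrays <- detectTandemArrays(familyIds, loci,
                                 config$maxIntervening, config$maxDistance)
    genome <- list(chromosome_distribution = dist, tandem_arrays = arrays)
    summary$n_tandem_arrays <- length(arrays)
    summary$n_tandem_genes <- sum(lengths(lapply(arrays, `[[`, "members")))
    if (!is.null(orthoProteome)) {
      rbh <- reciprocalBestHits(.seqChar(proteome), .seqChar(orthoProteome),
                                config$rbhMinCoverage, config$rbhMinIdentity)
      genome$orthologs <- rbh
      summary$n_ortholog_pairs <- nrow(rbh)
    }
  } else missing <- c(missing, "genome_context")
  expr <- NULL
  if (!is.null(expressionSet)) {
    f <- fpkm(expressionSet)
    organs <- SummarizedExperiment::colData(expressionSet)$organ
    ef <- expressedFlags(f, organs, config$fpkmThreshold)
    spec <- organSpecific(ef$flags)
    expr <- list(fpkm = f, expressed = ef, organ_specific = spec)
    summary$n_expressed <- ef$n_expressed
    summary$n_organ_specific <- nrow(spec)
    if (!is.null(contrast)) {
      deg <- degTest(expressionSet, contrast[1], contrast[2],
                     fdr = config$fdr, foldChange = config$foldChange)
      expr$deg <- deg
      summary$n_deg <- sum(deg$is_deg)
    }
  } else missing <- c(missing, "expression")
  prom <- NULL
  if (!is.null(promoters)) {
    motifs <- defaultCisMotifs()
    hits <- scanPromoters(promoters, motifs)
    stress <- stressElementSummary(hits, names(promoters), motifs)
    prom <- list(hits = hits, stress_summary = stress)
    summary$n_promoters_with_stress_element <- sum(stress$any_stress)
  } else missing <- c(missing, "promoter_scan")
  list(identification = ident, genome = genome, expression = expr,
       promoters = prom, summary = summary, missing_stages = missing,
       config = config)
}
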