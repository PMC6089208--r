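#' Assemble an expression experiment
#'
#' Bundles a count matrix, gene lengths and a sample sheet into a
#' [SummarizedExperiment::SummarizedExperiment]. Library sizes default to
#' the column sums of the counts.
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param geneLengths Named numeric vector of gene (exon-model) lengths in
#'   bp.
#' @param samples `data.frame` with one row per sample: at least `sample`
#'   plus any of `organ`, `condition`, `library_size`.
#' @return A `SummarizedExperiment` with assay `counts`, `rowData$length`
#'   and the sample sheet as `colData`.
#' @export
makeExpressionSet <- function(counts, geneLengths, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample dimnames")
  lens <- geneLengths[rownames(counts)]
  if (anyNA(lens) || any(lens <= 0)) stop("invalid or missing gene lengths")
  samples <- as.data.frame(samples)
  if (!all(colnames(counts) == samples$sample))
    stop("sample sheet does not match count columns")
  if (is.null(samples$library_size)) samples$library_size <- colSums(counts)
  if (any(samples$library_size <= 0)) stop("library sizes must be positive")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(length = unname(lens)),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample))
}

#' FPKM from counts
#'
#' FPKM[g, s] = 1e9 * count[g, s] / (length[g] * library_size[s]).
#'
#' @param se A `SummarizedExperiment` from [makeExpressionSet()].
#' @return Numeric matrix of FPKM values, genes x samples.
#' @export
fpkm <- function(se) {
  counts <- SummarizedExperiment::assay(se, "counts")
  lens <- SummarizedExperiment::rowData(se)$length
  libs <- SummarizedExperiment::colData(se)$library_size
  if (any(libs == 0)) stop("zero library size")
  1e9 * sweep(counts / lens, 2L, libs, "/")
}

#' Expressed-gene flags per organ
#'
#' Replicate FPKMs are averaged per organ first; a gene is expressed in an
#' organ when its mean FPKM is greater than or equal to `threshold` (the
#' boundary is inclusive).
#'
#' @param fpkmMat FPKM matrix (genes x samples).
#' @param organs Character vector assigning each sample column to an organ.
#' @param threshold Expression threshold (default 1.0).
#' @return A list: `flags` (logical genes x organ matrix), `organ_fpkm`
#'   (mean-FPKM matrix) and `n_expressed` (genes expressed in >= 1 organ).
#' @export
expressedFlags <- function(fpkmMat, organs, threshold = 1.0) {
  stopifnot(length(organs) == ncol(fpkmMat))
  uo <- unique(organs)
  means <- vapply(uo, function(o)
    rowMeans(fpkmMat[, organs == o, drop = FALSE]),
    numeric(nrow(fpkmMat)))
  flags <- means >= threshold
  list(flags = flags, organ_fpkm = means,
       n_expressed = sum(rowSums(flags) >= 1L))
}

#' Organ-specific genes
#'
#' @param flags Logical genes x organ matrix (see [expressedFlags()]).
#' @return `data.frame` of genes expressed in exactly one organ, with that
#'   organ.
#' @export
organSpecific <- function(flags) {
  if (ncol(flags) < 2L) stop("organ specificity needs at least 2 organs")
  one <- rowSums(flags) == 1L
  data.frame(
    gene_id = rownames(flags)[one],
    organ = colnames(flags)[apply(flags[one, , drop = FALSE], 1L, which)],
    row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()] after validating the input).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression between two conditions
#'
#' For each gene, replicate counts are summed within condition and a
#' two-sided exact conditional binomial test is applied to the pooled
#' count, with success probability equal to condition B's share of the
#' summed library sizes. Fold changes are computed on mean FPKM with a
#' pseudocount of 1 (so organ-restricted genes get finite fold changes),
#' and q-values by Benjamini-Hochberg. A gene is called differentially
#' expressed when q < `fdr` and |log2 fold change| > log2(`foldChange`)
#' (the fold-change bound is strict).
#'
#' The binomial test is exactly calibrated under Poisson count sampling;
#' with overdispersed counts p-values are anticonservative and the
#' fold-change gate carries the specificity (see the methods vignette).
#'
#' @param se A `SummarizedExperiment` with a `condition` column in
#'   `colData`.
#' @param conditionA,conditionB Condition labels; fold change is B over A.
#' @param fdr FDR threshold (default 0.05).
#' @param foldChange Linear fold-change threshold, exceeded strictly
#'   (default 2).
#' @return `data.frame` with gene_id, log2_fc, p_value, q_value, is_deg.
#' @export
degTest <- function(se, conditionA, conditionB, fdr = 0.05, foldChange = 2) {
  cond <- SummarizedExperiment::colData(se)$condition
  if (is.null(cond)) stop("colData(se) must have a condition column")
  selA <- cond == conditionA
  selB <- cond == conditionB
  if (!any(selA) || !any(selB)) stop("condition labels not found")
  counts <- SummarizedExperiment::assay(se, "counts")
  f <- fpkm(se)
  libs <- SummarizedExperiment::colData(se)$library_size
  sumA <- rowSums(counts[, selA, drop = FALSE])
  sumB <- rowSums(counts[, selB, drop = FALSE])
  libA <- sum(libs[selA]); libB <- sum(libs[selB])
  prB <- libB / (libA + libB)
  meanA <- rowMeans(f[, selA, drop = FALSE])
  meanB <- rowMeans(f[, selB, drop = FALSE])
  lfc <- log2((meanB + 1) / (meanA + 1))
  p <- vapply(seq_len(nrow(counts)), function(i) {
    tot <- sumA[i] + sumB[i]
    if (tot == 0) return(1)
    stats::binom.test(sumB[i], tot, p = prB)$p.value
  }, numeric(1))
  lfc[sumA + sumB == 0] <- 0
  q <- bhAdjust(p)
  data.frame(gene_id = rownames(counts), log2_fc = unname(lfc),
             p_value = p, q_value = q,
             is_deg = q < fdr & abs(lfc) > log2(foldChange),
             row.names = NULL)
}
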