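mkLoci <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start, df$start + 999L),
                         strand = "+", gene_id = df$id)
}

test_that("chromosome distribution conserves the gene count", {
  loci <- mkLoci(data.frame(chrom = rep(c("c1", "c2"), c(6, 4)),
                            start = seq(1e4, 1e5, length.out = 10),
                            id = paste0("g", 1:10)))
  d <- chromosomeDistribution(paste0("g", 1:10), loci)
  expect_equal(unname(d[c("c1", "c2", "unanchored")]), c(6L, 4L, 0L))
  d2 <- chromosomeDistribution(c(paste0("g", 1:10), "orphan"), loci)
  expect_equal(unname(d2[["unanchored"]]), 1L)
  expect_equal(sum(d2), 11L)
  dupLoci <- c(loci, loci[1])
  expect_error(chromosomeDistribution("g1", dupLoci), "duplicate")
})

test_that("tandem arrays respect the adjacency and distance rules", {
  # family pair split by two background genes: no array
  loci <- mkLoci(data.frame(chrom = "c1",
                            start = c(1e4, 3e4, 5e4, 7e4),
                            id = c("f1", "b1", "b2", "f2")))
  expect_length(detectTandemArrays(c("f1", "f2"), loci), 0L)
  # one intervening background gene within distance: an array
  loci2 <- mkLoci(data.frame(chrom = "c1", start = c(1e4, 3e4, 5e4),
                             id = c("f1", "b1", "f2")))
  arr <- detectTandemArrays(c("f1", "f2"), loci2)
  expect_length(arr, 1L)
  expect_identical(arr[[1]]$members, c("f1", "f2"))
  # beyond the bp ceiling: no array even when adjacent
  loci3 <- mkLoci(data.frame(chrom = "c1", start = c(1e4, 2e5),
                             id = c("f1", "f2")))
  expect_length(detectTandemArrays(c("f1", "f2"), loci3), 0L)
  # a 3-run is one maximal array, never two overlapping pairs
  loci4 <- mkLoci(data.frame(chrom = "c1", start = c(1e4, 3e4, 5e4),
                             id = c("f1", "f2", "f3")))
  arr4 <- detectTandemArrays(c("f1", "f2", "f3"), loci4)
  expect_length(arr4, 1L)
  expect_identical(arr4[[1]]$members, c("f1", "f2", "f3"))
})

test_that("the planted family layout yields seven arrays of sixteen genes", {
  lay <- simulateGenomeLayout(seed = 41)
  arr <- detectTandemArrays(lay$family_ids, lay$loci)
  expect_length(arr, 7L)
  members <- unlist(lapply(arr, `[[`, "members"))
  expect_length(members, 16L)
  expect_identical(anyDuplicated(members), 0L)
  sizes <- sort(vapply(arr, function(a) length(a$members), integer(1)))
  expect_equal(sizes, c(2L, 2L, 2L, 2L, 2L, 3L, 3L))
  # arrays agree with the generator's truth
  tru <- split(lay$truth$gene_id[!is.na(lay$truth$array_id)],
               lay$truth$array_id[!is.na(lay$truth$array_id)])
  expect_setequal(vapply(tru, paste, character(1), collapse = ","),
                  vapply(arr, function(a) paste(a$members, collapse = ","),
                         character(1)))
})

test_that("reciprocal best hits form a filtered partial matching", {
  set.seed(42)
  base <- vapply(1:4, function(i) randomProtein(60), character(1))
  A <- setNames(base, paste0("a", 1:4))
  B <- setNames(base, paste0("b", 1:4))
  rbh <- reciprocalBestHits(A, B)
  expect_identical(rbh$subject_id[match(paste0("a", 1:4), rbh$query_id)],
                   paste0("b", 1:4))
  # duplicated query: only one partner keeps b (RBH uniqueness)
  A2 <- c(A, a5 = unname(base[1]))
  rbh2 <- reciprocalBestHits(A2, B)
  expect_identical(anyDuplicated(rbh2$subject_id), 0L)
  expect_identical(anyDuplicated(rbh2$query_id), 0L)
  # coverage gate suppresses a dovetail overlap: perfect identity on a
  # 40-residue shared block, but only 2/3 of the shorter sequence aligns
  m <- randomProtein(40)
  dvA <- c(dv = paste0(randomProtein(20), m))
  dvB <- c(dw = paste0(m, randomProtein(20)))
  al <- reciprocalBestHits(dvA, dvB, minCoverage = 0)
  expect_gt(al$identity, 0.9)
  expect_lt(al$coverage, 0.75)
  rbh3 <- reciprocalBestHits(dvA, dvB, minCoverage = 0.75)
  expect_identical(nrow(rbh3), 0L)
  expect_identical(nrow(reciprocalBestHits(character(0), B)), 0L)
})

test_that("collinearity keeps ordered blocks and drops isolated pairs", {
  pairs <- data.frame(query_id = paste0("a", 1:6),
                      subject_id = paste0("b", 1:6),
                      identity = 0.9, coverage = 1)
  ordA <- data.frame(gene_id = paste0("a", 1:6), chrom = "cA", rank = 1:6)
  ordB <- data.frame(gene_id = paste0("b", 1:6), chrom = "cB", rank = 1:6)
  # perfect collinear run: everything survives
  syn <- collinearOrthologs(pairs, ordA, ordB)
  expect_identical(nrow(syn), 6L)
  expect_true(all(syn$query_id %in% pairs$query_id))
  # isolated pair on its own chromosome pair is dropped
  ordA2 <- ordA; ordA2$chrom[6] <- "cA2"
  syn2 <- collinearOrthologs(pairs, ordA2, ordB)
  expect_false("a6" %in% syn2$query_id)
  # inverted block: order consistency allows reversal
  ordB3 <- ordB; ordB3$rank <- 6:1
  syn3 <- collinearOrthologs(pairs, ordA, ordB3)
  expect_identical(nrow(syn3), 6L)
  expect_error(collinearOrthologs(
    data.frame(query_id = "zz", subject_id = "b1", identity = 1, coverage = 1),
    ordA, ordB), "absent")
})
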