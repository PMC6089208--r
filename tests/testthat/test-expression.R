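mkSe <- function(counts, lens = NULL, organs = NULL, libs = NULL) {
  if (is.null(lens)) lens <- setNames(rep(1000, nrow(counts)),
                                      rownames(counts))
  if (is.null(organs)) organs <- colnames(counts)
  samples <- data.frame(sample = colnames(counts), organ = organs,
                        condition = organs,
                        library_size = if (is.null(libs)) 1e7 else libs)
  makeExpressionSet(counts, lens, samples)
}

test_that("FPKM implements the count-length-library formula", {
  counts <- matrix(c(100, 0), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  f <- fpkm(mkSe(counts))
  expect_equal(f["g1", "s1"], 10.0)  # 1e9 * 100 / (1000 * 1e7)
  expect_equal(f["g2", "s1"], 0)
  # doubling the library size halves every FPKM of that sample
  f2 <- fpkm(mkSe(counts, libs = 2e7))
  expect_equal(f2, f / 2)
  # linear in counts
  f3 <- fpkm(mkSe(counts * 3))
  expect_equal(f3, f * 3)
})

test_that("the expressed threshold is inclusive at FPKM 1", {
  counts <- matrix(c(10, 9.9), 2, 1,  # FPKM 1.0 and 0.99
                   dimnames = list(c("at", "below"), "s1"))
  f <- fpkm(mkSe(counts))
  ef <- expressedFlags(f, organs = "organ1")
  expect_true(ef$flags["at", 1])
  expect_false(ef$flags["below", 1])
  expect_identical(ef$n_expressed, 1L)
  zero <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_identical(expressedFlags(fpkm(mkSe(zero)), c("a", "b"))$n_expressed,
                   0L)
})

test_that("organ-specific genes are expressed in exactly one organ", {
  flags <- matrix(c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), 3, 2,
                  dimnames = list(c("only1", "both", "neither"),
                                  c("bud", "leaf")))
  flags["both", ] <- TRUE
  flags["neither", ] <- FALSE
  sp <- organSpecific(flags)
  expect_identical(sp$gene_id, "only1")
  expect_identical(sp$organ, "bud")
  expect_error(organSpecific(flags[, 1, drop = FALSE]), "2 organs")
})

test_that("planted organ-specific genes are recovered exactly", {
  specific <- setNames(rep("bud", 6), sprintf("gene%03d", 1:6))
  sim <- simulateCounts(nGenes = 60, groups = c("bud", "leaf", "root"),
                        nReps = 3, specific = specific, seed = 51)
  f <- fpkm(sim$se)
  organs <- SummarizedExperiment::colData(sim$se)$organ
  ef <- expressedFlags(f, organs)
  sp <- organSpecific(ef$flags)
  expect_setequal(sp$gene_id, names(specific))
  expect_true(all(sp$organ == "bud"))
  # generator contract: high in the planted organ, near-zero elsewhere
  expect_true(all(ef$organ_fpkm[names(specific), "bud"] >= 5))
  expect_true(all(ef$organ_fpkm[names(specific), c("leaf", "root")] < 0.5))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(52)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bhAdjust(p), oracleBH(p))
  }
})

test_that("the exact test behaves at its boundaries", {
  counts <- matrix(c(400, 0, 90,   410, 0, 90,   390, 0, 90,
                     405, 0, 190,  395, 0, 190,  400, 0, 190),
                   nrow = 3,
                   dimnames = list(c("flat", "allzero", "twofold"),
                                   paste0("s", 1:6)))
  se <- mkSe(counts, organs = rep(c("A", "B"), each = 3))
  deg <- degTest(se, "A", "B")
  flat <- deg[deg$gene_id == "flat", ]
  expect_lt(abs(flat$log2_fc), 0.1)
  expect_false(flat$is_deg)
  zero <- deg[deg$gene_id == "allzero", ]
  expect_equal(zero$p_value, 1)
  expect_equal(zero$log2_fc, 0)
  expect_false(zero$is_deg)
  # fold change exactly 2 on the pseudocounted scale is not enough (> is strict)
  two <- deg[deg$gene_id == "twofold", ]
  expect_equal(two$log2_fc, 1, tolerance = 1e-12)
  expect_false(two$is_deg)
})

test_that("log2 fold change is invariant under joint library scaling", {
  counts <- matrix(rpois(40, 200), 10, 4,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  orgs <- rep(c("A", "B"), each = 2)
  d1 <- degTest(mkSe(counts, organs = orgs, libs = 1e7), "A", "B")
  d2 <- degTest(mkSe(counts, organs = orgs, libs = 3e7), "A", "B")
  expect_false(isTRUE(all.equal(d1$log2_fc, d2$log2_fc)))  # pseudocount shifts
  d3 <- degTest(mkSe(counts * 1L, organs = orgs, libs = 1e7), "A", "B")
  expect_equal(d1$p_value, d3$p_value)
})

test_that("planted four-fold effects are recovered with few false calls", {
  de <- setNames(rep(4, 8), sprintf("gene%03d", 1:8))
  rec <- fp <- integer(5)
  for (k in 1:5) {
    sim <- simulateCounts(nGenes = 100, groups = c("ctl", "trt"), nReps = 3,
                          de = de, dispersion = 0.1, seed = 5200 + k)
    deg <- degTest(sim$se, "ctl", "trt")
    called <- deg$gene_id[deg$is_deg]
    rec[k] <- length(intersect(called, names(de)))
    fp[k] <- length(setdiff(called, names(de)))
  }
  expect_gte(median(rec), 7)
  expect_lte(median(fp), 1)
})

test_that("q-value calls are calibrated under the test's own Poisson model", {
  frac <- numeric(5)
  for (k in 1:5) {
    sim <- simulateCounts(nGenes = 200, groups = c("ctl", "trt"), nReps = 3,
                          dispersion = 0, seed = 5300 + k)
    deg <- degTest(sim$se, "ctl", "trt")
    frac[k] <- mean(deg$q_value < 0.05)
  }
  expect_lte(mean(frac), 0.05)
})
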