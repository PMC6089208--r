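test_that("signal-peptide heuristic follows the stated core and cleavage rules", {
  # engineered positive: M + hydrophobic core + spacer with small (-3,-1)
  sp <- predictSignalPeptide(paste0("MK", strrep("L", 10), "SAGA",
                                    strrep("N", 25)))
  expect_true(sp$present)
  # (-3,-1) rule: the -1 and -3 residues of the reported site are small
  res <- strsplit(paste0("MK", strrep("L", 10), "SAGA", strrep("N", 25)),
                  "")[[1]]
  expect_true(res[sp$cleavage_len] %in% c("A", "G", "S", "C", "T"))
  expect_true(res[sp$cleavage_len - 2] %in% c("A", "G", "S", "C", "T"))
  expect_gte(sp$cleavage_len, 10L)
  expect_gt(sp$score, 0)

  # no hydrophobic core: all charged/polar
  expect_false(predictSignalPeptide(strrep("D", 50))$present)
  # core too late (after the first-12 start window past the N-region)
  late <- paste0("M", strrep("N", 20), strrep("L", 10), "SAGA",
                 strrep("N", 10))
  expect_false(predictSignalPeptide(late)$present)
  expect_error(predictSignalPeptide("MKLLLLLLLL"), "shorter than 30")
})

test_that("generated precursors satisfy the signal heuristic with planted length", {
  set.seed(11)
  for (i in 1:40) {
    p <- makePrecursor(sample(c("1", "2", "C", "D", "E", "G"), 1L),
                       strict = FALSE)
    sp <- predictSignalPeptide(p$sequence)
    expect_true(sp$present)
    expect_identical(sp$cleavage_len, p$truth$sp_len)
    expect_true(sp$cleavage_len >= 17L && sp$cleavage_len <= 34L)
  }
})

test_that("GPI heuristic fires on planted type G and nowhere else", {
  set.seed(12)
  for (i in 1:20) {
    g <- makePrecursor("G", strict = FALSE)
    call <- predictGpiAnchor(g$sequence)
    expect_true(call$present)
    expect_identical(call$omega_pos, g$truth$omega_pos)
    expect_gte(nchar(g$sequence) - call$omega_pos, 10L)
    other <- makePrecursor(sample(c("1", "2", "C", "D", "E"), 1L),
                           strict = FALSE)
    expect_false(predictGpiAnchor(other$sequence)$present)
  }
  # fully charged C-terminus can never be a GPI tail
  expect_false(predictGpiAnchor(paste0(strrep("L", 30), strrep("E", 25)))$present)
})

test_that("HyPRP rule gates on both length and proline fraction", {
  preP <- paste(sample(c(rep("P", 10), rep("A", 20))), collapse = "")
  s <- paste0(strrep("L", 20), preP, "CAA")
  expect_true(isHyprp(s, spLen = 20))
  # short pre-motif region fails regardless of proline content
  expect_false(isHyprp(paste0(strrep("L", 20), "PPPPPPPPPP", "CAA"),
                       spLen = 20))
  # long but proline-poor region fails
  expect_false(isHyprp(paste0(strrep("L", 20), strrep("A", 30), "CAA"),
                       spLen = 20))
  set.seed(13)
  p <- makePrecursor("1", strict = FALSE)
  expect_false(isHyprp(p$sequence, p$truth$sp_len))
})

test_that("similarity exclusion keys on identity and coverage", {
  set.seed(14)
  refs <- makeExclusionRefs(2L)
  expect_true(excludeBySimilarity(refs[[1]], refs))
  far <- makeOutlier(strict = FALSE)$sequence
  expect_false(excludeBySimilarity(far, refs))
  expect_warning(flag <- excludeBySimilarity(refs[[1]], character(0)),
                 "empty exclusion")
  expect_false(flag)
  # a shuffled sequence keeps composition but loses identity
  shuffled <- paste(sample(strsplit(refs[[1]], "")[[1]]), collapse = "")
  expect_lt(pairwiseIdentity(shuffled, refs[[1]]), 0.40)
})

test_that("the filter cascade is conservative and stage-ordered", {
  set.seed(15)
  sim <- simulateProteome(
    nPerType = c(`1` = 6, `2` = 6, C = 3, D = 6, E = 3, G = 6),
    decoyCounts = c(nocys = 3, nosp = 3, hyprp = 3, inhibitor = 2))
  casc <- runFilterCascade(sim$proteins, exclusionRefs = sim$exclusion_refs)
  expect_identical(nrow(casc$kept) + nrow(casc$rejected),
                   length(sim$proteins))
  truth <- sim$truth; rownames(truth) <- truth$id
  # every decoy is rejected at its planted stage; every true protein kept
  stageOf <- c(decoy_nocys = "no_8cm", decoy_nosp = "no_signal_peptide",
               decoy_inhibitor = "similar_to_exclusion",
               decoy_hyprp = "hyprp")
  for (i in seq_len(nrow(casc$rejected))) {
    cls <- truth[casc$rejected$id[i], "class"]
    expect_identical(casc$rejected$reason[i], unname(stageOf[cls]))
  }
  expect_setequal(casc$kept$id, truth$id[!grepl("^decoy", truth$class)])
  # empty input
  e <- runFilterCascade(character(0))
  expect_identical(unname(e$stage_counts[["input"]]), 0L)
  expect_identical(nrow(e$kept), 0L)
})

test_that("external predictor calls substitute for the built-in heuristics", {
  set.seed(16)
  p <- makePrecursor("1", strict = FALSE)
  ext <- data.frame(id = "x", sp_present = FALSE, sp_len = NA,
                    gpi_present = FALSE, omega_pos = NA)
  casc <- runFilterCascade(setNames(p$sequence, "x"), externalCalls = ext)
  expect_identical(casc$rejected$reason, "no_signal_peptide")
  ext$sp_present <- TRUE; ext$sp_len <- p$truth$sp_len
  casc2 <- runFilterCascade(setNames(p$sequence, "x"), externalCalls = ext)
  expect_identical(casc2$kept$id, "x")
  expect_identical(casc2$kept$sp_len, p$truth$sp_len)
})
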