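# build a backbone string from the five variable gaps, filler "A"
backboneSeq <- function(gaps, filler = "A", centre = "A") {
  paste0("C", strrep(filler, gaps[1]), "C", strrep(filler, gaps[2]), "CC",
         strrep(filler, gaps[3]), "C", centre, "C",
         strrep(filler, gaps[4]), "C", strrep(filler, gaps[5]), "C")
}

test_that("planted spacings are recovered exactly", {
  # type 1 canonical layout
  m <- findEightCM(paste0("MKT", backboneSeq(c(9, 13, 19, 19, 13)), "SA"))
  expect_false(is.null(m))
  expect_equal(unname(spacingSignature(m)), c(9, 13, 19, 19, 13))
  # type 2 and type C canonical layouts
  expect_equal(unname(spacingSignature(
    findEightCM(backboneSeq(c(7, 13, 8, 23, 5))))), c(7, 13, 8, 23, 5))
  expect_equal(unname(spacingSignature(
    findEightCM(backboneSeq(c(9, 16, 9, 12, 6))))), c(9, 16, 9, 12, 6))
  # minimal contiguous motif
  expect_equal(unname(spacingSignature(
    findEightCM(backboneSeq(rep(2, 5))))), rep(2, 5))
})

test_that("sequences without eight usable cysteines do not match", {
  expect_null(findEightCM("MKACDEACDEACDE"))
  seven <- sub("C$", "S", backboneSeq(c(9, 13, 19, 19, 13)))
  expect_null(findEightCM(seven))
  # gaps outside the bounds are rejected
  expect_null(findEightCM(backboneSeq(c(1, 13, 19, 19, 13)), minGap = 2))
  expect_null(findEightCM(backboneSeq(c(41, 13, 19, 19, 13)), maxGap = 40))
})

test_that("ambiguous assignments resolve to the lexicographically smallest", {
  # a 9th cysteine ahead of the backbone creates two valid assignments
  s <- paste0("CAA", backboneSeq(rep(3, 5)))
  m <- findEightCM(s)
  oracle <- oracle8cm(s)
  expect_equal(unname(motifPositions(m)), unname(oracle))
})

test_that("detection agrees with exhaustive 8-subset enumeration", {
  set.seed(101)
  hits <- 0L
  for (i in 1:150) {
    s <- randomCysProtein(len = sample(40:120, 1L))
    m <- findEightCM(s)
    o <- oracle8cm(s)
    if (is.null(o)) {
      expect_null(m)
    } else {
      hits <- hits + 1L
      expect_equal(unname(motifPositions(m)), unname(o))
    }
  }
  expect_gt(hits, 10L)  # the case mix must exercise both outcomes
})

test_that("grammar membership follows the per-type allowed sets", {
  g <- ltpGrammars()
  expect_true(matchesGrammar(c(9, 14, 19, 21, 13), g[["1"]]))
  expect_true(matchesGrammar(c(7, 13, 8, 23, 6), g[["2"]]))
  expect_false(matchesGrammar(c(9, 13, 19, 19, 12), g[["1"]]))
  expect_true(matchesGrammar(c(13, 15, 9, 22, 6), g[["E"]]))
  expect_false(matchesGrammar(c(6, 11, 12, 23, 5), g[["1"]]))
  expect_true(matchesGrammar(c(6, 11, 12, 23, 5), g[["G"]]))
})

test_that("grammar-generated precursors are always detected with the planted signature", {
  set.seed(202)
  g <- ltpGrammars()
  for (i in 1:100) {
    type <- sample(names(g), 1L)
    p <- makePrecursor(type, strict = FALSE)
    m <- findEightCM(p$sequence)
    expect_false(is.null(m))
    expect_equal(unname(spacingSignature(m)), p$truth$signature)
    expect_true(matchesGrammar(spacingSignature(m), g[[type]]))
  }
})

test_that("disulfide pairing follows the CXC-centre hydrophobicity", {
  sD <- backboneSeq(c(9, 13, 19, 19, 13), centre = "D")
  mD <- findEightCM(sD)
  expect_equal(predictDisulfidePairing(sD, mD)[, "from"], c(1, 2, 4, 5))
  expect_equal(predictDisulfidePairing(sD, mD)[, "to"], c(6, 3, 7, 8))
  sL <- backboneSeq(c(7, 13, 8, 23, 5), centre = "L")
  mL <- findEightCM(sL)
  expect_equal(predictDisulfidePairing(sL, mL)[, "from"], c(1, 2, 4, 6))
  expect_equal(predictDisulfidePairing(sL, mL)[, "to"], c(5, 3, 7, 8))
  # the 2-3 and 4-7 bridges are invariant under both modes
  for (ctr in c("D", "L", "S", "V")) {
    s <- backboneSeq(c(9, 16, 9, 12, 6), centre = ctr)
    pairs <- predictDisulfidePairing(s, findEightCM(s))
    expect_true(all(c("2-3", "4-7") %in% paste(pairs[, 1], pairs[, 2], sep = "-")))
  }
})

test_that("the match object enforces its structural invariants", {
  expect_error(new("EightCMMatch", positions = c(1L, 3L, 6L, 7L, 9L, 11L, 13L, 15L),
                   gaps = rep(1L, 5L)), "inconsistent|CXC")
  m <- findEightCM(backboneSeq(rep(2, 5)))
  expect_true(validObject(m))
  p <- motifPositions(m)
  expect_identical(p[4], p[3] + 1L)
  expect_identical(p[6], p[5] + 2L)
})
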