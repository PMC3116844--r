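submat <- loadSubstitutionMatrix()

test_that("scan thresholds keep exactly the qualifying alignments", {
  als <- list(
    mkProfileAlignment(1:5, 1:5, pssmId = "p1", evalue = 1e-5, pssmLength = 5),
    mkProfileAlignment(1:5, 1:5, pssmId = "p2", evalue = 0.5, pssmLength = 5),
    mkProfileAlignment(1:3, 1:3, pssmId = "p3", evalue = 1e-9, pssmLength = 5),
    mkProfileAlignment(1:4, 1:4, pssmId = "p4", evalue = 0.01, pssmLength = 5))
  strict <- filterAlignments(als, scanThresholds("strict"))
  expect_equal(vapply(strict, function(a) a@pssmId, character(1)),
               c("p1", "p3", "p4"))   # 0.5 > 0.01 dropped; 0.01 inclusive
  perm <- filterAlignments(als, scanThresholds("permissive"))
  expect_equal(vapply(perm, function(a) a@pssmId, character(1)),
               c("p1", "p2", "p4"))   # coverage 3/5 = 0.60 < 0.80 dropped
})

test_that("library scans honour both presets end to end", {
  lib <- new("FoldLibrary", fold = "fx",
             pssms = list(motifPSSM(strsplit("WWWWWWWWCC", "")[[1]],
                                    id = "strong"),
                          motifPSSM(c("C", "C"), hit = 1, id = "weak")),
             provenance = list())
  # full-length match against "strong": huge score, tiny E, coverage 1
  als <- scanLibrary("WWWWWWWWCC", lib, scanThresholds("strict"))
  expect_equal(vapply(als, function(a) a@pssmId, character(1)), "strong")
  # partial match: 6/10 columns -> coverage 0.6 fails the permissive preset
  als2 <- scanLibrary("AAWWWWWWAA", lib, scanThresholds("permissive"))
  expect_length(als2, 0)
  als3 <- scanLibrary("AAWWWWWWAA", lib, scanThresholds("strict"))
  expect_equal(vapply(als3, function(a) a@pssmId, character(1)), "strong")
  # empty library
  empty <- new("FoldLibrary", fold = "fy", pssms = list(motifPSSM("W")),
               provenance = list())
  expect_length(scanLibrary("AAAA", empty), 0)
})

test_that("positional scores add BLOSUM62 values for positive pairs only", {
  refs <- c(p1 = "LD", p2 = "LL")
  # query position 1 is L aligned to reference L: +4
  a1 <- mkProfileAlignment(1, 1, pssmId = "p1", pssmLength = 2)
  P <- positionalScores(setNames("LK", "q"), list(a1), refs = refs)
  expect_equal(P, c(4, 0))
  # L aligned to D scores -4 -> contributes nothing
  a2 <- mkProfileAlignment(1, 2, pssmId = "p1", pssmLength = 2)
  expect_equal(positionalScores(setNames("LK", "q"), list(a2), refs = refs),
               c(0, 0))
  # conserved non-identical pair contributes its positive score (I vs L: +2)
  a3 <- mkProfileAlignment(1, 1, pssmId = "p2", pssmLength = 2)
  expect_equal(positionalScores(setNames("IK", "q"), list(a3), refs = refs),
               c(2, 0))
  # two alignments hitting the same position sum
  both <- list(mkProfileAlignment(1, 1, pssmId = "p2", pssmLength = 2),
               mkProfileAlignment(1, 2, pssmId = "p2", pssmLength = 2))
  expect_equal(positionalScores(setNames("LK", "q"), both, refs = refs),
               c(8, 0))
  # out-of-range positions are rejected
  bad <- mkProfileAlignment(5, 1, pssmId = "p1", pssmLength = 2)
  expect_error(positionalScores(setNames("LK", "q"), list(bad), refs = refs),
               "out-of-range")
})

test_that("column-max partner pairing uses the top-scoring column residue", {
  # reference is L but the column scores W highest
  sc <- matrix(-2, 2, 20, dimnames = list(NULL, aaAlphabet()))
  sc[, "W"] <- 3
  lib <- new("FoldLibrary", fold = "f",
             pssms = list(PSSM("p1", "LL", sc, fold = "f")),
             provenance = list())
  al <- mkProfileAlignment(1, 1, pssmId = "p1", pssmLength = 2)
  # reference pairing: W vs L scores -2 -> nothing
  expect_equal(positionalScores(setNames("WK", "q"), list(al),
                                library = lib)[1], 0)
  # column-max pairing: W vs W scores +11
  expect_equal(positionalScores(setNames("WK", "q"), list(al), library = lib,
                                partner = "column-max")[1], 11)
})

test_that("fold-specific score divides positive positional mass by length", {
  expect_equal(foldSpecificScore(rep(0, 10)), 0)
  expect_equal(foldSpecificScore(c(5, 0, 3)), 8 / 3)
  expect_equal(foldSpecificScore(numeric(0)), 0)
  # appending unmatched residues (P = 0) halves the score exactly
  P <- c(5, 0, 3)
  expect_identical(foldSpecificScore(c(P, rep(0, 3))),
                   foldSpecificScore(P) / 2)
})

test_that("positional tracks from real scans are non-negative", {
  set.seed(41)
  for (i in 1:5) {
    lib <- new("FoldLibrary", fold = "fr",
               pssms = lapply(1:3, function(k)
                 randomPSSM(sample(8:20, 1), id = paste0("p", k))),
               provenance = list())
    q <- setNames(randomSeq(sample(10:30, 1)), "q")
    als <- scanLibrary(q, lib, scanThresholds(maxEvalue = 1e10,
                                              minCoverage = 0))
    P <- positionalScores(q, als, library = lib)
    expect_true(all(P >= 0))
    expect_length(P, nchar(q[[1]]))
  }
})

test_that("structural profiles follow the collection axis order", {
  mk <- function(fid, res) new("FoldLibrary", fold = fid,
                               pssms = list(motifPSSM(res, id = paste0(fid, "p"),
                                                      fold = fid)),
                               provenance = list())
  libs <- list(mk("fa", c("D", "D", "D", "D", "D")),
               mk("fb", c("W", "W", "W", "W", "W")),
               mk("fc", c("H", "H", "H", "H", "H")))
  coll <- compileCollection(libs)
  prof <- structuralProfile(setNames("AWWWWWA", "q"), coll)
  expect_equal(prof@folds, c("fa", "fb", "fc"))
  expect_equal(prof@scores[c(1, 3)], c(0, 0))
  expect_gt(prof@scores[2], 0)
  # permuting the axis order permutes the vector identically
  coll2 <- compileCollection(libs[c(2, 3, 1)])
  prof2 <- structuralProfile(setNames("AWWWWWA", "q"), coll2)
  expect_equal(profileScores(prof2)[prof@folds], profileScores(prof))
  # a query hitting nothing is all zero
  expect_true(all(structuralProfile(setNames("AAAA", "q0"), coll)@scores == 0))
})

test_that("structural similarity matches the Pearson definition", {
  expect_equal(structuralSimilarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(structuralSimilarity(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(structuralSimilarity(c(2, 2, 2), c(1, 5, 3)), 0)
  expect_error(structuralSimilarity(c(1, 2), c(1, 2, 3)), "axes")
  expect_error(structuralSimilarity(1, 2), "at least 2")
  p1 <- new("StructuralProfile", queryId = "a", folds = c("x", "y"),
            scores = c(1, 2))
  p2 <- new("StructuralProfile", queryId = "b", folds = c("y", "x"),
            scores = c(2, 1))
  expect_error(structuralSimilarity(p1, p2), "axes")
  set.seed(42)
  for (i in 1:50) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(length(x))
    expect_equal(structuralSimilarity(x, y), cor(x, y), tolerance = 1e-12)
    expect_equal(structuralSimilarity(x, y), structuralSimilarity(y, x))
  }
})

test_that("fold calls take the highest axis with deterministic ties", {
  expect_equal(predictFold(setNames(c(0, 0.5, 0.2), c("a", "b", "c"))), "b")
  expect_equal(predictFold(setNames(c(0, 0, 0), c("a", "b", "c"))),
               "unassigned")
  expect_equal(predictFold(setNames(c(0.5, 0.5), c("a", "b"))), "a")
})

test_that("similarity matrices are symmetric with self-pairs excluded", {
  set.seed(43)
  prof <- matrix(runif(15), 3, 5,
                 dimnames = list(c("q1", "q2", "q3"), paste0("f", 1:5)))
  sm <- similarityMatrix(prof)
  expect_true(all(is.na(diag(sm))))
  expect_equal(sm["q1", "q2"], sm["q2", "q1"])
  expect_equal(sm["q1", "q3"], structuralSimilarity(prof["q1", ], prof["q3", ]))
  expect_error(similarityMatrix(prof[1, , drop = FALSE]), "at least 2")
})
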