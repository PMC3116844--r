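submat <- loadSubstitutionMatrix()

test_that("near-identical filtering removes candidates at or above threshold", {
  refs <- setNames("ACDEFGHIKL", "ref")
  cands <- setNames(c("ACDEFGHIKL",   # identical -> removed
                      "ACDEFGHIKV",   # exactly 0.90 -> removed (inclusive)
                      "ACDEFWYHPM"),  # ~0.5 -> kept
                    c("c1", "c2", "c3"))
  expect_equal(percentIdentity(cands[["c2"]], refs[[1]]), 0.90)
  out <- filterNearIdentical(cands, refs)
  expect_equal(names(out), "c3")
  expect_warning(out2 <- filterNearIdentical(cands, character(0)), "empty")
  expect_equal(out2, cands)
})

test_that("redundancy filtering is a greedy keep-first sweep", {
  seqs <- setNames(c("AAAA", "AAAA", "WWWW"), c("x", "y", "z"))
  expect_equal(names(filterRedundant(seqs)), c("x", "z"))

  # exactly at the 0.40 threshold -> dropped (inclusive)
  pair <- setNames(c("AACDE", "AAWYH"), c("u", "v"))
  expect_equal(percentIdentity(pair[[1]], pair[[2]]), 0.40)
  expect_equal(names(filterRedundant(pair, threshold = 0.40)), "u")
  expect_equal(names(filterRedundant(pair, threshold = 0.41)), c("u", "v"))
})

test_that("redundancy chain keeps first and third of A~B~C", {
  # identities: A-B and B-C >= 0.5, A-C low -> keep A, drop B, keep C
  A <- "ACDEFGHIKLACDEFGHIKL"
  B <- "ACDEFGHIKLWYHPMNQRST"
  C <- "PPPPPPPPPPWYHPMNQRST"
  expect_gte(percentIdentity(A, B), 0.40)
  expect_gte(percentIdentity(B, C), 0.40)
  expect_lt(percentIdentity(A, C), 0.40)
  out <- filterRedundant(setNames(c(A, B, C), c("a", "b", "c")))
  expect_equal(names(out), c("a", "c"))
})

test_that("redundancy filter output has all pairwise identities below threshold", {
  set.seed(31)
  base <- randomSeq(30)
  pool <- setNames(c(
    vapply(1:6, function(i) mutateToIdentity(base, 0.6, indelRate = 0,
                                             seed = i, tol = 0.05), character(1)),
    vapply(1:4, function(i) randomSeq(30), character(1))),
    paste0("s", 1:10))
  out <- FoldScanR:::.asSeqs(filterRedundant(pool, threshold = 0.40))
  if (length(out) > 1) {
    for (i in seq_len(length(out) - 1))
      for (j in seq.int(i + 1, length(out)))
        expect_lt(percentIdentity(out[[i]], out[[j]]), 0.40)
  }
})

test_that("degenerate homolog sets give the seed residue the top score", {
  seed <- setNames("ACDEF", "s")
  p <- buildPSSM(seed, rep(setNames("ACDEF", "h"), 50))
  top <- aaAlphabet()[apply(pssmScores(p), 1, which.max)]
  expect_equal(top, c("A", "C", "D", "E", "F"))
  expect_equal(p@metadata$nseq, 51L)
})

test_that("single-sequence PSSM columns track the substitution-matrix rows", {
  ref <- "ACDEFGHIKLMNPQRSTVWY"
  p <- buildPSSM(setNames(ref, "s1"))
  for (j in 1:20) {
    r <- substring(ref, j, j)
    expect_gte(cor(pssmScores(p)[j, ], submat[r, aaAlphabet()]), 0.9)
  }
})

test_that("columns at background frequencies score zero", {
  bg <- FoldScanR:::.matrixBackground(submat)
  f <- rbind(bg$p, bg$p)
  sc <- FoldScanR:::.pssmScoresFromFrequencies(f, alpha = c(0, 7))
  expect_true(all(abs(sc) <= 0.01))
})

test_that("PSSM construction is deterministic, finite and bounded", {
  set.seed(32)
  seed <- setNames(randomSeq(40), "s")
  homs <- setNames(vapply(1:5, function(i)
    mutateToIdentity(seed, 0.5, seed = i, tol = 0.05), character(1)),
    paste0("h", 1:5))
  p1 <- buildPSSM(seed, homs)
  p2 <- buildPSSM(seed, homs)
  expect_identical(p1@scores, p2@scores)
  bg <- FoldScanR:::.matrixBackground(submat)$p
  bound <- log2(1 / min(bg)) + 1
  expect_true(all(is.finite(p1@scores)))
  expect_true(all(abs(p1@scores) <= bound))
})

test_that("seed columns with unknown residues score zero everywhere", {
  p <- buildPSSM(setNames("ACXDE", "s"))
  expect_true(all(pssmScores(p)[3, ] == 0))
  expect_false(all(pssmScores(p)[1, ] == 0))
})

test_that("fold libraries apply both filters and keep one PSSM per seed", {
  set.seed(33)
  anc <- randomSeq(35)
  mkset <- function(sid, k) {
    seed <- setNames(mutateToIdentity(anc, 0.6, seed = k, tol = 0.05), sid)
    homs <- setNames(c(seed[[1]],                      # = seed, filtered at 0.90
                       vapply(1:4, function(i)
                         mutateToIdentity(seed, 0.55, seed = 100 * k + i,
                                          tol = 0.05), character(1))),
                     paste0(sid, "_h", 0:4))
    list(seed = seed, homologs = homs)
  }
  lib <- buildFoldLibrary("b.1", list(mkset("s1", 1), mkset("s2", 2),
                                      mkset("s3", 3)))
  expect_s4_class(lib, "FoldLibrary")
  expect_length(pssms(lib), 3)
  expect_equal(foldId(lib), "b.1")
  counts <- lib@provenance$homologCounts
  expect_true(all(vapply(counts, function(x) x["after"] < x["before"],
                         logical(1))))
})

test_that("a homolog set collapsing to empty still yields a PSSM", {
  seed <- setNames("ACDEFGHIKLMNPQRSTVWY", "s1")
  homs <- setNames(rep(seed, 3), paste0("h", 1:3))  # all removed at 0.90
  lib <- buildFoldLibrary("x.1", list(list(seed = seed, homologs = homs)))
  expect_length(pssms(lib), 1)
  expect_equal(pssms(lib)[[1]]@metadata$nseq, 1L)
})

test_that("collections preserve axis order across serialization", {
  set.seed(34)
  libs <- lapply(paste0("f", 1:4), function(fid)
    new("FoldLibrary", fold = fid,
        pssms = list(randomPSSM(6, id = paste0(fid, "p"), fold = fid)),
        provenance = list()))
  d <- withr::local_tempdir()
  coll <- compileCollection(libs, dir = d)
  expect_equal(foldIds(readCollectionManifest(file.path(d, "manifest.tsv"))),
               foldIds(coll))
})
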