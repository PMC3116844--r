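# Shared fixtures, built in code.

# a PSSM whose columns score `hit` for the given residues and `miss`
# otherwise; handy for fully controlled alignment outcomes
motifPSSM <- function(residues, hit = 10, miss = -5, id = "motif",
                      fold = "fx") {
  L <- length(residues)
  sc <- matrix(miss, L, 20, dimnames = list(NULL, aaAlphabet()))
  sc[cbind(seq_len(L), match(residues, aaAlphabet()))] <- hit
  PSSM(id, paste(residues, collapse = ""), sc, fold = fold)
}

# a hand-made ProfileAlignment; coverage defaults to the spanned fraction of
# a PSSM of length pssmLength
mkProfileAlignment <- function(qpos, ppos, queryId = "q", pssmId = "p",
                               foldId = "f", score = 10, evalue = 1e-3,
                               coverage = NULL, pssmLength = max(ppos)) {
  if (is.null(coverage))
    coverage <- (max(ppos) - min(ppos) + 1) / pssmLength
  new("ProfileAlignment", queryId = queryId, pssmId = pssmId, foldId = foldId,
      qstart = as.integer(min(qpos)), qend = as.integer(max(qpos)),
      pstart = as.integer(min(ppos)), pend = as.integer(max(ppos)),
      pairs = cbind(qpos = as.integer(qpos), ppos = as.integer(ppos)),
      score = score, evalue = evalue, coverage = coverage)
}

# the fixed-seed end-to-end benchmark world shared by the acceptance tests;
# built lazily once per test run
.fixture_env <- new.env()
benchmarkWorld <- function() {
  if (is.null(.fixture_env$world)) {
    spec <- syntheticFoldSpec(nFolds = 8, seedsPerFold = 2,
                              homologsPerSeed = 15, queriesPerFold = 5,
                              identityBand = c(0.20, 0.30), seed = 20260101)
    bm <- makeBenchmark(spec)
    coll <- buildBenchmarkCollection(bm)
    prof <- structuralProfiles(bm@queries, coll)
    .fixture_env$world <- list(spec = spec, bm = bm, coll = coll,
                               prof = prof)
  }
  .fixture_env$world
}
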