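# Brute-force alignment oracles used to validate the DP kernels.
#
# An alignment is represented by its set of matched (i, j) pairs, strictly
# increasing in both coordinates. Between consecutive matched pairs (and at
# the ends, for global alignment) the unmatched stretches form gaps: a run of
# k unmatched residues costs gapOpen + k * gapExtend, and unmatched runs in
# both sequences between the same two matched pairs form two separate gaps.
# Enumerating every matched-pair set is exhaustive for the alignment problem
# under these costs.

# all strictly-increasing pairings of k positions out of m and n
.enumPairings <- function(m, n) {
  out <- list(list(qi = integer(0), pj = integer(0)))
  for (k in seq_len(min(m, n))) {
    qi <- utils::combn(m, k, simplify = FALSE)
    pj <- utils::combn(n, k, simplify = FALSE)
    for (a in qi) for (b in pj)
      out[[length(out) + 1L]] <- list(qi = a, pj = b)
  }
  out
}

.gapCost <- function(ka, kb, gapOpen, gapExtend) {
  cost <- 0
  if (ka > 0) cost <- cost + gapOpen + ka * gapExtend
  if (kb > 0) cost <- cost + gapOpen + kb * gapExtend
  cost
}

# optimal global score by exhaustive enumeration
bruteGlobalScore <- function(a, b, submat, gapOpen = 10, gapExtend = 0.5) {
  ra <- strsplit(a, "")[[1]]
  rb <- strsplit(b, "")[[1]]
  m <- length(ra); n <- length(rb)
  best <- -Inf
  for (al in .enumPairings(m, n)) {
    qi <- al$qi; pj <- al$pj
    sc <- sum(submat[cbind(ra[qi], rb[pj])])
    bounds_i <- c(0L, qi, m + 1L)
    bounds_j <- c(0L, pj, n + 1L)
    for (s in seq_len(length(qi) + 1L)) {
      ka <- bounds_i[s + 1L] - bounds_i[s] - 1L
      kb <- bounds_j[s + 1L] - bounds_j[s] - 1L
      sc <- sc - .gapCost(ka, kb, gapOpen, gapExtend)
    }
    if (sc > best) best <- sc
  }
  best
}

# optimal local score by exhaustive enumeration: non-empty pairings, no
# terminal gap cost, internal gaps as in the global case
bruteLocalScore <- function(S, gapOpen, gapExtend) {
  m <- nrow(S); n <- ncol(S)
  best <- 0
  for (al in .enumPairings(m, n)) {
    qi <- al$qi; pj <- al$pj
    if (length(qi) == 0L) next
    sc <- sum(S[cbind(qi, pj)])
    if (length(qi) > 1L) {
      for (s in seq_len(length(qi) - 1L)) {
        ka <- qi[s + 1L] - qi[s] - 1L
        kb <- pj[s + 1L] - pj[s] - 1L
        sc <- sc - .gapCost(ka, kb, gapOpen, gapExtend)
      }
    }
    if (sc > best) best <- sc
  }
  best
}

# random test sequences
randomSeq <- function(len) {
  paste(sample(aaAlphabet(), len, replace = TRUE), collapse = "")
}

# random PSSM with scores in roughly the log-odds range
randomPSSM <- function(L, id = "rp", fold = "fx") {
  sc <- round(matrix(stats::rnorm(L * 20, -0.5, 2), L, 20), 2)
  PSSM(id, paste(sample(aaAlphabet(), L, replace = TRUE), collapse = ""),
       sc, fold = fold)
}
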