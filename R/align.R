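#' @include AllClasses.R substitution.R
NULL

# pair-score matrix for two residue vectors under a substitution matrix
.pairScoreMatrix <- function(a, b, submat) {
  rn <- rownames(submat)
  a[!(a %in% rn)] <- "X"
  b[!(b %in% rn)] <- "X"
  unname(submat[a, b, drop = FALSE])
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch alignment with affine gap costs: a gap of length k costs
#' `gapOpen + k * gapExtend` (so one 1-residue gap costs 10.5 under the
#' defaults). The identity fraction counts identical columns over all
#' alignment columns, gap columns included.
#'
#' @param a,b Sequences (single-entry [Biostrings::AAStringSet], character
#'   string, or named character).
#' @param matrix Substitution matrix from [loadSubstitutionMatrix()].
#' @param gapOpen,gapExtend Affine gap penalties (positive).
#' @return A [GlobalAlignment-class] object.
#' @export
#' @examples
#' globalAlign("ACD", "ACD")  # score 19 = 4 + 9 + 6
globalAlign <- function(a, b, matrix = loadSubstitutionMatrix(),
                        gapOpen = 10, gapExtend = 0.5) {
  sa <- .asSeq1(a); sb <- .asSeq1(b)
  if (nchar(sa) == 0L || nchar(sb) == 0L)
    stop("cannot align an empty sequence")
  ra <- strsplit(sa, "")[[1L]]
  rb <- strsplit(sb, "")[[1L]]
  S <- .pairScoreMatrix(ra, rb, matrix)
  res <- cpp_nw_affine(S, gapOpen, gapExtend)
  ops <- res$ops
  ai <- character(length(ops)); bi <- character(length(ops))
  i <- 0L; j <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) { i <- i + 1L; j <- j + 1L; ai[k] <- ra[i]; bi[k] <- rb[j] }
    else if (ops[k] == 1L) { i <- i + 1L; ai[k] <- ra[i]; bi[k] <- "-" }
    else { j <- j + 1L; ai[k] <- "-"; bi[k] <- rb[j] }
  }
  ident <- sum(ai == bi & ai != "-") / length(ops)
  new("GlobalAlignment", alignedA = paste(ai, collapse = ""),
      alignedB = paste(bi, collapse = ""),
      score = res$score, identity = ident)
}

#' Pairwise percent identity from a global alignment
#'
#' Convenience wrapper over [globalAlign()] returning only the identity
#' fraction (identical columns / all alignment columns).
#'
#' @inheritParams globalAlign
#' @return Identity fraction in `[0, 1]`.
#' @export
percentIdentity <- function(a, b, matrix = loadSubstitutionMatrix(),
                            gapOpen = 10, gapExtend = 0.5) {
  globalAlign(a, b, matrix, gapOpen, gapExtend)@identity
}

#' Optimal local alignment of a query against a PSSM
#'
#' Smith-Waterman alignment in which pairing query residue r with PSSM
#' column j scores `pssmScores(pssm)[j, r]`, under affine gap costs (a gap
#' of length k costs `gapOpen + k * gapExtend`). Returns `NULL` when no
#' alignment with positive score exists. Query residues outside the 20
#' standard letters (e.g. `X`) score 0 against every column.
#'
#' Default gap penalties are the BLAST protein defaults (11/1 in half-bits)
#' re-expressed on the bit scale of the PSSM scores.
#'
#' Among co-optimal alignments the kernel deterministically reports the one
#' whose end cell comes first in row-major (query, then profile) order, with
#' state preference match > query-gap > profile-gap during traceback.
#'
#' @param query Query sequence (single-entry container).
#' @param pssm A [PSSM-class].
#' @param gapOpen,gapExtend Positive affine gap penalties, in score units.
#' @param ka [KAParams-class] used to attach an E-value; when `NULL`, default
#'   constants with `m` = query length and `n` = PSSM length are used.
#' @return A [ProfileAlignment-class] or `NULL`.
#' @export
localProfileAlign <- function(query, pssm, gapOpen = 5.5, gapExtend = 0.5,
                              ka = NULL) {
  stopifnot(is(pssm, "PSSM"), gapOpen > 0, gapExtend > 0)
  sq <- .asSeq1(query)
  qid <- names(.asSeqs(query))[1L]
  rq <- strsplit(sq, "")[[1L]]
  idx <- match(rq, aaAlphabet())
  L <- nchar(pssm@refseq)
  # S[i, j] = pssm score of query residue i at profile column j;
  # unknown residues score 0
  S <- matrix(0, nrow = length(rq), ncol = L)
  known <- !is.na(idx)
  S[known, ] <- t(pssm@scores[, idx[known], drop = FALSE])
  res <- cpp_sw_affine(S, gapOpen, gapExtend)
  if (!isTRUE(res$found) || res$score <= 0) return(NULL)
  if (is.null(ka)) ka <- kaParams(m = length(rq), n = L)
  new("ProfileAlignment",
      queryId = qid, pssmId = pssm@id, foldId = pssm@fold,
      qstart = res$qstart, qend = res$qend,
      pstart = res$pstart, pend = res$pend,
      pairs = cbind(qpos = res$qpos, ppos = res$ppos),
      score = res$score,
      evalue = estimateEvalue(res$score, ka),
      coverage = (res$pend - res$pstart + 1) / L)
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of distinct local
#' alignments scoring at least S between random sequences of effective
#' lengths m and n.
#'
#' @param S Raw local alignment score (finite).
#' @param params A [KAParams-class].
#' @return The E-value (positive; monotonically decreasing in S).
#' @export
#' @examples
#' estimateEvalue(40, kaParams(lambda = 0.267, K = 0.041, m = 100, n = 1e4))
estimateEvalue <- function(S, params) {
  stopifnot(is(params, "KAParams"))
  if (!all(is.finite(S))) stop("alignment score must be finite")
  params@K * params@m * params@n * exp(-params@lambda * S)
}

# maximum-likelihood fit of a Gumbel (extreme value) distribution;
# beta solves beta = mean(x) - sum(x e^{-x/b}) / sum(e^{-x/b})
.fitGumbel <- function(x) {
  f <- function(b) {
    w <- exp(-(x - max(x)) / b)      # shifted for numerical stability
    b - mean(x) + sum(x * w) / sum(w)
  }
  lo <- sd(x) * 0.1; hi <- sd(x) * 5
  beta <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root,
                   error = function(e) sd(x) * sqrt(6) / pi)
  mu <- -beta * log(mean(exp(-(x - max(x)) / beta))) + max(x)
  list(mu = mu, beta = beta)
}

#' Calibrate Karlin-Altschul parameters for a PSSM
#'
#' Fits `lambda` and `K` by a maximum-likelihood Gumbel fit to optimal local
#' alignment scores of random background-composition queries against the
#' PSSM: for score maxima, `P(S >= x) ~ K m n exp(-lambda x)` corresponds to
#' a Gumbel with `lambda = 1/beta` and `K = exp(lambda mu) / (m n)`.
#' Deterministic given `seed`.
#'
#' @param pssm A [PSSM-class].
#' @param background Residue sampling frequencies (defaults to the
#'   matrix-implied background).
#' @param nShuffles Number of random queries (>= 100).
#' @param seed Integer seed for the simulation stream.
#' @param queryLength Length of the random queries.
#' @param gapOpen,gapExtend Gap penalties used for the fitted regime; the
#'   very large defaults calibrate the ungapped statistics.
#' @return A [KAParams-class] with `m = queryLength`, `n` = PSSM length.
#' @export
calibrateParams <- function(pssm, background = NULL, nShuffles = 200,
                            seed = 1L, queryLength = 100,
                            gapOpen = 1e6, gapExtend = 1e6) {
  stopifnot(is(pssm, "PSSM"), nShuffles >= 100)
  if (all(pssm@scores <= 0))
    stop("calibration error: degenerate PSSM (no positive column scores)")
  if (is.null(background)) background <- .matrixBackground()$p
  L <- nchar(pssm@refseq)
  scores <- withr::with_seed(seed, {
    vapply(seq_len(nShuffles), function(i) {
      q <- paste(sample(aaAlphabet(), queryLength, replace = TRUE,
                        prob = background), collapse = "")
      al <- localProfileAlign(q, pssm, gapOpen = gapOpen,
                              gapExtend = gapExtend)
      if (is.null(al)) 0 else al@score
    }, numeric(1))
  }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
     .rng_sample_kind = "Rejection")
  fit <- .fitGumbel(scores)
  lambda <- 1 / fit$beta
  K <- exp(lambda * fit$mu) / (queryLength * L)
  kaParams(lambda = lambda, K = K, m = queryLength, n = L)
}
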