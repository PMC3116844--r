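#' @include scoring.R
NULL

#' Build a labelled all-against-all pair table
#'
#' Combines a structural similarity matrix with fold truth labels into the
#' evaluation container: every unordered pair of queries with its score and
#' a same-fold / different-fold label. Self-pairs are excluded.
#'
#' @param simmat Symmetric similarity matrix from [similarityMatrix()].
#' @param truth Named character vector mapping query id to fold id (or a
#'   data.frame with columns `query` and `fold`).
#' @return A [RankedPairTable-class].
#' @export
rankedPairTable <- function(simmat, truth) {
  if (is.data.frame(truth)) truth <- setNames(truth$fold, truth$query)
  ids <- rownames(simmat)
  if (is.null(ids) || !all(ids %in% names(truth)))
    stop("every query in the similarity matrix needs a truth label")
  n <- length(ids)
  idx <- which(upper.tri(simmat), arr.ind = TRUE)
  pairs <- data.frame(
    a = ids[idx[, 1L]], b = ids[idx[, 2L]],
    score = simmat[idx],
    sameFold = truth[ids[idx[, 1L]]] == truth[ids[idx[, 2L]]],
    row.names = NULL, stringsAsFactors = FALSE)
  new("RankedPairTable", pairs = pairs, ids = ids)
}

#' ROC curve of a ranked pair table
#'
#' Sweeps a global score threshold over the pooled pairs; at each threshold
#' pairs scoring at or above it are called positive, and
#' `sensitivity = TP / (TP + FN)` and `FPR = FP / (FP + TN)` are recorded.
#' The AUC is the trapezoidal area under the (FPR, sensitivity) curve.
#'
#' @param table A [RankedPairTable-class] with at least one same-fold and one
#'   different-fold pair.
#' @return A [ROCCurve-class].
#' @export
rocCurve <- function(table) {
  stopifnot(is(table, "RankedPairTable"))
  p <- table@pairs
  npos <- sum(p$sameFold)
  nneg <- sum(!p$sameFold)
  if (npos == 0L || nneg == 0L)
    stop("ROC undefined: need at least one positive and one negative pair")
  th <- sort(unique(p$score), decreasing = TRUE)
  pts <- t(vapply(th, function(t) {
    pred <- p$score >= t
    c(fpr = sum(pred & !p$sameFold) / nneg,
      sensitivity = sum(pred & p$sameFold) / npos)
  }, c(fpr = 0, sensitivity = 0)))
  pts <- data.frame(threshold = c(Inf, th),
                    fpr = c(0, pts[, "fpr"]),
                    sensitivity = c(0, pts[, "sensitivity"]))
  if (pts$fpr[nrow(pts)] < 1 || pts$sensitivity[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, sensitivity = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$sensitivity, -1) +
                              pts$sensitivity[-1]) / 2)
  new("ROCCurve", points = pts, auc = auc)
}

#' Sensitivity at a given false-positive rate
#'
#' Reads the highest sensitivity attained at or below the requested FPR off
#' a computed ROC curve.
#'
#' @param roc A [ROCCurve-class].
#' @param fpr Target false-positive rate.
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivityAtFPR <- function(roc, fpr = 0.01) {
  stopifnot(is(roc, "ROCCurve"))
  ok <- roc@points$fpr <= fpr
  if (!any(ok)) return(0)
  max(roc@points$sensitivity[ok])
}

#' Top-k confusion sets of a ranked pair table
#'
#' For every query, its partners are ranked by similarity score (descending,
#' ties by partner id) and the top `k` taken: same-fold partners in the
#' top k are true-positive pairs, different-fold partners in the top k are
#' false positives, and same-fold partners outside the top k are false
#' negatives. Queries with fewer than `k` partners use all of them. Sets are
#' keyed by unordered id pairs for Venn-style comparison across methods.
#'
#' @param table A [RankedPairTable-class].
#' @param k Ranking depth (default 9, the usual reporting depth).
#' @return List with character-vector elements `TP`, `FP`, `FN` of
#'   `"a|b"` pair keys (lexicographically ordered within the key; a pair can
#'   appear in both `TP` and `FN` when it ranks inside one endpoint's top k
#'   but outside the other's), plus `perQuery`, a data.frame of per-query
#'   TP/FP/FN counts satisfying `TP + FN = same-fold partners` per query.
#' @export
topkConfusion <- function(table, k = 9) {
  stopifnot(is(table, "RankedPairTable"), k >= 1)
  p <- table@pairs
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "|")
  TP <- FP <- FN <- character(0)
  perQuery <- data.frame(query = table@ids, TP = 0L, FP = 0L, FN = 0L)
  for (qi in seq_along(table@ids)) {
    q <- table@ids[qi]
    sel <- p$a == q | p$b == q
    partner <- ifelse(p$a[sel] == q, p$b[sel], p$a[sel])
    sc <- p$score[sel]
    same <- p$sameFold[sel]
    ord <- order(-sc, partner)
    top <- seq_along(ord) <= k
    perQuery$TP[qi] <- sum(top & same[ord])
    perQuery$FP[qi] <- sum(top & !same[ord])
    perQuery$FN[qi] <- sum(!top & same[ord])
    TP <- c(TP, key(q, partner[ord][top & same[ord]]))
    FP <- c(FP, key(q, partner[ord][top & !same[ord]]))
    FN <- c(FN, key(q, partner[ord][!top & same[ord]]))
  }
  list(TP = unique(TP), FP = unique(FP), FN = unique(FN),
       perQuery = perQuery)
}

#' Compare top-k confusion sets across methods
#'
#' Pairwise intersection sizes and per-method unique counts for each of the
#' TP / FP / FN categories.
#'
#' @param confusions Named list (>= 2 methods) of [topkConfusion()] results.
#' @return List per category with elements `sizes` (named set sizes),
#'   `shared` (methods x methods intersection-size matrix) and `unique`
#'   (pairs present in that method and absent from every other).
#' @export
compareMethods <- function(confusions) {
  stopifnot(length(confusions) >= 2L, !is.null(names(confusions)))
  methods <- names(confusions)
  out <- list()
  for (cat in c("TP", "FP", "FN")) {
    sets <- lapply(confusions, `[[`, cat)
    nm <- length(methods)
    shared <- array(0L, dim = c(nm, nm), dimnames = list(methods, methods))
    for (i in seq_len(nm)) for (j in seq_len(nm))
      shared[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    uniq <- vapply(seq_len(nm), function(i)
      length(setdiff(sets[[i]], unlist(sets[-i]))), integer(1))
    out[[cat]] <- list(sizes = vapply(sets, length, integer(1)),
                       shared = shared,
                       unique = setNames(uniq, methods))
  }
  out
}

#' Empirical cumulative distribution with threshold reports
#'
#' @param values Non-empty numeric vector (e.g. pairwise identities or
#'   structural similarity scores).
#' @param thresholds Thresholds for which the fraction of values strictly
#'   above each is reported (e.g. the 0.1 similarity calling threshold).
#' @return List with elements `ecdf` (a [stats::ecdf] function) and
#'   `fractionAbove` (named numeric vector).
#' @export
cumulativeDistribution <- function(values, thresholds = numeric(0)) {
  if (length(values) == 0L) stop("empty input")
  list(ecdf = ecdf(values),
       fractionAbove = setNames(vapply(thresholds, function(t)
         mean(values > t), numeric(1)), thresholds))
}
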