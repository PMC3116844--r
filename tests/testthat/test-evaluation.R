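# random labelled pair table over n queries in g fold groups
randomPairTable <- function(n = 8, g = 3, signal = 1) {
  ids <- sprintf("q%02d", seq_len(n))
  folds <- setNames(sample(paste0("f", seq_len(g)), n, replace = TRUE), ids)
  sm <- diag(NA_real_, n)
  dimnames(sm) <- list(ids, ids)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    same <- folds[i] == folds[j]
    sm[i, j] <- sm[j, i] <- rnorm(1, mean = if (same) signal else 0, sd = 1)
  }
  rankedPairTable(sm, folds)
}

# Mann-Whitney AUC: fraction of (positive, negative) score pairs correctly
# ordered, ties counting half -- an independent closed form for ROC area
mwAUC <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("ROC curves match the rank-statistic AUC on random tables", {
  set.seed(61)
  for (i in 1:20) {
    tab <- randomPairTable(n = sample(5:11, 1), g = sample(2:3, 1))
    np <- sum(tab@pairs$sameFold)
    if (np == 0 || np == nrow(tab@pairs)) next
    roc <- rocCurve(tab)
    expect_equal(roc@auc, mwAUC(tab@pairs$score, tab@pairs$sameFold),
                 tolerance = 1e-12)
    expect_true(all(diff(roc@points$fpr) >= 0))
    expect_true(all(diff(roc@points$sensitivity) >= 0))
    expect_true(all(roc@points$fpr >= 0 & roc@points$fpr <= 1))
  }
})

test_that("degenerate score configurations give the expected AUC", {
  ids <- paste0("q", 1:4)
  folds <- setNames(c("a", "a", "b", "b"), ids)
  sep <- diag(NA_real_, 4); dimnames(sep) <- list(ids, ids)
  sep[lower.tri(sep)] <- 0; sep <- pmax(sep, t(sep), na.rm = TRUE)
  diag(sep) <- NA
  sep["q1", "q2"] <- sep["q2", "q1"] <- 1   # the only same-fold pair...
  sep["q3", "q4"] <- sep["q4", "q3"] <- 1   # ...and another, both top
  expect_equal(rocCurve(rankedPairTable(sep, folds))@auc, 1.0)

  flat <- diag(NA_real_, 4); dimnames(flat) <- list(ids, ids)
  flat[is.na(diag(4)) | TRUE] <- 0.3; diag(flat) <- NA
  expect_equal(rocCurve(rankedPairTable(flat, folds))@auc, 0.5)

  onecls <- setNames(rep("a", 4), ids)
  expect_error(rocCurve(rankedPairTable(flat, onecls)), "undefined")
})

test_that("sensitivity follows TP / (TP + FN) at each threshold", {
  # 10 same-fold pairs: 6 score high, 4 low; negatives in between
  ids <- paste0("q", 1:20)
  pairs <- data.frame(
    a = ids[seq(1, 20, 2)], b = ids[seq(2, 20, 2)],
    score = c(rep(1, 6), rep(0, 4)),
    sameFold = TRUE)
  neg <- data.frame(a = "q1", b = ids[3:12], score = 0.5, sameFold = FALSE)
  tab <- new("RankedPairTable", pairs = rbind(pairs, neg), ids = ids)
  roc <- rocCurve(tab)
  at1 <- roc@points[roc@points$threshold == 1, ]
  expect_equal(at1$sensitivity, 0.6)
  expect_equal(at1$fpr, 0)
  expect_equal(sensitivityAtFPR(roc, 0), 0.6)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(62)
  tab <- randomPairTable(n = 9, g = 3)
  a1 <- rocCurve(tab)@auc
  tab2 <- tab
  tab2@pairs$score <- exp(3 * tab2@pairs$score) - 5
  expect_equal(rocCurve(tab2)@auc, a1, tolerance = 1e-12)
})

test_that("top-k sets follow the counting protocol", {
  # one query with 5 same-fold partners, 3 inside the top 9
  ids <- c("q", paste0("s", 1:5), paste0("d", 1:8))
  folds <- setNames(c("a", rep("a", 5), rep("b", 8)), ids)
  sm <- diag(NA_real_, 14); dimnames(sm) <- list(ids, ids)
  sm[lower.tri(sm)] <- 0; sm <- pmax(sm, t(sm), na.rm = TRUE); diag(sm) <- NA
  # q's partners: s1..s3 high, s4, s5 low, d1..d8 middling
  sm["q", paste0("s", 1:3)] <- sm[paste0("s", 1:3), "q"] <- 0.9
  sm["q", paste0("d", 1:8)] <- sm[paste0("d", 1:8), "q"] <- 0.5
  sm["q", c("s4", "s5")] <- sm[c("s4", "s5"), "q"] <- 0.1
  tab <- rankedPairTable(sm, folds)
  conf <- topkConfusion(tab, k = 9)
  qrow <- conf$perQuery[conf$perQuery$query == "q", ]
  expect_equal(qrow$TP, 3)    # 3 of 5 same-fold partners inside the top 9
  expect_equal(qrow$FN, 2)
  expect_equal(qrow$FP, 6)    # the 9 slots minus the 3 same-fold hits
})

test_that("top-k conserves TP + FN = same-fold partners per query", {
  set.seed(63)
  for (i in 1:10) {
    tab <- randomPairTable(n = sample(6:12, 1), g = 2)
    k <- sample(1:5, 1)
    conf <- topkConfusion(tab, k = k)
    for (qi in seq_along(tab@ids)) {
      q <- tab@ids[qi]
      sel <- tab@pairs$a == q | tab@pairs$b == q
      npos <- sum(tab@pairs$sameFold[sel])
      row <- conf$perQuery[conf$perQuery$query == q, ]
      expect_equal(row$TP + row$FN, npos)
      expect_lte(row$TP + row$FP, k)
    }
  }
})

test_that("fewer than k partners uses all ranked partners", {
  ids <- c("x", "y", "z")
  folds <- setNames(c("a", "a", "b"), ids)
  sm <- diag(NA_real_, 3); dimnames(sm) <- list(ids, ids)
  sm[lower.tri(sm)] <- c(0.9, 0.2, 0.1)
  sm <- pmax(sm, t(sm), na.rm = TRUE); diag(sm) <- NA
  conf <- topkConfusion(rankedPairTable(sm, folds), k = 9)
  expect_setequal(conf$TP, "x|y")
  expect_length(conf$FN, 0)
})

test_that("method comparison reports shared and unique pair sets", {
  c1 <- list(TP = c("a|b", "a|c", "b|c"), FP = c("d|e"), FN = character(0))
  expect_equal(unname(compareMethods(list(m1 = c1, m2 = c1))$TP$unique),
               c(0L, 0L))
  expect_equal(compareMethods(list(m1 = c1, m2 = c1))$TP$shared["m1", "m2"], 3L)
  c2 <- list(TP = c("x|y", "y|z"), FP = character(0), FN = c("a|b"))
  cmp <- compareMethods(list(m1 = c1, m2 = c2))
  expect_equal(unname(cmp$TP$unique), c(3L, 2L))
  expect_equal(cmp$TP$shared["m1", "m2"], 0L)

  # brute-force set algebra on random small sets
  set.seed(64)
  universe <- apply(utils::combn(letters[1:6], 2), 2, paste, collapse = "|")
  for (i in 1:10) {
    sets <- lapply(1:3, function(j)
      list(TP = sample(universe, sample(0:8, 1)),
           FP = sample(universe, sample(0:8, 1)),
           FN = sample(universe, sample(0:8, 1))))
    names(sets) <- c("A", "B", "C")
    cmp <- compareMethods(sets)
    for (cat in c("TP", "FP", "FN")) {
      for (m in names(sets)) {
        others <- unlist(lapply(sets[setdiff(names(sets), m)], `[[`, cat))
        expect_equal(cmp[[cat]]$unique[[m]],
                     sum(!(sets[[m]][[cat]] %in% others)))
      }
    }
  }
})

test_that("cumulative distributions report threshold exceedance", {
  cd <- cumulativeDistribution(c(0, 1), thresholds = 0.5)
  expect_equal(unname(cd$fractionAbove), 0.5)
  expect_equal(unname(cumulativeDistribution(c(0.01, 0.05),
                                             thresholds = 0.1)$fractionAbove),
               0)
  set.seed(65)
  v <- rnorm(100)
  F <- cumulativeDistribution(v)$ecdf
  grid <- seq(min(v), max(v), length.out = 50)
  expect_true(all(diff(F(grid)) >= 0))
  expect_equal(F(max(v)), 1)
  expect_error(cumulativeDistribution(numeric(0)), "empty")
})
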