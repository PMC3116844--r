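#' @include scoring.R
NULL

#' Identity x coverage feature vectors over one fold library
#'
#' Represents each entity (candidate template domain or modelling target) as
#' a vector with one entry per PSSM in the fold library: the best surviving
#' local alignment's identity fraction (identical aligned pairs / aligned
#' pair count) multiplied by its PSSM coverage, or 0 when no alignment
#' survives the thresholds. Axis order is the library's PSSM order.
#'
#' @param entities Sequence set (targets and candidate domains).
#' @param library A [FoldLibrary-class].
#' @inheritParams scanLibrary
#' @return Numeric matrix, entities x PSSMs, entries in `[0, 1]`.
#' @export
templateFeatures <- function(entities, library,
                             thresholds = scanThresholds("strict"),
                             ka = NULL, gapOpen = 5.5, gapExtend = 0.5) {
  stopifnot(is(library, "FoldLibrary"), length(library@pssms) >= 1L)
  seqs <- .asSeqs(entities)
  ids <- .seqIds(entities)
  pids <- vapply(library@pssms, pssmId, character(1))
  out <- array(0, dim = c(length(seqs), length(pids)),
               dimnames = list(ids, pids))
  for (i in seq_along(seqs)) {
    als <- scanLibrary(setNames(seqs[i], ids[i]), library, thresholds,
                       ka, gapOpen, gapExtend)
    for (al in als) {
      ref <- refSequence(library@pssms[[match(al@pssmId, pids)]])
      q <- strsplit(seqs[[i]], "")[[1L]][al@pairs[, 1L]]
      r <- substring(ref, al@pairs[, 2L], al@pairs[, 2L])
      out[i, al@pssmId] <- mean(q == r) * al@coverage
    }
  }
  out
}

#' Hierarchically cluster template feature vectors
#'
#' Agglomerative clustering with distance `1 - Pearson` (zero-variance
#' vectors are treated as uncorrelated, similarity 0, as in
#' [structuralSimilarity()]). Rows are ordered lexicographically by id before
#' clustering so tie handling is deterministic.
#'
#' @param features Entity x PSSM feature matrix from [templateFeatures()]
#'   (at least 2 rows).
#' @param linkage Linkage passed to [stats::hclust()]; default `"average"`
#'   (UPGMA), the standard choice for correlation-based profiles.
#' @return An [stats::hclust] dendrogram (merge heights are `1 - similarity`).
#' @export
clusterTemplates <- function(features, linkage = "average") {
  if (nrow(features) < 2L) stop("at least 2 feature vectors required")
  features <- features[order(rownames(features)), , drop = FALSE]
  n <- nrow(features)
  d <- array(0, dim = c(n, n), dimnames = list(rownames(features),
                                               rownames(features)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d[i, j] <- d[j, i] <- 1 - structuralSimilarity(features[i, ],
                                                     features[j, ])
    }
  }
  hclust(as.dist(d), method = linkage)
}

#' Select modelling templates for a target
#'
#' Ranks all non-target entities by Pearson similarity of their
#' identity x coverage feature vectors to the target's and returns the top
#' `k` (by default 3, the usual maximum number of templates passed on to
#' downstream modelling). Ties are broken by id order, so the selection is
#' deterministic. The dendrogram from [clusterTemplates()] complements the
#' ranking for visual inspection but does not alter it.
#'
#' @param features Entity x PSSM feature matrix including the target row.
#' @param targetId Row name of the target.
#' @param k Number of templates to return; when larger than the number of
#'   candidates, all candidates are returned ranked.
#' @return Character vector of template ids, best first.
#' @export
selectTemplates <- function(features, targetId, k = 3) {
  if (!(targetId %in% rownames(features)))
    stop("target \"", targetId, "\" not among the feature vectors")
  target <- features[targetId, ]
  others <- setdiff(rownames(features), targetId)
  sims <- vapply(others, function(id)
    structuralSimilarity(features[id, ], target), numeric(1))
  ranked <- others[order(-sims, others)]
  head(ranked, k)
}
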