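#' @include pssm-build.R
NULL

#' Scan a query against one fold-specific library
#'
#' Runs [localProfileAlign()] against every PSSM in the library (one best
#' local alignment per PSSM) and keeps the alignments satisfying
#' `E <= maxEvalue` and `coverage >= minCoverage`.
#'
#' @param query Query sequence (single-entry container).
#' @param library A [FoldLibrary-class].
#' @param thresholds A [ScanThresholds-class]; default the `"strict"` preset
#'   (E <= 0.01, no coverage requirement).
#' @param ka Optional [KAParams-class]; when `NULL`, default constants with
#'   `m` = query length and `n` = total library PSSM length.
#' @param gapOpen,gapExtend Profile alignment gap penalties.
#' @return List of surviving [ProfileAlignment-class] objects (possibly
#'   empty).
#' @export
scanLibrary <- function(query, library, thresholds = scanThresholds("strict"),
                        ka = NULL, gapOpen = 5.5, gapExtend = 0.5) {
  stopifnot(is(library, "FoldLibrary"), is(thresholds, "ScanThresholds"))
  if (is.null(ka)) {
    ndb <- sum(vapply(library@pssms, function(p) nchar(p@refseq), numeric(1)))
    ka <- kaParams(m = nchar(.asSeq1(query)), n = ndb)
  }
  out <- list()
  for (p in library@pssms) {
    al <- localProfileAlign(query, p, gapOpen, gapExtend, ka = ka)
    if (!is.null(al)) out[[length(out) + 1L]] <- al
  }
  filterAlignments(out, thresholds)
}

#' Filter profile alignments by E-value and coverage
#'
#' Keeps exactly the alignments with `E <= maxEvalue` and
#' `coverage >= minCoverage` (both thresholds inclusive).
#'
#' @param alignments List of [ProfileAlignment-class] objects.
#' @param thresholds A [ScanThresholds-class].
#' @return The surviving subset, input order preserved.
#' @export
filterAlignments <- function(alignments, thresholds) {
  stopifnot(is(thresholds, "ScanThresholds"))
  keep <- vapply(alignments, function(al)
    al@evalue <= thresholds@maxEvalue &&
      al@coverage >= thresholds@minCoverage, logical(1))
  alignments[keep]
}

#' Accumulate per-residue positional scores from surviving alignments
#'
#' For every aligned pair (query residue q at position i, PSSM reference
#' residue r): when the substitution score `matrix(q, r)` is positive -- which
#' covers both identical and conserved (non-identical but positively scoring)
#' pairs -- that score is added to the positional score `P[i]`. Pairs scoring
#' <= 0 and gaps contribute nothing, so the track is non-negative. Scores sum
#' over all alignments of the query against the library's PSSMs.
#'
#' The aligned partner of a query residue is the PSSM's reference residue at
#' the aligned column.
#'
#' @param query The scanned query (single-entry container).
#' @param alignments List of [ProfileAlignment-class] from one library scan
#'   of this query; each PSSM reference is looked up in `refs`.
#' @param refs Named character vector mapping pssm id to reference sequence;
#'   when `NULL` it must be recoverable from `library`.
#' @param library Optional [FoldLibrary-class] supplying the references.
#' @param matrix Substitution matrix.
#' @param partner `"reference"` (default) pairs each query residue with the
#'   PSSM's reference residue at the aligned column; `"column-max"` pairs it
#'   with the column's top-scoring residue instead (requires `library`).
#' @return Numeric vector `P` of length `nchar(query)` (all entries >= 0).
#' @export
positionalScores <- function(query, alignments, library = NULL, refs = NULL,
                             matrix = loadSubstitutionMatrix(),
                             partner = c("reference", "column-max")) {
  partner <- match.arg(partner)
  sq <- .asSeq1(query)
  rq <- strsplit(sq, "")[[1L]]
  if (partner == "column-max") {
    if (is.null(library))
      stop("partner = \"column-max\" requires `library`")
    refs <- vapply(library@pssms, function(p)
      paste(aaAlphabet()[apply(p@scores, 1L, which.max)], collapse = ""),
      character(1))
    names(refs) <- vapply(library@pssms, function(p) p@id, character(1))
  } else if (is.null(refs)) {
    if (is.null(library))
      stop("supply either `refs` or `library` to resolve PSSM references")
    refs <- vapply(library@pssms, function(p) p@refseq, character(1))
    names(refs) <- vapply(library@pssms, function(p) p@id, character(1))
  }
  P <- numeric(length(rq))
  for (al in alignments) {
    ref <- refs[[al@pssmId]]
    if (is.null(ref)) stop("unknown PSSM id in alignment: ", al@pssmId)
    qpos <- al@pairs[, 1L]
    ppos <- al@pairs[, 2L]
    if (any(qpos < 1L | qpos > length(rq)) ||
        any(ppos < 1L | ppos > nchar(ref)))
      stop("alignment references out-of-range positions")
    sc <- .pairScore(matrix, rq[qpos], substring(ref, ppos, ppos))
    pos <- sc > 0
    if (any(pos)) {
      add <- tapply(sc[pos], qpos[pos], sum)
      P[as.integer(names(add))] <- P[as.integer(names(add))] + add
    }
  }
  P
}

#' Fold-specific score of a query for one library
#'
#' The sum of all positive positional scores divided by the query length:
#' `score = sum(max(P_i, 0)) / n`. An empty track (no surviving alignments)
#' scores 0.
#'
#' @param track Numeric positional score vector from [positionalScores()].
#' @param n Query length; defaults to `length(track)`.
#' @return Non-negative fold-specific score.
#' @export
#' @examples
#' foldSpecificScore(c(5, 0, 3))  # 8/3
foldSpecificScore <- function(track, n = length(track)) {
  if (length(track) == 0L || n == 0L) return(0)
  sum(pmax(track, 0)) / n
}

#' Structural sequence profile of a query
#'
#' Scans the query against every fold library in the collection and records
#' one fold-specific score per library, in the collection's axis order.
#'
#' @param query Query sequence (single-entry container).
#' @param collection A [LibraryCollection-class].
#' @inheritParams scanLibrary
#' @param matrix Substitution matrix for the positional scoring.
#' @return A [StructuralProfile-class].
#' @export
structuralProfile <- function(query, collection,
                              thresholds = scanThresholds("strict"),
                              ka = NULL, matrix = loadSubstitutionMatrix(),
                              gapOpen = 5.5, gapExtend = 0.5) {
  stopifnot(is(collection, "LibraryCollection"))
  n <- nchar(.asSeq1(query))
  scores <- vapply(collection@libraries, function(lib) {
    als <- scanLibrary(query, lib, thresholds, ka, gapOpen, gapExtend)
    foldSpecificScore(positionalScores(query, als, library = lib,
                                       matrix = matrix), n = n)
  }, numeric(1))
  new("StructuralProfile", queryId = .seqIds(query)[1L],
      folds = foldIds(collection), scores = unname(scores))
}

#' Structural sequence profiles for a set of queries
#'
#' @param queries Sequence set.
#' @inheritParams structuralProfile
#' @return Numeric matrix, queries x folds, rownames = query ids, colnames =
#'   the collection's fold axis order.
#' @export
structuralProfiles <- function(queries, collection,
                               thresholds = scanThresholds("strict"),
                               ka = NULL, matrix = loadSubstitutionMatrix(),
                               gapOpen = 5.5, gapExtend = 0.5) {
  seqs <- .asSeqs(queries)
  ids <- .seqIds(queries)
  rows <- lapply(seq_along(seqs), function(i) {
    structuralProfile(setNames(seqs[i], ids[i]), collection, thresholds,
                      ka, matrix, gapOpen, gapExtend)@scores
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(ids, foldIds(collection))
  out
}

#' Structural similarity score of two profiles
#'
#' Pearson's correlation coefficient of the two structural sequence profiles
#' over the fold axes, computed from the explicit definition
#' `PC(X, Y) = sum((X - mean(X)) (Y - mean(Y))) / (n sd(X) sd(Y))` with the
#' number of measuring folds `n`. If either profile has zero standard
#' deviation the correlation is undefined and 0 is returned ("no evidence of
#' similarity"). In the published protocol pairs scoring above 0.1 are
#' treated as structurally related.
#'
#' @param X,Y [StructuralProfile-class] objects or plain numeric vectors
#'   with identical fold axes (length >= 2).
#' @return Similarity in `[-1, 1]`; symmetric in its arguments.
#' @export
structuralSimilarity <- function(X, Y) {
  if (is(X, "StructuralProfile") && is(Y, "StructuralProfile")) {
    if (!identical(X@folds, Y@folds))
      stop("profiles have different fold axes")
    x <- X@scores; y <- Y@scores
  } else {
    x <- as.numeric(X); y <- as.numeric(Y)
    if (length(x) != length(y)) stop("profiles have different fold axes")
  }
  if (length(x) < 2L) stop("at least 2 fold axes required")
  dx <- x - mean(x)
  dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(0)
  sum(dx * dy) / den
}

#' Predict the fold of a query from its structural profile
#'
#' The fold with the highest fold-specific score; an all-zero profile gives
#' `"unassigned"`; ties go to the earliest axis.
#'
#' @param profile A [StructuralProfile-class] (or named numeric vector of
#'   fold-specific scores).
#' @return A fold id or `"unassigned"`.
#' @export
predictFold <- function(profile) {
  if (is(profile, "StructuralProfile")) {
    sc <- profile@scores; folds <- profile@folds
  } else {
    sc <- as.numeric(profile); folds <- names(profile)
  }
  if (all(sc == 0)) return("unassigned")
  folds[which.max(sc)]
}

#' All-against-all structural similarity matrix
#'
#' @param profiles A queries x folds profile matrix from
#'   [structuralProfiles()] (or a list of [StructuralProfile-class] objects
#'   sharing axes).
#' @return Symmetric numeric matrix of pairwise structural similarity scores
#'   with query ids as dimnames; the diagonal (self-pairs) is set to `NA`
#'   and is excluded from downstream rankings.
#' @export
similarityMatrix <- function(profiles) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    axes <- profiles[[1L]]@folds
    for (p in profiles) if (!identical(p@folds, axes))
      stop("profiles have different fold axes")
    ids <- vapply(profiles, queryId, character(1))
    profiles <- do.call(rbind, lapply(profiles, function(p) p@scores))
    rownames(profiles) <- ids
  }
  n <- nrow(profiles)
  if (n < 2L) stop("at least 2 profiles required")
  out <- diag(NA_real_, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      out[i, j] <- out[j, i] <- structuralSimilarity(profiles[i, ],
                                                     profiles[j, ])
    }
  }
  dimnames(out) <- list(rownames(profiles), rownames(profiles))
  out
}
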