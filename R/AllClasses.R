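#' @include FoldScanR-package.R
NULL

## Central S4 containers. Sequences travel as Biostrings::AAStringSet (or
## named character vectors); all coordinates in serialized files are 1-based
## and inclusive, and the same convention is used internally throughout.

#' PSSM: a position-specific scoring matrix for one reference sequence
#'
#' Per-position log2-odds scores over the 20 standard residues, anchored on a
#' reference (seed) sequence. One PSSM is one member of a fold-specific
#' library.
#'
#' @slot id Unique PSSM identifier.
#' @slot fold Fold label this PSSM belongs to (`NA` if unassigned).
#' @slot refseq Reference sequence (uppercase residue string).
#' @slot scores Numeric matrix, one row per reference position, 20 columns in
#'   [aaAlphabet()] order. Scores are log2 odds rounded to 2 decimals.
#' @slot metadata List of construction parameters (number of contributing
#'   sequences `nseq`, pseudocount weight `beta`).
#' @export
setClass("PSSM", representation(
  id = "character", fold = "character", refseq = "character",
  scores = "matrix", metadata = "list"
))

setValidity("PSSM", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (nrow(object@scores) != nchar(object@refseq))
    msg <- c(msg, "number of score rows must equal reference length")
  if (ncol(object@scores) != 20L || !identical(colnames(object@scores), aaAlphabet()))
    msg <- c(msg, "scores must have 20 columns in ARNDCQEGHILKMFPSTWYV order")
  if (!all(is.finite(object@scores)))
    msg <- c(msg, "all scores must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a PSSM object
#'
#' @param id PSSM identifier.
#' @param refseq Reference residue string.
#' @param scores Numeric L x 20 matrix (columns in [aaAlphabet()] order;
#'   column names are set if missing).
#' @param fold Fold label.
#' @param metadata List of construction metadata.
#' @return A [PSSM-class] object.
#' @export
PSSM <- function(id, refseq, scores, fold = NA_character_, metadata = list()) {
  scores <- as.matrix(scores)
  colnames(scores) <- aaAlphabet()
  new("PSSM", id = as.character(id), fold = as.character(fold),
      refseq = toupper(as.character(refseq)), scores = scores,
      metadata = metadata)
}

#' FoldLibrary: the set of PSSMs defining one fold
#'
#' @slot fold Fold identifier (e.g. a SCOP-style label such as "b.1").
#' @slot pssms List of [PSSM-class] objects with unique ids.
#' @slot provenance List of notes (e.g. sequence counts before/after
#'   redundancy filtering).
#' @export
setClass("FoldLibrary", representation(
  fold = "character", pssms = "list", provenance = "list"
))

setValidity("FoldLibrary", function(object) {
  msg <- character(0)
  if (length(object@pssms) < 1L)
    msg <- c(msg, "a fold library must contain at least one PSSM")
  if (!all(vapply(object@pssms, is, logical(1), "PSSM")))
    msg <- c(msg, "pssms must all be PSSM objects")
  ids <- vapply(object@pssms, function(p) p@id, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "PSSM ids must be unique within a library")
  if (length(msg)) msg else TRUE
})

#' LibraryCollection: an ordered set of fold libraries
#'
#' The order of the libraries is the axis order of every structural sequence
#' profile computed against the collection; it is fixed at compile time.
#'
#' @slot libraries List of [FoldLibrary-class] objects with unique fold ids.
#' @export
setClass("LibraryCollection", representation(libraries = "list"))

setValidity("LibraryCollection", function(object) {
  msg <- character(0)
  if (!all(vapply(object@libraries, is, logical(1), "FoldLibrary")))
    msg <- c(msg, "libraries must all be FoldLibrary objects")
  ids <- vapply(object@libraries, function(l) l@fold, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "fold ids must be unique in a collection")
  if (length(msg)) msg else TRUE
})

#' StructuralProfile: the structural sequence profile of one query
#'
#' A vector of fold-specific scores, one per fold library in the collection
#' the query was scanned against, in that collection's axis order.
#'
#' @slot queryId Query identifier.
#' @slot folds Character vector of fold ids (the axes).
#' @slot scores Numeric vector of fold-specific scores (non-negative).
#' @export
setClass("StructuralProfile", representation(
  queryId = "character", folds = "character", scores = "numeric"
))

setValidity("StructuralProfile", function(object) {
  msg <- character(0)
  if (length(object@folds) != length(object@scores))
    msg <- c(msg, "one score per fold axis required")
  if (any(object@scores < 0))
    msg <- c(msg, "fold-specific scores are non-negative")
  if (length(msg)) msg else TRUE
})

#' GlobalAlignment: an optimal global (Needleman-Wunsch) alignment
#'
#' @slot alignedA,alignedB Aligned strings with `-` gap characters; equal
#'   length, and removing gaps recovers the input sequences.
#' @slot score Optimal affine-gap alignment score (a gap of length k costs
#'   `gapOpen + k * gapExtend`).
#' @slot identity Fraction of identical columns over all alignment columns
#'   (gap columns included in the denominator).
#' @export
setClass("GlobalAlignment", representation(
  alignedA = "character", alignedB = "character",
  score = "numeric", identity = "numeric"
))

#' ProfileAlignment: a local alignment of a query against one PSSM
#'
#' @slot queryId,pssmId,foldId Identifiers.
#' @slot qstart,qend,pstart,pend 1-based inclusive alignment intervals on the
#'   query and on the PSSM.
#' @slot pairs Integer matrix with columns `qpos`, `ppos`: the aligned
#'   (query position, PSSM position) pairs, strictly increasing in both.
#' @slot score Raw local alignment score.
#' @slot evalue Karlin-Altschul E-value assigned to the score.
#' @slot coverage `(pend - pstart + 1) / PSSM length`, in (0, 1].
#' @export
setClass("ProfileAlignment", representation(
  queryId = "character", pssmId = "character", foldId = "character",
  qstart = "integer", qend = "integer", pstart = "integer", pend = "integer",
  pairs = "matrix", score = "numeric", evalue = "numeric", coverage = "numeric"
))

setValidity("ProfileAlignment", function(object) {
  msg <- character(0)
  if (object@coverage <= 0 || object@coverage > 1)
    msg <- c(msg, "coverage must be in (0, 1]")
  qp <- object@pairs[, 1L]; pp <- object@pairs[, 2L]
  if (length(qp) > 1L && (any(diff(qp) <= 0L) || any(diff(pp) <= 0L)))
    msg <- c(msg, "aligned pairs must be strictly increasing in both coordinates")
  if (length(msg)) msg else TRUE
})

#' ScanThresholds: E-value and coverage filters for library scans
#'
#' Two presets mirror the method's standard settings: `"strict"` keeps
#' statistically significant alignments (E <= 0.01, no coverage requirement)
#' and `"permissive"` admits any E-value (up to 1e10) but requires the
#' alignment to span at least 80% of the PSSM.
#'
#' @slot maxEvalue Maximum E-value retained.
#' @slot minCoverage Minimum PSSM coverage retained.
#' @export
setClass("ScanThresholds", representation(
  maxEvalue = "numeric", minCoverage = "numeric"
))

#' @param preset `"strict"` (E <= 0.01, coverage >= 0) or `"permissive"`
#'   (E <= 1e10, coverage >= 0.80); ignored when both numeric thresholds are
#'   supplied.
#' @param maxEvalue,minCoverage Explicit thresholds overriding the preset.
#' @return A [ScanThresholds-class] object.
#' @rdname ScanThresholds-class
#' @export
#' @examples
#' scanThresholds("strict")
#' scanThresholds(maxEvalue = 1, minCoverage = 0.5)
scanThresholds <- function(preset = c("strict", "permissive"),
                           maxEvalue = NULL, minCoverage = NULL) {
  if (is.null(maxEvalue) || is.null(minCoverage)) {
    preset <- match.arg(preset)
    def <- switch(preset,
                  strict = c(0.01, 0.0),
                  permissive = c(1e10, 0.80))
    if (is.null(maxEvalue)) maxEvalue <- def[1L]
    if (is.null(minCoverage)) minCoverage <- def[2L]
  }
  stopifnot(maxEvalue > 0, minCoverage >= 0, minCoverage <= 1)
  new("ScanThresholds", maxEvalue = maxEvalue, minCoverage = minCoverage)
}

#' Karlin-Altschul parameters for E-value assignment
#'
#' E-values for local profile alignment scores are computed as
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' The default constants are the BLAST gapped BLOSUM62 constants re-expressed
#' on the bit scale of this package's PSSM scores (lambda = 0.534 nats per
#' bit, i.e. 2 x 0.267, which is the published constant per half-bit;
#' K = 0.041). Run [calibrateParams()] for PSSM-specific statistics.
#'
#' @slot lambda Scale parameter (nats per score unit), positive.
#' @slot K Karlin-Altschul K, positive.
#' @slot m Effective query length.
#' @slot n Effective database (profile) length.
#' @export
setClass("KAParams", representation(
  lambda = "numeric", K = "numeric", m = "numeric", n = "numeric"
))

setValidity("KAParams", function(object) {
  if (object@lambda <= 0 || object@K <= 0)
    "lambda and K must be positive" else TRUE
})

#' @param lambda,K Karlin-Altschul constants.
#' @param m,n Effective query and database lengths.
#' @return A [KAParams-class] object.
#' @rdname KAParams-class
#' @export
#' @examples
#' kaParams(m = 100, n = 1e4)
kaParams <- function(lambda = 0.534, K = 0.041, m = 1, n = 1) {
  new("KAParams", lambda = lambda, K = K, m = as.numeric(m), n = as.numeric(n))
}

#' RankedPairTable: labelled all-against-all similarity pairs
#'
#' Holds every unordered pair of queries with its structural similarity score
#' and a same-fold (positive) / different-fold (negative) truth label; the
#' input to ROC and top-k evaluation.
#'
#' @slot pairs data.frame with columns `a`, `b` (ids, a < b), `score`,
#'   `sameFold` (logical).
#' @slot ids All query ids in the table.
#' @export
setClass("RankedPairTable", representation(pairs = "data.frame", ids = "character"))

#' ROCCurve: receiver operating characteristic of a ranked pair table
#'
#' @slot points data.frame with columns `threshold`, `fpr`, `sensitivity`,
#'   swept over all score thresholds (pairs scoring at or above a threshold
#'   are called positive).
#' @slot auc Trapezoidal area under the curve, in `[0, 1]`.
#' @export
setClass("ROCCurve", representation(points = "data.frame", auc = "numeric"))

#' SyntheticBenchmark: a self-contained fold-recognition benchmark world
#'
#' Generated fold families (ancestor-derived seed and homolog sets at a
#' controlled pairwise identity) plus held-out labelled queries.
#'
#' @slot spec The generating [syntheticFoldSpec()] list.
#' @slot seedSets Per fold: a list of seed sets, each
#'   `list(seed = <named character>, homologs = <named character vector>)`.
#' @slot queries Named character vector of query sequences.
#' @slot truth data.frame with columns `query`, `fold`.
#' @export
setClass("SyntheticBenchmark", representation(
  spec = "list", seedSets = "list", queries = "character", truth = "data.frame"
))

## ---- show methods ----------------------------------------------------------

setMethod("show", "PSSM", function(object) {
  cat("PSSM", object@id, "(fold", object@fold, ")",
      nchar(object@refseq), "positions x 20 residues\n")
})

setMethod("show", "FoldLibrary", function(object) {
  cat("FoldLibrary", object@fold, "with", length(object@pssms), "PSSM(s)\n")
})

setMethod("show", "LibraryCollection", function(object) {
  cat("LibraryCollection with", length(object@libraries),
      "fold axes:", paste(foldIds(object), collapse = ", "), "\n")
})

setMethod("show", "StructuralProfile", function(object) {
  cat("StructuralProfile for", object@queryId, "over",
      length(object@folds), "folds\n")
  print(setNames(object@scores, object@folds))
})

setMethod("show", "ProfileAlignment", function(object) {
  cat(sprintf("ProfileAlignment %s vs %s (fold %s): q[%d-%d] p[%d-%d] S=%.2f E=%.3g cov=%.2f\n",
              object@queryId, object@pssmId, object@foldId,
              object@qstart, object@qend, object@pstart, object@pend,
              object@score, object@evalue, object@coverage))
})

setMethod("show", "GlobalAlignment", function(object) {
  cat(sprintf("GlobalAlignment score=%.1f identity=%.3f\n%s\n%s\n",
              object@score, object@identity, object@alignedA, object@alignedB))
})

setMethod("show", "SyntheticBenchmark", function(object) {
  cat("SyntheticBenchmark:", length(object@seedSets), "folds,",
      length(object@queries), "labelled queries\n")
})

## ---- accessors -------------------------------------------------------------

#' Accessors for the core fold-recognition containers
#'
#' @param x A [PSSM-class], [FoldLibrary-class], [LibraryCollection-class] or
#'   [StructuralProfile-class] object, as appropriate.
#' @return `pssmId`/`foldId`/`queryId` return single identifiers; `foldIds`
#'   the fold axis order of a collection; `refSequence` the reference residue
#'   string; `pssmScores` the L x 20 score matrix; `pssms`/`libraries` the
#'   member lists; `profileScores` the named fold-specific score vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pssmId", function(x) standardGeneric("pssmId"))
#' @rdname accessors
#' @export
setMethod("pssmId", "PSSM", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("foldId", function(x) standardGeneric("foldId"))
#' @rdname accessors
#' @export
setMethod("foldId", "PSSM", function(x) x@fold)
#' @rdname accessors
#' @export
setMethod("foldId", "FoldLibrary", function(x) x@fold)

#' @rdname accessors
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))
#' @rdname accessors
#' @export
setMethod("refSequence", "PSSM", function(x) x@refseq)

#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))
#' @rdname accessors
#' @export
setMethod("pssmScores", "PSSM", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("pssms", function(x) standardGeneric("pssms"))
#' @rdname accessors
#' @export
setMethod("pssms", "FoldLibrary", function(x) x@pssms)

#' @rdname accessors
#' @export
setGeneric("libraries", function(x) standardGeneric("libraries"))
#' @rdname accessors
#' @export
setMethod("libraries", "LibraryCollection", function(x) x@libraries)

#' @rdname accessors
#' @export
setGeneric("foldIds", function(x) standardGeneric("foldIds"))
#' @rdname accessors
#' @export
setMethod("foldIds", "LibraryCollection", function(x)
  vapply(x@libraries, function(l) l@fold, character(1)))

#' @rdname accessors
#' @export
setGeneric("queryId", function(x) standardGeneric("queryId"))
#' @rdname accessors
#' @export
setMethod("queryId", "StructuralProfile", function(x) x@queryId)

#' @rdname accessors
#' @export
setGeneric("profileScores", function(x) standardGeneric("profileScores"))
#' @rdname accessors
#' @export
setMethod("profileScores", "StructuralProfile", function(x)
  setNames(x@scores, x@folds))
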