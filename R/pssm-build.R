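#' @include align.R
NULL

#' Remove candidates nearly identical to a reference set
#'
#' Drops every candidate whose global percent identity ([percentIdentity()],
#' Needleman-Wunsch) to ANY reference is at or above `threshold`. Used when
#' assembling fold libraries to discard database hits that are effectively
#' the query itself.
#'
#' @param candidates,references Sequence sets ([Biostrings::AAStringSet] or
#'   named character).
#' @param threshold Inclusive identity cutoff in (0, 1]; default 0.90
#'   (candidates with >= 90% identity are removed).
#' @param matrix,gapOpen,gapExtend Alignment settings for the identity
#'   computation.
#' @return The surviving candidates, same container type as the input.
#' @export
filterNearIdentical <- function(candidates, references, threshold = 0.90,
                                matrix = loadSubstitutionMatrix(),
                                gapOpen = 10, gapExtend = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  refs <- if (length(references)) .asSeqs(references) else character(0)
  if (length(refs) == 0L) {
    warning("empty reference set: returning candidates unchanged")
    return(candidates)
  }
  cand <- .asSeqs(candidates)
  keep <- vapply(seq_along(cand), function(i) {
    for (r in refs) {
      if (percentIdentity(cand[[i]], r, matrix, gapOpen, gapExtend) >= threshold)
        return(FALSE)
    }
    TRUE
  }, logical(1))
  candidates[keep]
}

#' Remove redundant sequences by a greedy identity sweep
#'
#' Greedy keep-first sweep in input order: a sequence is dropped when its
#' global percent identity to any already-kept sequence is at or above
#' `threshold`; output order is preserved. Guarantees all pairwise identities
#' among the survivors are below `threshold`.
#'
#' @param sequences Sequence set.
#' @param threshold Inclusive identity cutoff in (0, 1]; default 0.40.
#' @inheritParams filterNearIdentical
#' @return The surviving sequences, same container type as the input.
#' @export
filterRedundant <- function(sequences, threshold = 0.40,
                            matrix = loadSubstitutionMatrix(),
                            gapOpen = 10, gapExtend = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  seqs <- .asSeqs(sequences)
  kept <- integer(0)
  for (i in seq_along(seqs)) {
    redundant <- FALSE
    for (k in kept) {
      if (percentIdentity(seqs[[i]], seqs[[k]], matrix, gapOpen,
                          gapExtend) >= threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  sequences[kept]
}

# Henikoff position-based sequence weights for an aligned residue matrix
# (rows = sequences, cols = positions, "-" marks an unaligned position).
# Each column distributes 1/(r * s) to every sequence holding one of its r
# distinct residues, s being that residue's count; gaps contribute nothing.
.henikoffWeights <- function(alnmat) {
  n <- nrow(alnmat)
  w <- numeric(n)
  for (j in seq_len(ncol(alnmat))) {
    res <- alnmat[, j]
    obs <- which(res %in% aaAlphabet())
    if (!length(obs)) next
    tab <- table(res[obs])
    r <- length(tab)
    w[obs] <- w[obs] + 1 / (r * as.numeric(tab[res[obs]]))
  }
  if (sum(w) == 0) rep(1 / n, n) else w / sum(w)
}

# Position-wise observed residue frequencies and the per-column effective
# observation count alpha (number of distinct residues - 1, PSI-BLAST style).
.columnCounts <- function(alnmat, weights) {
  aa <- aaAlphabet()
  L <- ncol(alnmat)
  f <- matrix(0, nrow = L, ncol = 20, dimnames = list(NULL, aa))
  alpha <- numeric(L)
  for (j in seq_len(L)) {
    res <- alnmat[, j]
    obs <- which(res %in% aa)
    if (!length(obs)) next
    wj <- weights[obs] / sum(weights[obs])
    for (k in seq_along(obs)) f[j, res[obs[k]]] <- f[j, res[obs[k]]] + wj[k]
    alpha[j] <- length(unique(res[obs])) - 1
  }
  list(f = f, alpha = alpha)
}

# log2-odds scores from observed column frequencies: mix the observations
# with matrix-derived (Tatusov-style) pseudocounts, weight beta relative to
# the effective observation count alpha, then score against the
# matrix-implied background.
.pssmScoresFromFrequencies <- function(f, alpha, beta = 10,
                                       matrix = loadSubstitutionMatrix()) {
  bg <- .matrixBackground(matrix)
  g <- f %*% bg$cond                       # pseudocount frequencies
  q <- (alpha * f + beta * g) / (alpha + beta)
  sc <- log2(sweep(q, 2, bg$p, "/"))
  round(sc, 2)
}

#' Build a PSSM from a seed sequence and collected homologs
#'
#' Each homolog is globally aligned to the seed ([globalAlign()]) to place
#' its residues on seed columns; per-column observed counts are weighted by
#' Henikoff position-based sequence weights; matrix-derived (Tatusov-style)
#' pseudocounts with weight `beta` relative to the per-column effective
#' observation count are mixed in; and scores are log2 odds against the
#' background implied by the substitution matrix, rounded to 2 decimals.
#' Columns where the seed residue is not one of the 20 standard letters
#' score 0 everywhere. Deterministic.
#'
#' With no homologs the construction reduces to the single-sequence limit:
#' each column's scores are an affine transform of the substitution-matrix
#' row of the seed residue.
#'
#' @param seed Seed sequence (single-entry container); becomes the PSSM
#'   reference.
#' @param homologs Homologous sequences (possibly empty).
#' @param matrix Substitution matrix.
#' @param beta Pseudocount weight (default 10).
#' @param id PSSM id (defaults to the seed id).
#' @param fold Fold label to record.
#' @param gapOpen,gapExtend Gap penalties for homolog placement.
#' @return A [PSSM-class].
#' @export
buildPSSM <- function(seed, homologs = NULL,
                      matrix = loadSubstitutionMatrix(), beta = 10,
                      id = NULL, fold = NA_character_,
                      gapOpen = 10, gapExtend = 0.5) {
  sseed <- .asSeq1(seed)
  if (nchar(sseed) == 0L) stop("seed sequence must be non-empty")
  if (is.null(id)) id <- .seqIds(seed)[1L]
  L <- nchar(sseed)
  homs <- if (is.null(homologs) || length(homologs) == 0L) character(0)
          else .asSeqs(homologs)

  alnmat <- array("-", dim = c(1L + length(homs), L))
  alnmat[1L, ] <- strsplit(sseed, "")[[1L]]
  for (h in seq_along(homs)) {
    al <- globalAlign(homs[[h]], sseed, matrix, gapOpen, gapExtend)
    ha <- strsplit(al@alignedA, "")[[1L]]
    sa <- strsplit(al@alignedB, "")[[1L]]
    col <- cumsum(sa != "-")
    place <- which(sa != "-" & ha != "-")
    alnmat[h + 1L, col[place]] <- ha[place]
  }

  w <- .henikoffWeights(alnmat)
  cc <- .columnCounts(alnmat, w)
  sc <- .pssmScoresFromFrequencies(cc$f, cc$alpha, beta, matrix)
  seedres <- alnmat[1L, ]
  sc[!(seedres %in% aaAlphabet()), ] <- 0
  PSSM(id = id, refseq = sseed, scores = sc, fold = fold,
       metadata = list(nseq = 1L + length(homs), beta = beta))
}

#' Build a fold-specific PSSM library
#'
#' For each seed set, the homologs are first cleaned by
#' [filterNearIdentical()] against the seed (default cutoff 0.90) and then by
#' [filterRedundant()] (default cutoff 0.40), and a PSSM is built per seed
#' with [buildPSSM()]. Library provenance records sequence counts before and
#' after filtering.
#'
#' @param foldId Fold label for the library.
#' @param seedSets List of seed sets, each a list with elements `seed`
#'   (single sequence) and optionally `homologs` (sequence set).
#' @param matrix Substitution matrix.
#' @param beta Pseudocount weight passed to [buildPSSM()].
#' @param nearIdentical,redundant Identity cutoffs of the two filters.
#' @return A [FoldLibrary-class].
#' @export
buildFoldLibrary <- function(foldId, seedSets,
                             matrix = loadSubstitutionMatrix(), beta = 10,
                             nearIdentical = 0.90, redundant = 0.40) {
  stopifnot(length(seedSets) >= 1L)
  counts <- list()
  ps <- lapply(seedSets, function(ss) {
    seed <- ss$seed
    homs <- ss$homologs
    n0 <- length(homs)
    if (!is.null(homs) && length(homs)) {
      homs <- filterNearIdentical(homs, seed, nearIdentical, matrix)
      homs <- filterRedundant(homs, redundant, matrix)
    }
    sid <- .seqIds(seed)[1L]
    counts[[sid]] <<- c(before = n0, after = length(homs))
    buildPSSM(seed, homs, matrix, beta, id = sid, fold = foldId)
  })
  new("FoldLibrary", fold = as.character(foldId), pssms = ps,
      provenance = list(homologCounts = counts))
}

#' Compile fold libraries into an ordered collection
#'
#' Fixes the profile axis order to the input library order. When `dir` is
#' given, the collection is also serialized (PSSM files plus manifest) via
#' [writeCollectionManifest()]; the manifest line order is the axis order.
#'
#' @param libs List of [FoldLibrary-class] objects with unique fold ids.
#' @param dir Optional output directory.
#' @return A [LibraryCollection-class].
#' @export
compileCollection <- function(libs, dir = NULL) {
  if (is(libs, "FoldLibrary")) libs <- list(libs)
  ids <- vapply(libs, foldId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate fold id: ", ids[duplicated(ids)][1L])
  coll <- new("LibraryCollection", libraries = libs)
  if (!is.null(dir)) writeCollectionManifest(coll, dir)
  coll
}
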