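#' @include scoring.R
NULL

# deterministic derived seeds for named sub-streams (kept below 2^31)
.deriveSeed <- function(seed, i) {
  as.integer((as.double(seed %% 100000L) * 20011 + as.double(i) * 7919) %%
               2147483563) + 1L
}

.withSeed <- function(seed, code) {
  withr::with_seed(seed, code,
                   .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion",
                   .rng_sample_kind = "Rejection")
}

#' Specification of a synthetic fold-recognition benchmark
#'
#' Describes a benchmark world of `nFolds` independent fold families. Each
#' family descends from one random ancestor; its library sequences (seeds and
#' homologs) and held-out queries are mutants whose Needleman-Wunsch identity
#' to the ancestor is controlled to lie in `identityBand` -- the twilight-zone
#' regime the method targets. Sequence lengths are drawn from a truncated
#' normal with the given mean and spread (defaults mimic a twilight-zone
#' benchmark set averaging ~135 +/- 89 residues).
#'
#' @param nFolds Number of fold families.
#' @param seedsPerFold PSSM seeds per fold.
#' @param homologsPerSeed Homologs collected per seed.
#' @param queriesPerFold Held-out labelled queries per fold.
#' @param lengthMean,lengthSd Ancestor length distribution; lengths are
#'   truncated below at 40 residues.
#' @param identityBand Target pairwise identity band (fractions), default
#'   `c(0.20, 0.30)`.
#' @param indelRate Per-residue indel rate applied during mutation.
#' @param seed Integer master seed; one seed drives all generator streams.
#' @return A validated list of class `"syntheticFoldSpec"`.
#' @export
syntheticFoldSpec <- function(nFolds = 8, seedsPerFold = 2,
                              homologsPerSeed = 15, queriesPerFold = 5,
                              lengthMean = 135, lengthSd = 90,
                              identityBand = c(0.20, 0.30),
                              indelRate = 0.02, seed = 1L) {
  stopifnot(nFolds >= 1, seedsPerFold >= 1, homologsPerSeed >= 0,
            queriesPerFold >= 1, lengthMean >= 1,
            length(identityBand) == 2L,
            identityBand[1] > 0, identityBand[2] < 1,
            identityBand[1] <= identityBand[2],
            indelRate >= 0, indelRate < 1)
  structure(list(nFolds = nFolds, seedsPerFold = seedsPerFold,
                 homologsPerSeed = homologsPerSeed,
                 queriesPerFold = queriesPerFold,
                 lengthMean = lengthMean, lengthSd = lengthSd,
                 identityBand = identityBand, indelRate = indelRate,
                 seed = as.integer(seed)),
            class = "syntheticFoldSpec")
}

#' Draw a random ancestor sequence from background frequencies
#'
#' @param length Sequence length (>= 1).
#' @param background Residue frequencies over [aaAlphabet()]; defaults to
#'   the substitution-matrix-implied background.
#' @param seed Integer seed (deterministic output).
#' @param id Name given to the sequence.
#' @return Named character vector of length 1.
#' @export
generateAncestor <- function(length, background = NULL, seed = 1L,
                             id = "ancestor") {
  stopifnot(length >= 1)
  if (is.null(background)) background <- .matrixBackground()$p
  s <- .withSeed(seed, paste(sample(aaAlphabet(), length, replace = TRUE,
                                    prob = background), collapse = ""))
  setNames(s, id)
}

#' Mutate a sequence to a target global identity
#'
#' Applies an indel process (rate `indelRate` per residue; indels of length
#' 1-3, insertions drawn from the background) followed by iterative point
#' substitution until the Needleman-Wunsch identity ([percentIdentity()],
#' measured with the same settings used throughout the package) to the
#' ancestor falls within `target +/- tol`. Substitution sites are drawn from
#' `mutable` ancestor positions (all by default), preferring sites still
#' matching the ancestor; replacement residues mix matrix-derived
#' (conservative) exchange probabilities with a uniform draw, so positively
#' scoring substitution structure survives in the mutants. Deterministic
#' given `seed`.
#'
#' @param ancestor Single sequence.
#' @param target Target identity in (0, 1].
#' @param indelRate Per-residue indel probability.
#' @param matrix Substitution matrix (drives conservative exchanges and the
#'   identity measurement).
#' @param seed Integer seed.
#' @param mutable Optional integer vector of ancestor positions open to
#'   substitution; positions outside it form a conserved core.
#' @param tol Acceptance half-width around `target` (default 0.03).
#' @param maxIter Maximum substitution batches before giving up.
#' @param conservativeWeight Mixing weight of the matrix-derived exchange
#'   distribution versus uniform (default 0.5).
#' @param id Name of the returned mutant.
#' @return Named character vector of length 1.
#' @export
mutateToIdentity <- function(ancestor, target, indelRate = 0.02,
                             matrix = loadSubstitutionMatrix(), seed = 1L,
                             mutable = NULL, tol = 0.03, maxIter = 200L,
                             conservativeWeight = 0.5, id = "mutant") {
  stopifnot(target > 0, target <= 1)
  anc <- .asSeq1(ancestor)
  aa <- aaAlphabet()
  bg <- .matrixBackground(matrix)
  L0 <- nchar(anc)
  if (is.null(mutable)) mutable <- seq_len(L0)

  out <- .withSeed(seed, {
    cur <- strsplit(anc, "")[[1L]]
    orig <- seq_len(L0)                  # ancestor position of each residue
    done <- FALSE

    measure <- function() percentIdentity(paste(cur, collapse = ""), anc,
                                          matrix)
    if (abs(measure() - target) <= tol) {
      done <- TRUE
    } else {
      # indel phase: Poisson number of events, length 1-3 each; an event
      # that would already drop identity below the band is rolled back
      nev <- stats::rpois(1L, indelRate * L0)
      for (e in seq_len(nev)) {
        prevCur <- cur; prevOrig <- orig
        len <- sample(1:3, 1L)
        if (stats::runif(1) < 0.5 && length(cur) > len + 5L) {   # deletion
          at <- sample(length(cur) - len, 1L)
          keep <- setdiff(seq_along(cur), at:(at + len - 1L))
          cur <- cur[keep]; orig <- orig[keep]
        } else {                                                  # insertion
          at <- sample(length(cur), 1L)
          ins <- sample(aa, len, replace = TRUE, prob = bg$p)
          cur <- append(cur, ins, after = at)
          orig <- append(orig, rep(NA_integer_, len), after = at)
        }
        if (measure() < target - tol) { cur <- prevCur; orig <- prevOrig }
      }
    }

    # substitution phase: batches sized by the remaining identity excess;
    # a batch that jumps over the band (possible on short sequences, where
    # one substitution can restructure the optimal alignment) is rolled
    # back and retried smaller with freshly drawn sites
    iter <- 0L
    batchCap <- Inf
    while (!done) {
      iter <- iter + 1L
      if (iter > maxIter)
        stop("target identity unreachable within ", maxIter,
             " substitution batches")
      idn <- measure()
      if (abs(idn - target) <= tol) {
        done <- TRUE
        break
      }
      if (idn < target - tol)
        stop("target identity unreachable: identity ", round(idn, 3),
             " already below ", target, " - ", tol)
      sites <- which(!is.na(orig) & orig %in% mutable)
      fresh <- sites[cur[sites] == substring(anc, orig[sites], orig[sites])]
      pool <- if (length(fresh)) fresh else sites
      if (!length(pool))
        stop("target identity unreachable: no mutable positions left above ",
             "identity ", round(idn, 3))
      batch <- max(1L, min(length(pool), batchCap,
                           round(length(cur) * (idn - target) / 2)))
      prevCur <- cur
      for (pos in sample(pool, batch)) {
        a <- cur[pos]
        pr <- if (a %in% aa)
          conservativeWeight * bg$cond[a, ] + (1 - conservativeWeight) / 19
        else rep(1 / 20, 20)
        if (a %in% aa) pr[a] <- 0
        cur[pos] <- sample(aa, 1L, prob = pr)
      }
      if (measure() < target - tol) {
        cur <- prevCur                       # overshot the band: retry
        batchCap <- max(1L, batch %/% 2L)
      }
    }
    paste(cur, collapse = "")
  })
  setNames(out, id)
}

#' Generate a synthetic fold-recognition benchmark
#'
#' For each fold: one random ancestor is drawn; a conserved core (fraction
#' equal to the lower edge of the identity band) is fixed; seeds, homologs
#' and held-out queries are independent mutants of the ancestor, each dialled
#' by [mutateToIdentity()] into the identity band with substitutions confined
#' to the non-core positions. Sharing the mutable-site set keeps pairwise
#' identities between family members inside the band while different folds
#' stay at background identity. The same master seed reproduces the benchmark
#' byte-identically.
#'
#' @param spec A [syntheticFoldSpec()].
#' @param dir Optional directory; when given, writes per-fold seed and
#'   homolog FASTA files, a query FASTA and a `truth.tsv`.
#' @return A [SyntheticBenchmark-class].
#' @export
makeBenchmark <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "syntheticFoldSpec"))
  submat <- loadSubstitutionMatrix()
  band <- spec$identityBand
  folds <- sprintf("f%02d", seq_len(spec$nFolds))
  seedSets <- list()
  queries <- character(0)
  truth <- data.frame(query = character(0), fold = character(0),
                      stringsAsFactors = FALSE)
  ctr <- 0L
  nextSeed <- function() {
    ctr <<- ctr + 1L
    .deriveSeed(spec$seed, ctr)
  }

  for (b in seq_along(folds)) {
    fid <- folds[b]
    L <- .withSeed(nextSeed(),
                   max(40L, round(rnorm(1, spec$lengthMean, spec$lengthSd))))
    anc <- generateAncestor(L, seed = nextSeed(), id = paste0(fid, "_anc"))
    core <- .withSeed(nextSeed(),
                      sort(sample(L, round(band[1] * L))))
    mutable <- setdiff(seq_len(L), core)
    mutant <- function(mid) {
      t <- .withSeed(nextSeed(), runif(1, band[1], band[2]))
      mutateToIdentity(anc, target = t, indelRate = spec$indelRate,
                       matrix = submat, seed = nextSeed(),
                       mutable = mutable, id = mid)
    }
    sets <- lapply(seq_len(spec$seedsPerFold), function(s) {
      seedRec <- mutant(sprintf("%s_s%d", fid, s))
      homs <- unlist(lapply(seq_len(spec$homologsPerSeed), function(h)
        mutant(sprintf("%s_s%d_h%02d", fid, s, h))))
      list(seed = seedRec, homologs = if (is.null(homs)) character(0) else homs)
    })
    seedSets[[fid]] <- sets
    qs <- unlist(lapply(seq_len(spec$queriesPerFold), function(q)
      mutant(sprintf("%s_q%d", fid, q))))
    queries <- c(queries, qs)
    truth <- rbind(truth, data.frame(query = names(qs), fold = fid,
                                     stringsAsFactors = FALSE))
  }

  bm <- new("SyntheticBenchmark", spec = unclass(spec), seedSets = seedSets,
            queries = queries, truth = truth)
  if (!is.null(dir)) writeBenchmark(bm, dir)
  bm
}

#' Write a synthetic benchmark to disk
#'
#' Emits, per fold, `<fold>/seeds.fasta` and `<fold>/homologs/<seed>.fasta`,
#' plus a top-level `queries.fasta` and `truth.tsv` -- a layout ready for
#' [buildFoldLibrary()] per fold. Output is byte-identical across runs for
#' the same benchmark.
#'
#' @param bm A [SyntheticBenchmark-class].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
writeBenchmark <- function(bm, dir) {
  stopifnot(is(bm, "SyntheticBenchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fid in names(bm@seedSets)) {
    fdir <- file.path(dir, fid)
    dir.create(file.path(fdir, "homologs"), showWarnings = FALSE,
               recursive = TRUE)
    sets <- bm@seedSets[[fid]]
    writeFasta(unlist(lapply(sets, `[[`, "seed")),
               file.path(fdir, "seeds.fasta"))
    for (s in sets)
      writeFasta(s$homologs,
                 file.path(fdir, "homologs", paste0(names(s$seed), ".fasta")))
  }
  writeFasta(bm@queries, file.path(dir, "queries.fasta"))
  write.table(bm@truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Build the fold libraries of a synthetic benchmark
#'
#' Convenience wrapper running [buildFoldLibrary()] on every fold of the
#' benchmark and compiling the result into an ordered collection.
#'
#' @param bm A [SyntheticBenchmark-class].
#' @param matrix Substitution matrix.
#' @param beta Pseudocount weight.
#' @return A [LibraryCollection-class] with one axis per benchmark fold.
#' @export
buildBenchmarkCollection <- function(bm, matrix = loadSubstitutionMatrix(),
                                     beta = 10) {
  stopifnot(is(bm, "SyntheticBenchmark"))
  libs <- lapply(names(bm@seedSets), function(fid)
    buildFoldLibrary(fid, bm@seedSets[[fid]], matrix, beta))
  compileCollection(libs)
}
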