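#' @include AllClasses.R
NULL

#' Load a substitution matrix
#'
#' Loads the built-in BLOSUM62 (identical entry-for-entry to the NCBI
#' distribution) or parses an NCBI-format matrix file. The returned matrix is
#' a plain integer matrix with residue dimnames and a `"name"` attribute.
#'
#' Ambiguity handling: if the file carries no `X` row, `X` is added scoring
#' -1 against everything (common BLAST behaviour); rows present in the file
#' (B, Z, X, `*`) are kept as distributed.
#'
#' @param name_or_path `"BLOSUM62"` or the path to an NCBI-format matrix file
#'   (comment lines starting with `#`, a header row of residue letters, then
#'   one labelled score row per residue).
#' @return Symmetric numeric matrix of pair scores with residue dimnames.
#' @export
#' @examples
#' m <- loadSubstitutionMatrix()
#' m["W", "W"]   # 11
#' m["L", "D"]   # -4
loadSubstitutionMatrix <- function(name_or_path = "BLOSUM62") {
  key <- paste0("submat::", name_or_path)
  if (!is.null(.fsr_cache[[key]])) return(.fsr_cache[[key]])
  if (identical(name_or_path, "BLOSUM62")) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "FoldScanR")
    name <- "BLOSUM62"
  } else {
    path <- name_or_path
    name <- basename(name_or_path)
    if (!file.exists(path))
      stop("unknown matrix name or missing file: ", name_or_path)
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("substitution matrix format error: no data rows in ", path)
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  bad <- which(vapply(rows, length, integer(1)) != length(cols) + 1L)
  if (length(bad))
    stop("substitution matrix format error at data row ", bad[1L], " of ", path)
  rn <- vapply(rows, `[`, character(1), 1L)
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  dimnames(m) <- list(rn, cols)
  if (!isSymmetric(unname(m)))
    stop("substitution matrix format error: matrix in ", path, " is not symmetric")
  if (!all(aaAlphabet() %in% rn))
    stop("substitution matrix format error: missing standard residues in ", path)
  if (!("X" %in% rn)) {
    m <- rbind(cbind(m, X = -1), X = c(rep(-1, ncol(m)), -1))
  }
  attr(m, "name") <- name
  .fsr_cache[[key]] <- m
  m
}

# Residue pair score with 'X' fallback for residues absent from the matrix.
.pairScore <- function(matrix, a, b) {
  rn <- rownames(matrix)
  a[!(a %in% rn)] <- "X"
  b[!(b %in% rn)] <- "X"
  matrix[cbind(a, b)]
}

# Robinson & Robinson (1991) amino-acid frequencies, the standard BLAST
# protein background, in aaAlphabet() order.
.robinsonFrequencies <- function() {
  setNames(c(0.07805, 0.05129, 0.04487, 0.05364, 0.01925, 0.04264, 0.06295,
             0.07377, 0.02199, 0.05142, 0.09019, 0.05744, 0.02243, 0.03856,
             0.05203, 0.07120, 0.05841, 0.01330, 0.03216, 0.06441),
           aaAlphabet())
}

# Background and pseudocount model implied by a substitution matrix.
#
# BLOSUM-type scores are s(a,b) = 2*log2(q_ab / (p_a p_b)) up to rounding.
# Seeding with the Robinson-Robinson frequencies, the implied pair
# frequencies Q ∝ p0_a p0_b 2^(s/2) are normalised to sum 1 and give
#   * p: the marginals of Q -- the background residue frequencies used in
#     PSSM log-odds, and
#   * cond[a, r] = Q[a, r] / p_a: the conditional substitution probabilities
#     used for Tatusov-style pseudocounts.
# Because Q is symmetric with marginals p, sum_a p_a cond[a, r] = p_r holds
# exactly, making the pseudocount model self-consistent: a column whose
# observed frequencies equal the background scores exactly zero.
.matrixBackground <- function(matrix = loadSubstitutionMatrix()) {
  key <- paste0("bg::", attr(matrix, "name"))
  if (!is.null(.fsr_cache[[key]])) return(.fsr_cache[[key]])
  aa <- aaAlphabet()
  s <- matrix[aa, aa]
  p0 <- .robinsonFrequencies()
  Q <- outer(p0, p0) * 2^(s / 2)
  Q <- Q / sum(Q)
  p <- rowSums(Q)
  names(p) <- aa
  cond <- Q / p            # rows: source residue a, cols: substituted r
  dimnames(cond) <- list(aa, aa)
  out <- list(p = p, cond = cond)
  .fsr_cache[[key]] <- out
  out
}
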