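#' @include AllClasses.R
NULL

## Plain-text PSSM format (this package's own, versioned):
##   # FoldScanR PSSM v1
##   id      <id>
##   fold    <fold>
##   length  <L>
##   nseq    <n>        (construction metadata; optional)
##   beta    <w>        (construction metadata; optional)
##   residues A R N D C Q E G H I L K M F P S T W Y V
##   <pos> <ref residue> <20 scores, 2 decimals>
## Positions are 1-based and scores are serialized at fixed 2-decimal
## precision, matching the precision PSSM objects carry in memory, so the
## write -> read round trip is exact.

#' Write a PSSM to its text serialization
#'
#' @param pssm A [PSSM-class] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [readPSSM()]
#' @export
writePSSM <- function(pssm, path) {
  stopifnot(is(pssm, "PSSM"))
  validObject(pssm)
  con <- file(path, open = "wt")
  on.exit(close(con))
  L <- nchar(pssm@refseq)
  writeLines(c(
    "# FoldScanR PSSM v1",
    paste0("id\t", pssm@id),
    paste0("fold\t", pssm@fold),
    paste0("length\t", L),
    paste0("nseq\t", if (is.null(pssm@metadata$nseq)) NA else pssm@metadata$nseq),
    paste0("beta\t", if (is.null(pssm@metadata$beta)) NA else pssm@metadata$beta),
    paste0("residues\t", paste(aaAlphabet(), collapse = " "))
  ), con)
  res <- strsplit(pssm@refseq, "")[[1L]]
  for (j in seq_len(L)) {
    writeLines(paste(j, res[j],
                     paste(sprintf("%.2f", pssm@scores[j, ]), collapse = " "),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a PSSM from its text serialization
#'
#' @param path Path written by [writePSSM()].
#' @return A [PSSM-class] object.
#' @export
readPSSM <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[a-z]+\t", lines[i])) {
    kv <- strsplit(lines[i], "\t")[[1L]]
    fields[[kv[1L]]] <- kv[2L]
    i <- i + 1L
  }
  for (need in c("id", "length", "residues"))
    if (is.null(fields[[need]]))
      stop("PSSM format error in ", path, ": missing header line '", need, "'")
  if (!identical(strsplit(fields$residues, " ")[[1L]], aaAlphabet()))
    stop("PSSM format error in ", path, ": unexpected residue order")
  L <- as.integer(fields$length)
  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  if (length(body) != L)
    stop("PSSM format error in ", path, ": ", length(body),
         " score rows but declared length ", L)
  parts <- strsplit(body, "\t")
  res <- vapply(parts, `[`, character(1), 2L)
  scores <- do.call(rbind, lapply(parts, function(p)
    as.numeric(strsplit(p[3L], " ")[[1L]])))
  if (ncol(scores) != 20L || anyNA(scores))
    stop("PSSM format error in ", path, ": malformed score rows")
  meta <- list()
  if (!is.null(fields$nseq) && fields$nseq != "NA")
    meta$nseq <- as.integer(fields$nseq)
  if (!is.null(fields$beta) && fields$beta != "NA")
    meta$beta <- as.numeric(fields$beta)
  PSSM(id = fields$id, refseq = paste(res, collapse = ""), scores = scores,
       fold = if (is.null(fields$fold)) NA_character_ else fields$fold,
       metadata = meta)
}

## Collection manifest: one line per fold, tab-separated,
##   <fold id> <TAB> <relative pssm path> [<TAB> more paths ...]
## Line order defines the profile axis order and is the single source of
## axis-order truth.

#' Write a library collection (PSSM files plus manifest)
#'
#' Writes every member PSSM under `<dir>/<fold>/<pssm id>.pssm` and a
#' `manifest.tsv` whose line order fixes the profile axis order.
#'
#' @param collection A [LibraryCollection-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeCollectionManifest <- function(collection, dir) {
  stopifnot(is(collection, "LibraryCollection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  for (lib in collection@libraries) {
    folddir <- file.path(dir, lib@fold)
    dir.create(folddir, showWarnings = FALSE)
    rel <- vapply(lib@pssms, function(p) {
      rp <- file.path(lib@fold, paste0(p@id, ".pssm"))
      writePSSM(p, file.path(dir, rp))
      rp
    }, character(1))
    manifest <- c(manifest, paste(c(lib@fold, rel), collapse = "\t"))
  }
  path <- file.path(dir, "manifest.tsv")
  writeLines(c("# FoldScanR collection manifest v1", manifest), path)
  invisible(path)
}

#' Read a library collection from a manifest
#'
#' @param path Path to a `manifest.tsv` written by
#'   [writeCollectionManifest()] (or hand-edited; reordering its lines
#'   permutes the profile axes identically).
#' @return A [LibraryCollection-class].
#' @export
readCollectionManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  base <- dirname(path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t")
  folds <- vapply(parts, `[`, character(1), 1L)
  if (anyDuplicated(folds))
    stop("manifest error: duplicate fold id \"", folds[duplicated(folds)][1L], "\"")
  libs <- lapply(parts, function(p) {
    fold <- p[1L]; rel <- p[-1L]
    missing <- rel[!file.exists(file.path(base, rel))]
    if (length(missing))
      stop("manifest error: missing PSSM file ", missing[1L])
    ps <- lapply(file.path(base, rel), readPSSM)
    new("FoldLibrary", fold = fold, pssms = ps, provenance = list())
  })
  new("LibraryCollection", libraries = libs)
}
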