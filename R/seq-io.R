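#' @include AllClasses.R
NULL

## Sequence containers: user-facing functions accept either a
## Biostrings::AAStringSet or a named character vector; internally sequences
## are plain uppercase residue strings.

# normalise any accepted sequence container to a named character vector
.asSeqs <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- toupper(x)
  } else if (is(x, "XString")) {
    out <- as.character(x)
    names(out) <- "seq"
  } else {
    stop("sequences must be an AAStringSet or a (named) character vector")
  }
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  toupper(out)
}

# one sequence as a character string
.asSeq1 <- function(x) {
  s <- .asSeqs(x)
  if (length(s) != 1L) stop("expected exactly one sequence")
  s
}

# id = first whitespace-delimited token of the FASTA header
.seqIds <- function(x) {
  nm <- if (is(x, "XStringSet")) names(x) else names(.asSeqs(x))
  sub("\\s.*$", "", nm)
}

#' Read amino-acid sequences from a FASTA file
#'
#' Sequences are uppercased, `*` terminators are stripped, and records with
#' zero residues are rejected. The full header line is kept as the name; the
#' record id is its first whitespace-delimited token.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] with one entry per record.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("FASTA format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(x) == 0L)
    stop("FASTA format error in ", path, ": no records")
  seqs <- toupper(gsub("\\*", "", as.character(x)))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    ids <- sub("\\s.*$", "", names(x)[empty])
    stop("FASTA format error in ", path, ": record \"", ids[1L],
         "\" has no residues")
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- names(x)
  out
}

#' Write amino-acid sequences to a FASTA file
#'
#' Standard FASTA with 60-column line wrapping. An empty input writes an
#' empty file.
#'
#' @param records An [Biostrings::AAStringSet] or named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(records, path) {
  seqs <- if (length(records)) .asSeqs(records) else character(0)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
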