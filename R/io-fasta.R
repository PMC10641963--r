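#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read (soft-masking case is not meaningful to
#' the screen; masking state travels with the annotations instead).  IUPAC
#' ambiguity letters are preserved and record order follows the file.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` (default) validates against IUPAC nucleotide
#'   codes; `"protein"` against amino-acid letters (plus `*` and `X`).
#' @return Named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("FASTA parse error at line 1: file is empty")
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1],
         ": expected '>' header, got: ", lines[nonblank[1]])
  }
  bad <- if (alphabet == "dna") "[^ACGTURYSWKMBDHVNacgturyswkmbdhvn.-]"
  else "[^A-Za-z*.-]"
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (nchar(ln) == 1L) stop("FASTA parse error at line ", i, ": empty header")
    } else if (grepl(bad, ln)) {
      stop("FASTA parse error at line ", i, ": illegal sequence character")
    }
  }
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(1L, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
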