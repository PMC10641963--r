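#' Construct a genomic interval
#'
#' The package's coordinate backbone: a located span on a named sequence,
#' 0-based, half-open (`start` inclusive, `end` exclusive), as in BED.
#'
#' @param seq_id Sequence (chromosome/contig) name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `0 <= start < end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unstranded).
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(seq_id, start, end, strand = "*") {
  stopifnot(is.character(seq_id), length(seq_id) == 1L, nzchar(seq_id))
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Length of a genomic interval
#' @param x A `genomic_interval`.
#' @return Integer width `end - start`.
#' @export
interval_length <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$seq_id, x$start, x$end, x$strand))
  invisible(x)
}

## 0-based half-open -> 1-based inclusive (and back).  Kept as explicit,
## tested helpers so the convention lives in exactly one place.
to_one_based <- function(start0, end0) list(begin = start0 + 1L, end = end0)
to_zero_based <- function(begin1, end1) list(start = begin1 - 1L, end = end1)

#' Reverse complement of a nucleotide string
#'
#' Involution over the full IUPAC alphabet (so `revcomp(revcomp(s)) == s`).
#'
#' @param s A single character string of IUPAC nucleotide letters.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
}

## Shannon entropy (bits/base) of a nucleotide string; used by the
## low-complexity guard on TIR/TSD candidates.
seq_entropy <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  p <- table(ch) / length(ch)
  -sum(p * log2(p))
}

## Translate a DNA string in frame 0 using the standard genetic code.
## Codons containing characters outside ACGT translate to "X"; trailing
## partial codon is ignored.
translate_dna <- function(s) {
  s <- toupper(s)
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  codons <- substring(s, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

## Map a sorted base-count composition to the IUPAC ambiguity letter.
iupac_for_bases <- function(bases) {
  key <- paste0(sort(unique(bases)), collapse = "")
  map <- setNames(names(Biostrings::IUPAC_CODE_MAP),
                  vapply(Biostrings::IUPAC_CODE_MAP, function(x) {
                    paste0(sort(strsplit(x, "")[[1]]), collapse = "")
                  }, character(1)))
  out <- map[[key]]
  if (is.null(out)) "N" else out
}
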