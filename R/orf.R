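#' Find open reading frames in all six frames
#'
#' Deterministic stop-to-stop scan: within each stop-bounded segment of each
#' frame (both strands), the ORF runs from the first ATG to the segment end.
#' Codons containing ambiguity letters translate to `X` and never initiate.
#' Calls shorter than `orf_min_aa` are retained but flagged, so downstream
#' classification — not the finder — decides what counts as an intact
#' transposase ORF.
#'
#' @param element_seq Nucleotide string (the candidate element).
#' @param config A [curation_config()]; only `orf_min_aa` is used.
#' @return `data.frame` sorted by decreasing protein length: `start`, `end`
#'   (0-based half-open on the input sequence, including the terminal stop
#'   codon when present), `frame` (1..3 forward, -1..-3 reverse), `protein`
#'   (no stop symbol), `has_terminal_stop`, `meets_min_aa`.
#' @export
find_orfs <- function(element_seq, config = curation_config()) {
  element_seq <- toupper(element_seq)
  n <- nchar(element_seq)
  if (n < 3L) stop("sequence shorter than one codon")
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") element_seq else revcomp(element_seq)
    for (off in 0:2) {
      ncod <- (n - off) %/% 3L
      if (ncod < 1L) next
      starts <- off + seq(1L, by = 3L, length.out = ncod)
      codons <- substring(s, starts, starts + 2L)
      aa <- unname(Biostrings::GENETIC_CODE[codons])
      aa[is.na(aa)] <- "X"
      stops <- which(aa == "*")
      seg_start <- c(1L, stops + 1L)          # codon index where segments begin
      seg_end <- c(stops - 1L, ncod)          # last coding codon of segment
      seg_term <- c(rep(TRUE, length(stops)), FALSE)
      for (k in seq_along(seg_start)) {
        a <- seg_start[k]; b <- seg_end[k]
        if (a > b) next
        m <- which(codons[a:b] == "ATG")
        if (length(m) == 0L) next
        m0 <- a + m[1] - 1L                   # first ATG codon index
        prot <- paste0(aa[m0:b], collapse = "")
        term <- seg_term[k]
        ## codon-space -> nucleotide span on strand s (1-based)
        nt_from <- off + (m0 - 1L) * 3L + 1L
        nt_to <- off + b * 3L + (if (term) 3L else 0L)
        if (strand == "+") {
          st0 <- nt_from - 1L; en0 <- nt_to
          fr <- off + 1L
        } else {
          st0 <- n - nt_to; en0 <- n - nt_from + 1L
          fr <- -(off + 1L)
        }
        res[[length(res) + 1L]] <- data.frame(
          start = st0, end = en0, frame = fr, protein = prot,
          has_terminal_stop = term, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      protein = character(), has_terminal_stop = logical(),
                      meets_min_aa = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$meets_min_aa <- nchar(out$protein) >= config$orf_min_aa
  out <- out[order(-nchar(out$protein), out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
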