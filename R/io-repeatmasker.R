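#' Read a RepeatMasker `.out` annotation file
#'
#' Parses the standard whitespace-delimited layout (three header lines, then
#' one record per repeat hit).  The 1-based inclusive query coordinates are
#' converted to the package's 0-based half-open convention; orientation
#' `"C"` maps to strand `"-"`.  Records flagged with a trailing `"*"`
#' (overlapped by a higher-scoring hit) are retained and marked in the
#' `overlapped` column — the containment screen uses them by default, as raw
#' genome-browser RepeatMasker tracks do.
#'
#' No installed R package parses this format, so the tabular reader here is
#' purpose-written.
#'
#' @param path Path to a `.out` file.
#' @return A `data.frame` with columns `seq_id`, `start`, `end`, `strand`,
#'   `repeat_name`, `repeat_class`, `divergence_pct`, `score`, `record_id`,
#'   `overlapped`.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("RepeatMasker parse error: fewer than 3 header lines")
  body <- lines[-(1:3)]
  body_ln <- seq_along(lines)[-(1:3)]
  keep <- nzchar(trimws(body))
  body <- body[keep]
  body_ln <- body_ln[keep]
  rows <- vector("list", length(body))
  for (k in seq_along(body)) {
    f <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (!length(f) %in% c(15L, 16L)) {
      stop("RepeatMasker parse error at line ", body_ln[k],
           ": expected 15 or 16 columns, got ", length(f))
    }
    star <- length(f) == 16L && f[16] == "*"
    strand <- f[9]
    if (!strand %in% c("+", "C")) {
      stop("RepeatMasker parse error at line ", body_ln[k],
           ": bad orientation column '", strand, "'")
    }
    begin1 <- suppressWarnings(as.integer(f[6]))
    end1 <- suppressWarnings(as.integer(f[7]))
    if (is.na(begin1) || is.na(end1)) {
      stop("RepeatMasker parse error at line ", body_ln[k],
           ": non-numeric coordinates")
    }
    zb <- to_zero_based(begin1, end1)
    rows[[k]] <- data.frame(
      seq_id = f[5], start = zb$start, end = zb$end,
      strand = if (strand == "C") "-" else "+",
      repeat_name = f[10], repeat_class = f[11],
      divergence_pct = as.numeric(f[2]), score = as.numeric(f[1]),
      record_id = f[15],
      overlapped = star, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    seq_id = character(), start = integer(), end = integer(),
    strand = character(), repeat_name = character(),
    repeat_class = character(), divergence_pct = numeric(),
    score = numeric(), record_id = character(), overlapped = logical(),
    stringsAsFactors = FALSE)
  if (any(!nzchar(out$repeat_class))) {
    stop("RepeatMasker parse error: empty repeat class")
  }
  rownames(out) <- NULL
  out
}

#' Write repeat annotations in RepeatMasker `.out` layout
#'
#' Inverse of [read_repeatmasker_out()]: coordinates go back to 1-based
#' inclusive and minus-strand records are written with orientation `"C"`.
#'
#' @param repeats A repeat-annotation `data.frame`
#'   (see [read_repeatmasker_out()] for columns).
#' @param path Output path.
#' @param seq_lengths Optional named integer vector of sequence lengths,
#'   used to fill the `(left)` columns; zero otherwise.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(repeats, path, seq_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
    "score   div. del. ins.  sequence   begin    end          (left)   repeat         class/family      begin  end (left)     ID",
    ""), con)
  if (nrow(repeats)) {
    left <- rep("(0)", nrow(repeats))
    if (!is.null(seq_lengths)) {
      left <- paste0("(", seq_lengths[repeats$seq_id] - repeats$end, ")")
    }
    ob <- to_one_based(repeats$start, repeats$end)
    rlen <- repeats$end - repeats$start
    lines <- sprintf("%5.0f %6.1f  0.0  0.0  %s %8d %8d %8s %s %-18s %-16s %6d %6d (0) %6s%s",
                     repeats$score, repeats$divergence_pct, repeats$seq_id,
                     ob$begin, ob$end, left,
                     ifelse(repeats$strand == "-", "C", "+"),
                     repeats$repeat_name, repeats$repeat_class,
                     1L, rlen, repeats$record_id,
                     ifelse(repeats$overlapped, " *", ""))
    writeLines(lines, con)
  }
  invisible(path)
}
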