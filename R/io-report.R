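#' Write a tabular report
#'
#' TSV output keeps the `data.frame` column order and writes a header row;
#' BED output emits `seq_id`, `start`, `end` plus a name column when one is
#' available (0-based half-open, as BED requires).  Output is deterministic
#' for a given input.
#'
#' @param x A `data.frame` (e.g. overlap events or curation evidence).
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  if (format == "tsv") {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  } else {
    req <- c("seq_id", "start", "end")
    alt <- c("seq_id", "te_start", "te_end")
    if (all(req %in% names(x))) {
      bed <- x[, req, drop = FALSE]
    } else if (all(alt %in% names(x))) {
      bed <- setNames(x[, alt, drop = FALSE], req)
    } else {
      stop("BED output needs seq_id/start/end (or te_start/te_end) columns")
    }
    namecol <- intersect(c("name", "repeat_name", "gene_id", "element_id"),
                         names(x))
    bed$name <- if (length(namecol)) x[[namecol[1]]] else "."
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame`.
#' @export
read_report <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "")
}
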