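#' Construct a gene model
#'
#' A transcript-level gene model: ordered coding (CDS) intervals, all on one
#' sequence and strand, 0-based half-open.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param seq_id Sequence name.
#' @param strand `"+"` or `"-"`.
#' @param cds `data.frame` with integer columns `start`, `end`; intervals
#'   must be non-overlapping (they are sorted internally).
#' @param utr5,utr3 Optional `data.frame`s of UTR intervals.
#' @param biotype Free-text biotype, default `"protein_coding"`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, seq_id, strand, cds,
                       utr5 = NULL, utr3 = NULL, biotype = "protein_coding") {
  stopifnot(is.data.frame(cds), nrow(cds) >= 1L,
            all(c("start", "end") %in% names(cds)))
  if (!strand %in% c("+", "-")) stop("gene strand must be '+' or '-'")
  cds <- data.frame(start = as.integer(cds$start), end = as.integer(cds$end))
  cds <- cds[order(cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  if (any(cds$start >= cds$end)) stop("CDS interval with start >= end")
  if (nrow(cds) > 1L && any(cds$start[-1] < cds$end[-nrow(cds)])) {
    stop("overlapping CDS intervals in transcript ", transcript_id)
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 seq_id = seq_id, strand = strand, cds = cds,
                 utr5 = utr5, utr3 = utr3, biotype = biotype),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s/%s %s:%d-%d(%s), %d CDS interval(s), %d bp coding>\n",
              x$gene_id, x$transcript_id, x$seq_id, min(x$cds$start),
              max(x$cds$end), x$strand, nrow(x$cds), cds_length(x)))
  invisible(x)
}

#' Total coding length of a gene model
#' @param gene A `gene_model`.
#' @return Integer sum of CDS interval widths.
#' @export
cds_length <- function(gene) sum(gene$cds$end - gene$cds$start)

#' Flatten gene models to a per-CDS-interval table
#'
#' @param genes List of `gene_model` objects.
#' @return `data.frame` with one row per CDS interval: `seq_id`, `start`,
#'   `end`, `strand`, `gene_id`, `transcript_id`.
#' @export
cds_table <- function(genes) {
  if (length(genes) == 0L) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      transcript_id = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(genes, function(g) {
    data.frame(seq_id = g$seq_id, start = g$cds$start, end = g$cds$end,
               strand = g$strand, gene_id = g$gene_id,
               transcript_id = g$transcript_id, stringsAsFactors = FALSE)
  }))
}

#' Read gene models from GFF3
#'
#' Collects `CDS` features by their `Parent` attribute (the transcript),
#' converting GFF3's 1-based inclusive coordinates to 0-based half-open.
#' CDS features with no `Parent` are skipped with a warning; transcripts
#' whose CDS features disagree on strand or sequence are an error.  The
#' gene id is taken from the parent `mRNA`/`transcript` feature when
#' present, else it falls back to the transcript id.
#'
#' @param path Path to a GFF3 file.
#' @return List of [gene_model()] objects, ordered by transcript id.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ## transcript -> gene map from mRNA/transcript features
  tx_gene <- character()
  is_tx <- as.character(md$type) %in% c("mRNA", "transcript")
  if (any(is_tx)) {
    tid <- as.character(md$ID[is_tx])
    par <- md$Parent[is_tx]
    gid <- vapply(seq_along(tid), function(i) {
      p <- unlist(par[i])
      if (length(p)) as.character(p[1]) else tid[i]
    }, character(1))
    tx_gene <- setNames(gid, tid)
  }
  is_cds <- as.character(md$type) == "CDS"
  if (!any(is_cds)) return(list())
  cds <- gr[is_cds]
  parents <- S4Vectors::mcols(cds)$Parent
  npar <- lengths(parents) == 0L
  if (any(npar)) {
    warning(sum(npar), " CDS feature(s) without Parent attribute skipped")
    cds <- cds[!npar]
    parents <- parents[!npar]
  }
  if (length(cds) == 0L) return(list())
  ## a CDS may name several parents; expand
  idx <- rep(seq_along(cds), lengths(parents))
  tx <- unlist(lapply(parents, as.character))
  out <- list()
  for (t in sort(unique(tx))) {
    sel <- idx[tx == t]
    sub <- cds[sel]
    str <- unique(as.character(BiocGenerics::strand(sub)))
    if (length(str) > 1L) stop("mixed strands within transcript ", t)
    sq <- unique(as.character(GenomicRanges::seqnames(sub)))
    if (length(sq) > 1L) stop("CDS of transcript ", t, " on multiple sequences")
    if (str == "*") str <- "+"
    gid <- if (t %in% names(tx_gene)) tx_gene[[t]] else t
    out[[t]] <- gene_model(
      gene_id = gid, transcript_id = t, seq_id = sq, strand = str,
      cds = data.frame(start = BiocGenerics::start(sub) - 1L,
                       end = BiocGenerics::end(sub)))
  }
  unname(out)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features with `ID`/`Parent` wiring, using
#' GFF3's 1-based inclusive coordinates.  Output is deterministic: models
#' are written in the order given.
#'
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  seen_gene <- character()
  for (g in genes) {
    ob <- to_one_based(min(g$cds$start), max(g$cds$end))
    if (!g$gene_id %in% seen_gene) {
      writeLines(sprintf("%s\ttescreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                         g$seq_id, ob$begin, ob$end, g$strand, g$gene_id), con)
      seen_gene <- c(seen_gene, g$gene_id)
    }
    writeLines(sprintf("%s\ttescreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$seq_id, ob$begin, ob$end, g$strand,
                       g$transcript_id, g$gene_id), con)
    ph <- cds_phases(g)
    for (i in seq_len(nrow(g$cds))) {
      cb <- to_one_based(g$cds$start[i], g$cds$end[i])
      writeLines(sprintf("%s\ttescreen\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s;Parent=%s",
                         g$seq_id, cb$begin, cb$end, g$strand, ph[i],
                         g$transcript_id, g$transcript_id), con)
    }
  }
  invisible(path)
}

## GFF3 phase column for each CDS interval, honouring strand-aware
## translation order.
cds_phases <- function(g) {
  widths <- g$cds$end - g$cds$start
  ord <- if (g$strand == "-") rev(seq_along(widths)) else seq_along(widths)
  ph <- integer(length(widths))
  consumed <- 0L
  for (i in ord) {
    ph[i] <- (3L - consumed %% 3L) %% 3L
    consumed <- consumed + widths[i]
  }
  ph
}

#' Write gene models as BED12
#'
#' One line per transcript; blocks are the CDS intervals (thickStart and
#' thickEnd span the coding region).  BED is natively 0-based half-open, so
#' no coordinate shift is applied.
#'
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_genes <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    s <- min(g$cds$start); e <- max(g$cds$end)
    sizes <- paste0(g$cds$end - g$cds$start, collapse = ",")
    starts <- paste0(g$cds$start - s, collapse = ",")
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            g$seq_id, s, e, g$transcript_id, g$strand, s, e,
            nrow(g$cds), sizes, starts)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from BED12
#'
#' Blocks become CDS intervals; `name` is used as both gene and transcript
#' id (BED carries no gene/transcript hierarchy).
#'
#' @param path Path to a BED12 file.
#' @return List of [gene_model()] objects.
#' @export
read_bed_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)
  lapply(seq_along(gr), function(i) {
    b <- bl[[i]]
    str <- as.character(BiocGenerics::strand(gr[i]))
    if (str == "*") str <- "+"
    gene_model(
      gene_id = gr$name[i], transcript_id = gr$name[i],
      seq_id = as.character(GenomicRanges::seqnames(gr[i])), strand = str,
      cds = data.frame(start = BiocGenerics::start(b) - 1L,
                       end = BiocGenerics::end(b)))
  })
}

#' Read candidate loci from BED (3+ columns)
#'
#' @param path Path to a BED file.
#' @return `data.frame` with `seq_id`, `start`, `end`, `name`, `strand`
#'   (0-based half-open).
#' @export
read_bed_loci <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name)) gr$name else paste0("locus_", seq_along(gr))
  str <- as.character(BiocGenerics::strand(gr))
  str[str == "*"] <- "+"
  data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
             name = nm, strand = str, stringsAsFactors = FALSE)
}
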