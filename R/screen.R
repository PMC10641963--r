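#' Configuration for the misannotation containment screen
#'
#' Mirrors the stringent intersection used to flag TEs annotated inside
#' protein-coding regions: only repeats whose span is covered by a single
#' CDS interval at fraction `min_te_fraction` (default 1.00, i.e. full
#' containment) are reported, simple/low-complexity repeats are excluded,
#' and loci longer than `min_te_length_for_review` bp qualify for the
#' manual-review sample.
#'
#' @param min_te_fraction Minimum fraction of the TE covered by one CDS
#'   interval, in (0, 1]; default 1.00.
#' @param exclude_simple_repeats Drop `Simple_repeat` / `Low_complexity`
#'   classes (default `TRUE`).
#' @param min_te_length_for_review Strict length cutoff (bp) for
#'   [select_review_sample()]; default 1000.
#' @param strand_aware Require repeat and gene on the same strand
#'   (default `FALSE`; interval intersection is strand-blind).
#' @param collapse_gene Report at most one event per (repeat, gene) rather
#'   than per (repeat, transcript); default `FALSE`.
#' @return A `screen_config` list.
#' @export
screen_config <- function(min_te_fraction = 1.00,
                          exclude_simple_repeats = TRUE,
                          min_te_length_for_review = 1000L,
                          strand_aware = FALSE,
                          collapse_gene = FALSE) {
  if (!(min_te_fraction > 0 && min_te_fraction <= 1)) {
    stop("min_te_fraction must be in (0, 1]")
  }
  structure(list(min_te_fraction = min_te_fraction,
                 exclude_simple_repeats = exclude_simple_repeats,
                 min_te_length_for_review = as.integer(min_te_length_for_review),
                 strand_aware = strand_aware,
                 collapse_gene = collapse_gene),
            class = "screen_config")
}

empty_events <- function() {
  data.frame(seq_id = character(), te_start = integer(), te_end = integer(),
             repeat_name = character(), repeat_class = character(),
             record_id = character(), gene_id = character(),
             transcript_id = character(), cds_start = integer(),
             cds_end = integer(), overlap_bp = integer(),
             te_fraction = numeric(), stringsAsFactors = FALSE)
}

#' Find TEs contained in coding sequence
#'
#' Intersects repeat annotations with the individual CDS intervals of gene
#' models and reports every (repeat, CDS interval) pair whose overlap covers
#' at least `min_te_fraction` of the repeat.  With the default fraction of
#' 1.00 only repeats fully inside a single CDS interval are reported, so a
#' TE spanning an intron of a spliced transcript is not flagged — the
#' containment semantics of intersecting flat interval files.
#'
#' @param repeats Repeat-annotation `data.frame`
#'   (see [read_repeatmasker_out()]).
#' @param genes List of [gene_model()] objects.
#' @param config A [screen_config()].
#' @return `data.frame` of overlap events, sorted by
#'   (`seq_id`, `te_start`, `repeat_name`, `gene_id`, `transcript_id`):
#'   columns `seq_id`, `te_start`, `te_end`, `repeat_name`, `repeat_class`,
#'   `record_id`, `gene_id`, `transcript_id`, `cds_start`, `cds_end`,
#'   `overlap_bp`, `te_fraction`.
#' @export
contained_overlaps <- function(repeats, genes, config = screen_config()) {
  stopifnot(is(config, "screen_config"))
  cds <- cds_table(genes)
  if (is.null(repeats) || nrow(repeats) == 0L || nrow(cds) == 0L) {
    return(empty_events())
  }
  if (config$exclude_simple_repeats) {
    root <- sub("/.*$", "", repeats$repeat_class)
    repeats <- repeats[!root %in% c("Simple_repeat", "Low_complexity"), ,
                       drop = FALSE]
    if (nrow(repeats) == 0L) return(empty_events())
  }
  rg <- GenomicRanges::GRanges(repeats$seq_id,
                               IRanges::IRanges(repeats$start + 1L, repeats$end))
  cg <- GenomicRanges::GRanges(cds$seq_id,
                               IRanges::IRanges(cds$start + 1L, cds$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(rg, cg, ignore.strand = TRUE))
  if (length(hits) == 0L) return(empty_events())
  ri <- S4Vectors::queryHits(hits)
  ci <- S4Vectors::subjectHits(hits)
  ov <- pmin(repeats$end[ri], cds$end[ci]) - pmax(repeats$start[ri], cds$start[ci])
  te_len <- repeats$end[ri] - repeats$start[ri]
  frac <- ov / te_len
  keep <- frac >= config$min_te_fraction
  if (config$strand_aware) keep <- keep & repeats$strand[ri] == cds$strand[ci]
  if (!any(keep)) return(empty_events())
  ri <- ri[keep]; ci <- ci[keep]
  ev <- data.frame(
    seq_id = repeats$seq_id[ri], te_start = repeats$start[ri],
    te_end = repeats$end[ri], repeat_name = repeats$repeat_name[ri],
    repeat_class = repeats$repeat_class[ri], record_id = repeats$record_id[ri],
    gene_id = cds$gene_id[ci], transcript_id = cds$transcript_id[ci],
    cds_start = cds$start[ci], cds_end = cds$end[ci],
    overlap_bp = ov[keep], te_fraction = frac[keep], stringsAsFactors = FALSE)
  ev <- ev[order(ev$seq_id, ev$te_start, ev$repeat_name, ev$gene_id,
                 ev$transcript_id, ev$cds_start), , drop = FALSE]
  if (config$collapse_gene) {
    key <- paste(ev$seq_id, ev$te_start, ev$te_end, ev$record_id, ev$gene_id)
    ev <- ev[!duplicated(key), , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' Coarse TE class of a RepeatMasker class/family label
#'
#' Roll-up used for reporting: class 1 (retrotransposons: LINE, SINE, LTR,
#' Retroposon, Penelope), class 2 (DNA transposons, incl. rolling-circle
#' `RC` elements), or `other` (satellites, unknown, etc.).
#'
#' @param repeat_class Character vector of `Class/Family` labels.
#' @return Character vector: `"class1"`, `"class2"` or `"other"`.
#' @export
te_class_category <- function(repeat_class) {
  root <- sub("[/?].*$", "", repeat_class)
  root <- sub("\\?$", "", root)
  out <- rep("other", length(repeat_class))
  out[root %in% c("LINE", "SINE", "LTR", "Retroposon", "Penelope", "PLE")] <- "class1"
  out[root %in% c("DNA", "RC")] <- "class2"
  out
}

#' Summarize overlap events by TE class
#'
#' @param events Events from [contained_overlaps()].
#' @return `data.frame` with one row per `repeat_class`: `repeat_class`,
#'   `category` (class1/class2/other), `n_events`, `n_genes` (distinct
#'   genes), `total_bp` (summed overlap).  A roll-up over `category` is
#'   attached as attribute `"rollup"`.  Per-class event counts always sum
#'   to `nrow(events)`.
#' @export
summarize_by_class <- function(events) {
  if (is.null(events) || nrow(events) == 0L) {
    out <- data.frame(repeat_class = character(), category = character(),
                      n_events = integer(), n_genes = integer(),
                      total_bp = numeric(), stringsAsFactors = FALSE)
    attr(out, "rollup") <- data.frame(category = character(),
                                      n_events = integer(),
                                      stringsAsFactors = FALSE)
    return(out)
  }
  cls <- sort(unique(events$repeat_class))
  out <- data.frame(
    repeat_class = cls,
    category = te_class_category(cls),
    n_events = vapply(cls, function(k) sum(events$repeat_class == k), integer(1)),
    n_genes = vapply(cls, function(k) {
      length(unique(events$gene_id[events$repeat_class == k]))
    }, integer(1)),
    total_bp = vapply(cls, function(k) {
      as.numeric(sum(events$overlap_bp[events$repeat_class == k]))
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  cats <- sort(unique(out$category))
  attr(out, "rollup") <- data.frame(
    category = cats,
    n_events = vapply(cats, function(k) sum(out$n_events[out$category == k]),
                      integer(1)),
    stringsAsFactors = FALSE)
  out
}

#' Select events for manual review
#'
#' Keeps events whose repeat is strictly longer than
#' `min_te_length_for_review` bp, then deduplicates per gene (first event
#' in the deterministic sort order wins).
#'
#' @param events Events from [contained_overlaps()].
#' @param config A [screen_config()].
#' @return Filtered event `data.frame`.
#' @export
select_review_sample <- function(events, config = screen_config()) {
  if (is.null(events) || nrow(events) == 0L) return(empty_events())
  keep <- (events$te_end - events$te_start) > config$min_te_length_for_review
  ev <- events[keep, , drop = FALSE]
  ev <- ev[order(ev$seq_id, ev$te_start, ev$repeat_name, ev$gene_id), ,
           drop = FALSE]
  ev <- ev[!duplicated(ev$gene_id), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
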