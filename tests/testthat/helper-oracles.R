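## Independent brute-force oracles and small fixture builders.  These are
## deliberately written with different mechanics than the package
## implementations they check.

## all-pairs containment oracle: explicit cross join of every repeat with
## every CDS interval, no interval index or sweep
oracle_contained_overlaps <- function(repeats, genes, min_frac = 1.00,
                                      exclude_simple = TRUE) {
  if (exclude_simple) {
    keep <- !sub("/.*$", "", repeats$repeat_class) %in%
      c("Simple_repeat", "Low_complexity")
    repeats <- repeats[keep, , drop = FALSE]
  }
  cds <- do.call(rbind, lapply(genes, function(g) {
    data.frame(seq_id = g$seq_id, cds_start = g$cds$start,
               cds_end = g$cds$end, gene_id = g$gene_id,
               transcript_id = g$transcript_id, stringsAsFactors = FALSE)
  }))
  if (is.null(cds) || nrow(repeats) == 0L) return(NULL)
  pairs <- expand.grid(i = seq_len(nrow(repeats)), j = seq_len(nrow(cds)))
  r <- repeats[pairs$i, ]; c <- cds[pairs$j, ]
  ov <- pmin(r$end, c$cds_end) - pmax(r$start, c$cds_start)
  frac <- ov / (r$end - r$start)
  sel <- r$seq_id == c$seq_id & ov > 0 & frac >= min_frac
  if (!any(sel)) return(NULL)
  out <- data.frame(seq_id = r$seq_id, te_start = r$start, te_end = r$end,
                    repeat_name = r$repeat_name, gene_id = c$gene_id,
                    transcript_id = c$transcript_id, cds_start = c$cds_start,
                    cds_end = c$cds_end, overlap_bp = ov, te_fraction = frac,
                    stringsAsFactors = FALSE)[sel, , drop = FALSE]
  out[order(out$seq_id, out$te_start, out$repeat_name, out$gene_id,
            out$transcript_id, out$cds_start), , drop = FALSE]
}

## six-frame ORF oracle: translate whole frames with Biostrings, split the
## protein at stops with a regex, take the first M of each segment
oracle_find_orfs <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (off in 0:2) {
      ncod <- (n - off) %/% 3
      if (ncod < 1) next
      sub <- substr(ss, off + 1, off + 3 * ncod)
      prot <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                 no.init.codon = TRUE))
      segs <- strsplit(prot, "*", fixed = TRUE)[[1]]
      ## trailing segment: translate() output has no terminal marker, so
      ## track codon offsets manually
      pos <- 1L
      nseg <- length(segs)
      ends_with_stop <- substring(prot, nchar(prot)) == "*"
      for (k in seq_along(segs)) {
        seg <- segs[k]
        term <- k < nseg || ends_with_stop
        m <- regexpr("M", seg, fixed = TRUE)
        if (m > 0) {
          cod_start <- pos + as.integer(m) - 1L       # 1-based codon index
          cod_end <- pos + nchar(seg) - 1L
          protein <- substring(seg, as.integer(m))
          nt_from <- off + (cod_start - 1L) * 3L + 1L
          nt_to <- off + cod_end * 3L + (if (term) 3L else 0L)
          if (strand == "+") {
            st0 <- nt_from - 1L; en0 <- nt_to; fr <- off + 1L
          } else {
            st0 <- n - nt_to; en0 <- n - nt_from + 1L; fr <- -(off + 1L)
          }
          out[[length(out) + 1L]] <- data.frame(
            start = st0, end = en0, frame = fr, protein = protein,
            has_terminal_stop = term, stringsAsFactors = FALSE)
        }
        pos <- pos + nchar(seg) + 1L
      }
    }
  }
  if (!length(out)) return(NULL)
  o <- do.call(rbind, out)
  o[order(o$start, o$frame), , drop = FALSE]
}

random_dna_str <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random repeat-annotation table on a shared seq_id namespace
random_repeats <- function(n, seq_ids = c("chr1", "chr2"), max_pos = 10000L) {
  starts <- sample.int(max_pos - 200L, n, replace = TRUE)
  widths <- sample(20:150, n, replace = TRUE)
  data.frame(
    seq_id = sample(seq_ids, n, replace = TRUE), start = starts,
    end = starts + widths, strand = sample(c("+", "-"), n, replace = TRUE),
    repeat_name = paste0("rep", seq_len(n)),
    repeat_class = sample(c("DNA/hAT", "LINE/L1", "LTR/Gypsy",
                            "Simple_repeat", "SINE/Alu"), n, replace = TRUE),
    divergence_pct = round(runif(n, 0, 30), 1), score = sample(100:5000, n,
                                                               replace = TRUE),
    record_id = as.character(seq_len(n)), overlapped = FALSE,
    stringsAsFactors = FALSE)
}

## random gene models, some spliced
random_genes <- function(n, seq_ids = c("chr1", "chr2"), max_pos = 10000L) {
  lapply(seq_len(n), function(i) {
    nexon <- sample(1:3, 1)
    widths <- sample(50:300, nexon, replace = TRUE)
    gaps <- sample(50:200, nexon, replace = TRUE)
    starts <- integer(nexon)
    cur <- sample.int(max_pos - 2000L, 1)
    for (k in seq_len(nexon)) {
      starts[k] <- cur
      cur <- cur + widths[k] + gaps[k]
    }
    gene_model(paste0("g", i), paste0("g", i, ".t1"),
               sample(seq_ids, 1), sample(c("+", "-"), 1),
               data.frame(start = starts, end = starts + widths))
  })
}

## normalize event tables for oracle comparison
event_key <- function(ev) {
  if (is.null(ev) || nrow(ev) == 0) return(character())
  sprintf("%s:%d-%d|%s|%s|%d-%d|%d", ev$seq_id, ev$te_start, ev$te_end,
          ev$repeat_name, ev$transcript_id, ev$cds_start, ev$cds_end,
          ev$overlap_bp)
}
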