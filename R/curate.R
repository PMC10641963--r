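#' Configuration for structural curation of candidate hAT elements
#'
#' Defaults target autonomous hAT DNA transposons: an 8-bp target-site
#' duplication (the superfamily's hallmark), short terminal inverted
#' repeats (10-30 bp searched within 50 bp of each element end, up to 15%
#' mismatch), flanks extended 1000 bp where possible, and an "intact" ORF
#' of at least 300 aa (deliberately permissive — hAT transposases are
#' substantially longer).  All thresholds are exposed so other DNA-TE
#' superfamilies can be targeted.
#'
#' @param flank_bp Flank extension on each side (default 1000).
#' @param tir_min_len,tir_max_len TIR length window (default 10-30).
#' @param tir_search_window bp from each element end searched for TIRs
#'   (default 50).
#' @param tir_max_mismatch_frac Maximum mismatch fraction between the 5'
#'   TIR and the reverse complement of the 3' TIR (default 0.15).
#' @param tsd_len_range Integer pair, allowed TSD lengths (default `c(8, 8)`).
#' @param tsd_max_mismatch Maximum mismatches between the two TSD copies
#'   (default 0).
#' @param tsd_search_window bp outside each boundary scanned for TSDs
#'   (default 20).
#' @param orf_min_aa Minimum protein length for an "intact" ORF
#'   (default 300).
#' @param min_entropy Low-complexity guard: candidate TIR/TSD sequences
#'   with Shannon entropy below this (bits/base) are rejected (default 1.0),
#'   preventing poly-A artifacts.
#' @return A `curation_config` list.
#' @export
curation_config <- function(flank_bp = 1000L, tir_min_len = 10L,
                            tir_max_len = 30L, tir_search_window = 50L,
                            tir_max_mismatch_frac = 0.15,
                            tsd_len_range = c(8L, 8L), tsd_max_mismatch = 0L,
                            tsd_search_window = 20L, orf_min_aa = 300L,
                            min_entropy = 1.0) {
  stopifnot(flank_bp >= 0L, tir_min_len <= tir_max_len,
            length(tsd_len_range) == 2L, all(tsd_len_range > 0L),
            tsd_len_range[1] <= tsd_len_range[2])
  structure(list(flank_bp = as.integer(flank_bp),
                 tir_min_len = as.integer(tir_min_len),
                 tir_max_len = as.integer(tir_max_len),
                 tir_search_window = as.integer(tir_search_window),
                 tir_max_mismatch_frac = tir_max_mismatch_frac,
                 tsd_len_range = as.integer(tsd_len_range),
                 tsd_max_mismatch = as.integer(tsd_max_mismatch),
                 tsd_search_window = as.integer(tsd_search_window),
                 orf_min_aa = as.integer(orf_min_aa),
                 min_entropy = min_entropy),
            class = "curation_config")
}

#' Extract an element with extended flanks
#'
#' Returns the genomic sequence covering the element plus `flank_bp` on
#' each side, clipped to chromosome bounds ("where possible"), together
#' with the offset mapping local to genomic coordinates
#' (`genomic = local + offset`).
#'
#' @param element A [genomic_interval()].
#' @param genome Named character vector of chromosome sequences.
#' @param config A [curation_config()].
#' @return List: `seq` (local sequence), `element_local` (integer pair,
#'   0-based half-open position of the element within `seq`), `offset`
#'   (genomic coordinate of local position 0), `seq_id`.
#' @export
extend_flanks <- function(element, genome, config = curation_config()) {
  if (!element$seq_id %in% names(genome)) {
    stop("element sequence '", element$seq_id, "' not found in genome")
  }
  chrom <- genome[[element$seq_id]]
  n <- nchar(chrom)
  if (element$end > n) stop("element extends beyond chromosome end")
  lo <- max(0L, element$start - config$flank_bp)
  hi <- min(n, element$end + config$flank_bp)
  list(seq = substr(chrom, lo + 1L, hi),
       element_local = c(element$start - lo, element$end - lo),
       offset = lo, seq_id = element$seq_id)
}

## Ordered comparison of TIR candidates: higher score, then longer, then
## 5'-most (smaller a), then smaller b.  Returns TRUE if x beats y.
tir_better <- function(x, y) {
  if (is.null(y)) return(TRUE)
  if (x$score != y$score) return(x$score > y$score)
  if (x$length != y$length) return(x$length > y$length)
  if (x$a != y$a) return(x$a < y$a)
  x$b < y$b
}

#' Detect terminal inverted repeats
#'
#' Searches the first and last `tir_search_window` bp of the element for
#' the highest-scoring pair (prefix substring, suffix substring) such that
#' the prefix matches the reverse complement of the suffix with mismatch
#' fraction at most `tir_max_mismatch_frac` and length within the
#' configured window.  Score is `matches - mismatches`; ties prefer the
#' longer pair, then the 5'-most.  Candidates failing the low-complexity
#' entropy guard are rejected.
#'
#' @param local_seq Sequence containing the element (e.g. from
#'   [extend_flanks()]).
#' @param element_local Integer pair: 0-based half-open element position
#'   within `local_seq`.
#' @param config A [curation_config()].
#' @return `NULL` when nothing qualifies, else a list: `five_start`,
#'   `five_end`, `three_start`, `three_end` (local 0-based half-open),
#'   `length`, `mismatches`, `five_seq`, `three_seq`.
#' @export
find_tirs <- function(local_seq, element_local, config = curation_config()) {
  el_s <- element_local[1]; el_e <- element_local[2]
  n <- el_e - el_s
  if (n < 2L * config$tir_min_len) {
    message("element too short for TIR search (", n, " bp)")
    return(NULL)
  }
  elem <- substr(local_seq, el_s + 1L, el_e)
  W <- min(config$tir_search_window, n %/% 2L)
  if (W < config$tir_min_len) return(NULL)
  w5 <- strsplit(substr(elem, 1L, W), "")[[1]]
  rc3 <- strsplit(revcomp(substr(elem, n - W + 1L, n)), "")[[1]]
  best <- NULL
  for (L in seq(min(config$tir_max_len, W), config$tir_min_len)) {
    max_mm <- floor(L * config$tir_max_mismatch_frac)
    for (d in seq(-(W - L), W - L)) {
      i0 <- max(1L, 1L - d); i1 <- min(W, W - d)
      if (i1 - i0 + 1L < L) next
      v <- w5[i0:i1] != rc3[(i0 + d):(i1 + d)]
      cs <- cumsum(c(0L, v))
      nw <- length(v) - L + 1L
      mm <- cs[(L + 1L):(L + nw)] - cs[1:nw]
      ok <- which(mm <= max_mm)
      for (j in ok) {
        a <- i0 + j - 2L            # 0-based start offset of 5' TIR
        b <- a + d                  # 0-based end offset of 3' TIR
        cand <- list(a = a, b = b, length = L, mismatches = mm[j],
                     score = L - 2L * mm[j])
        if (!tir_better(cand, best)) next
        five_seq <- substr(elem, a + 1L, a + L)
        three_seq <- substr(elem, n - b - L + 1L, n - b)
        if (min(seq_entropy(five_seq), seq_entropy(three_seq)) <
            config$min_entropy) next
        cand$five_seq <- five_seq
        cand$three_seq <- three_seq
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(five_start = el_s + best$a, five_end = el_s + best$a + best$length,
       three_start = el_e - best$b - best$length, three_end = el_e - best$b,
       length = best$length, mismatches = as.integer(best$mismatches),
       five_seq = best$five_seq, three_seq = best$three_seq)
}

#' Detect the target-site duplication
#'
#' Scans windows of `tsd_search_window` bp immediately outside the element
#' boundaries (or outside the TIRs when a TIR pair is supplied) for a
#' direct-repeat pair within the configured length range and mismatch
#' budget.  Pairs abutting the boundaries are preferred (smallest total
#' gap), then longer pairs, then fewer mismatches.
#'
#' @param local_seq Sequence containing the element and flanks.
#' @param element_local Integer pair, element position within `local_seq`.
#' @param tir Optional TIR pair from [find_tirs()]; when given, boundaries
#'   are the outer TIR edges.
#' @param config A [curation_config()].
#' @return `NULL` when nothing qualifies, else a list: `left_start`,
#'   `left_end`, `right_start`, `right_end` (local 0-based half-open),
#'   `seq_left`, `seq_right`, `mismatches`, `gap_left`, `gap_right`.
#' @export
find_tsds <- function(local_seq, element_local, tir = NULL,
                      config = curation_config()) {
  lb <- if (!is.null(tir)) tir$five_start else element_local[1]
  rb <- if (!is.null(tir)) tir$three_end else element_local[2]
  n <- nchar(local_seq)
  win <- config$tsd_search_window
  best <- NULL
  for (L in seq(config$tsd_len_range[2], config$tsd_len_range[1])) {
    for (gl in 0:(win - 1L)) {
      ls <- lb - gl - L
      if (ls < 0L) break
      seq_left <- substr(local_seq, ls + 1L, ls + L)
      lchars <- strsplit(seq_left, "")[[1]]
      for (gr in 0:(win - 1L)) {
        rs <- rb + gr
        if (rs + L > n) break
        seq_right <- substr(local_seq, rs + 1L, rs + L)
        mm <- sum(lchars != strsplit(seq_right, "")[[1]])
        if (mm > config$tsd_max_mismatch) next
        cand <- list(gap = gl + gr, L = L, mm = mm, gl = gl, gr = gr,
                     ls = ls, rs = rs, seq_left = seq_left,
                     seq_right = seq_right)
        better <- is.null(best) ||
          cand$gap < best$gap ||
          (cand$gap == best$gap && cand$L > best$L) ||
          (cand$gap == best$gap && cand$L == best$L && cand$mm < best$mm) ||
          (cand$gap == best$gap && cand$L == best$L && cand$mm == best$mm &&
             cand$gl < best$gl)
        if (!better) next
        if (min(seq_entropy(seq_left), seq_entropy(seq_right)) <
            config$min_entropy) next
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(left_start = best$ls, left_end = best$ls + best$L,
       right_start = best$rs, right_end = best$rs + best$L,
       seq_left = best$seq_left, seq_right = best$seq_right,
       mismatches = as.integer(best$mm),
       gap_left = best$gl, gap_right = best$gr)
}

#' Classify a candidate element from its structural evidence
#'
#' Autonomous iff TSDs, TIRs and an intact ORF (at least `orf_min_aa`
#' residues) are all present and all five DDE/RW catalytic residues were
#' found; partial/non-autonomous when at least one structural feature (TIR,
#' TSD, or an ORF with substantial catalytic homology, i.e. three or more
#' of the five residues) is present but the conjunction fails; otherwise
#' not a TE.
#'
#' @param tir TIR pair from [find_tirs()] or `NULL`.
#' @param tsd TSD pair from [find_tsds()] or `NULL`.
#' @param orf A single ORF call (one-row `data.frame` or list with a
#'   `protein` field) or `NULL`.
#' @param motif Result of [scan_catalytic_residues()] or `NULL`.
#' @param config A [curation_config()].
#' @return `"autonomous"`, `"partial_non_autonomous"` or `"not_te"`.
#' @export
classify_element <- function(tir, tsd, orf, motif,
                             config = curation_config()) {
  orf_intact <- !is.null(orf) && nchar(orf$protein) >= config$orf_min_aa
  motif_full <- !is.null(motif) && motif$n_found == 5L
  if (!is.null(tir) && !is.null(tsd) && orf_intact && motif_full) {
    return("autonomous")
  }
  orf_homology <- !is.null(orf) && !is.null(motif) && motif$n_found >= 3L
  if (!is.null(tir) || !is.null(tsd) || orf_homology) {
    return("partial_non_autonomous")
  }
  "not_te"
}

#' Curate one candidate element
#'
#' Runs the full structural procedure: flank extension, TIR and TSD
#' detection, six-frame ORF finding, catalytic-residue anchoring on the
#' longest ORFs, and classification.
#'
#' @param element A [genomic_interval()].
#' @param genome Named character vector of chromosome sequences.
#' @param reference A [transposase_reference()] for DDE/RW anchoring.
#' @param config A [curation_config()].
#' @param element_id Identifier used in reports.
#' @return A `curation_result` list: `element_id`, `element`, `tir`, `tsd`,
#'   `orf`, `motif`, `verdict`, plus `offset` for local-to-genomic mapping.
#'   TIR/TSD/ORF coordinates are reported in genomic space.
#' @export
curate_element <- function(element, genome,
                           reference = synthetic_reference_transposase(),
                           config = curation_config(),
                           element_id = "element") {
  fl <- extend_flanks(element, genome, config)
  tir <- find_tirs(fl$seq, fl$element_local, config)
  tsd <- find_tsds(fl$seq, fl$element_local, tir, config)
  elem_seq <- substr(fl$seq, fl$element_local[1] + 1L, fl$element_local[2])
  orfs <- if (nchar(elem_seq) >= 3L) find_orfs(elem_seq, config) else NULL
  orf <- NULL; motif <- NULL
  if (!is.null(orfs) && nrow(orfs) > 0L) {
    ## anchor the catalytic scan on the longest ORFs (either strand) and
    ## keep the best-supported one
    ntop <- min(3L, nrow(orfs))
    best <- NULL; best_m <- NULL
    for (i in seq_len(ntop)) {
      m <- scan_catalytic_residues(orfs$protein[i], reference)
      if (is.null(best) || m$n_found > best_m$n_found ||
          (m$n_found == best_m$n_found &&
             m$alignment_score > best_m$alignment_score)) {
        best <- orfs[i, , drop = FALSE]; best_m <- m
      }
    }
    orf <- as.list(best)
    motif <- best_m
  }
  verdict <- classify_element(tir, tsd, orf, motif, config)
  to_genomic <- function(x, fields) {
    if (is.null(x)) return(NULL)
    for (f in fields) x[[f]] <- x[[f]] + fl$offset
    x
  }
  res <- list(
    element_id = element_id, element = element,
    tir = to_genomic(tir, c("five_start", "five_end", "three_start", "three_end")),
    tsd = to_genomic(tsd, c("left_start", "left_end", "right_start", "right_end")),
    orf = if (is.null(orf)) NULL else {
      orf$start <- orf$start + element$start
      orf$end <- orf$end + element$start
      orf
    },
    motif = motif, verdict = verdict, offset = fl$offset)
  class(res) <- "curation_result"
  res
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf("<curation_result %s %s:%d-%d verdict=%s tir=%s tsd=%s orf=%s motif=%s>\n",
              x$element_id, x$element$seq_id, x$element$start, x$element$end,
              x$verdict, !is.null(x$tir), !is.null(x$tsd),
              if (is.null(x$orf)) "none" else paste0(nchar(x$orf$protein), "aa"),
              if (is.null(x$motif)) "none" else paste0(x$motif$n_found, "/5")))
  invisible(x)
}

#' Curate a set of candidate loci
#'
#' @param loci `data.frame` with `seq_id`, `start`, `end` and optionally
#'   `name` (0-based half-open), e.g. from [read_bed_loci()].
#' @param genome Named character vector of chromosome sequences.
#' @param reference A [transposase_reference()].
#' @param config A [curation_config()].
#' @return List with `results` (list of `curation_result`) and `evidence`
#'   (per-element `data.frame` suitable for [write_report()]).
#' @export
curate_loci <- function(loci, genome,
                        reference = synthetic_reference_transposase(),
                        config = curation_config()) {
  ids <- if ("name" %in% names(loci)) loci$name else
    paste0("locus_", seq_len(nrow(loci)))
  results <- lapply(seq_len(nrow(loci)), function(i) {
    curate_element(genomic_interval(loci$seq_id[i], loci$start[i],
                                    loci$end[i]),
                   genome, reference, config, element_id = ids[i])
  })
  list(results = results, evidence = curation_evidence(results))
}

#' Tabulate curation results
#'
#' @param results List of `curation_result` objects.
#' @return One row per element: coordinates and presence/detail columns for
#'   TSD, TIR, ORF and catalytic residues, plus the verdict.
#' @export
curation_evidence <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      element_id = r$element_id, seq_id = r$element$seq_id,
      start = r$element$start, end = r$element$end,
      tir_found = !is.null(r$tir),
      tir_len = if (is.null(r$tir)) NA_integer_ else r$tir$length,
      tir_mismatches = if (is.null(r$tir)) NA_integer_ else r$tir$mismatches,
      tir5_start = if (is.null(r$tir)) NA_integer_ else r$tir$five_start,
      tir3_end = if (is.null(r$tir)) NA_integer_ else r$tir$three_end,
      tir_seq = if (is.null(r$tir)) NA_character_ else r$tir$five_seq,
      tsd_found = !is.null(r$tsd),
      tsd_seq = if (is.null(r$tsd)) NA_character_ else r$tsd$seq_left,
      tsd_left_start = if (is.null(r$tsd)) NA_integer_ else r$tsd$left_start,
      tsd_right_start = if (is.null(r$tsd)) NA_integer_ else r$tsd$right_start,
      orf_found = !is.null(r$orf),
      orf_len_aa = if (is.null(r$orf)) NA_integer_ else nchar(r$orf$protein),
      orf_frame = if (is.null(r$orf)) NA_integer_ else r$orf$frame,
      motif_n_found = if (is.null(r$motif)) NA_integer_ else r$motif$n_found,
      residues_found = if (is.null(r$motif)) NA_character_ else
        paste(names(r$motif$found)[r$motif$found], collapse = ","),
      verdict = r$verdict, stringsAsFactors = FALSE)
  }))
}

#' Column-wise conservation of a TIR family
#'
#' Takes the 5' TIRs as given and the 3' TIRs reverse-complemented into the
#' 5' orientation, left-anchors them (TIRs begin at the element boundary),
#' pads to equal length, and reports per-column base frequencies with a
#' majority-rule consensus; ties become IUPAC ambiguity letters.
#'
#' @param tir_pairs List of TIR pairs from [find_tirs()].
#' @return `data.frame`: `column`, counts `A`, `C`, `G`, `T`, `consensus`,
#'   `majority_freq`.
#' @export
tir_conservation <- function(tir_pairs) {
  if (length(tir_pairs) < 2L) {
    stop("need at least 2 TIR pairs to assess conservation")
  }
  seqs <- c(vapply(tir_pairs, function(p) p$five_seq, character(1)),
            vapply(tir_pairs, function(p) revcomp(p$three_seq), character(1)))
  width <- max(nchar(seqs))
  padded <- vapply(seqs, function(s) {
    paste0(s, strrep("-", width - nchar(s)))
  }, character(1))
  mat <- do.call(rbind, strsplit(padded, ""))
  out <- lapply(seq_len(width), function(j) {
    col <- mat[, j]
    cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(col == b), integer(1))
    tot <- sum(cnt)
    if (tot == 0L) {
      cons <- "-"; mf <- NA_real_
    } else {
      top <- which(cnt == max(cnt))
      cons <- if (length(top) == 1L) names(cnt)[top] else
        iupac_for_bases(names(cnt)[top])
      mf <- max(cnt) / tot
    }
    data.frame(column = j, A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]],
               T = cnt[["T"]], consensus = cons, majority_freq = mf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise percent-identity matrix of pre-aligned sequences
#'
#' `identity(i, j) = 100 * matches / columns where neither sequence has a
#' gap`; the diagonal is 100 and the matrix symmetric.
#'
#' @param aligned_seqs Character vector (optionally named) of equal-length
#'   aligned sequences; `-` marks gaps.
#' @return Symmetric numeric matrix of percent identities.
#' @export
pairwise_identity_matrix <- function(aligned_seqs) {
  n <- length(aligned_seqs)
  if (n < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(aligned_seqs))) != 1L) {
    stop("sequences must be pre-aligned to equal length")
  }
  chars <- lapply(toupper(aligned_seqs), function(s) strsplit(s, "")[[1]])
  nm <- if (!is.null(names(aligned_seqs))) names(aligned_seqs) else
    paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ungapped <- chars[[i]] != "-" & chars[[j]] != "-"
      if (!any(ungapped)) {
        m[i, j] <- m[j, i] <- NA_real_
      } else {
        m[i, j] <- m[j, i] <-
          100 * sum(chars[[i]][ungapped] == chars[[j]][ungapped]) / sum(ungapped)
      }
    }
  }
  m
}
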