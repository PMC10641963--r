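#' Translate the spliced CDS of a gene model
#'
#' Strand-aware: CDS intervals are concatenated in genomic order, reverse
#' complemented for minus-strand models, and translated with the standard
#' code.  A trailing partial codon is trimmed with a warning.  Internal
#' stop codons are permitted — they are exactly what a TE misannotated as
#' a gene tends to produce — and are counted rather than rejected.
#'
#' @param gene A [gene_model()].
#' @param genome Named character vector of chromosome sequences.
#' @return Amino-acid string (stops as `*`; a terminal stop is trimmed)
#'   with attribute `n_internal_stops`.
#' @export
translate_cds <- function(gene, genome) {
  if (!gene$seq_id %in% names(genome)) {
    stop("gene sequence '", gene$seq_id, "' not found in genome")
  }
  chrom <- genome[[gene$seq_id]]
  if (max(gene$cds$end) > nchar(chrom)) {
    stop("CDS of ", gene$transcript_id, " outside genome bounds")
  }
  parts <- substring(chrom, gene$cds$start + 1L, gene$cds$end)
  nt <- paste0(parts, collapse = "")
  if (gene$strand == "-") nt <- revcomp(nt)
  if (nchar(nt) %% 3L != 0L) {
    warning("CDS length of ", gene$transcript_id,
            " not divisible by 3; trailing ", nchar(nt) %% 3L, " nt trimmed")
    nt <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
  }
  aa <- translate_dna(nt)
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  n_stops <- lengths(regmatches(aa, gregexpr("*", aa, fixed = TRUE)))
  attr(aa, "n_internal_stops") <- as.integer(n_stops)
  aa
}

#' Calibrate the homology-screen score cutoff by a shuffle null
#'
#' For one translated CDS, permutes its residues `n_shuffles` times, takes
#' for each permutation the best local-alignment score against the TE
#' protein library, and returns the 99th percentile of that null
#' distribution.  Local alignment of a shuffled protein preserves length
#' and composition, so scores at or above this cutoff indicate order-level
#' (i.e. genuine) homology.
#'
#' @param protein Translated CDS (amino-acid string).
#' @param te_proteins Named character vector of TE peptides.
#' @param n_shuffles Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param percentile Null quantile used as cutoff (default 0.99).
#' @param gap_opening,gap_extension Affine gap penalties (defaults 11, 1).
#' @return Numeric score cutoff.
#' @export
calibrate_homology_cutoff <- function(protein, te_proteins,
                                      n_shuffles = 1000L, seed = 1L,
                                      percentile = 0.99,
                                      gap_opening = 11, gap_extension = 1) {
  stopifnot(length(te_proteins) >= 1L)
  chars <- strsplit(as.character(protein), "")[[1]]
  shuffled <- with_local_seed(seed, {
    vapply(seq_len(n_shuffles),
           function(i) paste0(sample(chars), collapse = ""), character(1))
  })
  mat <- get_blosum62()
  per_pep <- vapply(te_proteins, function(pep) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(shuffled), Biostrings::AAString(pep),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = TRUE)
  }, numeric(n_shuffles))
  null_best <- if (length(te_proteins) == 1L) as.numeric(per_pep) else
    apply(per_pep, 1L, max)
  as.numeric(quantile(null_best, percentile, names = FALSE))
}

#' Screen gene models for translated homology to TE proteins
#'
#' The proposed last-step annotation filter: each gene model's translated
#' CDS is locally aligned (affine gaps, BLOSUM62) against every peptide in
#' a TE protein library; the best hit per (gene, peptide) pair is kept and
#' flagged when its score reaches the cutoff.  When `cutoff` is `NULL` a
#' per-gene cutoff is calibrated from a shuffle null
#' ([calibrate_homology_cutoff()]), so flagging reflects order-level
#' homology rather than composition.
#'
#' @param genes List of [gene_model()] objects.
#' @param genome Named character vector of chromosome sequences.
#' @param te_proteins Named character vector of TE peptides (e.g. read
#'   with [read_fasta()] from a transposase library).
#' @param cutoff Fixed score cutoff, or `NULL` to calibrate per gene.
#' @param n_shuffles Permutations for calibration (default 1000).
#' @param seed Seed for the calibration shuffles.
#' @param gap_opening,gap_extension Affine gap penalties (defaults 11, 1).
#' @return `data.frame`, one row per (gene, peptide): `gene_id`,
#'   `transcript_id`, `te_protein_id`, `score`, `cutoff`,
#'   `percent_identity` (fraction of identical residues within the local
#'   alignment), `flagged`, `n_internal_stops`.  Deterministic order:
#'   (`gene_id`, `transcript_id`, `te_protein_id`).
#' @export
screen_gene_models <- function(genes, genome, te_proteins, cutoff = NULL,
                               n_shuffles = 1000L, seed = 1L,
                               gap_opening = 11, gap_extension = 1) {
  if (length(te_proteins) == 0L) stop("TE protein library is empty")
  if (is.null(names(te_proteins))) {
    names(te_proteins) <- paste0("te_protein_", seq_along(te_proteins))
  }
  mat <- get_blosum62()
  rows <- list()
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    prot <- translate_cds(g, genome)
    if (!nzchar(prot)) {
      warning("empty translated CDS for ", g$transcript_id, "; skipped")
      next
    }
    cut_g <- if (is.null(cutoff)) {
      calibrate_homology_cutoff(prot, te_proteins, n_shuffles = n_shuffles,
                                seed = seed + gi,
                                gap_opening = gap_opening,
                                gap_extension = gap_extension)
    } else cutoff
    for (pi in seq_along(te_proteins)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(as.character(prot)),
        Biostrings::AAString(te_proteins[[pi]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = gap_opening, gapExtension = gap_extension)
      sc <- Biostrings::score(pa)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, transcript_id = g$transcript_id,
        te_protein_id = names(te_proteins)[pi], score = sc,
        cutoff = cut_g, percent_identity = Biostrings::pid(pa) / 100,
        flagged = sc >= cut_g,
        n_internal_stops = attr(prot, "n_internal_stops"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(), transcript_id = character(),
                      te_protein_id = character(), score = numeric(),
                      cutoff = numeric(), percent_identity = numeric(),
                      flagged = logical(), n_internal_stops = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$transcript_id, out$te_protein_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
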