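#' Configuration for the synthetic-genome generator
#'
#' The generator emulates the study inputs — a genome carrying implanted
#' hAT-like DNA transposons (8-bp TSDs, short TIRs, a transposase ORF with
#' DDE/RW residues), some copies truncated, and gene models whose CDS fully
#' contain some elements — together with RepeatMasker-style and GFF3
#' annotations and ground-truth tables.
#'
#' @param genome_length Chromosome length in bp (default 200000).
#' @param gc_content Background GC fraction (default 0.41, vertebrate-like).
#' @param n_autonomous Autonomous elements to implant.
#' @param n_truncated Truncated copies (TIRs/TSDs but no transposase ORF).
#' @param n_genes Total gene models.
#' @param n_misannotated_genes Genes whose single CDS fully contains an
#'   element; must be `<= min(n_genes, n_autonomous + n_truncated)`.
#' @param tsd_len TSD length (default 8, the hAT hallmark).
#' @param tir_len TIR length (default 15).
#' @param transposase_len_aa Transposase length in aa (default 600).
#' @param mutation_rate Per-site substitution probability applied to each
#'   inserted block after construction (default 0).
#' @param n_simple_repeats `(TA)n` simple-repeat tracts to implant
#'   (default 2); the first is placed inside a TE-free gene's CDS when
#'   possible, to exercise the screen's simple-repeat exclusion.
#' @param spliced Also add one two-exon gene whose intron boundary cuts
#'   across an element (default `FALSE`).
#' @param chrom_name Chromosome name (default `"chr1"`).
#' @param seed Integer seed; equal seeds give byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 200000L, gc_content = 0.41,
                       n_autonomous = 5L, n_truncated = 3L, n_genes = 10L,
                       n_misannotated_genes = 4L, tsd_len = 8L,
                       tir_len = 15L, transposase_len_aa = 600L,
                       mutation_rate = 0, n_simple_repeats = 2L,
                       spliced = FALSE, chrom_name = "chr1", seed = 1L) {
  stopifnot(n_autonomous >= 0L, n_truncated >= 0L, n_genes >= 0L,
            n_misannotated_genes >= 0L, tsd_len >= 1L, tir_len >= 1L,
            transposase_len_aa >= 10L, mutation_rate >= 0, mutation_rate < 1)
  if (n_misannotated_genes > min(n_genes, n_autonomous + n_truncated)) {
    stop("n_misannotated_genes exceeds min(n_genes, n_autonomous + n_truncated)")
  }
  structure(list(genome_length = as.integer(genome_length),
                 gc_content = gc_content,
                 n_autonomous = as.integer(n_autonomous),
                 n_truncated = as.integer(n_truncated),
                 n_genes = as.integer(n_genes),
                 n_misannotated_genes = as.integer(n_misannotated_genes),
                 tsd_len = as.integer(tsd_len), tir_len = as.integer(tir_len),
                 transposase_len_aa = as.integer(transposase_len_aa),
                 mutation_rate = mutation_rate,
                 n_simple_repeats = as.integer(n_simple_repeats),
                 spliced = spliced, chrom_name = chrom_name,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## i.i.d. background sequence at a given GC content (uses current stream)
random_dna <- function(n, gc = 0.41) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

## random DNA resampled until its Shannon entropy clears the detector's
## low-complexity guard with margin (truth features must be detectable)
random_dna_complex <- function(n, gc = 0.41, min_entropy = 1.2) {
  for (i in 1:100) {
    s <- random_dna(n, gc)
    if (seq_entropy(s) >= min_entropy) return(s)
  }
  stop("could not draw a non-degenerate sequence of length ", n)
}

#' Apply uniform point mutations to a sequence
#'
#' Each site is independently substituted to a different base with
#' probability `rate`.
#'
#' @param seq Nucleotide string.
#' @param rate Substitution probability per site, in `[0, 1)` (1 is also
#'   accepted and forces a substitution at every site).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0 || !nzchar(seq)) return(seq)
  doit <- function() {
    ch <- strsplit(seq, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
    paste0(ch, collapse = "")
  }
  if (is.null(seed)) doit() else with_local_seed(seed, doit())
}

## encode a protein as DNA, sampling synonymous codons from the current
## stream; appends a TAA stop
encode_protein <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    if (a == "M") "ATG" else if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste0(paste0(codons, collapse = ""), "TAA")
}

## random protein with marked catalytic residues; starts with M
random_transposase <- function(len_aa) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p <- c("M", sample(aa20, len_aa - 1L, replace = TRUE))
  pos <- as.integer(round(len_aa * c(D1 = 0.30, D2 = 0.42, E = 0.63,
                                     R = 0.72, W = 0.85)))
  names(pos) <- c("D1", "D2", "E", "R", "W")
  letters5 <- c(D1 = "D", D2 = "D", E = "E", R = "R", W = "W")
  for (k in names(pos)) p[pos[[k]] + 1L] <- letters5[[k]]
  list(protein = paste0(p, collapse = ""), positions = pos)
}

## non-overlapping placement of blocks with margins; returns start positions
place_blocks <- function(lengths, genome_length, margin = 200L,
                         edge = 1100L, max_tries = 2000L) {
  occupied <- matrix(numeric(0), ncol = 2)
  starts <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(genome_length - lengths[i] - 2L * edge, 1L) + edge
      lo <- s - margin; hi <- s + lengths[i] + margin
      if (nrow(occupied) == 0L ||
          all(hi <= occupied[, 1] | lo >= occupied[, 2])) {
        occupied <- rbind(occupied, c(lo, hi))
        starts[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place all features without overlap; ",
           "increase genome_length")
    }
  }
  starts
}

#' Generate a synthetic genome with implanted hAT-like elements
#'
#' Builds an i.i.d. background chromosome, implants autonomous and
#' truncated hAT-like elements as `[TSD][TIR]core[revcomp(TIR)][TSD]` with
#' identical TSD copies (autonomous cores carry an ATG-initiated
#' transposase ORF with recorded D, D, E, R, W positions), applies point
#' mutations at `mutation_rate`, and builds gene models — some whose
#' single CDS strictly contains an element (frame-compatible with the
#' transposase ORF where one exists), the rest TE-free coding genes.
#' Everything is deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `repeats.out`, `genes.gff3`, `truth_elements.tsv`, `truth_genes.tsv`,
#'   `transposase.fa` and `transposase_positions.json`.
#' @return List: `genome` (named character), `repeats` (RepeatMasker-style
#'   `data.frame`), `genes` (list of [gene_model()]), `truth_elements`,
#'   `truth_genes` (`data.frame`s), `reference`
#'   (a [transposase_reference()]), `te_proteins` (named character),
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(is(config, "sim_config"))
  res <- with_local_seed(config$seed, simulate_genome_impl(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$genome, file.path(out_dir, "genome.fa"))
    write_repeatmasker_out(res$repeats, file.path(out_dir, "repeats.out"),
                           seq_lengths = setNames(nchar(res$genome),
                                                  names(res$genome)))
    write_gff3_genes(res$genes, file.path(out_dir, "genes.gff3"))
    write_report(res$truth_elements, file.path(out_dir, "truth_elements.tsv"))
    write_report(res$truth_genes, file.path(out_dir, "truth_genes.tsv"))
    write_fasta(res$te_proteins, file.path(out_dir, "transposase.fa"))
    jsonlite::write_json(as.list(res$reference$positions),
                         file.path(out_dir, "transposase_positions.json"),
                         auto_unbox = TRUE)
  }
  res
}

simulate_genome_impl <- function(config) {
  chrom <- config$chrom_name
  tirL <- config$tir_len
  tsdL <- config$tsd_len

  ## family-level features shared by all copies
  tir_seq <- random_dna_complex(tirL, config$gc_content)
  tp <- random_transposase(config$transposase_len_aa)
  orf_dna <- encode_protein(tp$protein)
  reference <- transposase_reference(tp$protein, tp$positions,
                                     id = "hATSYN1_transposase")

  build_element <- function(kind) {
    pad5 <- random_dna(30L, config$gc_content)
    core <- if (kind == "autonomous") {
      paste0(pad5, orf_dna, random_dna(30L, config$gc_content))
    } else {
      random_dna(400L, config$gc_content)
    }
    ## make the first five inward base pairs non-complementary so no
    ## extended TIR candidate can outscore or tie the implanted one under
    ## the detector's mismatch budget: the implanted TIR length is
    ## unambiguous truth
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    core_ch <- strsplit(core, "")[[1]]
    nc <- length(core_ch)
    for (i in 1:5) {
      if (core_ch[nc + 1L - i] == comp[[core_ch[i]]]) {
        core_ch[nc + 1L - i] <- sample(setdiff(c("A", "C", "G", "T"),
                                               comp[[core_ch[i]]]), 1L)
      }
    }
    core <- paste0(core_ch, collapse = "")
    paste0(tir_seq, core, revcomp(tir_seq))
  }

  n_elem <- config$n_autonomous + config$n_truncated
  kinds <- c(rep("autonomous", config$n_autonomous),
             rep("truncated", config$n_truncated))
  elem_ids <- c(sprintf("auto_%d", seq_len(config$n_autonomous)),
                sprintf("trunc_%d", seq_len(config$n_truncated)))
  strands <- if (n_elem) sample(c("+", "-"), n_elem, replace = TRUE) else character()

  elements <- lapply(seq_len(n_elem), function(i) {
    el <- build_element(kinds[i])
    tsd <- random_dna_complex(tsdL, config$gc_content)
    ## ORF coordinates within the element (forward orientation)
    orf_s <- if (kinds[i] == "autonomous") tirL + 30L else NA_integer_
    orf_e <- if (kinds[i] == "autonomous") orf_s + nchar(orf_dna) else NA_integer_
    if (strands[i] == "-") {
      n <- nchar(el)
      el <- revcomp(el)
      if (!is.na(orf_s)) {
        tmp <- orf_s
        orf_s <- n - orf_e
        orf_e <- n - tmp
      }
    }
    block <- paste0(tsd, el, tsd)
    mutated <- mutate_sequence(block, config$mutation_rate)
    ## realized divergence over the element span only
    bc <- strsplit(block, "")[[1]]
    mc <- strsplit(mutated, "")[[1]]
    span <- (tsdL + 1L):(tsdL + nchar(el))
    div <- 100 * sum(bc[span] != mc[span]) / nchar(el)
    list(id = elem_ids[i], kind = kinds[i], strand = strands[i],
         block = mutated, elem_len = nchar(el), tsd_planted = tsd,
         orf_s = orf_s, orf_e = orf_e, divergence = div)
  })

  ## TE-free genes (coding blocks of their own)
  n_free <- config$n_genes - config$n_misannotated_genes
  free_genes <- lapply(seq_len(n_free), function(i) {
    len_aa <- sample(250:400, 1L)
    aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    prot <- paste0(c("M", sample(aa20, len_aa - 1L, replace = TRUE)),
                   collapse = "")
    list(id = sprintf("gene_free_%d", i), dna = encode_protein(prot),
         strand = sample(c("+", "-"), 1L))
  })

  ## simple repeats
  simple_len <- 60L
  n_simple <- config$n_simple_repeats
  simple_in_gene <- n_simple >= 1L && n_free >= 1L
  n_simple_bg <- n_simple - as.integer(simple_in_gene)

  ## spliced-decoy element (its own extra copy, crossed by an intron)
  spliced_elem <- if (config$spliced) {
    el <- build_element("autonomous")
    tsd <- random_dna_complex(tsdL, config$gc_content)
    list(id = "spliced_decoy", block = paste0(tsd, el, tsd),
         elem_len = nchar(el))
  } else NULL

  ## place everything
  lens <- c(vapply(elements, function(e) nchar(e$block), integer(1)),
            vapply(free_genes, function(g) nchar(g$dna), integer(1)),
            rep(simple_len, n_simple_bg),
            if (!is.null(spliced_elem)) nchar(spliced_elem$block) + 300L)
  starts <- place_blocks(lens, config$genome_length)

  genome_chars <- strsplit(random_dna(config$genome_length,
                                      config$gc_content), "")[[1]]
  paste_block <- function(s0, block) {
    genome_chars[(s0 + 1L):(s0 + nchar(block))] <<- strsplit(block, "")[[1]]
  }

  idx <- 0L
  for (e in elements) {
    idx <- idx + 1L
    e$pos <- starts[idx]
    paste_block(e$pos, e$block)
    elements[[idx]] <- e
  }
  for (j in seq_len(n_free)) {
    idx <- idx + 1L
    g <- free_genes[[j]]
    g$pos <- starts[idx]
    block <- if (g$strand == "-") revcomp(g$dna) else g$dna
    paste_block(g$pos, block)
    free_genes[[j]] <- g
  }
  simple_positions <- integer(0)
  for (j in seq_len(n_simple_bg)) {
    idx <- idx + 1L
    paste_block(starts[idx], strrep("TA", simple_len / 2L))
    simple_positions <- c(simple_positions, starts[idx])
  }
  if (!is.null(spliced_elem)) {
    idx <- idx + 1L
    spliced_elem$pos <- starts[idx] + 150L
    paste_block(spliced_elem$pos, spliced_elem$block)
  }
  ## simple repeat inside the first TE-free gene's CDS
  if (simple_in_gene) {
    g <- free_genes[[1]]
    off <- g$pos + 90L
    paste_block(off, strrep("TA", simple_len / 2L))
    simple_positions <- c(simple_positions, off)
  }

  genome <- setNames(paste0(genome_chars, collapse = ""), chrom)

  ## gene models
  genes <- list()
  gene_truth <- list()
  host_idx <- if (n_elem && config$n_misannotated_genes > 0L) {
    sample(seq_len(n_elem), config$n_misannotated_genes)
  } else integer(0)
  for (k in seq_along(host_idx)) {
    e <- elements[[host_idx[k]]]
    el_s <- e$pos + tsdL            # genomic element start
    el_e <- el_s + e$elem_len
    gid <- sprintf("gene_mis_%d", k)
    pad_l <- sample(12:48, 1L)
    pad_r <- sample(12:48, 1L)
    if (e$kind == "autonomous") {
      orf_gs <- el_s + e$orf_s
      orf_ge <- el_s + e$orf_e
      if (e$strand == "+") {
        ## frame anchor at CDS start: need cs == orf_gs (mod 3)
        pad_l <- pad_l + (el_s - pad_l - orf_gs) %% 3L
      } else {
        ## frame anchor at CDS end: need ce == orf_ge (mod 3)
        pad_r <- pad_r - (el_e + pad_r - orf_ge) %% 3L
      }
    }
    cs <- el_s - pad_l
    ce <- el_e + pad_r
    ## whole-codon CDS, trimmed on the side away from the frame anchor
    if (e$kind == "autonomous" && e$strand == "-") {
      cs <- cs + (ce - cs) %% 3L
    } else {
      ce <- ce - (ce - cs) %% 3L
    }
    genes[[gid]] <- gene_model(gid, paste0(gid, ".t1"), chrom, e$strand,
                               data.frame(start = cs, end = ce))
    gene_truth[[gid]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      contains_element = e$id, te_kind = e$kind,
      transposase_bearing = e$kind == "autonomous",
      spans_intron = FALSE, stringsAsFactors = FALSE)
    elements[[host_idx[k]]]$host_gene <- gid
  }
  for (j in seq_len(n_free)) {
    g <- free_genes[[j]]
    gid <- g$id
    genes[[gid]] <- gene_model(gid, paste0(gid, ".t1"), chrom, g$strand,
                               data.frame(start = g$pos,
                                          end = g$pos + nchar(g$dna)))
    gene_truth[[gid]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      contains_element = NA_character_, te_kind = NA_character_,
      transposase_bearing = FALSE, spans_intron = FALSE,
      stringsAsFactors = FALSE)
  }
  if (!is.null(spliced_elem)) {
    el_s <- spliced_elem$pos + tsdL
    el_e <- el_s + spliced_elem$elem_len
    gid <- "gene_spliced_1"
    ## exon 1 ends inside the element; exon 2 starts after it
    cds <- data.frame(start = c(el_s - 60L, el_e + 21L),
                      end = c(el_s + 30L, el_e + 81L))
    genes[[gid]] <- gene_model(gid, paste0(gid, ".t1"), chrom, "+", cds)
    gene_truth[[gid]] <- data.frame(
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      contains_element = NA_character_, te_kind = NA_character_,
      transposase_bearing = FALSE, spans_intron = TRUE,
      stringsAsFactors = FALSE)
  }

  ## repeat annotations (.out-style table)
  rep_rows <- lapply(seq_along(elements), function(i) {
    e <- elements[[i]]
    el_s <- e$pos + tsdL
    data.frame(seq_id = chrom, start = el_s, end = el_s + e$elem_len,
               strand = e$strand, repeat_name = "hAT-SYN1",
               repeat_class = "DNA/hAT", divergence_pct = round(e$divergence, 1),
               score = 2000, record_id = as.character(i), overlapped = FALSE,
               stringsAsFactors = FALSE)
  })
  nrec <- length(rep_rows)
  if (!is.null(spliced_elem)) {
    nrec <- nrec + 1L
    el_s <- spliced_elem$pos + tsdL
    rep_rows[[nrec]] <- data.frame(
      seq_id = chrom, start = el_s, end = el_s + spliced_elem$elem_len,
      strand = "+", repeat_name = "hAT-SYN1", repeat_class = "DNA/hAT",
      divergence_pct = 0, score = 2000, record_id = as.character(nrec),
      overlapped = FALSE, stringsAsFactors = FALSE)
  }
  for (sp in simple_positions) {
    nrec <- nrec + 1L
    rep_rows[[nrec]] <- data.frame(
      seq_id = chrom, start = sp, end = sp + simple_len, strand = "+",
      repeat_name = "(TA)n", repeat_class = "Simple_repeat",
      divergence_pct = 0, score = 20, record_id = as.character(nrec),
      overlapped = FALSE, stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, rep_rows)
  repeats <- repeats[order(repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL

  ## element truth table
  truth_elements <- do.call(rbind, lapply(elements, function(e) {
    el_s <- e$pos + tsdL
    el_e <- el_s + e$elem_len
    data.frame(
      element_id = e$id, seq_id = chrom, start = el_s, end = el_e,
      strand = e$strand, kind = e$kind,
      tsd_left_start = e$pos, tsd_right_start = el_e,
      tsd_seq = substr(genome[[1]], e$pos + 1L, e$pos + tsdL),
      tir5_start = el_s, tir5_end = el_s + tirL,
      tir3_start = el_e - tirL, tir3_end = el_e,
      tir_seq = substr(genome[[1]], el_s + 1L, el_s + tirL),
      orf_start = if (is.na(e$orf_s)) NA_integer_ else el_s + e$orf_s,
      orf_end = if (is.na(e$orf_e)) NA_integer_ else el_s + e$orf_e,
      catalytic_positions = if (e$kind == "autonomous") {
        paste(sprintf("%s:%d", names(tp$positions), tp$positions),
              collapse = ",")
      } else NA_character_,
      host_gene_id = if (is.null(e$host_gene)) NA_character_ else e$host_gene,
      divergence_pct = round(e$divergence, 4),
      stringsAsFactors = FALSE)
  }))
  if (!is.null(truth_elements)) rownames(truth_elements) <- NULL

  truth_genes <- if (length(gene_truth)) {
    tg <- do.call(rbind, gene_truth)
    rownames(tg) <- NULL
    tg
  } else {
    data.frame(gene_id = character(), transcript_id = character(),
               contains_element = character(), te_kind = character(),
               transposase_bearing = logical(), spans_intron = logical(),
               stringsAsFactors = FALSE)
  }

  list(genome = genome, repeats = repeats, genes = unname(genes),
       truth_elements = truth_elements, truth_genes = truth_genes,
       reference = reference,
       te_proteins = setNames(tp$protein, reference$id),
       config = config)
}
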