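small_cfg <- function(seed, mutation_rate = 0, ...) {
  sim_config(genome_length = 120000, n_autonomous = 5, n_truncated = 3,
             n_genes = 6, n_misannotated_genes = 3,
             mutation_rate = mutation_rate, seed = seed, ...)
}

test_that("equal seeds give byte-identical output files; different seeds differ", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  simulate_genome(small_cfg(7), out_dir = d1)
  simulate_genome(small_cfg(7), out_dir = d2)
  simulate_genome(small_cfg(8), out_dir = d3)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                         unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("truth-table bookkeeping matches the configuration", {
  sim <- simulate_genome(small_cfg(7))
  expect_equal(nrow(sim$truth_elements), 8L)
  expect_equal(sum(sim$truth_elements$kind == "autonomous"), 5L)
  expect_equal(sum(sim$truth_elements$kind == "truncated"), 3L)
  expect_equal(length(sim$genes), 6L)
  expect_equal(sum(!is.na(sim$truth_genes$contains_element)), 3L)
  ## autonomous truth rows carry ORF coordinates and catalytic positions
  auto <- sim$truth_elements[sim$truth_elements$kind == "autonomous", ]
  expect_false(any(is.na(auto$orf_start)))
  expect_false(any(is.na(auto$catalytic_positions)))
  trunc <- sim$truth_elements[sim$truth_elements$kind == "truncated", ]
  expect_true(all(is.na(trunc$orf_start)))
})

test_that("implanted structure is present verbatim in the genome at mutation 0", {
  sim <- simulate_genome(small_cfg(19))
  g <- sim$genome[[1]]
  for (i in seq_len(nrow(sim$truth_elements))) {
    tr <- sim$truth_elements[i, ]
    tsd_l <- substr(g, tr$tsd_left_start + 1, tr$tsd_left_start + 8)
    tsd_r <- substr(g, tr$tsd_right_start + 1, tr$tsd_right_start + 8)
    expect_identical(tsd_l, tsd_r, info = tr$element_id)
    tir5 <- substr(g, tr$tir5_start + 1, tr$tir5_end)
    tir3 <- substr(g, tr$tir3_start + 1, tr$tir3_end)
    expect_identical(tir5, revcomp(tir3), info = tr$element_id)
  }
})

test_that("mutate_sequence honours its rate", {
  s <- random_dna_str(500)
  expect_identical(mutate_sequence(s, 0, seed = 1), s)
  m1 <- mutate_sequence(s, 1, seed = 2)
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))
  ## substitution count within 3 binomial sigma of the expectation
  s10k <- random_dna_str(10000)
  m <- mutate_sequence(s10k, 0.02, seed = 3)
  nmut <- sum(strsplit(m, "")[[1]] != strsplit(s10k, "")[[1]])
  expect_lt(abs(nmut - 200), 3 * sqrt(10000 * 0.02 * 0.98))
  ## deterministic per seed
  expect_identical(mutate_sequence(s, 0.1, seed = 9),
                   mutate_sequence(s, 0.1, seed = 9))
})

test_that("generated files re-parse cleanly and match the in-memory objects", {
  d <- withr::local_tempdir()
  sim <- simulate_genome(small_cfg(23), out_dir = d)
  expect_no_warning({
    genome <- read_fasta(file.path(d, "genome.fa"))
    reps <- read_repeatmasker_out(file.path(d, "repeats.out"))
    genes <- read_gff3_genes(file.path(d, "genes.gff3"))
  })
  expect_identical(genome, sim$genome)
  expect_equal(nrow(reps), nrow(sim$repeats))
  expect_equal(reps$start, sim$repeats$start)
  expect_equal(reps$repeat_class, sim$repeats$repeat_class)
  expect_length(genes, length(sim$genes))
})

test_that("the screen recovers exactly the truth set of misannotated genes", {
  for (seed in c(7, 23, 61)) {
    sim <- simulate_genome(small_cfg(seed))
    ev <- contained_overlaps(sim$repeats, sim$genes)
    truth <- sort(sim$truth_genes$gene_id[!is.na(sim$truth_genes$contains_element)])
    expect_identical(sort(unique(ev$gene_id)), truth, info = paste("seed", seed))
  }
})

test_that("a TE crossed by an intron is not reported at full containment", {
  sim <- simulate_genome(small_cfg(31, spliced = TRUE))
  ev <- contained_overlaps(sim$repeats, sim$genes)
  spliced_gene <- sim$truth_genes$gene_id[sim$truth_genes$spans_intron]
  expect_length(spliced_gene, 1L)
  expect_false(spliced_gene %in% ev$gene_id)
  ## it is picked up once the fraction requirement is relaxed far enough
  ev_loose <- contained_overlaps(sim$repeats, sim$genes,
                                 screen_config(min_te_fraction = 0.01))
  expect_true(spliced_gene %in% ev_loose$gene_id)
})

test_that("misannotation guards are honoured by the config validator", {
  expect_error(sim_config(n_genes = 2, n_autonomous = 1, n_truncated = 0,
                          n_misannotated_genes = 2), "exceeds")
  expect_error(sim_config(mutation_rate = 1), "mutation_rate")
})

test_that("curation recovers every unmutated implanted element", {
  sim <- simulate_genome(small_cfg(47))
  te <- sim$truth_elements
  out <- curate_loci(data.frame(seq_id = te$seq_id, start = te$start,
                                end = te$end, name = te$element_id),
                     sim$genome, sim$reference)
  ev <- out$evidence
  expect_identical(ev$verdict[te$kind == "autonomous"],
                   rep("autonomous", 5L))
  expect_false(any(ev$verdict[te$kind == "truncated"] == "autonomous"))
  expect_equal(ev$tir5_start, te$tir5_start)
  expect_equal(ev$tir3_end, te$tir3_end)
  expect_equal(ev$tsd_left_start, te$tsd_left_start)
  expect_equal(ev$tsd_right_start, te$tsd_right_start)
})
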