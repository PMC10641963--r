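simple_repeat_row <- function(seq_id, start, end, class = "DNA/hAT",
                              name = "te1", id = "1") {
  data.frame(seq_id = seq_id, start = start, end = end, strand = "+",
             repeat_name = name, repeat_class = class, divergence_pct = 1,
             score = 1000, record_id = id, overlapped = FALSE,
             stringsAsFactors = FALSE)
}

one_gene <- function(start, end, seq_id = "chr1", id = "g1") {
  gene_model(id, paste0(id, ".t1"), seq_id, "+",
             data.frame(start = start, end = end))
}

test_that("full containment is reported and boundary-crossers are not", {
  g <- list(one_gene(0, 100))
  ev <- contained_overlaps(simple_repeat_row("chr1", 10, 20), g)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$te_fraction, 1.0)
  expect_equal(ev$overlap_bp, 10L)

  ev2 <- contained_overlaps(simple_repeat_row("chr1", 90, 110), g)
  expect_equal(nrow(ev2), 0L)
  ## the same crosser is reported at half coverage
  ev3 <- contained_overlaps(simple_repeat_row("chr1", 90, 110), g,
                            screen_config(min_te_fraction = 0.5))
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$te_fraction, 0.5)
})

test_that("simple repeats are excluded by default but kept on request", {
  g <- list(one_gene(0, 100))
  r <- simple_repeat_row("chr1", 10, 20, class = "Simple_repeat")
  expect_equal(nrow(contained_overlaps(r, g)), 0L)
  cfg <- screen_config(exclude_simple_repeats = FALSE)
  expect_equal(nrow(contained_overlaps(r, g, cfg)), 1L)
})

test_that("empty inputs yield empty results, not errors", {
  expect_equal(nrow(contained_overlaps(simple_repeat_row("chr1", 1, 5),
                                       list())), 0L)
  r0 <- simple_repeat_row("chr1", 1, 5)[0, ]
  expect_equal(nrow(contained_overlaps(r0, list(one_gene(0, 100)))), 0L)
})

test_that("indexed intersection matches the all-pairs oracle on random instances", {
  set.seed(20240501)
  for (rep in 1:10) {
    reps <- random_repeats(200)
    genes <- random_genes(25)
    for (f in c(1.00, 0.5)) {
      cfg <- screen_config(min_te_fraction = f)
      got <- contained_overlaps(reps, genes, cfg)
      want <- oracle_contained_overlaps(reps, genes, min_frac = f)
      expect_identical(event_key(got), event_key(want),
                       info = sprintf("rep %d f=%.2f", rep, f))
    }
  }
})

test_that("lowering the containment fraction never removes events", {
  set.seed(99)
  reps <- random_repeats(300)
  genes <- random_genes(30)
  strict <- contained_overlaps(reps, genes, screen_config(1.00))
  loose <- contained_overlaps(reps, genes, screen_config(0.5))
  expect_true(all(event_key(strict) %in% event_key(loose)))
})

test_that("every emitted event satisfies its fraction invariant from raw coordinates", {
  set.seed(123)
  reps <- random_repeats(300)
  genes <- random_genes(30)
  ev <- contained_overlaps(reps, genes, screen_config(0.5))
  recomputed <- (pmin(ev$te_end, ev$cds_end) - pmax(ev$te_start, ev$cds_start)) /
    (ev$te_end - ev$te_start)
  expect_equal(ev$te_fraction, recomputed)
  expect_true(all(ev$overlap_bp > 0))
  expect_true(all(ev$te_fraction >= 0.5))
})

test_that("class summary partitions the event list and rolls up to class 1/2", {
  ev3 <- do.call(rbind, lapply(1:3, function(i) {
    contained_overlaps(simple_repeat_row("chr1", 10 * i, 10 * i + 5,
                                         name = paste0("hAT", i),
                                         id = as.character(i)),
                       list(one_gene(0, 100)))
  }))
  s <- summarize_by_class(ev3)
  expect_equal(s$repeat_class, "DNA/hAT")
  expect_equal(s$n_events, 3L)
  expect_equal(attr(s, "rollup")$category, "class2")
  expect_equal(attr(s, "rollup")$n_events, 3L)

  expect_equal(nrow(summarize_by_class(ev3[0, ])), 0L)

  set.seed(5)
  reps <- random_repeats(400)
  genes <- random_genes(40)
  ev <- contained_overlaps(reps, genes, screen_config(0.5))
  s2 <- summarize_by_class(ev)
  expect_equal(sum(s2$n_events), nrow(ev))
  expect_equal(sum(attr(s2, "rollup")$n_events), nrow(ev))
})

test_that("class roll-up follows repeat taxonomy", {
  expect_equal(te_class_category(c("DNA/hAT", "RC/Helitron", "LINE/L1",
                                   "SINE/Alu", "LTR/Gypsy", "Satellite",
                                   "Unknown")),
               c("class2", "class2", "class1", "class1", "class1",
                 "other", "other"))
})

test_that("review sample keeps only repeats strictly longer than the cutoff, one per gene", {
  g <- list(one_gene(0, 5000))
  long_te <- contained_overlaps(simple_repeat_row("chr1", 100, 1300), g)
  exact_te <- contained_overlaps(simple_repeat_row("chr1", 100, 1100), g)
  expect_equal(nrow(select_review_sample(long_te, screen_config())), 1L)
  ## length exactly 1000 is excluded (strictly greater than)
  expect_equal(nrow(select_review_sample(exact_te, screen_config())), 0L)

  set.seed(77)
  reps <- random_repeats(300)
  reps$end <- reps$start + sample(500:2000, 300, replace = TRUE)
  genes <- random_genes(30)
  genes <- lapply(genes, function(g) {
    g$cds$end <- g$cds$end + 2000L  # widen so long TEs can be contained
    g
  })
  ev <- contained_overlaps(reps, genes)
  got <- select_review_sample(ev, screen_config())
  want <- ev[(ev$te_end - ev$te_start) > 1000L, ]
  want <- want[order(want$seq_id, want$te_start, want$repeat_name,
                     want$gene_id), ]
  want <- want[!duplicated(want$gene_id), ]
  expect_equal(got$gene_id, want$gene_id)
  expect_equal(got$te_start, want$te_start)
})

test_that("collapse_gene reports one event per repeat and gene", {
  g1 <- gene_model("g1", "g1.t1", "chr1", "+", data.frame(start = 0, end = 100))
  g2 <- gene_model("g1", "g1.t2", "chr1", "+", data.frame(start = 0, end = 120))
  r <- simple_repeat_row("chr1", 10, 20)
  expect_equal(nrow(contained_overlaps(r, list(g1, g2))), 2L)
  expect_equal(nrow(contained_overlaps(r, list(g1, g2),
                                       screen_config(collapse_gene = TRUE))), 1L)
})
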