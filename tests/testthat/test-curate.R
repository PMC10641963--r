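## brute-force TIR oracle: direct substring comparison over every
## (length, start offset, end offset) triple, same scoring and tie rules
oracle_find_tirs <- function(elem, cfg) {
  n <- nchar(elem)
  if (n < 2 * cfg$tir_min_len) return(NULL)
  W <- min(cfg$tir_search_window, n %/% 2)
  best <- NULL
  for (L in cfg$tir_min_len:min(cfg$tir_max_len, W)) {
    for (a in 0:(W - L)) {
      for (b in 0:(W - L)) {
        five <- substr(elem, a + 1, a + L)
        three <- substr(elem, n - b - L + 1, n - b)
        mm <- sum(strsplit(five, "")[[1]] !=
                    strsplit(revcomp(three), "")[[1]])
        if (mm > floor(L * cfg$tir_max_mismatch_frac)) next
        ent5 <- -sum(prop.table(table(strsplit(five, "")[[1]])) *
                       log2(prop.table(table(strsplit(five, "")[[1]]))))
        ent3 <- -sum(prop.table(table(strsplit(three, "")[[1]])) *
                       log2(prop.table(table(strsplit(three, "")[[1]]))))
        if (min(ent5, ent3) < cfg$min_entropy) next
        sc <- L - 2 * mm
        better <- is.null(best) || sc > best$score ||
          (sc == best$score && L > best$length) ||
          (sc == best$score && L == best$length && a < best$a) ||
          (sc == best$score && L == best$length && a == best$a && b < best$b)
        if (better) best <- list(a = a, b = b, length = L, mismatches = mm,
                                 score = sc, five_seq = five,
                                 three_seq = three)
      }
    }
  }
  best
}

test_that("flank extension returns the right window and clips at chromosome ends", {
  genome <- c(chrA = random_dna_str(10000))
  cfg <- curation_config(flank_bp = 1000)
  fl <- extend_flanks(genomic_interval("chrA", 1000, 2000), genome, cfg)
  expect_equal(nchar(fl$seq), 3000L)
  expect_equal(fl$element_local, c(1000L, 2000L))
  expect_equal(fl$offset, 0L)

  fl2 <- extend_flanks(genomic_interval("chrA", 300, 900), genome, cfg)
  expect_equal(fl2$offset, 0L)
  expect_equal(fl2$element_local, c(300L, 900L))
  expect_equal(nchar(fl2$seq), 1900L)

  expect_error(extend_flanks(genomic_interval("chrZ", 0, 10), genome, cfg),
               "not found")
})

test_that("the local-to-genomic offset map round-trips every position", {
  set.seed(55)
  genome <- c(chrA = random_dna_str(20000))
  cfg <- curation_config(flank_bp = 1000)
  for (i in 1:20) {
    s <- sample.int(19000, 1); e <- s + sample(50:800, 1)
    fl <- extend_flanks(genomic_interval("chrA", s, e), genome, cfg)
    loc <- sample.int(nchar(fl$seq), 25)
    expect_identical(substring(fl$seq, loc, loc),
                     substring(genome[["chrA"]], loc + fl$offset,
                               loc + fl$offset))
  }
})

test_that("an exact 10 bp TIR at the element ends is recovered", {
  tir <- "CAGTGCCAAA"
  set.seed(3)
  core <- paste0("CCC", random_dna_str(60), "CCC")
  elem <- paste0(tir, core, revcomp(tir))
  got <- find_tirs(elem, c(0L, nchar(elem)), curation_config())
  expect_equal(got$five_seq, tir)
  expect_equal(got$three_seq, revcomp(tir))
  expect_equal(got$length, 10L)
  expect_equal(got$mismatches, 0L)
  expect_equal(got$five_start, 0L)
  expect_equal(got$three_end, nchar(elem))
})

test_that("degenerate poly-A elements yield no TIR call", {
  elem <- strrep("A", 200)
  expect_null(find_tirs(elem, c(0L, 200L), curation_config()))
  expect_message(
    expect_null(find_tirs("ACGTACGTACGTACG", c(0L, 15L), curation_config())),
    "too short")
})

test_that("the TIR search agrees with an exhaustive brute-force oracle", {
  cfg <- curation_config(tir_min_len = 8, tir_max_len = 16,
                         tir_search_window = 25)
  set.seed(606)
  for (i in 1:30) {
    elem <- if (i %% 2 == 0) {
      tir <- random_dna_str(12)
      body <- random_dna_str(150)
      mut <- strsplit(revcomp(tir), "")[[1]]
      if (i %% 4 == 0) mut[5] <- setdiff(c("A", "C", "G", "T"), mut[5])[1]
      paste0(tir, body, paste0(mut, collapse = ""))
    } else {
      random_dna_str(180)
    }
    got <- find_tirs(elem, c(0L, nchar(elem)), cfg)
    want <- oracle_find_tirs(elem, cfg)
    if (is.null(want)) {
      expect_null(got, info = paste("case", i))
    } else {
      expect_equal(got$five_seq, want$five_seq, info = paste("case", i))
      expect_equal(got$three_seq, want$three_seq, info = paste("case", i))
      expect_equal(got$mismatches, want$mismatches, info = paste("case", i))
      expect_equal(got$five_start, want$a, info = paste("case", i))
    }
  }
})

test_that("an abutting 8 bp TSD is recovered exactly", {
  set.seed(8)
  tsd <- "ACGTTAGC"
  elem <- paste0(tsd, random_dna_str(120), tsd)
  local <- paste0(random_dna_str(40), elem, random_dna_str(40))
  el <- c(48L, 48L + 120L)  # element proper: between the two TSD copies
  got <- find_tsds(local, el, tir = NULL, curation_config())
  expect_equal(got$seq_left, tsd)
  expect_equal(got$seq_right, tsd)
  expect_equal(got$mismatches, 0L)
  expect_equal(got$left_start, 40L)
  expect_equal(got$right_start, 168L)
  expect_equal(got$gap_left + got$gap_right, 0L)
})

test_that("unrelated random flanks almost never produce a zero-mismatch TSD", {
  set.seed(9090)
  cfg <- curation_config()
  hits <- 0L
  n_trials <- 1000L
  for (i in seq_len(n_trials)) {
    local <- random_dna_str(140)
    if (!is.null(find_tsds(local, c(50L, 90L), NULL, cfg))) hits <- hits + 1L
  }
  ## 20 bp windows give ~169 candidate pairs x 4^-8 chance each (~0.3%)
  expect_lt(hits / n_trials, 0.02)
})

test_that("the verdict rule is the stated conjunction", {
  cfg <- curation_config()
  tir <- list(length = 15)
  tsd <- list(seq_left = "ACGTACGT")
  orf <- list(protein = strrep("M", 400))
  short_orf <- list(protein = strrep("M", 100))
  motif5 <- list(n_found = 5L)
  motif2 <- list(n_found = 2L)
  motif3 <- list(n_found = 3L)
  expect_equal(classify_element(tir, tsd, orf, motif5, cfg), "autonomous")
  expect_equal(classify_element(tir, NULL, orf, motif5, cfg),
               "partial_non_autonomous")
  expect_equal(classify_element(tir, tsd, short_orf, motif5, cfg),
               "partial_non_autonomous")
  expect_equal(classify_element(tir, tsd, orf, motif2, cfg),
               "partial_non_autonomous")
  expect_equal(classify_element(NULL, NULL, orf, motif3, cfg),
               "partial_non_autonomous")
  expect_equal(classify_element(NULL, NULL, orf, motif2, cfg), "not_te")
  expect_equal(classify_element(NULL, NULL, NULL, NULL, cfg), "not_te")
})

test_that("curation results satisfy the verdict biconditional independently of the classifier", {
  sim <- simulate_genome(sim_config(genome_length = 120000, n_autonomous = 4,
                                    n_truncated = 3, n_genes = 4,
                                    n_misannotated_genes = 2, seed = 61))
  te <- sim$truth_elements
  out <- curate_loci(data.frame(seq_id = te$seq_id, start = te$start,
                                end = te$end, name = te$element_id),
                     sim$genome, sim$reference)
  cfg <- curation_config()
  for (r in out$results) {
    expected_auto <- !is.null(r$tir) && !is.null(r$tsd) && !is.null(r$orf) &&
      nchar(r$orf$protein) >= cfg$orf_min_aa &&
      !is.null(r$motif) && r$motif$n_found == 5L
    expect_equal(r$verdict == "autonomous", expected_auto,
                 info = r$element_id)
  }
})

test_that("TIR conservation reports consensus and ties as ambiguity codes", {
  p <- function(s) list(five_seq = s, three_seq = revcomp(s))
  same <- tir_conservation(list(p("ACGTACGTAC"), p("ACGTACGTAC")))
  expect_equal(paste0(same$consensus, collapse = ""), "ACGTACGTAC")
  expect_true(all(same$majority_freq == 1))

  mixed <- tir_conservation(list(p("ACGT"), p("ACGA")))
  expect_equal(paste0(mixed$consensus, collapse = ""), "ACGW")
  expect_equal(mixed$majority_freq[4], 0.5)

  expect_error(tir_conservation(list(p("ACGT"))), "at least 2")
})

test_that("per-column majority frequency tracks the simulated mutation rate", {
  set.seed(404)
  base <- random_dna_str(20)
  mu <- 0.1
  fam <- lapply(1:40, function(i) {
    list(five_seq = mutate_sequence(base, mu),
         three_seq = revcomp(mutate_sequence(base, mu)))
  })
  cons <- tir_conservation(fam)
  ## each column keeps the ancestral base w.p. 1 - mu
  expect_lt(abs(mean(cons$majority_freq) - (1 - mu)), 0.04)
})

test_that("pairwise identity matches hand-computed values and gap rules", {
  m <- pairwise_identity_matrix(c(a = "AAAA", b = "AAAT"))
  expect_equal(m["a", "b"], 75.0)
  expect_equal(diag(m), c(a = 100, b = 100))
  expect_equal(m, t(m))

  g <- pairwise_identity_matrix(c(x = "A-CG", y = "ATCG"))
  expect_equal(g["x", "y"], 100.0)  # 3 ungapped columns, all matching

  expect_equal(pairwise_identity_matrix(c("ACGT", "ACGT"))[1, 2], 100.0)
  expect_error(pairwise_identity_matrix(c("ACGT", "ACG")), "equal length")
  expect_error(pairwise_identity_matrix("ACGT"), "at least 2")
})
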