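# Synthetic-data generator: determinism, the mutation clock's binomial
# behaviour, truth-record consistency, and the background generator.

test_that("the synthetic consensus set is deterministic and well-formed", {
  a <- synthetic_consensus_set(); b <- synthetic_consensus_set()
  expect_identical(a$sequences, b$sequences)
  expect_identical(length(a$sequences), 12L)
  expect_true(all(nchar(a$sequences) == 290L))
  # generation does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(3)
  set.seed(99); invisible(synthetic_consensus_set()); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("cohort generation is reproducible given the seed", {
  cfg <- simulation_config(seed = 7, n_per_class = 2L)
  a <- simulate_cohort(the_registry, cfg)
  b <- simulate_cohort(the_registry, cfg)
  expect_identical(vapply(a$observations, `[[`, character(1), "filled_seq"),
                   vapply(b$observations, `[[`, character(1), "filled_seq"))
  expect_identical(a$truth, b$truth)
  c1 <- simulate_study_cohort(the_registry, seed = 3)
  c2 <- simulate_study_cohort(the_registry, seed = 3)
  expect_identical(vapply(c1$observations, `[[`, character(1), "filled_seq"),
                   vapply(c2$observations, `[[`, character(1), "filled_seq"))
})

test_that("the mutation clock matches its binomial expectation per site class", {
  set.seed(52)
  cons <- the_registry$records[["AluSx"]]
  clock <- clock_parameters()
  T_My <- 30
  n_rep <- 300
  cpg <- numeric(n_rep); ncpg <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    m <- apply_mutation_clock(cons$seq, T_My, clock, cons$cpg_sites)
    cpg[i] <- m$n_cpg_subs; ncpg[i] <- m$n_noncpg_subs
  }
  n_cpg <- length(cons$cpg_sites); n_ncpg <- nchar(cons$seq) - n_cpg
  p_cpg <- clock$k_cpg * T_My * 1e6; p_ncpg <- clock$k_noncpg * T_My * 1e6
  se_cpg <- sqrt(n_cpg * p_cpg * (1 - p_cpg) / n_rep)
  se_ncpg <- sqrt(n_ncpg * p_ncpg * (1 - p_ncpg) / n_rep)
  expect_lt(abs(mean(cpg) - n_cpg * p_cpg), 3 * se_cpg)
  expect_lt(abs(mean(ncpg) - n_ncpg * p_ncpg), 3 * se_ncpg)
  # CpG events are the counted deamination transitions
  m <- apply_mutation_clock(cons$seq, 60, clock, cons$cpg_sites)
  ch0 <- strsplit(cons$seq, "")[[1]]; ch1 <- strsplit(m$seq, "")[[1]]
  for (p in m$cpg_positions_hit) {
    expect_true((ch0[p + 1] == "C" && ch1[p + 1] == "T") ||
                (ch0[p + 1] == "G" && ch1[p + 1] == "A"))
  }
})

test_that("truth records round-trip through the annotator at age zero", {
  set.seed(53)
  cfg <- simulation_config()
  x <- simulate_tprt_locus(the_registry, cfg, age_My = 0, tsd_len = 12,
                           polyA_len = 25, locus_id = "rt")
  sp <- compute_polymorphic_span(x$obs)
  ann <- annotate_insertion(x$obs, sp,
                            the_registry$records[[x$truth$subfamily]])
  expect_identical(ann$tsd$length, 12L)
  expect_identical(ann$polyA$length, 25L)
  expect_identical(ann$trunc_5p, x$truth$trunc_5p)
  expect_identical(ann$en_site$mismatches_to_consensus, x$truth$en_mismatches)
  expect_identical(classify_mechanism(sp, ann)$mechanism, "TPRT")

  # NCAI with the minimal 2 bp filler is still classified NCAI
  y <- simulate_ncai_locus(the_registry, cfg, filler_len = 2L,
                           target_site_deletion = 0L, locus_id = "minf")
  spy <- compute_polymorphic_span(y$obs)
  anny <- annotate_insertion(y$obs, spy,
                             the_registry$records[[y$truth$subfamily]])
  expect_identical(classify_mechanism(spy, anny)$mechanism, "NCAI")

  # NCAI with 21 bp filler and 14 bp target-site deletion is fully recovered
  z <- simulate_ncai_locus(the_registry, cfg, filler_len = 21L,
                           target_site_deletion = 14L, locus_id = "nc21")
  spz <- compute_polymorphic_span(z$obs)
  annz <- annotate_insertion(z$obs, spz,
                             the_registry$records[[z$truth$subfamily]])
  expect_identical(annz$non_alu_3p, 21L)
  expect_identical(annz$target_site_deletion, 14L)
  expect_identical(classify_mechanism(spz, annz)$mechanism, "NCAI")
})

test_that("background divergences honour their moments and the zero bound", {
  bg <- simulate_background_divergences(20000, mean = 13.2, sd = 4.2, seed = 9)
  expect_true(all(bg >= 0))
  expect_lt(abs(mean(bg) - 13.2) / 13.2, 0.01)
  expect_lt(abs(stats::sd(bg) - 4.2) / 4.2, 0.02)
  expect_identical(simulate_background_divergences(5, mean = 7, sd = 0, seed = 1),
                   rep(7, 5))
  # an observed mean far below the background gives p ~ 0
  p <- permutation_test(13.2 - 5 * 4.2, bg[1:10000], n = 7,
                        n_resamples = 1e4, seed = 2)
  expect_equal(p$p_value, 0)
})

test_that("cohort IO round-trips through FASTA + TSV", {
  cfg <- simulation_config(seed = 11, n_per_class = 1L)
  coh <- simulate_cohort(the_registry, cfg,
                         categories = "PARTIAL_INTERNAL+NONE")
  dir <- tempfile("cohort")
  paths <- write_cohort(coh, dir, seed = 11)
  back <- read_cohort(paths$fasta, bed = paths$bed, truth = paths$truth)
  expect_identical(length(back), length(coh$observations))
  ids <- vapply(back, `[[`, character(1), "locus_id")
  for (o in coh$observations) {
    r <- back[[which(ids == o$locus_id)]]
    expect_identical(r$filled_seq, o$filled_seq)
    expect_identical(r$empty_seq, o$empty_seq)
    expect_identical(r$annotated_alu, o$annotated_alu)
  }
  tr <- read_tsv_report(paths$truth)
  expect_identical(nrow(tr), nrow(coh$truth))
  expect_true(any(grepl("^# seed: 11", readLines(paths$truth))))
})
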