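# Polymorphic-span computation: placement normalization against a
# brute-force oracle, involution safety, and post-deletion categories.

# Oracle: enumerate all placements of the length-d segment and return the
# leftmost start q such that deleting filled[q, q+d) reproduces the empty
# allele.
oracle_leftmost_placement <- function(filled, empty) {
  d <- nchar(filled) - nchar(empty)
  for (q in 0:nchar(empty)) {
    if (paste0(substr(filled, 1, q),
               substr(filled, q + d + 1, nchar(filled))) == empty) return(q)
  }
  NA_integer_
}

test_that("a unique inserted segment is located exactly", {
  obs <- locus_observation("t", paste0(strrep("GTCA", 8), "GTTTGGACCT", strrep("CTGA", 8)),
                           paste0(strrep("GTCA", 8), strrep("CTGA", 8)))
  sp <- compute_polymorphic_span(obs, min_flank = 10)
  expect_identical(sp$interval, c(32L, 42L))
  expect_false(sp$left_shifted)
  expect_identical(sp$target_site_deletion, 0L)
})

test_that("repeat-context indels are left-shifted to the oracle placement", {
  # classic repeat-context deletion plus randomized cases
  f0 <- paste0(strrep("CT", 12), "TTGCAAAAGG", strrep("GA", 12))
  e0 <- paste0(strrep("CT", 12), "TTGAAGG", strrep("GA", 12))
  sp <- compute_polymorphic_span(locus_observation("x", f0, e0), min_flank = 10)
  expect_identical(sp$interval[1], 24L + oracle_leftmost_placement("TTGCAAAAGG", "TTGAAGG"))

  set.seed(21)
  for (i in 1:25) {
    L <- alupoly:::random_dna(30); R <- alupoly:::random_dna(30)
    unit <- alupoly:::random_dna(sample(1:4, 1))
    reps <- sample(2:5, 1)
    ins <- strrep(unit, sample(1:3, 1))
    filled <- paste0(L, strrep(unit, reps), ins, R)
    empty <- paste0(L, strrep(unit, reps), R)
    sp <- compute_polymorphic_span(locus_observation("r", filled, empty),
                                   min_flank = 5)
    expect_identical(sp$interval[1], oracle_leftmost_placement(filled, empty))
    expect_identical(sp$length, nchar(ins))
  }
})

test_that("span computation is involution-safe on simulated loci", {
  set.seed(22)
  cfg <- simulation_config()
  for (i in 1:6) {
    x <- simulate_tprt_locus(the_registry, cfg, age_My = 10, locus_id = "inv")
    sp <- compute_polymorphic_span(x$obs)
    f <- x$obs$filled_seq
    rebuilt <- paste0(substr(f, 1, sp$interval[1]),
                      substr(f, sp$interval[2] + 1, nchar(f)))
    expect_identical(rebuilt, x$obs$empty_seq)
  }
})

test_that("degenerate allele pairs are rejected with informative errors", {
  expect_error(compute_polymorphic_span(
    locus_observation("same", strrep("ACGT", 20), strrep("ACGT", 20))),
    "no polymorphism")
  # two disjoint differences sharing a long identical block -> complex
  Lf <- alupoly:::random_dna(40); Rf <- alupoly:::random_dna(40)
  core <- alupoly:::random_dna(30)
  filled <- paste0(Lf, "TTTTTTTT", core, "GGGGGGGG", Rf)
  empty <- paste0(Lf, core, Rf)
  expect_error(compute_polymorphic_span(locus_observation("cx", filled, empty),
                                        complex_kmer = 20),
               "complex")
  expect_error(compute_polymorphic_span(
    locus_observation("fl", paste0("ACGT", strrep("GGCC", 10)),
                      strrep("GGCC", 10)), min_flank = 20),
    "flank")
})

test_that("replacement loci report the target-site deletion", {
  L <- alupoly:::random_dna(40); R <- alupoly:::random_dna(40)
  ins <- paste0("G", alupoly:::random_dna(60), "C")
  del <- "TTACTTACTTACTT"  # 14 bp lost from the empty allele on insertion
  obs <- locus_observation("repl", paste0(L, ins, R), paste0(L, del, R))
  sp <- compute_polymorphic_span(obs)
  expect_identical(sp$target_site_deletion, 14L)
  expect_identical(sp$deleted_site_seq, del)
  expect_identical(sp$length, nchar(ins))
})

test_that("category assignment covers the two-axis product and the partition", {
  cases <- list(
    list(span = c(150, 250), alu = c(100, 300), cat = "PARTIAL_INTERNAL+NONE",
         cls = "deletion_candidate"),
    list(span = c(100, 250), alu = c(100, 300), cat = "PARTIAL_5P+NONE",
         cls = "deletion_candidate"),
    list(span = c(150, 300), alu = c(100, 300), cat = "PARTIAL_3P+NONE",
         cls = "deletion_candidate"),
    list(span = c(80, 250), alu = c(100, 300), cat = "PARTIAL_5P+FIVE_PRIME",
         cls = "deletion_candidate"),
    list(span = c(150, 340), alu = c(100, 300), cat = "PARTIAL_3P+THREE_PRIME",
         cls = "deletion_candidate"),
    list(span = c(100, 340), alu = c(100, 300), cat = "ENTIRE+THREE_PRIME",
         cls = "ambiguous_full_plus_flank"),
    list(span = c(80, 340), alu = c(100, 300), cat = "ENTIRE+BOTH",
         cls = "ambiguous_full_plus_flank"),
    list(span = c(80, 300), alu = c(100, 300), cat = "ENTIRE+FIVE_PRIME",
         cls = "ambiguous_full_plus_flank"),
    list(span = c(100, 300), alu = c(100, 300), cat = "ENTIRE+NONE",
         cls = "insertion_candidate"),
    list(span = c(10, 60), alu = c(100, 300), cat = "NONE+NONE",
         cls = "flank_only")
  )
  for (cs in cases) {
    sp <- make_span_stub("X", "X")
    sp$interval <- as.integer(cs$span); sp$length <- cs$span[2] - cs$span[1]
    sp <- alupoly:::overlay_alu(sp, as.integer(cs$alu))
    got <- assign_post_deletion_category(sp)
    expect_identical(got$category, cs$cat)
    expect_identical(got$class, cs$cls)
  }
})

test_that("full-Alu deletions including both flanks are ENTIRE+BOTH", {
  set.seed(23)
  cfg <- simulation_config()
  d <- simulate_deletion_locus(the_registry, cfg, category = "ENTIRE+BOTH",
                               tsd_len = 14, age_My = 0, locus_id = "eb")
  sp <- compute_polymorphic_span(d$obs)
  expect_identical(sp$alu_overlap, "ENTIRE")
  expect_identical(sp$flank_included, "BOTH")
  expect_true(all(sp$interval[1] < d$obs$annotated_alu[1],
                  sp$interval[2] > d$obs$annotated_alu[2]))
})
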