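# Insertion annotation: poly-A rule against an exhaustive suffix oracle, TSD
# arbitration against split enumeration, endonuclease windows, truncation
# arithmetic, and flank-extension invariance.

# Oracle: scan all suffixes for the longest one satisfying the poly-A rule.
oracle_polyA <- function(seq, min_len = 6, min_a_frac = 0.9, max_run = 1) {
  ch <- strsplit(seq, "")[[1]]; n <- length(ch)
  for (i in seq_len(n)) {
    suf <- ch[i:n]; len <- n - i + 1
    if (len < min_len) break
    if (suf[1] != "A" || suf[len] != "A") next
    if (mean(suf == "A") < min_a_frac) next
    runs <- rle(suf == "A")
    if (any(!runs$values & runs$lengths > max_run)) next
    return(as.integer(len))
  }
  0L
}

# Oracle: all TSD lengths k with suffix(flank5, k) == suffix(inserted, k);
# the rule reports the maximum.
oracle_tsd_len <- function(flank5, inserted, min_tsd = 6) {
  l5 <- nchar(flank5); li <- nchar(inserted)
  ks <- integer(0)
  for (k in min_tsd:min(l5, li - 1)) {
    if (substr(flank5, l5 - k + 1, l5) == substr(inserted, li - k + 1, li))
      ks <- c(ks, k)
  }
  if (length(ks)) max(ks) else 0L
}

test_that("poly-A detection matches the exhaustive suffix oracle", {
  cases <- c(
    paste0(alupoly:::random_dna(40), "GCC", strrep("A", 25)),
    paste0(alupoly:::random_dna(40), "GCC"),                        # no tail
    paste0(alupoly:::random_dna(40), "C", strrep("A", 10), "G", strrep("A", 12)),
    paste0(alupoly:::random_dna(40), "GG", strrep("A", 5)),         # too short
    paste0(alupoly:::random_dna(40), strrep("A", 8), "GG"),         # ends non-A
    paste0(alupoly:::random_dna(30), "AAGAAGAA")                    # A-frac too low
  )
  set.seed(31)
  cases <- c(cases, replicate(30, paste0(
    alupoly:::random_dna(30),
    paste(sample(c("A", "A", "A", "A", "G"), sample(6:30, 1), replace = TRUE),
          collapse = ""))))
  for (s in cases) {
    got <- detect_polyA(s)
    expect_identical(if (is.null(got)) 0L else got$length, oracle_polyA(s),
                     info = s)
  }
  # the spec'd interrupted tail: 10 A, one G, 12 A -> one 23 nt tail
  tail23 <- detect_polyA(paste0("GCCGCCGCC", strrep("A", 10), "G", strrep("A", 12)))
  expect_identical(tail23$length, 23L)
})

test_that("TSD detection maximizes length and matches the enumeration oracle", {
  set.seed(32)
  # plain duplication, tail not adjoining the flank copy
  S <- "GATCGATCGCGT"; body <- paste0("G", alupoly:::random_dna(150), "GC")
  L <- paste0(alupoly:::random_dna(60), "TT")
  R <- alupoly:::random_dna(60)
  I <- paste0(body, strrep("A", 20), S)
  tsd <- detect_tsd(paste0(L, S), I, R)
  expect_identical(tsd$length, 12L)
  expect_identical(tsd$seq, S)
  expect_identical(detect_polyA(substr(I, 1, nchar(I) - tsd$length))$length, 20L)

  # A-terminal flank: the 3 adenines 5' of the duplication are absorbed,
  # TSD grows by 3 and the reported tail shrinks by 3
  L3 <- paste0(alupoly:::random_dna(60), "TCAAA")
  tsd3 <- detect_tsd(paste0(L3, S), I, R)
  expect_identical(tsd3$length, 15L)
  expect_identical(tsd3$seq, paste0("AAA", S))
  expect_identical(detect_polyA(substr(I, 1, nchar(I) - tsd3$length))$length, 17L)
  expect_identical(tsd3$length, oracle_tsd_len(paste0(L3, S), I))

  # randomized agreement with the oracle
  for (i in 1:25) {
    k <- sample(8:16, 1)
    S <- paste0("C", alupoly:::random_dna(k - 2), "G")
    nA <- sample(0:4, 1)
    L <- paste0(alupoly:::random_dna(50), "T", strrep("A", nA))
    I <- paste0("G", alupoly:::random_dna(120), "GC", strrep("A", 22), S)
    R <- alupoly:::random_dna(50)
    got <- detect_tsd(paste0(L, S), I, R)
    want <- oracle_tsd_len(paste0(L, S), I)
    expect_identical(if (is.null(got)) 0L else got$length, want)
    if (!is.null(got)) {
      # maximization conserves tsd + tail: the nA absorbed adenines move
      # from the tail into the duplication
      tail_left <- detect_polyA(substr(I, 1, nchar(I) - got$length))
      expect_identical(got$length, k + nA)
      expect_identical(tail_left$length, 22L - nA)
    }
  }
})

test_that("TSD detection respects min length and flank preconditions", {
  S <- "CGATT"  # 5 bp: below the default minimum
  I <- paste0("G", alupoly:::random_dna(80), "C", S)
  expect_null(detect_tsd(paste0(alupoly:::random_dna(40), "T", S), I,
                         alupoly:::random_dna(40)))
  expect_null(detect_tsd("ACG", I, alupoly:::random_dna(40)))
})

test_that("endonuclease windows score mismatches to TTTT/AA position-wise", {
  mk <- function(top_window) {
    # top_window occupies empty[b-2, b+4); set b = 20
    paste0(alupoly:::random_dna(18), top_window, alupoly:::random_dna(18))
  }
  en <- score_en_site(mk("TTAAAA"), insertion_point = 20L, tsd_length = 0L)
  expect_identical(en$window_seq, "TTTTAA")
  expect_identical(en$mismatches_to_consensus, 0L)

  en <- score_en_site(mk(alupoly:::revcomp("GGGGCC")), 20L, 0L)
  expect_identical(en$window_seq, "GGGGCC")
  expect_identical(en$mismatches_to_consensus, 6L)

  en <- score_en_site(mk(alupoly:::revcomp("TTCTAA")), 20L, 0L)
  expect_identical(en$window_seq, "TTCTAA")
  expect_identical(en$mismatches_to_consensus, 1L)

  # the nick sits at the TSD 5' boundary
  en_tsd <- score_en_site(paste0(alupoly:::random_dna(18), "TTAAAA",
                                 alupoly:::random_dna(18)),
                          insertion_point = 30L, tsd_length = 10L)
  expect_identical(en_tsd$window_seq, "TTTTAA")

  # running off the edge pads with N, which counts as mismatch
  en_edge <- score_en_site("TTAAAA", insertion_point = 1L, tsd_length = 0L)
  expect_identical(en_edge$mismatches_to_consensus,
                   sum(strsplit(en_edge$window_seq, "")[[1]] != c("T","T","T","T","A","A")))
  expect_true(grepl("N", en_edge$window_seq))
})

test_that("truncation measurement does coordinate arithmetic on constructions", {
  cons <- the_registry$records[["AluSx"]]
  full <- measure_truncation(cons$seq, cons)
  expect_identical(c(full$trunc_5p, full$trunc_3p, full$non_alu_5p, full$non_alu_3p),
                   c(0L, 0L, 0L, 0L))

  cut50 <- measure_truncation(alupoly:::seq_slice(cons$seq, 50, nchar(cons$seq)), cons)
  expect_identical(c(cut50$trunc_5p, cut50$trunc_3p, cut50$non_alu_5p, cut50$non_alu_3p),
                   c(50L, 0L, 0L, 0L))

  # doubly truncated right-monomer fragment with 21 bp 3' filler
  frag <- alupoly:::seq_slice(cons$seq, 205, 282)
  nxt <- substr(cons$seq, 283, 283)
  filler <- "GTGTGTGTGTGTGTGTGTGTG"
  if (substr(filler, 1, 1) == nxt) filler <- paste0("C", substr(filler, 2, 21))
  tr <- measure_truncation(paste0(frag, filler), cons)
  expect_identical(tr$trunc_5p, 205L)
  expect_identical(tr$trunc_3p, 8L)
  expect_identical(tr$non_alu_3p, 21L)

  none <- measure_truncation(alupoly:::random_dna(120), cons, min_score = 25)
  expect_false(none$has_homology)
})

test_that("annotation is invariant to extending both flanks", {
  set.seed(33)
  cfg <- simulation_config()
  x <- simulate_tprt_locus(the_registry, cfg, age_My = 0, locus_id = "ext")
  sp <- compute_polymorphic_span(x$obs)
  cons <- the_registry$records[[x$truth$subfamily]]
  base <- annotate_insertion(x$obs, sp, cons)

  pad5 <- alupoly:::random_dna(80); pad3 <- alupoly:::random_dna(80)
  obs2 <- locus_observation("ext2", paste0(pad5, x$obs$filled_seq, pad3),
                            paste0(pad5, x$obs$empty_seq, pad3))
  sp2 <- compute_polymorphic_span(obs2)
  ext <- annotate_insertion(obs2, sp2, cons)
  expect_identical(ext$tsd$length, base$tsd$length)
  expect_identical(ext$tsd$seq, base$tsd$seq)
  expect_identical(ext$polyA$length, base$polyA$length)
  expect_identical(ext$en_site$window_seq, base$en_site$window_seq)
})
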