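# Divergence, CpG-aware counting, clock ages, and the permutation test
# (against an exact enumeration oracle).

test_that("identity gives zero divergence and full site counts", {
  cons <- the_registry$records[["AluSg"]]
  d <- percent_divergence(cons$seq, cons, element_id = "self")
  expect_equal(d$percent_divergence, 0)
  expect_identical(d$cpg_subs, 0L)
  expect_identical(d$noncpg_subs, 0L)
  expect_identical(d$cpg_sites, length(cons$cpg_sites))
  expect_identical(d$noncpg_sites, nchar(cons$seq) - length(cons$cpg_sites))
  expect_equal(d$age_cpg, 0)
  expect_equal(d$age_noncpg, 0)
  expect_false(d$low_confidence)
})

test_that("hand-counted substitutions give the exact divergence", {
  set.seed(41)
  cons <- the_registry$records[["AluSx"]]
  pool <- setdiff(10:280, c(cons$cpg_sites, cons$cpg_sites + 1L))
  pos <- sample(pool, 15)
  seq <- cons$seq
  for (p in pos) seq <- put(seq, p, alupoly:::alt_base(substr(seq, p + 1, p + 1)))
  d <- percent_divergence(seq, cons)
  expect_equal(d$percent_divergence, 100 * 15 / nchar(cons$seq), tolerance = 1e-9)
  expect_identical(d$noncpg_subs, 15L)
  expect_identical(d$cpg_subs, 0L)
})

test_that("CpG substitutions count only the deamination transitions", {
  cons <- the_registry$records[["AluSz"]]
  cs <- cons$cpg_sites
  c_sites <- cs[chars_at(cons$seq, cs) == "C"]
  seq <- put(cons$seq, c_sites[1], "T")   # C->T at a CpG: counted
  seq <- put(seq, c_sites[2], "A")        # C->A at a CpG: not counted
  aln <- alupoly:::align_pair(seq, cons$seq, type = "global-local")
  counts <- count_cpg_substitutions(aln, cons)
  expect_identical(unname(counts["cpg_subs"]), 1L)
  expect_identical(unname(counts["noncpg_subs"]), 0L)
  expect_identical(unname(counts["cpg_sites"]), length(cs))
  # divergence still sees both changed columns
  expect_equal(percent_divergence(seq, cons)$percent_divergence,
               100 * 2 / nchar(cons$seq), tolerance = 1e-9)

  # 9 transitions -> density 9 / cpg_sites
  seq9 <- cons$seq
  g_sites <- cs[chars_at(cons$seq, cs) == "G"]
  hit <- c(c_sites[1:5], g_sites[1:4])
  for (p in hit) seq9 <- put(seq9, p, if (p %in% c_sites) "T" else "A")
  d9 <- percent_divergence(seq9, cons)
  expect_equal(d9$cpg_subs / d9$cpg_sites, 9 / length(cs), tolerance = 1e-9)
})

test_that("age estimation is the closed form density / k and is linear", {
  expect_equal(unname(estimate_age(0, 0)), c(0, 0))
  a <- estimate_age(cpg_density = 0.09, noncpg_density = 0.03)
  expect_equal(unname(a["age_noncpg"]), 20)         # 0.03 / 1.5e-9 years
  expect_equal(unname(a["age_cpg"]), 10)            # 0.09 / 9e-9 years
  expect_equal(unname(estimate_age(0.18, 0.06)), 2 * unname(a))  # linearity
  clock <- clock_parameters()
  expect_equal(clock$k_cpg / clock$k_noncpg, 6)

  # doubling the substitutions on a fixture doubles both measured ages
  cons <- the_registry$records[["AluSc"]]
  cs <- cons$cpg_sites
  c_sites <- cs[chars_at(cons$seq, cs) == "C"]
  pool <- setdiff(10:280, c(cs, cs + 1L))
  s1 <- cons$seq; s2 <- cons$seq
  for (p in c_sites[1:4]) { s1 <- put(s1, p, "T"); s2 <- put(s2, p, "T") }
  for (p in c_sites[5:8]) s2 <- put(s2, p, "T")
  for (p in pool[1:6]) {
    b <- alupoly:::alt_base(substr(cons$seq, p + 1, p + 1))
    s1 <- put(s1, p, b); s2 <- put(s2, p, b)
  }
  for (p in pool[7:12]) {
    s2 <- put(s2, p, alupoly:::alt_base(substr(cons$seq, p + 1, p + 1)))
  }
  d1 <- percent_divergence(s1, cons); d2 <- percent_divergence(s2, cons)
  expect_equal(d2$age_cpg, 2 * d1$age_cpg, tolerance = 1e-9)
  expect_equal(d2$age_noncpg, 2 * d1$age_noncpg, tolerance = 1e-9)
})

test_that("permutation test matches exact enumeration and is reproducible", {
  expect_equal(permutation_test(0.5, background = c(1, 2, 3), n = 3,
                                n_resamples = 1000, seed = 4)$p_value, 0)
  # exact oracle: n = 1 from {1,2,3}: Pr(draw < 2.5) = 2/3
  p <- permutation_test(2.5, background = c(1, 2, 3), n = 1,
                        n_resamples = 1e5, seed = 4)
  se <- sqrt((2 / 3) * (1 / 3) / 1e5)
  expect_lt(abs(p$p_value - 2 / 3), 3 * se)
  p2 <- permutation_test(2.5, background = c(1, 2, 3), n = 1,
                         n_resamples = 1e5, seed = 4)
  expect_identical(p$p_value, p2$p_value)
  expect_error(permutation_test(1, background = c(1, 2), n = 2, n_resamples = 0),
               "n_resamples")
})

test_that("background tables parse in both dialects", {
  out <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching  repeat",
    "score   div. del. ins.  sequence  begin  end  (left)   repeat    class/family",
    "",
    "  463   11.2  0.3  0.8  chr1      10001  10300 (blah)  +  AluSx  SINE/Alu     1  290  (0)   1",
    "  512   13.9  0.1  0.2  chr1      20001  20290 (blah)  C  AluSg  SINE/Alu     1  290  (0)   2",
    "  101    5.0  0.0  0.0  chr1      30001  30290 (blah)  +  L1MA4  LINE/L1      1  290  (0)   3"
  ), out)
  div <- read_background_divergence(out)
  expect_equal(div, c(11.2, 13.9, 5.0))
  expect_equal(read_background_divergence(out, repeat_filter = "^AluS"),
               c(11.2, 13.9))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("12.5", "8.25", "14"), tsv)
  expect_equal(read_background_divergence(tsv), c(12.5, 8.25, 14))

  md <- tempfile(fileext = ".tsv")
  writeLines(c("milliDiv", "125", "89"), md)
  expect_equal(read_background_divergence(md), c(12.5, 8.9))
})
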