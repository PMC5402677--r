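# Insertion annotation: poly-A tail, target site duplication (with the
# tail-versus-TSD arbitration rule), L1 ORF2p endonuclease site, truncation
# extents and non-Alu sequence.

EN_CONSENSUS <- "TTTTAA"  # negative strand, 5'-TTTT/AA-3', "/" marks the nick

#' Poly-A rule parameters
#' @export
polyA_rule <- function(min_len = 6L, min_a_frac = 0.9, max_non_a_run = 1L) {
  list(min_len = as.integer(min_len), min_a_frac = min_a_frac,
       max_non_a_run = as.integer(max_non_a_run))
}

#' Detect a 3' poly-A tail
#'
#' The tail is the longest suffix that starts and ends with A, is at least
#' `min_len` long, has adenine fraction >= `min_a_frac`, and contains no run
#' of non-A bases longer than `max_non_a_run`.
#'
#' @param seq Inserted segment in element-forward orientation.
#' @param rule A [polyA_rule()].
#' @return `NULL` if no suffix qualifies, else a list with `interval`
#'   (0-based half-open on `seq`) and `length`.
#' @export
detect_polyA <- function(seq, rule = polyA_rule()) {
  n <- nchar(seq)
  if (n < rule$min_len) return(NULL)
  ch <- seq_chars(seq)
  if (ch[n] != "A") return(NULL)
  is_a <- ch == "A"
  # the suffix may not reach across any non-A run longer than max_non_a_run
  runs <- rle(is_a)
  run_end <- cumsum(runs$lengths)
  bad <- !runs$values & runs$lengths > rule$max_non_a_run
  first_ok <- if (any(bad)) run_end[max(which(bad))] + 1L else 1L
  lo <- max(1L, first_ok)
  hi <- n - rule$min_len + 1L
  if (lo > hi) return(NULL)
  a_from <- rev(cumsum(rev(is_a)))  # number of A in [i..n]
  for (i in lo:hi) {
    if (!is_a[i]) next               # a tail starts with A
    if (a_from[i] / (n - i + 1L) >= rule$min_a_frac) {
      return(list(interval = c(i - 1L, n), length = n - i + 1L))
    }
  }
  NULL
}

# Poly-A run anchored at the element's 3' boundary inside a
# deletion-candidate span: the longest prefix of the downstream window that
# satisfies the same rule as detect_polyA. Alignment ends fray on diverged
# elements, so the run may start up to `max_offset` bases after the matched
# end.
scan_internal_tail <- function(seq, start_pos, rule = polyA_rule(),
                               max_window = 60L, max_offset = 8L) {
  for (off in 0:max_offset) {
    sp <- start_pos + off
    win <- seq_slice(seq, sp, min(nchar(seq), sp + max_window))
    n <- nchar(win)
    if (n < rule$min_len) return(NULL)
    ch <- seq_chars(win)
    if (ch[1] != "A") next
    is_a <- ch == "A"
    a_cum <- cumsum(is_a)
    run <- 0L; best <- 0L
    for (i in seq_len(n)) {
      if (is_a[i]) run <- 0L else run <- run + 1L
      if (run > rule$max_non_a_run) break
      if (is_a[i] && i >= rule$min_len && a_cum[i] / i >= rule$min_a_frac) best <- i
    }
    if (best > 0L) return(list(interval = c(sp, sp + best), length = best))
  }
  NULL
}

#' Detect a target site duplication with tail arbitration
#'
#' At the rightmost equivalent placement of an insertion the filled allele
#' reads `flank5 · inserted · flank3` with the left duplication copy ending
#' `flank5` and the right copy ending `inserted` (the empty allele is exactly
#' `flank5 · flank3` and carries one copy). The TSD is the longest string
#' `S` (length >= `min_tsd`) that is simultaneously a suffix of `flank5` and
#' of `inserted`. When the element's poly-A tail abuts the right copy,
#' trailing adenines of the tail can be absorbed into a longer duplication
#' whenever the 5' flank also carries them — TSD length is maximized at the
#' expense of poly-A tail length. Strip the returned TSD from `inserted`
#' before measuring the tail.
#'
#' @param flank5,flank3 Filled-allele sequence 5'/3' of the inserted segment
#'   (rightmost placement).
#' @param inserted Inserted segment (element + tail + right TSD copy).
#' @param min_tsd Minimum TSD length.
#' @return `NULL` if no duplication qualifies (including the degenerate case
#'   of a 5' flank shorter than `min_tsd`), else a list with `seq` and
#'   `length`.
#' @export
detect_tsd <- function(flank5, inserted, flank3, min_tsd = 6L) {
  l5 <- nchar(flank5); li <- nchar(inserted)
  if (l5 < min_tsd) return(NULL)  # flank shorter than min_tsd
  kmax <- min(l5, li - 1L)
  if (kmax < min_tsd) return(NULL)
  for (k in kmax:min_tsd) {
    S <- substr(flank5, l5 - k + 1L, l5)
    if (S != substr(inserted, li - k + 1L, li)) next
    # the empty allele (flank5 + flank3) must hold exactly one copy at the site
    site <- paste0(substr(flank5, max(1L, l5 - 2L * k + 1L), l5),
                   substr(flank3, 1L, min(nchar(flank3), 2L * k)))
    hits <- gregexpr(S, site, fixed = TRUE)[[1]]
    if (hits[1] != -1 && length(hits) == 1L) {
      return(list(seq = S, length = k))
    }
  }
  NULL
}

#' Score the L1 ORF2p endonuclease site at an insertion point
#'
#' Extracts the 6-nt negative-strand window across the inferred nick — the
#' TSD's 5' boundary — and counts mismatches to the published consensus
#' 5'-TTTT/AA-3' (4 nt 5' of the nick, 2 nt 3'). Windows running off the
#' sequence edge are padded with N, which counts as a mismatch.
#'
#' @param empty_seq The empty (pre-insertion) allele.
#' @param insertion_point 0-based position of the insertion junction in
#'   `empty_seq`.
#' @param tsd_length Length of the TSD (0 if none); the nick sits at the
#'   TSD's 5' boundary, `tsd_length` bases 5' of the junction.
#' @return List with `window_seq` (negative strand, 5' to 3'),
#'   `mismatches_to_consensus` in `[0, 6]`, and `nick_pos` (0-based, top
#'   strand).
#' @export
score_en_site <- function(empty_seq, insertion_point, tsd_length = 0L) {
  b <- insertion_point - tsd_length
  n <- nchar(empty_seq)
  # top-strand window [b-2, b+4); negative strand read 5'->3' is its
  # reverse complement
  idx <- (b - 2L):(b + 3L)
  top <- vapply(idx, function(i) {
    if (i < 0L || i >= n) "N" else substr(empty_seq, i + 1L, i + 1L)
  }, character(1))
  top <- paste(top, collapse = "")
  win <- chartr("ACGTN", "TGCAN", top)
  win <- paste(rev(seq_chars(win)), collapse = "")
  mism <- sum(seq_chars(win) != seq_chars(EN_CONSENSUS))
  list(window_seq = win, mismatches_to_consensus = as.integer(mism), nick_pos = b)
}

#' Measure truncation and non-Alu sequence of an inserted core
#'
#' Locally aligns the element core (tail removed) to the consensus.
#' `trunc_5p`/`trunc_3p` count consensus bases missing before/after the
#' matched region; `non_alu_5p`/`non_alu_3p` count inserted bases outside the
#' Alu-homologous core.
#'
#' @param element_seq Inserted core (poly-A tail already removed).
#' @param consensus A [consensus_record()].
#' @param min_score Alignment score below which the segment is declared to
#'   have no Alu homology.
#' @return List with `trunc_5p`, `trunc_3p`, `non_alu_5p`, `non_alu_3p`,
#'   `element_span`, `consensus_span` (0-based half-open), `identity`, and
#'   `has_homology`.
#' @export
measure_truncation <- function(element_seq, consensus, min_score = 20) {
  aln <- align_pair(element_seq, consensus$seq, type = "local")
  if (aln$score < min_score) {
    return(list(trunc_5p = NA_integer_, trunc_3p = NA_integer_,
                non_alu_5p = NA_integer_, non_alu_3p = NA_integer_,
                element_span = NULL, consensus_span = NULL,
                identity = NA_real_, has_homology = FALSE))
  }
  L <- nchar(consensus$seq)
  cols <- alignment_columns(aln)
  both <- !is.na(cols$p_pos) & !is.na(cols$s_pos)
  ident <- sum(cols$p_char[both] == cols$s_char[both]) / sum(both)
  list(
    trunc_5p = aln$subject_span[1],
    trunc_3p = L - aln$subject_span[2],
    non_alu_5p = aln$pattern_span[1],
    non_alu_3p = nchar(element_seq) - aln$pattern_span[2],
    element_span = aln$pattern_span,
    consensus_span = aln$subject_span,
    identity = ident, has_homology = TRUE
  )
}

#' Annotate an insertion candidate locus
#'
#' Orchestrates the TPRT-diagnostic measurements for a locus whose
#' polymorphic span is (or may be) an inserted element: extracts the
#' rightmost-placement inserted segment and flanks, detects the poly-A tail,
#' arbitrates the TSD, scores the endonuclease site, and measures truncation
#' against the assigned subfamily consensus. The inserted segment is assumed
#' to be in consensus-forward orientation (normalize upstream via
#' [classify_subfamily()]).
#'
#' @param obs A [locus_observation()].
#' @param span Its [compute_polymorphic_span()] result.
#' @param consensus The assigned subfamily [consensus_record()].
#' @param min_tsd Minimum TSD length.
#' @param polyA_rule Poly-A tail rule parameters.
#' @param full_length_tol Truncation (bp) still counted as full-length.
#' @return Object of class `insertion_annotation`.
#' @export
annotate_insertion <- function(obs, span, consensus, min_tsd = 6L,
                               polyA_rule = alupoly::polyA_rule(),
                               full_length_tol = 5L) {
  f <- obs$filled_seq
  q <- span$shift_range[2]                     # rightmost placement start
  d <- span$length
  flank5 <- seq_slice(f, 0L, q)
  inserted <- seq_slice(f, q, q + d)
  flank3 <- seq_slice(f, q + d, nchar(f))
  tsd <- detect_tsd(flank5, inserted, flank3, min_tsd = min_tsd)
  k <- if (is.null(tsd)) 0L else tsd$length
  core_tail <- seq_slice(inserted, 0L, nchar(inserted) - k)
  tail <- detect_polyA(core_tail, polyA_rule)
  core <- seq_slice(core_tail, 0L,
                    nchar(core_tail) - (if (is.null(tail)) 0L else tail$length))
  tr <- measure_truncation(core, consensus)
  tail_source <- if (!is.null(tail)) "suffix" else NA_character_
  if (is.null(tail) && tr$has_homology &&
      !is.na(tr$trunc_3p) && tr$trunc_3p <= full_length_tol + 8L &&
      tr$element_span[2] < nchar(core)) {
    # deletion-candidate geometry: the element's tail lies inside the span,
    # immediately 3' of the Alu-homologous core
    tail <- scan_internal_tail(core, tr$element_span[2], polyA_rule)
    if (!is.null(tail)) {
      tail_source <- "internal"
      tr$non_alu_3p <- tr$non_alu_3p - tail$length
    }
  }
  polyA <- if (is.null(tail)) NULL else {
    list(interval = tail$interval, length = tail$length, source = tail_source)
  }
  # insertion junction in empty-allele coordinates = length of the 5' flank
  en <- score_en_site(obs$empty_seq, insertion_point = q, tsd_length = k)
  structure(list(
    locus_id = obs$locus_id,
    element_span = tr$element_span, consensus_span = tr$consensus_span,
    has_homology = tr$has_homology, identity = tr$identity,
    trunc_5p = tr$trunc_5p, trunc_3p = tr$trunc_3p,
    non_alu_5p = tr$non_alu_5p, non_alu_3p = tr$non_alu_3p,
    polyA = polyA, tsd = tsd,
    target_site_deletion = span$target_site_deletion,
    en_site = en, full_length_tol = full_length_tol,
    full_length = tr$has_homology &&
      !is.na(tr$trunc_5p) && tr$trunc_5p <= full_length_tol &&
      !is.na(tr$trunc_3p) && tr$trunc_3p <= full_length_tol
  ), class = "insertion_annotation")
}

#' @export
print.insertion_annotation <- function(x, ...) {
  cat(sprintf("<insertion_annotation> %s\n", x$locus_id))
  cat(sprintf("  trunc 5'/3': %s/%s bp, non-Alu 5'/3': %s/%s bp\n",
              x$trunc_5p, x$trunc_3p, x$non_alu_5p, x$non_alu_3p))
  cat(sprintf("  poly-A: %s, TSD: %s, EN window %s (%d mismatches)\n",
              if (is.null(x$polyA)) "absent" else sprintf("%d bp", x$polyA$length),
              if (is.null(x$tsd)) "absent" else sprintf("%d bp '%s'", x$tsd$length, x$tsd$seq),
              x$en_site$window_seq, x$en_site$mismatches_to_consensus))
  invisible(x)
}
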