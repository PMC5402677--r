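# End-to-end per-locus characterization and cohort assembly: span ->
# subfamily -> insertion annotation -> mechanism -> divergence/age.

#' Characterize one locus end to end
#'
#' Runs the full pipeline on one filled/empty pair: polymorphic-span
#' computation, subfamily classification (with diagnostic-panel tally),
#' insertion annotation against the assigned subfamily consensus, mechanism
#' classification, and (for loci whose element is fully contained in the
#' span) divergence and age estimation.
#'
#' @param obs A [locus_observation()].
#' @param registry An `alu_registry`.
#' @param panel Diagnostic panel from [find_diagnostic_positions()].
#' @param clock [clock_parameters()].
#' @param min_tsd,full_length_tol,polyA_rule Annotation thresholds.
#' @return List with `span`, `subfamily`, `annotation`, `mechanism`,
#'   `divergence` (NULL where not computed), and `row` (a one-row summary
#'   data.frame).
#' @export
characterize_locus <- function(obs, registry, panel,
                               clock = clock_parameters(),
                               min_tsd = 6L, full_length_tol = 5L,
                               polyA_rule = alupoly::polyA_rule()) {
  span <- compute_polymorphic_span(obs)
  # element sequence for subfamily/divergence work: the annotated Alu when
  # the locus is reference-annotated, otherwise the inserted core
  if (!is.null(obs$annotated_alu)) {
    element_seq <- seq_slice(obs$filled_seq, obs$annotated_alu[1], obs$annotated_alu[2])
  } else {
    q <- span$shift_range[2]
    inserted <- seq_slice(obs$filled_seq, q, q + span$length)
    tsd0 <- detect_tsd(seq_slice(obs$filled_seq, 0L, q), inserted,
                       seq_slice(obs$filled_seq, q + span$length, nchar(obs$filled_seq)),
                       min_tsd = min_tsd)
    element_seq <- seq_slice(inserted, 0L,
                             nchar(inserted) - (if (is.null(tsd0)) 0L else tsd0$length))
  }
  sub <- classify_subfamily(element_seq, registry, panel = panel,
                            element_id = obs$locus_id)
  cons_label <- if (!is.na(sub$best_subfamily) && sub$best_subfamily != "UNRESOLVED")
    sub$best_subfamily
  else if (!is.na(sub$tie_representative)) sub$tie_representative
  else registry$anchor
  cons <- registry$records[[cons_label]]
  ann <- annotate_insertion(obs, span, cons, min_tsd = min_tsd,
                            polyA_rule = polyA_rule,
                            full_length_tol = full_length_tol)
  mech <- classify_mechanism(span, ann)
  div <- NULL
  if (span$alu_overlap == "ENTIRE") {
    div <- percent_divergence(element_seq, cons, clock = clock,
                              element_id = obs$locus_id)
  }
  row <- data.frame(
    locus_id = obs$locus_id,
    span_start = span$interval[1], span_end = span$interval[2],
    span_length = span$length,
    alu_overlap = span$alu_overlap, flank_included = span$flank_included,
    category = mech$category, mechanism = mech$mechanism,
    subfamily = sub$best_subfamily, family = sub$family,
    trunc_5p = ann$trunc_5p, trunc_3p = ann$trunc_3p,
    non_alu_5p = ann$non_alu_5p, non_alu_3p = ann$non_alu_3p,
    polyA_len = if (is.null(ann$polyA)) 0L else ann$polyA$length,
    tsd_len = if (is.null(ann$tsd)) 0L else ann$tsd$length,
    tsd_seq = if (is.null(ann$tsd)) NA_character_ else ann$tsd$seq,
    target_site_deletion = span$target_site_deletion,
    en_window = ann$en_site$window_seq,
    en_mismatches = ann$en_site$mismatches_to_consensus,
    percent_divergence = if (is.null(div)) NA_real_ else div$percent_divergence,
    age_cpg = if (is.null(div)) NA_real_ else div$age_cpg,
    age_noncpg = if (is.null(div)) NA_real_ else div$age_noncpg,
    validated = obs$validated,
    stringsAsFactors = FALSE
  )
  list(span = span, subfamily = sub, annotation = ann, mechanism = mech,
       divergence = div, row = row)
}

#' Characterize a cohort of loci
#'
#' @param observations List of [locus_observation()]s.
#' @inheritParams characterize_locus
#' @return List with `loci` (one summary row per locus), `calls` (list of
#'   `mechanism_call`s), `details` (full per-locus results), and `summary`
#'   ([summarize_cohort()] output respecting validation flags).
#' @export
characterize_cohort <- function(observations, registry, panel,
                                clock = clock_parameters(), ...) {
  details <- lapply(observations, characterize_locus, registry = registry,
                    panel = panel, clock = clock, ...)
  loci <- do.call(rbind, lapply(details, `[[`, "row"))
  calls <- lapply(details, `[[`, "mechanism")
  validated <- vapply(observations, `[[`, logical(1), "validated")
  list(loci = loci, calls = calls, details = details,
       summary = summarize_cohort(calls, validated))
}
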