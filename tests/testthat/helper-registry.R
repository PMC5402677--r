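# Shared fixtures: the synthetic registry and its diagnostic panel are
# deterministic and moderately expensive, so build them once per test run.

the_registry <- synthetic_registry()
the_panel <- find_diagnostic_positions(the_registry,
                                       alupoly:::ALU_S_LABELS,
                                       alupoly:::ALU_Y_LABELS)
S_LABELS <- alupoly:::ALU_S_LABELS
Y_LABELS <- alupoly:::ALU_Y_LABELS

# Toy registry wrapper: find_diagnostic_positions only needs the cached MSA.
toy_registry <- function(seqs, anchor = names(seqs)[1]) {
  structure(list(records = NULL, anchor = anchor,
                 msa = star_alignment(seqs, anchor = anchor)),
            class = "alu_registry")
}

# Overwrite 0-based positions of a sequence (test-side twin of the internal).
put <- function(seq, pos0, value) alupoly:::set_chars(seq, pos0, value)

# Vectorized character accessor at 0-based positions (substr does not
# vectorize over positions).
chars_at <- function(seq, pos0) strsplit(seq, "")[[1]][pos0 + 1]

# Stub span/annotation builders for decision-tree checks.
make_span_stub <- function(alu_overlap, flank_included, locus_id = "stub",
                           target_site_deletion = 0L) {
  structure(list(locus_id = locus_id, interval = c(100L, 400L), length = 300L,
                 left_shifted = FALSE, shift_range = c(100L, 100L),
                 target_site_deletion = target_site_deletion,
                 deleted_site_seq = "",
                 alu_overlap = alu_overlap, flank_included = flank_included),
            class = "polymorphic_span")
}

make_ann_stub <- function(trunc_5p = 0L, trunc_3p = 0L, polyA = TRUE,
                          tsd = TRUE, non_alu_3p = 0L, non_alu_5p = 0L,
                          en_mismatches = 0L, tol = 5L) {
  structure(list(
    locus_id = "stub", element_span = c(0L, 290L), consensus_span = c(0L, 290L),
    has_homology = TRUE, identity = 1,
    trunc_5p = trunc_5p, trunc_3p = trunc_3p,
    non_alu_5p = non_alu_5p, non_alu_3p = non_alu_3p,
    polyA = if (polyA) list(interval = c(260L, 285L), length = 25L) else NULL,
    tsd = if (tsd) list(seq = "ACGTACGTACGT", length = 12L) else NULL,
    target_site_deletion = 0L,
    en_site = list(window_seq = "TTTTAA", mismatches_to_consensus = en_mismatches,
                   nick_pos = 88L),
    full_length_tol = tol,
    full_length = trunc_5p <= tol && trunc_3p <= tol
  ), class = "insertion_annotation")
}
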