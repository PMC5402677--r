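# Subfamily classification: best-consensus alignment divergence, the
# AluS-versus-AluY diagnostic-nucleotide tally, and reconciliation with
# external subfamily calls.

#' Family group of a subfamily label
#' @keywords internal
label_family <- function(label) {
  ifelse(grepl("^AluS", label), "AluS",
    ifelse(grepl("^AluY", label), "AluY",
      ifelse(grepl("^AluJ", label), "AluJ", "OTHER")))
}

#' Normalize an element to consensus-forward orientation
#'
#' Aligns both orientations of `seq` to the registry anchor and returns the
#' better-scoring orientation. All elements are analyzed 5' to 3' in
#' consensus orientation.
#'
#' @return List with `seq` (possibly reverse-complemented) and `reversed`.
#' @export
normalize_strand <- function(seq, registry) {
  anchor_seq <- registry$records[[registry$anchor]]$seq
  fwd <- align_pair(seq, anchor_seq, type = "global-local")
  rev <- align_pair(revcomp(seq), anchor_seq, type = "global-local")
  if (rev$score > fwd$score) list(seq = revcomp(seq), reversed = TRUE)
  else list(seq = seq, reversed = FALSE)
}

# Divergence of an element against one consensus: substituted columns over
# aligned non-gap columns (indel columns excluded from both counts).
pair_divergence <- function(element_seq, consensus_seq, type = "global-local") {
  aln <- align_pair(element_seq, consensus_seq, type = type)
  cols <- alignment_columns(aln)
  both <- !is.na(cols$p_pos) & !is.na(cols$s_pos)
  n <- sum(both)
  subs <- sum(cols$p_char[both] != cols$s_char[both])
  list(divergence = if (n > 0) 100 * subs / n else NA_real_,
       aligned_columns = n, substitutions = subs, aln = aln)
}

#' Classify an element's subfamily by best-consensus alignment
#'
#' The element is strand-normalized, its poly-A tail trimmed, and the result
#' aligned to every registry consensus (element fully aligned, consensus ends
#' free). The best subfamily minimizes percent divergence; ties are reported
#' as UNRESOLVED at the subfamily level (lexicographically smallest label
#' kept as tie representative) but the family may still be resolvable through
#' the diagnostic panel.
#'
#' @param element_seq DNA string of the element (any orientation).
#' @param registry An `alu_registry`.
#' @param panel Optional diagnostic panel from [find_diagnostic_positions()];
#'   if supplied, the AluS/AluY tally is computed and used when the family is
#'   ambiguous.
#' @param min_len Elements shorter than this after tail trimming are returned
#'   UNRESOLVED with reason `"too short"`.
#' @return Object of class `subfamily_call`: `element_id`, `best_subfamily`,
#'   `family`, `per_consensus_divergence`, `diagnostic_tally`, `reason`.
#' @export
classify_subfamily <- function(element_seq, registry, panel = NULL,
                               element_id = NA_character_, min_len = 30L) {
  tail <- detect_polyA(element_seq)
  trimmed <- if (is.null(tail)) element_seq else seq_slice(element_seq, 0L, tail$interval[1])
  if (nchar(trimmed) < min_len) {
    return(new_subfamily_call(element_id, "UNRESOLVED", "UNRESOLVED",
                              divs = NULL, tally = empty_tally(),
                              reason = "too short"))
  }
  norm <- normalize_strand(trimmed, registry)
  divs <- vapply(registry$records, function(r) {
    pair_divergence(norm$seq, r$seq)$divergence
  }, numeric(1))
  best <- names(divs)[divs == min(divs)]
  tally <- if (!is.null(panel)) diagnostic_tally(norm$seq, registry, panel) else empty_tally()
  if (length(best) == 1) {
    call <- new_subfamily_call(element_id, best, label_family(best), divs, tally)
  } else {
    fams <- unique(label_family(best))
    fam <- if (length(fams) == 1) fams else tally_family(tally)
    call <- new_subfamily_call(element_id, "UNRESOLVED", fam, divs, tally,
                               reason = sprintf("tie: %s", paste(sort(best), collapse = ",")),
                               tie_representative = sort(best)[1])
  }
  call$reversed <- norm$reversed
  call
}

empty_tally <- function() {
  c(matches_S = 0L, matches_Y = 0L, matches_both = 0L, matches_neither = 0L,
    positions_covered = 0L)
}

new_subfamily_call <- function(element_id, best, family, divs, tally,
                               reason = NA_character_, tie_representative = NA_character_) {
  structure(list(element_id = element_id, best_subfamily = best, family = family,
                 per_consensus_divergence = divs, diagnostic_tally = tally,
                 reason = reason, tie_representative = tie_representative),
            class = "subfamily_call")
}

#' @export
print.subfamily_call <- function(x, ...) {
  cat(sprintf("<subfamily_call> %s: %s (family %s)\n",
              x$element_id, x$best_subfamily, x$family))
  t <- x$diagnostic_tally
  cat(sprintf("  diagnostic tally: S=%d Y=%d both=%d neither=%d of %d covered\n",
              t["matches_S"], t["matches_Y"], t["matches_both"],
              t["matches_neither"], t["positions_covered"]))
  invisible(x)
}

# Tally an element against the diagnostic panel. The element is aligned to
# the panel's anchor consensus; panel positions outside the aligned span are
# dropped from positions_covered.
diagnostic_tally <- function(element_seq, registry, panel) {
  anchor_seq <- registry$records[[registry$anchor]]$seq
  aln <- align_pair(element_seq, anchor_seq, type = "global-local")
  map <- subject_to_pattern_map(aln, nchar(anchor_seq))
  tally <- empty_tally()
  for (i in seq_len(nrow(panel))) {
    ap <- panel$anchor_pos[i]
    if (is.na(ap)) next
    b <- map[ap + 1L]
    if (is.na(b) || b == "-") next
    s_set <- strsplit(panel$s_bases[i], ",", fixed = TRUE)[[1]]
    y_set <- strsplit(panel$y_bases[i], ",", fixed = TRUE)[[1]]
    in_s <- b %in% s_set; in_y <- b %in% y_set
    tally["positions_covered"] <- tally["positions_covered"] + 1L
    if (in_s && in_y) tally["matches_both"] <- tally["matches_both"] + 1L
    else if (in_s) tally["matches_S"] <- tally["matches_S"] + 1L
    else if (in_y) tally["matches_Y"] <- tally["matches_Y"] + 1L
    else tally["matches_neither"] <- tally["matches_neither"] + 1L
  }
  tally
}

tally_family <- function(tally) {
  if (tally["positions_covered"] == 0L) return("UNRESOLVED")
  if (tally["matches_S"] > tally["matches_Y"]) "AluS"
  else if (tally["matches_Y"] > tally["matches_S"]) "AluY"
  else "UNRESOLVED"
}

#' Resolve AluS versus AluY membership through the diagnostic panel
#'
#' Majority vote over the diagnostic-nucleotide panel: family is AluS if more
#' covered positions match an AluS-only base than an AluY-only base, AluY for
#' the converse, and UNRESOLVED on a tie or when no panel position is covered.
#' Positions consistent with both groups (possible at relaxed positions) or
#' with neither (novel bases) are tallied but uninformative for the vote.
#'
#' @inheritParams classify_subfamily
#' @param panel Diagnostic panel from [find_diagnostic_positions()].
#' @return A `subfamily_call` with the family decision and full tally.
#' @export
resolve_s_vs_y <- function(element_seq, registry, panel,
                           element_id = NA_character_) {
  norm <- normalize_strand(element_seq, registry)
  tally <- diagnostic_tally(norm$seq, registry, panel)
  call <- new_subfamily_call(element_id, NA_character_, tally_family(tally),
                             divs = NULL, tally = tally)
  call$reversed <- norm$reversed
  call
}

#' Reconcile external subfamily calls with the internal call
#'
#' External calls (e.g. prior annotation-tool assignments carried in the
#' locus table) are compared with the internal alignment-based call:
#' agreement on a single label is `AGREE`; disagreement confined to one
#' family is `MINOR_DISAGREE` and the internal call wins; disagreement across
#' families is `MAJOR_DISAGREE` and the final family comes from the
#' diagnostic-panel resolution carried by `internal`.
#'
#' @param calls Character vector of external subfamily labels (>= 1).
#' @param internal A `subfamily_call` for the same element.
#' @return List with `status`, `final_label`, `final_family`.
#' @export
reconcile_calls <- function(calls, internal) {
  stopifnot(length(calls) >= 1)
  labs <- unique(calls)
  fams <- unique(label_family(calls))
  internal_lab <- internal$best_subfamily
  has_internal_lab <- !is.na(internal_lab) && internal_lab != "UNRESOLVED"
  if (length(labs) == 1) {
    return(list(status = "AGREE", final_label = labs, final_family = fams))
  }
  if (length(fams) > 1) {
    # cross-family conflict: the diagnostic-panel/internal resolution decides
    fam <- if (internal$family != "UNRESOLVED") internal$family
           else tally_family(internal$diagnostic_tally)
    lab <- if (has_internal_lab) internal_lab else fam
    return(list(status = "MAJOR_DISAGREE", final_label = lab, final_family = fam))
  }
  # within-family label disagreement: internal alignment-based call wins
  lab <- if (has_internal_lab) internal_lab else labs[1]
  list(status = "MINOR_DISAGREE", final_label = lab, final_family = label_family(lab))
}
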