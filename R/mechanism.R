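# Mechanism classification: a total, deterministic decision tree mapping a
# polymorphic span plus its insertion annotation to one of
# {DELETION_CANDIDATE, NCAI, INTERNAL_PRIMING, TPRT, UNRESOLVED}.

MECHANISMS <- c("DELETION_CANDIDATE", "NCAI", "INTERNAL_PRIMING", "TPRT",
                "UNRESOLVED")

#' Classify the mechanism of origin of one locus
#'
#' Decision logic:
#' * partial-Alu spans are deletion candidates (part of the Alu is fixed);
#' * spans covering the entire Alu plus flanking sequence are deletion
#'   candidates when the element is full-length with a poly-A tail (a TSD is
#'   not required there: it may be unascertainable, e.g. another repeat
#'   immediately 5'), and non-classical insertions (NCAI) when the element
#'   is doubly truncated without a TSD;
#' * spans that are exactly the element are insertion candidates: poly-A
#'   tail + TSD + intact 3' end is TPRT (5' truncation allowed — premature
#'   termination of reverse transcription 5'-truncates TPRT products);
#'   full-length + TSD without a tail is internal priming; no TSD with 3'
#'   truncation or non-Alu sequence is NCAI;
#' * anything else, including spans not touching the Alu, is UNRESOLVED with
#'   the evidence trail explaining why.
#'
#' A TSD reported "unascertainable" (5' context occluded) is distinct from
#' "absent" and never vetoes a deletion call.
#'
#' @param span A `polymorphic_span`.
#' @param ann An `insertion_annotation` (may be NULL for partial-Alu spans).
#' @param en_supportive_max EN-site mismatch count (vs TTTT/AA) still counted
#'   as supportive evidence; reported in the trail, never decisive.
#' @param tsd_state Override for the TSD evidence state: `"present"`,
#'   `"absent"` or `"unascertainable"`; defaults to presence in `ann`.
#' @return Object of class `mechanism_call` with `mechanism`, `category`,
#'   and an `evidence` data.frame of (feature, value, rule).
#' @export
classify_mechanism <- function(span, ann = NULL, en_supportive_max = 2L,
                               tsd_state = NULL) {
  cat0 <- assign_post_deletion_category(span)
  ev <- list()
  note <- function(feature, value, rule) {
    ev[[length(ev) + 1L]] <<- data.frame(feature = feature,
                                         value = as.character(value),
                                         rule = rule, stringsAsFactors = FALSE)
  }
  note("category", cat0$category, "span x annotated-Alu overlay")

  has_tail <- !is.null(ann) && !is.null(ann$polyA)
  if (is.null(tsd_state)) {
    tsd_state <- if (!is.null(ann) && !is.null(ann$tsd)) "present" else "absent"
  }
  full <- !is.null(ann) && isTRUE(ann$full_length)
  tol <- if (!is.null(ann)) ann$full_length_tol else 5L
  t5 <- if (!is.null(ann) && !is.na(ann$trunc_5p %||% NA)) ann$trunc_5p else NA_integer_
  t3 <- if (!is.null(ann) && !is.na(ann$trunc_3p %||% NA)) ann$trunc_3p else NA_integer_
  doubly_trunc <- !is.na(t5) && !is.na(t3) && t5 > tol && t3 > tol
  non_alu <- !is.null(ann) &&
    (isTRUE(ann$non_alu_5p > 0L) || isTRUE(ann$non_alu_3p > 0L))
  intact_3p <- !is.na(t3) && t3 <= tol
  if (!is.null(ann)) {
    note("polyA", if (has_tail) sprintf("%d bp", ann$polyA$length) else "absent",
         "longest rule-satisfying suffix")
    note("tsd", if (tsd_state == "present") sprintf("%d bp", ann$tsd$length) else tsd_state,
         "maximized exact duplication")
    note("truncation", sprintf("5':%s 3':%s", t5, t3), "local alignment to consensus")
    if (!is.null(ann$en_site)) {
      note("en_site", sprintf("%s (%d mismatches)", ann$en_site$window_seq,
                              ann$en_site$mismatches_to_consensus),
           sprintf("supportive if <= %d mismatches", en_supportive_max))
    }
  }

  mech <- "UNRESOLVED"
  if (cat0$class == "flank_only") {
    note("decision", "flank-only variant", "span does not touch the Alu; excluded")
  } else if (cat0$class == "deletion_candidate") {
    mech <- "DELETION_CANDIDATE"
    note("decision", mech, "part of the Alu is fixed: partial-Alu span")
  } else if (cat0$class == "ambiguous_full_plus_flank") {
    if (has_tail && !doubly_trunc) {
      # a poly-A tail at the element's 3' boundary marks an intact 3' end
      # even when the alignment end frays on a diverged element
      mech <- "DELETION_CANDIDATE"
      note("decision", mech,
           "entire Alu + flank, full-length element with poly-A tail: deletion of a fixed insertion")
    } else if (doubly_trunc && tsd_state != "present") {
      mech <- "NCAI"
      note("decision", mech,
           "entire Alu + flank, doubly truncated fragment without TSD")
    } else {
      note("decision", "UNRESOLVED", "full+flank span with mixed evidence")
    }
  } else { # insertion candidate: span is exactly the element
    if (tsd_state == "present" && has_tail && intact_3p) {
      mech <- "TPRT"
      note("decision", mech, "intact 3' end + poly-A tail + TSD")
    } else if (tsd_state == "present" && !has_tail && full) {
      mech <- "INTERNAL_PRIMING"
      note("decision", mech, "full-length + TSD, no poly-A tail")
    } else if (tsd_state != "present" && (doubly_trunc || (!is.na(t3) && t3 > tol) || non_alu)) {
      mech <- "NCAI"
      note("decision", mech, "no TSD with truncation and/or non-Alu sequence")
    } else {
      note("decision", "UNRESOLVED", "feature combination matches no mechanism")
    }
  }
  structure(list(
    locus_id = span$locus_id, mechanism = mech, category = cat0$category,
    category_class = cat0$class, evidence = do.call(rbind, ev)
  ), class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call> %s: %s (category %s)\n",
              x$locus_id, x$mechanism, x$category))
  invisible(x)
}

#' Summarize mechanism calls over a cohort
#'
#' Counts and integer-rounded percentages per mechanism and per post-deletion
#' category. Calls with `validated = FALSE` stay in the cohort denominator
#' but are excluded from the mechanism counts (reported under
#' `NOT_VALIDATED`), mirroring how unvalidated insertion candidates are
#' handled in cohort reporting.
#'
#' @param calls List of `mechanism_call`s.
#' @param validated Logical vector parallel to `calls` (default all TRUE).
#' @return List with `n`, `by_mechanism` and `by_category` data.frames, and
#'   `insertion_breakdown` (mechanism shares among validated insertion
#'   candidates only).
#' @export
summarize_cohort <- function(calls, validated = rep(TRUE, length(calls))) {
  stopifnot(length(calls) >= 1, length(validated) == length(calls))
  n <- length(calls)
  mech <- vapply(calls, `[[`, character(1), "mechanism")
  cat_ <- vapply(calls, `[[`, character(1), "category")
  mech[!validated] <- "NOT_VALIDATED"
  lev <- c(MECHANISMS, "NOT_VALIDATED")
  cnt <- table(factor(mech, levels = lev))
  by_mech <- data.frame(mechanism = names(cnt), count = as.integer(cnt),
                        percent = as.integer(round(100 * as.integer(cnt) / n)),
                        stringsAsFactors = FALSE)
  ct <- table(cat_)
  by_cat <- data.frame(category = names(ct), count = as.integer(ct),
                       percent = as.integer(round(100 * as.integer(ct) / n)),
                       stringsAsFactors = FALSE)
  ins <- mech[validated & mech %in% c("TPRT", "INTERNAL_PRIMING", "NCAI")]
  ins_n <- length(ins)
  ins_t <- table(factor(ins, levels = c("TPRT", "INTERNAL_PRIMING", "NCAI")))
  ins_bd <- data.frame(mechanism = names(ins_t), count = as.integer(ins_t),
                       percent = if (ins_n > 0)
                         as.integer(round(100 * as.integer(ins_t) / ins_n))
                       else rep(0L, 3),
                       stringsAsFactors = FALSE)
  list(n = n, by_mechanism = by_mech, by_category = by_cat,
       insertion_breakdown = ins_bd, n_validated_insertions = ins_n)
}
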