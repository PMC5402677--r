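# Filled/empty allele comparison: locate the polymorphic span, normalize its
# placement, overlay the annotated Alu, and assign the post-deletion category.

#' Construct a locus observation
#'
#' One polymorphism: the Alu-containing ("filled") allele, the "empty"
#' allele, and optional reference annotation of the Alu interval within the
#' filled allele. The two alleles must share their flanking sequence outside
#' the polymorphic span.
#'
#' @param locus_id Label.
#' @param filled_seq,empty_seq DNA strings; `filled_seq` carries the Alu.
#' @param annotated_alu Optional 0-based half-open interval of the annotated
#'   Alu within `filled_seq` (for reference-annotated loci).
#' @param subfamily_hint Optional prior subfamily label(s) carried as data
#'   (see [reconcile_calls()]).
#' @param in_reference Is the Alu present in the reference assembly?
#' @param validated PCR-validation flag (used only by cohort summaries).
#' @param chrom,pos Free-text genomic anchor.
#' @return Object of class `locus_observation`.
#' @export
locus_observation <- function(locus_id, filled_seq, empty_seq,
                              annotated_alu = NULL, subfamily_hint = NULL,
                              in_reference = !is.null(annotated_alu),
                              validated = TRUE, chrom = NA_character_,
                              pos = NA_integer_) {
  filled_seq <- toupper(filled_seq); empty_seq <- toupper(empty_seq)
  assert_dna(filled_seq, sprintf("locus %s filled allele", locus_id))
  assert_dna(empty_seq, sprintf("locus %s empty allele", locus_id))
  if (!is.null(annotated_alu)) {
    annotated_alu <- as.integer(annotated_alu)
    stopifnot(length(annotated_alu) == 2,
              annotated_alu[1] >= 0, annotated_alu[2] <= nchar(filled_seq),
              annotated_alu[1] < annotated_alu[2])
  }
  structure(list(locus_id = locus_id, filled_seq = filled_seq,
                 empty_seq = empty_seq, annotated_alu = annotated_alu,
                 subfamily_hint = subfamily_hint, in_reference = in_reference,
                 validated = validated, chrom = chrom, pos = pos),
            class = "locus_observation")
}

#' @export
print.locus_observation <- function(x, ...) {
  cat(sprintf("<locus_observation> %s: filled %d nt, empty %d nt%s\n",
              x$locus_id, nchar(x$filled_seq), nchar(x$empty_seq),
              if (!is.null(x$annotated_alu))
                sprintf(", annotated Alu %s", format_interval(x$annotated_alu))
              else ""))
  invisible(x)
}

#' Compute the polymorphic span of a filled/empty allele pair
#'
#' Locates the single contiguous difference between the alleles and reports
#' it on the filled allele, left-shifted to its leftmost equivalent placement
#' within any repeat context (VCF-style indel normalization). A replacement
#' (sequence present in the empty allele but absent from the filled allele's
#' reconstruction, i.e. a target-site deletion) is permitted; two alleles
#' whose difference decomposes into multiple disjoint blocks (detected as a
#' shared `complex_kmer`-mer between the replaced segments) are rejected as
#' a complex locus.
#'
#' @param obs A [locus_observation()].
#' @param min_flank Minimum shared flank required on each side (bp).
#' @param complex_kmer Shared k-mer length between inserted and deleted
#'   segments above which the locus is declared complex.
#' @return Object of class `polymorphic_span`: `interval` (0-based half-open
#'   on the filled allele, leftmost placement), `length`, `left_shifted`,
#'   `shift_range` (leftmost/rightmost placement starts),
#'   `target_site_deletion` (bp of empty-allele sequence absent from the
#'   filled allele), `deleted_site_seq`, `alu_overlap`, `flank_included`.
#' @export
compute_polymorphic_span <- function(obs, min_flank = 20L, complex_kmer = 20L) {
  f <- obs$filled_seq; e <- obs$empty_seq
  lf <- nchar(f); le <- nchar(e)
  if (f == e) stop(sprintf("locus %s: no polymorphism", obs$locus_id), call. = FALSE)
  if (lf <= le) stop(sprintf("locus %s: filled allele must be the longer allele",
                             obs$locus_id), call. = FALSE)
  P <- lcp_len(f, e); S <- lcs_len(f, e)
  tsd_del <- 0L; deleted_seq <- ""
  if (P + S < le) {
    # replacement: empty carries sequence absent from filled
    deleted_seq <- seq_slice(e, P, le - S)
    inserted <- seq_slice(f, P, lf - S)
    if (shares_kmer(deleted_seq, inserted, complex_kmer)) {
      stop(sprintf("locus %s: complex locus (multiple disjoint differences)",
                   obs$locus_id), call. = FALSE)
    }
    tsd_del <- nchar(deleted_seq)
    start_min <- start_max <- P
  } else {
    if (P + S > le) S <- le - P   # overlapping prefix/suffix matches
    start_min <- le - lcs_len(f, e)            # leftmost placement
    start_min <- max(start_min, 0L)
    start_max <- P                              # rightmost placement
  }
  d <- lf - le + tsd_del
  start <- start_min
  if (start < min_flank || (lf - (start + d)) < min_flank) {
    stop(sprintf("locus %s: shared flank shorter than %d bp", obs$locus_id, min_flank),
         call. = FALSE)
  }
  interval <- c(start, start + d)
  span <- structure(list(
    locus_id = obs$locus_id, interval = interval, length = d,
    left_shifted = start_min < start_max, shift_range = c(start_min, start_max),
    target_site_deletion = tsd_del, deleted_site_seq = deleted_seq,
    alu_overlap = NA_character_, flank_included = NA_character_
  ), class = "polymorphic_span")
  overlay_alu(span, obs$annotated_alu)
}

# Overlay the annotated Alu interval (if any) on the span.
overlay_alu <- function(span, alu) {
  if (is.null(alu)) {
    # non-reference locus: the span is the inserted element itself
    span$alu_overlap <- "ENTIRE"
    span$flank_included <- "NONE"
    return(span)
  }
  s <- span$interval[1]; e <- span$interval[2]
  a <- alu[1]; b <- alu[2]
  span$alu_overlap <-
    if (e <= a || s >= b) "NONE"
    else if (s <= a && e >= b) "ENTIRE"
    else if (s <= a) "PARTIAL_5P"          # covers Alu 5' end, not 3' end
    else if (e >= b) "PARTIAL_3P"
    else "PARTIAL_INTERNAL"
  five <- s < a; three <- e > b
  span$flank_included <-
    if (span$alu_overlap %in% c("NONE")) "NONE"
    else if (five && three) "BOTH"
    else if (five && span$alu_overlap == "ENTIRE") "FIVE_PRIME"
    else if (three && span$alu_overlap == "ENTIRE") "THREE_PRIME"
    else if (five) "FIVE_PRIME"
    else if (three) "THREE_PRIME"
    else "NONE"
  span
}

#' @export
print.polymorphic_span <- function(x, ...) {
  cat(sprintf("<polymorphic_span> %s: %s (%d bp), Alu overlap %s, flank %s%s\n",
              x$locus_id, format_interval(x$interval), x$length,
              x$alu_overlap, x$flank_included,
              if (x$target_site_deletion > 0)
                sprintf(", %d bp target-site deletion", x$target_site_deletion)
              else ""))
  invisible(x)
}

#' Assign the post-deletion category of a polymorphic span
#'
#' Categories are the cross of `alu_overlap` and `flank_included`.
#' Partial-Alu spans are deletion candidates; spans covering the entire Alu
#' plus flanking sequence are ambiguous (deletion or non-classical insertion)
#' and routed to insertion annotation; a span that is exactly the Alu
#' (`ENTIRE`, no flank) is an insertion candidate, not a deletion candidate;
#' spans not touching the Alu are flank-only variants excluded from the Alu
#' polymorphism set. `PARTIAL_BOTH_ENDS` is retained in the enum for
#' completeness but is unreachable for a contiguous span.
#'
#' @param span A `polymorphic_span` with `alu_overlap` computed.
#' @return List with `category` (e.g. `"PARTIAL_INTERNAL+NONE"`) and `class`
#'   (`deletion_candidate`, `ambiguous_full_plus_flank`, `insertion_candidate`
#'   or `flank_only`).
#' @export
assign_post_deletion_category <- function(span) {
  ov <- span$alu_overlap; fl <- span$flank_included
  category <- paste(ov, fl, sep = "+")
  class <-
    if (ov == "NONE") "flank_only"
    else if (startsWith(ov, "PARTIAL")) "deletion_candidate"
    else if (ov == "ENTIRE" && fl == "NONE") "insertion_candidate"
    else "ambiguous_full_plus_flank"
  list(category = category, class = class)
}
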