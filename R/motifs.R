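# Conservation of retrotransposition-critical motifs: RNA polymerase III
# A/B boxes, SRP9/14 binding sites and the AC dinucleotides, scored across a
# set of elements as mismatch tallies and position frequency matrices.

PFM_ROWS <- c("A", "C", "G", "T", "-")

#' Extract an element's bases at a motif's consensus columns
#'
#' Lifts the motif interval (defined on its anchor consensus) onto the
#' element through a pairwise alignment; deleted columns are reported as
#' `"-"`.
#'
#' @param element_seq Element sequence (consensus-forward orientation).
#' @param motif A motif definition from the registry (interval on the anchor).
#' @param anchor_record The anchor [consensus_record()].
#' @param aln Optional precomputed [align_pair()] alignment of element to
#'   anchor (pattern = element).
#' @return Character scalar of length = motif length, or `NULL` when the
#'   aligned span misses the motif entirely (motif not covered).
#' @export
extract_motif <- function(element_seq, motif, anchor_record, aln = NULL) {
  if (is.null(aln)) {
    aln <- align_pair(element_seq, anchor_record$seq, type = "global-local")
  }
  map <- subject_to_pattern_map(aln, nchar(anchor_record$seq))
  iv <- motif$interval
  got <- map[(iv[1] + 1L):iv[2]]
  if (all(is.na(got))) return(NULL)  # motif not covered
  got[is.na(got)] <- "-"
  paste(got, collapse = "")
}

#' Score conservation of one motif across elements
#'
#' @param elements Named character vector of element sequences.
#' @param motif Motif definition (from the registry config).
#' @param anchor_record The anchor [consensus_record()].
#' @return Object of class `conservation_report`: per-element extracted
#'   sequence and mismatch count, key-position match counts, the count of
#'   fully conserved columns (identical across elements and equal to the
#'   motif consensus), a position frequency matrix (rows A/C/G/T/-), and the
#'   CpG-membership flags of imperfect columns.
#' @export
score_conservation <- function(elements, motif, anchor_record) {
  stopifnot(length(elements) >= 1, !is.null(names(elements)))
  cons <- seq_chars(motif$consensus_seq)
  L <- length(cons)
  per <- list()
  pfm <- matrix(0L, nrow = length(PFM_ROWS), ncol = L,
                dimnames = list(PFM_ROWS, NULL))
  kept <- character(0)
  for (nm in names(elements)) {
    ex <- extract_motif(elements[[nm]], motif, anchor_record)
    if (is.null(ex)) next
    ch <- seq_chars(ex)
    mism <- sum(ch != cons)
    key_rel <- motif$key_positions - motif$interval[1]
    key_match <- if (length(key_rel)) sum(ch[key_rel + 1L] == cons[key_rel + 1L])
                 else NA_integer_
    per[[nm]] <- data.frame(element_id = nm, extracted_seq = ex,
                            mismatches = mism,
                            key_position_matches = key_match,
                            stringsAsFactors = FALSE)
    for (i in seq_len(L)) pfm[ch[i], i] <- pfm[ch[i], i] + 1L
    kept <- c(kept, nm)
  }
  if (!length(per)) stop("no element covers the motif", call. = FALSE)
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  col_perfect <- vapply(seq_len(L), function(i) {
    pfm[cons[i], i] == length(kept) && sum(pfm[, i]) == length(kept)
  }, logical(1))
  imperfect <- which(!col_perfect) - 1L + motif$interval[1]  # anchor coords
  cpg_imperfect <- imperfect[motif$cpg_flags[which(!col_perfect)]]
  structure(list(
    motif_name = motif$name, consensus_seq = motif$consensus_seq,
    per_element = per,
    fully_conserved_positions = sum(col_perfect),
    motif_length = L, n_elements = length(kept),
    pfm = pfm,
    imperfect_positions = imperfect,
    cpg_flagged_mismatch_positions = cpg_imperfect
  ), class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> %s (%d nt, %d elements)\n",
              x$motif_name, x$motif_length, x$n_elements))
  cat(sprintf("  fully conserved columns: %d/%d; mismatches per element: %s\n",
              x$fully_conserved_positions, x$motif_length,
              paste(sort(x$per_element$mismatches), collapse = ",")))
  invisible(x)
}

#' Check conservation of the left and right AC dinucleotides
#'
#' Thin wrapper over [score_conservation()] for the two 2-nt motifs that
#' stabilize the closed-loop conformation of Alu RNA.
#'
#' @inheritParams score_conservation
#' @param left_def,right_def The `AC_dinucleotide_left` / `_right` motif
#'   definitions.
#' @return List with `left` and `right` `conservation_report`s.
#' @export
ac_dinucleotide_check <- function(elements, left_def, right_def, anchor_record) {
  list(left = score_conservation(elements, left_def, anchor_record),
       right = score_conservation(elements, right_def, anchor_record))
}

#' Information content per PFM column
#'
#' 2 - Shannon entropy (bits) of the base frequencies, gaps excluded — the
#' numeric content of a sequence logo.
#'
#' @param pfm Matrix with rows A/C/G/T/- as produced by
#'   [score_conservation()].
#' @return Numeric vector, one value per column.
#' @export
pfm_information_content <- function(pfm) {
  apply(pfm[c("A", "C", "G", "T"), , drop = FALSE], 2, function(col) {
    n <- sum(col)
    if (n == 0) return(0)
    p <- col[col > 0] / n
    2 + sum(p * log2(p))
  })
}

#' Write a PFM as a plain-text matrix
#'
#' Columns = motif positions (1-based in the header), rows = A/C/G/T/gap.
#' @param pfm PFM matrix.
#' @param path Output path.
#' @export
write_pfm <- function(pfm, path) {
  df <- as.data.frame(pfm)
  names(df) <- sprintf("pos%d", seq_len(ncol(pfm)))
  df <- cbind(base = rownames(pfm), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
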