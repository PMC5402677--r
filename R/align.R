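# Pairwise and star multiple alignment built on Biostrings::pairwiseAlignment.
# Scoring follows the registry default: match +1, mismatch -1, gap open 5,
# gap extend 1 (penalties). Consensus sequences are >85% identical, so any
# sane scoring yields the same columns; parameters are echoed into reports.

default_sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = TRUE)
}

#' Pairwise alignment returning gapped strings
#'
#' @param pattern,subject DNA strings (character).
#' @param type alignment type passed to [Biostrings::pairwiseAlignment()]:
#'   `"global"`, `"global-local"` (pattern fully aligned, subject ends free)
#'   or `"local"`.
#' @return List with `p`, `s` (gapped aligned strings), `score`, and 0-based
#'   half-open `pattern_span` / `subject_span` of the aligned region on the
#'   original sequences.
#' @keywords internal
align_pair <- function(pattern, subject, type = "global",
                       gap_open = 5, gap_extend = 1) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(pattern),
    subject = Biostrings::DNAString(subject),
    type = type,
    substitutionMatrix = default_sub_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend
  )
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  list(
    p = p, s = s, score = Biostrings::score(pa),
    pattern_span = c(Biostrings::start(Biostrings::pattern(pa)) - 1L,
                     Biostrings::end(Biostrings::pattern(pa))),
    subject_span = c(Biostrings::start(Biostrings::subject(pa)) - 1L,
                     Biostrings::end(Biostrings::subject(pa)))
  )
}

#' Per-column walk of a pairwise alignment
#'
#' @return data.frame with one row per alignment column: `p_char`, `s_char`,
#'   `p_pos`, `s_pos` (0-based positions on the original sequences, NA at
#'   gaps). Positions are offset by the aligned-region starts so they index
#'   the full original sequences.
#' @keywords internal
alignment_columns <- function(aln) {
  pc <- seq_chars(aln$p); sc <- seq_chars(aln$s)
  p_pos <- cumsum(pc != "-") - 1L + aln$pattern_span[1]
  s_pos <- cumsum(sc != "-") - 1L + aln$subject_span[1]
  p_pos[pc == "-"] <- NA_integer_
  s_pos[sc == "-"] <- NA_integer_
  data.frame(p_char = pc, s_char = sc, p_pos = p_pos, s_pos = s_pos,
             stringsAsFactors = FALSE)
}

#' Map positions of a subject sequence to the aligned pattern base
#'
#' @return Character vector of length `nchar(subject)`; entry i+1 is the
#'   pattern base aligned to subject position i (0-based), `"-"` where the
#'   pattern has a gap, `NA` where the subject position is outside the
#'   aligned span.
#' @keywords internal
subject_to_pattern_map <- function(aln, subject_len) {
  cols <- alignment_columns(aln)
  out <- rep(NA_character_, subject_len)
  keep <- !is.na(cols$s_pos)
  out[cols$s_pos[keep] + 1L] <- cols$p_char[keep]
  out
}

#' Star multiple alignment around an anchor sequence
#'
#' Each sequence is aligned pairwise (global) to the anchor; insertions
#' relative to the anchor are merged so that the result is a character matrix
#' of single columns. With near-identical inputs (the registry use case) the
#' result is invariant to the anchor choice.
#'
#' @param seqs Named character vector of DNA strings.
#' @param anchor Name of the anchor sequence (default: first).
#' @return List with `matrix` (rows = sequences, columns = alignment
#'   columns), `anchor`, and `anchor_pos` (0-based anchor position per
#'   column, NA for columns inserted relative to the anchor).
#' @export
star_alignment <- function(seqs, anchor = names(seqs)[1]) {
  stopifnot(!is.null(names(seqs)), anchor %in% names(seqs))
  others <- setdiff(names(seqs), anchor)
  la <- nchar(seqs[[anchor]])
  # per sequence: matched base per anchor position, plus insertions keyed by
  # the anchor position they precede (la = trailing insertions)
  per <- list()
  ins_len <- integer(la + 1L)
  for (nm in others) {
    aln <- align_pair(seqs[[nm]], seqs[[anchor]], type = "global")
    cols <- alignment_columns(aln)
    base <- rep("-", la)
    ins <- vector("list", la + 1L)
    pending <- character(0)
    for (i in seq_len(nrow(cols))) {
      if (is.na(cols$s_pos[i])) {            # insertion relative to anchor
        pending <- c(pending, cols$p_char[i])
      } else {
        ap <- cols$s_pos[i] + 1L
        if (length(pending)) { ins[[ap]] <- pending; pending <- character(0) }
        base[ap] <- cols$p_char[i]
      }
    }
    if (length(pending)) ins[[la + 1L]] <- pending
    per[[nm]] <- list(base = base, ins = ins)
    ins_len <- pmax(ins_len, vapply(ins, length, integer(1)))
  }
  # assemble columns: for each anchor position, first the insertion block
  # preceding it (right-padded with gaps), then the anchor column itself
  n_col <- la + sum(ins_len)
  nms <- names(seqs)
  mat <- matrix("-", nrow = length(nms), ncol = n_col, dimnames = list(nms, NULL))
  anchor_pos <- rep(NA_integer_, n_col)
  anchor_chars <- seq_chars(seqs[[anchor]])
  col <- 0L
  emit_ins <- function(slot, col) {
    if (ins_len[slot] == 0L) return(col)
    for (nm in others) {
      v <- per[[nm]]$ins[[slot]]
      if (length(v)) mat[nm, col + seq_along(v)] <<- v
    }
    col + ins_len[slot]
  }
  for (ap in seq_len(la)) {
    col <- emit_ins(ap, col)
    col <- col + 1L
    anchor_pos[col] <- ap - 1L
    mat[anchor, col] <- anchor_chars[ap]
    for (nm in others) mat[nm, col] <- per[[nm]]$base[ap]
  }
  col <- emit_ins(la + 1L, col)
  list(matrix = mat, anchor = anchor, anchor_pos = anchor_pos)
}
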