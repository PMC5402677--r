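# Internal sequence/interval helpers. All intervals are 0-based half-open
# (BED convention); reports convert to 1-based inclusive at the printing edge.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet pairwiseAlignment alignedPattern alignedSubject
#'   nucleotideSubstitutionMatrix
#' @importFrom IRanges IRanges
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Substring by 0-based half-open interval
#' @noRd
seq_slice <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

seq_len_nt <- function(x) nchar(x)

#' Reverse complement of a DNA string (character in, character out)
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

assert_dna <- function(x, what = "sequence") {
  bad <- regexpr("[^ACGT]", x)
  if (bad > 0) {
    stop(sprintf("%s contains non-ACGT character '%s' at position %d",
                 what, substr(x, bad, bad), bad), call. = FALSE)
  }
  invisible(x)
}

#' CpG dinucleotide member positions of a sequence
#'
#' Returns every 0-based position belonging to a CG dinucleotide: for each
#' occurrence of "CG" both the C and the G position are reported.
#' @param seq DNA string.
#' @return Sorted integer vector of 0-based positions.
#' @keywords internal
cpg_positions <- function(seq) {
  hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  sort(unique(c(hits - 1L, hits)))  # hits are 1-based starts of C
}

#' Longest common prefix / suffix lengths of two strings
#' @noRd
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  ca <- utf8ToInt(substr(a, 1, n)); cb <- utf8ToInt(substr(b, 1, n))
  d <- which(ca != cb)
  if (length(d) == 0) n else d[1] - 1L
}

lcs_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  ca <- utf8ToInt(substr(a, nchar(a) - n + 1, nchar(a)))
  cb <- utf8ToInt(substr(b, nchar(b) - n + 1, nchar(b)))
  d <- which(rev(ca) != rev(cb))
  if (length(d) == 0) n else d[1] - 1L
}

#' Does any k-mer of `a` occur in `b`?
#' @noRd
shares_kmer <- function(a, b, k = 20L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(FALSE)
  ka <- substring(a, 1:(na - k + 1), k:na)
  kb <- substring(b, 1:(nb - k + 1), k:nb)
  any(ka %in% kb)
}

#' Draw a random DNA string
#' @noRd
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Derive a bounded child seed from a user seed (keeps values < 2^31)
#' @noRd
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * k) %% 2147483647
}

format_interval <- function(iv) {
  if (is.null(iv)) return("NA")
  sprintf("%d-%d", iv[1] + 1L, iv[2])  # 1-based inclusive for reports
}
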