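# Consensus registry: subfamily consensus sequences with structural and motif
# annotations, plus the AluS/AluY diagnostic-nucleotide panel derived from a
# multiple alignment of all registry members.

#' Construct a consensus record
#'
#' A subfamily consensus sequence with structural annotations. Intervals are
#' 0-based half-open and must be ordered
#' `left_monomer < a_rich_linker < right_monomer` within the sequence.
#' CpG sites are always computed from the sequence itself, never taken from
#' configuration.
#'
#' @param subfamily Subfamily label (e.g. `"AluSx"`).
#' @param seq Upper-case A/C/G/T consensus sequence.
#' @param left_monomer,a_rich_linker,right_monomer Integer length-2 vectors,
#'   0-based half-open.
#' @param motifs Optional data.frame of motif definitions mapped onto this
#'   record (see [load_registry()]).
#' @return Object of class `consensus_record`.
#' @export
consensus_record <- function(subfamily, seq, left_monomer, a_rich_linker,
                             right_monomer, motifs = NULL,
                             length_bounds = c(250L, 350L)) {
  seq <- toupper(seq)
  assert_dna(seq, sprintf("consensus '%s'", subfamily))
  n <- nchar(seq)
  if (n < length_bounds[1] || n > length_bounds[2]) {
    stop(sprintf("consensus '%s' length %d outside [%d, %d]",
                 subfamily, n, length_bounds[1], length_bounds[2]), call. = FALSE)
  }
  ivs <- list(left_monomer = left_monomer, a_rich_linker = a_rich_linker,
              right_monomer = right_monomer)
  for (nm in names(ivs)) {
    iv <- ivs[[nm]]
    if (length(iv) != 2 || iv[1] < 0 || iv[2] > n || iv[1] >= iv[2]) {
      stop(sprintf("consensus '%s': interval %s [%d,%d) out of bounds",
                   subfamily, nm, iv[1], iv[2]), call. = FALSE)
    }
  }
  if (!(left_monomer[2] <= a_rich_linker[1] && a_rich_linker[2] <= right_monomer[1])) {
    stop(sprintf("consensus '%s': intervals must be ordered and non-overlapping",
                 subfamily), call. = FALSE)
  }
  structure(list(
    subfamily = subfamily, seq = seq,
    left_monomer = as.integer(left_monomer),
    a_rich_linker = as.integer(a_rich_linker),
    right_monomer = as.integer(right_monomer),
    cpg_sites = cpg_positions(seq),
    motifs = motifs
  ), class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("<consensus_record> %s  %d nt, %d CpG site positions\n",
              x$subfamily, nchar(x$seq), length(x$cpg_sites)))
  cat(sprintf("  left monomer %s | A-rich linker %s | right monomer %s\n",
              format_interval(x$left_monomer), format_interval(x$a_rich_linker),
              format_interval(x$right_monomer)))
  invisible(x)
}

MOTIF_NAMES <- c("A_box", "B_box", "SRP914_left_major", "SRP914_left_minor",
                 "SRP914_right_major", "SRP914_right_minor",
                 "AC_dinucleotide_left", "AC_dinucleotide_right")
MOTIF_FIXED_LEN <- c(A_box = 11L, B_box = 9L,
                     AC_dinucleotide_left = 2L, AC_dinucleotide_right = 2L)

validate_motif <- function(m, anchor_seq) {
  if (!m$name %in% MOTIF_NAMES) {
    stop(sprintf("unknown motif name '%s'", m$name), call. = FALSE)
  }
  iv <- as.integer(m$interval)
  len <- iv[2] - iv[1]
  if (iv[1] < 0 || iv[2] > nchar(anchor_seq) || len <= 0) {
    stop(sprintf("motif %s: interval [%d,%d) out of bounds", m$name, iv[1], iv[2]),
         call. = FALSE)
  }
  if (!is.null(m$consensus_seq) && nchar(m$consensus_seq) != len) {
    stop(sprintf("motif %s: consensus_seq length %d != interval length %d",
                 m$name, nchar(m$consensus_seq), len), call. = FALSE)
  }
  if (m$name %in% names(MOTIF_FIXED_LEN) && len != MOTIF_FIXED_LEN[[m$name]]) {
    stop(sprintf("motif %s must be %d nt, got %d",
                 m$name, MOTIF_FIXED_LEN[[m$name]], len), call. = FALSE)
  }
  key <- as.integer(m$key_positions %||% integer(0))
  if (length(key) && (min(key) < iv[1] || max(key) >= iv[2])) {
    stop(sprintf("motif %s: key_positions outside interval", m$name), call. = FALSE)
  }
  cons <- m$consensus_seq %||% seq_slice(anchor_seq, iv[1], iv[2])
  cpg <- cpg_positions(anchor_seq)
  list(name = m$name, interval = iv, consensus_seq = toupper(cons),
       key_positions = key,
       cpg_flags = (iv[1]:(iv[2] - 1L)) %in% cpg)
}

#' Load a consensus registry from FASTA plus an annotation config
#'
#' The FASTA holds one consensus per subfamily (headers are the unique
#' subfamily labels). The YAML config carries per-subfamily structural
#' intervals and a motif block defined on a designated anchor consensus;
#' motif coordinates are lifted onto every other record through pairwise
#' alignment to the anchor. CpG sites are computed from each sequence.
#'
#' Config schema (all coordinates 0-based half-open):
#' ```yaml
#' anchor: AluY
#' records:
#'   AluSx: {left_monomer: [0, 130], a_rich_linker: [130, 150],
#'           right_monomer: [150, 290]}
#' motifs:
#'   - name: A_box
#'     interval: [6, 17]
#'     consensus_seq: GGTCGGGAGTC   # optional; defaults to anchor bases
#'     key_positions: []            # absolute anchor coordinates
#' ```
#'
#' @param consensus_fasta Path to the consensus FASTA.
#' @param annotation_config Path to the YAML config.
#' @param length_bounds Allowed consensus length range (real Alu consensuses
#'   are ~300 bp; relax for miniature fixtures).
#' @return Object of class `alu_registry`: a list of [consensus_record()]s
#'   plus the anchor name and the cached inter-consensus star alignment.
#' @export
load_registry <- function(consensus_fasta, annotation_config,
                          length_bounds = c(250L, 350L)) {
  fa <- Biostrings::readDNAStringSet(consensus_fasta)
  seqs <- stats::setNames(as.character(fa), sub("\\s.*$", "", names(fa)))
  if (anyDuplicated(names(seqs))) stop("duplicate subfamily headers in FASTA", call. = FALSE)
  cfg <- yaml::read_yaml(annotation_config)
  anchor <- cfg$anchor %||% names(seqs)[1]
  if (!anchor %in% names(seqs)) {
    stop(sprintf("anchor subfamily '%s' not present in FASTA", anchor), call. = FALSE)
  }
  seqs <- vapply(seqs, toupper, character(1))
  for (nm in names(seqs)) assert_dna(seqs[[nm]], sprintf("consensus '%s'", nm))
  missing <- setdiff(names(cfg$records), names(seqs))
  if (length(missing)) {
    stop(sprintf("config references missing subfamily: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  motifs_anchor <- lapply(cfg$motifs %||% list(), validate_motif,
                          anchor_seq = seqs[[anchor]])
  records <- list()
  for (nm in names(seqs)) {
    rc <- cfg$records[[nm]]
    if (is.null(rc)) {
      stop(sprintf("config provides no intervals for subfamily '%s'", nm), call. = FALSE)
    }
    motifs <- lift_motifs(motifs_anchor, seqs[[anchor]], seqs[[nm]],
                          identical(nm, anchor))
    records[[nm]] <- consensus_record(
      nm, seqs[[nm]],
      left_monomer = as.integer(rc$left_monomer),
      a_rich_linker = as.integer(rc$a_rich_linker),
      right_monomer = as.integer(rc$right_monomer),
      motifs = motifs, length_bounds = length_bounds
    )
  }
  msa <- star_alignment(seqs, anchor = anchor)
  structure(list(records = records, anchor = anchor, msa = msa,
                 alignment_params = list(match = 1, mismatch = -1,
                                         gap_open = 5, gap_extend = 1)),
            class = "alu_registry")
}

# Lift anchor-coordinate motifs onto another consensus via pairwise alignment.
lift_motifs <- function(motifs_anchor, anchor_seq, target_seq, is_anchor) {
  if (!length(motifs_anchor)) return(motifs_anchor)
  if (is_anchor) return(motifs_anchor)
  aln <- align_pair(target_seq, anchor_seq, type = "global")
  cols <- alignment_columns(aln)
  map <- rep(NA_integer_, nchar(anchor_seq))
  keep <- !is.na(cols$s_pos) & !is.na(cols$p_pos)
  map[cols$s_pos[keep] + 1L] <- cols$p_pos[keep]
  lapply(motifs_anchor, function(m) {
    st <- map[m$interval[1] + 1L]; en <- map[m$interval[2]]  # last column
    if (is.na(st) || is.na(en)) return(m)  # not liftable; keep anchor coords
    m$interval_target <- c(st, en + 1L)
    m
  })
}

#' @export
print.alu_registry <- function(x, ...) {
  cat(sprintf("<alu_registry> %d consensus records (anchor %s)\n",
              length(x$records), x$anchor))
  for (r in x$records) {
    cat(sprintf("  %-8s %3d nt  %2d CpG positions\n",
                r$subfamily, nchar(r$seq), length(r$cpg_sites)))
  }
  invisible(x)
}

#' @export
`[[.alu_registry` <- function(x, i) {
  if (is.character(i) && i %in% names(unclass(x)$records)) {
    return(unclass(x)$records[[i]])
  }
  unclass(x)[[i]]
}

registry_labels <- function(registry) names(registry$records)

#' Find AluS/AluY diagnostic positions in the registry alignment
#'
#' Scans the cached inter-consensus multiple alignment for columns that
#' discriminate two groups of subfamilies. *Strict* positions have no gaps,
#' a unanimous base within each group, and different bases between the
#' groups. *Relaxed* positions tolerate at most one deviating member per
#' group and require the two group-majority bases to differ. The function is
#' symmetric in group order up to swapping the reported group bases.
#'
#' @param registry An `alu_registry`.
#' @param group_s,group_y Character vectors of subfamily labels (disjoint,
#'   non-empty).
#' @param include_relaxed Include relaxed positions (default TRUE).
#' @return data.frame with one row per diagnostic position: `alignment_column`
#'   and `anchor_pos` (0-based), `s_base`/`y_base` (group majority bases),
#'   `s_bases`/`y_bases` (all bases seen within the group, collapsed with
#'   `","`), and logical `strict`; sorted by column.
#' @export
find_diagnostic_positions <- function(registry, group_s, group_y,
                                      include_relaxed = TRUE) {
  if (!length(group_s) || !length(group_y)) stop("empty group", call. = FALSE)
  if (length(intersect(group_s, group_y))) stop("groups must be disjoint", call. = FALSE)
  mat <- registry$msa$matrix
  absent <- setdiff(c(group_s, group_y), rownames(mat))
  if (length(absent)) {
    stop(sprintf("alignment missing group member: %s", paste(absent, collapse = ", ")),
         call. = FALSE)
  }
  ms <- mat[group_s, , drop = FALSE]
  my <- mat[group_y, , drop = FALSE]
  out <- list()
  for (col in seq_len(ncol(mat))) {
    bs <- ms[, col]; by <- my[, col]
    if (any(bs == "-") || any(by == "-")) next
    us <- unique(bs); uy <- unique(by)
    strict <- length(us) == 1 && length(uy) == 1 && us != uy
    rel <- FALSE
    maj_s <- names(sort(table(bs), decreasing = TRUE))[1]
    maj_y <- names(sort(table(by), decreasing = TRUE))[1]
    if (!strict && include_relaxed) {
      ok_s <- sum(bs != maj_s) <= 1 && sum(bs == maj_s) > length(bs) / 2
      ok_y <- sum(by != maj_y) <= 1 && sum(by == maj_y) > length(by) / 2
      rel <- ok_s && ok_y && maj_s != maj_y
    }
    if (strict || rel) {
      out[[length(out) + 1L]] <- data.frame(
        alignment_column = col - 1L,
        anchor_pos = registry$msa$anchor_pos[col],
        s_base = maj_s, y_base = maj_y,
        s_bases = paste(sort(us), collapse = ","),
        y_bases = paste(sort(uy), collapse = ","),
        strict = strict, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(alignment_column = integer(0), anchor_pos = integer(0),
                      s_base = character(0), y_base = character(0),
                      s_bases = character(0), y_bases = character(0),
                      strict = logical(0)))
  }
  do.call(rbind, out)
}
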