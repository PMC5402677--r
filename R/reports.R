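# Report writers: TSV tables with a commented header block (tool version,
# parameters, seed) and JSON sidecars. TSV column order is stable and
# diff-friendly.

#' Write a TSV report with a provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param params Named list echoed into `#` header lines.
#' @param seed Seed recorded in the header (optional).
#' @export
write_tsv_report <- function(df, path, params = list(), seed = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("alupoly")),
                  error = function(e) "dev")
  writeLines(sprintf("# alupoly %s", ver), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  for (nm in names(params)) {
    writeLines(sprintf("# %s: %s", nm, paste(format(params[[nm]]), collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV report (skipping the header block)
#' @param path Path written by [write_tsv_report()].
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write cohort observations as FASTA plus truth TSV
#'
#' FASTA records are named `<locus_id>|filled` and `<locus_id>|empty`.
#'
#' @param cohort List with `observations` and `truth` (from the simulators).
#' @param dir Output directory.
#' @param seed Seed echoed into the truth header.
#' @return Invisible list of the paths written.
#' @export
write_cohort <- function(cohort, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- unlist(lapply(cohort$observations, function(o) {
    stats::setNames(c(o$filled_seq, o$empty_seq),
                    paste0(o$locus_id, c("|filled", "|empty")))
  }))
  fa <- file.path(dir, "loci.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  truth <- file.path(dir, "truth.tsv")
  write_tsv_report(cohort$truth, truth, seed = seed)
  alu <- do.call(rbind, lapply(cohort$observations, function(o) {
    if (is.null(o$annotated_alu)) return(NULL)
    data.frame(locus_id = o$locus_id, start = o$annotated_alu[1],
               end = o$annotated_alu[2], stringsAsFactors = FALSE)
  }))
  bed <- NULL
  if (!is.null(alu)) {
    bed <- file.path(dir, "annotated_alu.bed")
    utils::write.table(alu[, c("locus_id", "start", "end")], bed, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(list(fasta = fa, truth = truth, bed = bed))
}

#' Read cohort observations back from FASTA (+ optional BED / validation TSV)
#'
#' Inverse of [write_cohort()] for the sequence part; truth stays separate.
#'
#' @param fasta Path to a `<locus_id>|filled` / `<locus_id>|empty` FASTA.
#' @param bed Optional BED (locus_id, start, end; 0-based half-open) of
#'   annotated Alu intervals on the filled allele.
#' @param truth Optional truth TSV carrying a `validated` column.
#' @return List of [locus_observation()]s.
#' @export
read_cohort <- function(fasta, bed = NULL, truth = NULL) {
  fa <- Biostrings::readDNAStringSet(fasta)
  nm <- names(fa)
  ids <- unique(sub("\\|(filled|empty)$", "", nm))
  alu <- NULL
  if (!is.null(bed)) {
    alu <- utils::read.delim(bed, header = FALSE,
                             col.names = c("locus_id", "start", "end"))
  }
  tr <- if (!is.null(truth)) read_tsv_report(truth) else NULL
  lapply(ids, function(id) {
    f <- as.character(fa[[paste0(id, "|filled")]])
    e <- as.character(fa[[paste0(id, "|empty")]])
    iv <- NULL
    if (!is.null(alu) && id %in% alu$locus_id) {
      r <- alu[alu$locus_id == id, ][1, ]
      iv <- c(r$start, r$end)
    }
    val <- TRUE
    if (!is.null(tr) && id %in% tr$locus_id) val <- tr$validated[tr$locus_id == id][1]
    locus_observation(id, f, e, annotated_alu = iv, validated = val)
  })
}
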