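# Consensus registry: loading/validation, CpG site computation, and the
# diagnostic-position finder against a brute-force oracle.

# Independent oracle: enumerate alignment columns and test unanimity and
# difference directly on the character matrix.
oracle_strict_columns <- function(mat, group_s, group_y) {
  out <- integer(0)
  for (j in seq_len(ncol(mat))) {
    bs <- unique(mat[group_s, j]); by <- unique(mat[group_y, j])
    if (length(bs) == 1 && length(by) == 1 && bs != "-" && by != "-" && bs != by)
      out <- c(out, j - 1L)
  }
  out
}

test_that("registry loads 12 validated records with self-consistent CpG sites", {
  reg <- the_registry
  expect_setequal(names(reg$records), c(S_LABELS, Y_LABELS))
  for (r in reg$records) {
    expect_true(nchar(r$seq) >= 250 && nchar(r$seq) <= 350)
    # every recorded CpG position pair satisfies the CG condition
    cs <- r$cpg_sites
    c_pos <- cs[chars_at(r$seq, cs) == "C"]
    expect_true(all(chars_at(r$seq, c_pos + 1) == "G"))
    expect_true(all(chars_at(r$seq, cs) %in% c("C", "G")))
    expect_setequal(cs, alupoly:::cpg_positions(r$seq))
    expect_true(r$left_monomer[2] <= r$a_rich_linker[1])
    expect_true(r$a_rich_linker[2] <= r$right_monomer[1])
  }
  abox <- Filter(function(m) m$name == "A_box", reg$records[[reg$anchor]]$motifs)[[1]]
  expect_identical(nchar(abox$consensus_seq), 11L)
  bbox <- Filter(function(m) m$name == "B_box", reg$records[[reg$anchor]]$motifs)[[1]]
  expect_identical(nchar(bbox$consensus_seq), 9L)
})

test_that("registry loader rejects malformed inputs with informative errors", {
  cs <- synthetic_consensus_set()
  dir <- tempfile("reg"); dir.create(dir)
  fa <- file.path(dir, "c.fasta"); cfg_path <- file.path(dir, "c.yaml")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cs$sequences), fa)

  bad <- cs$config
  bad$motifs[[1]]$interval <- list(6L, 16L)  # 10-base A box
  bad$motifs[[1]]$consensus_seq <- substr(bad$motifs[[1]]$consensus_seq, 1, 10)
  yaml::write_yaml(bad, cfg_path)
  expect_error(load_registry(fa, cfg_path), "A_box must be 11")

  bad <- cs$config
  bad$records[["AluQx"]] <- bad$records[[1]]
  yaml::write_yaml(bad, cfg_path)
  expect_error(load_registry(fa, cfg_path), "missing subfamily")

  bad <- cs$config
  bad$records[["AluSx"]]$right_monomer <- list(150L, 9999L)
  yaml::write_yaml(bad, cfg_path)
  expect_error(load_registry(fa, cfg_path), "out of bounds")

  seqs2 <- cs$sequences
  seqs2[["AluSx"]] <- sub("G", "N", seqs2[["AluSx"]])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs2), fa)
  yaml::write_yaml(cs$config, cfg_path)
  expect_error(load_registry(fa, cfg_path), "non-ACGT.*position", perl = TRUE)
})

test_that("diagnostic finder: identical groups yield no positions; toy case found", {
  reg <- toy_registry(c(a1 = "ACGT", a2 = "ACGT", b1 = "ACGT", b2 = "ACGT"))
  expect_identical(nrow(find_diagnostic_positions(reg, c("a1", "a2"), c("b1", "b2"))), 0L)

  reg <- toy_registry(c(a1 = "ACGT", a2 = "ACGT", b1 = "ACCT", b2 = "ACCT"))
  pos <- find_diagnostic_positions(reg, c("a1", "a2"), c("b1", "b2"))
  expect_identical(nrow(pos), 1L)
  expect_identical(pos$alignment_column, 2L)
  expect_identical(pos$s_base, "G")
  expect_identical(pos$y_base, "C")
  expect_true(pos$strict)
})

test_that("the 12-subfamily registry yields 5 strict positions, 2 left + 3 right", {
  strict <- the_panel[the_panel$strict, ]
  expect_identical(nrow(strict), 5L)
  left <- the_registry$records[[the_registry$anchor]]$left_monomer
  right <- the_registry$records[[the_registry$anchor]]$right_monomer
  expect_identical(sum(strict$anchor_pos >= left[1] & strict$anchor_pos < left[2]), 2L)
  expect_identical(sum(strict$anchor_pos >= right[1] & strict$anchor_pos < right[2]), 3L)
  expect_identical(nrow(the_panel), 12L)  # 5 strict + 7 relaxed
  expect_false(is.unsorted(the_panel$alignment_column))
})

test_that("strict positions match the brute-force oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:5) {
    base <- alupoly:::random_dna(120)
    seqs <- stats::setNames(rep(base, 8), c(paste0("s", 1:4), paste0("y", 1:4)))
    for (p in sample(0:119, 6)) {
      yb <- alupoly:::alt_base(substr(base, p + 1, p + 1))
      for (nm in paste0("y", 1:4)) seqs[[nm]] <- put(seqs[[nm]], p, yb)
    }
    for (nm in names(seqs)) {   # sprinkle private noise
      p <- sample(0:119, 2)
      for (q in p) seqs[[nm]] <- put(seqs[[nm]], q,
                                     alupoly:::alt_base(substr(seqs[[nm]], q + 1, q + 1), 2))
    }
    reg <- toy_registry(seqs)
    got <- find_diagnostic_positions(reg, paste0("s", 1:4), paste0("y", 1:4))
    expect_setequal(got$alignment_column[got$strict],
                    oracle_strict_columns(reg$msa$matrix, paste0("s", 1:4), paste0("y", 1:4)))
  }
})

test_that("diagnostic finder is symmetric and stable under member duplication", {
  fwd <- find_diagnostic_positions(the_registry, S_LABELS, Y_LABELS)
  rev <- find_diagnostic_positions(the_registry, Y_LABELS, S_LABELS)
  expect_identical(fwd$alignment_column, rev$alignment_column)
  expect_identical(fwd$s_base, rev$y_base)
  expect_identical(fwd$y_base, rev$s_base)
  expect_identical(fwd$strict, rev$strict)

  # duplicating an existing group member never changes the strict set
  seqs <- stats::setNames(
    vapply(the_registry$records, `[[`, character(1), "seq"),
    names(the_registry$records))
  seqs[["AluSx_dup"]] <- seqs[["AluSx"]]
  reg2 <- toy_registry(seqs, anchor = the_registry$anchor)
  got2 <- find_diagnostic_positions(reg2, c(S_LABELS, "AluSx_dup"), Y_LABELS)
  expect_setequal(got2$alignment_column[got2$strict],
                  fwd$alignment_column[fwd$strict])
})

test_that("star alignment merges insertions relative to the anchor", {
  seqs <- c(anchor = "ACGTACGTAC", ins = "ACGTTTACGTAC", del = "ACGTCGTAC")
  msa <- star_alignment(seqs, anchor = "anchor")
  # every row reproduces its input after deleting gaps
  for (nm in names(seqs)) {
    expect_identical(gsub("-", "", paste(msa$matrix[nm, ], collapse = "")),
                     unname(seqs[[nm]]))
  }
  # anchor positions are a strictly increasing subsequence over columns
  ap <- msa$anchor_pos[!is.na(msa$anchor_pos)]
  expect_identical(ap, 0:(nchar(seqs[["anchor"]]) - 1L))
})
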