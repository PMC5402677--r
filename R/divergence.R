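# Divergence from subfamily consensus, CpG-aware substitution densities,
# two-rate neutral-clock age estimation, and the permutation test against a
# genome-background divergence distribution.

#' Neutral clock parameters
#'
#' Substitution rates per nucleotide position per year: non-CpG sites evolve
#' at `k_noncpg` and CpG sites six-fold faster (spontaneous deamination of
#' methylated cytosines), the rates used throughout primate Alu dating.
#'
#' @param k_noncpg Non-CpG rate (default 1.5e-9 /site/year).
#' @param k_cpg CpG rate (default 9e-9 /site/year).
#' @export
clock_parameters <- function(k_noncpg = 1.5e-9, k_cpg = 9e-9) {
  stopifnot(k_noncpg > 0, k_cpg > 0)
  list(k_noncpg = k_noncpg, k_cpg = k_cpg)
}

#' Count CpG and non-CpG substitutions in an element/consensus alignment
#'
#' Sites are classed by the consensus: positions belonging to a consensus
#' CpG dinucleotide are CpG sites, everything else non-CpG. At CpG sites only
#' C-to-T (at the C) and G-to-A (at the G) changes are counted as
#' substitutions — the deamination signature the CpG clock is calibrated on;
#' other changes at CpG sites are ignored. At non-CpG sites every base change
#' counts. Indel columns are excluded from both numerator and denominator.
#'
#' @param aln Pairwise alignment from [align_pair()] (pattern = element,
#'   subject = consensus).
#' @param consensus A [consensus_record()].
#' @return Named integer vector: `cpg_subs`, `cpg_sites`, `noncpg_subs`,
#'   `noncpg_sites` (site counts are the consensus positions of each class
#'   present in the alignment).
#' @export
count_cpg_substitutions <- function(aln, consensus) {
  cols <- alignment_columns(aln)
  both <- !is.na(cols$p_pos) & !is.na(cols$s_pos)
  cols <- cols[both, , drop = FALSE]
  is_cpg <- cols$s_pos %in% consensus$cpg_sites
  cp <- cols[is_cpg, , drop = FALSE]
  ncp <- cols[!is_cpg, , drop = FALSE]
  cpg_subs <- sum((cp$s_char == "C" & cp$p_char == "T") |
                  (cp$s_char == "G" & cp$p_char == "A"))
  c(cpg_subs = as.integer(cpg_subs),
    cpg_sites = nrow(cp),
    noncpg_subs = as.integer(sum(ncp$p_char != ncp$s_char)),
    noncpg_sites = nrow(ncp))
}

#' Estimate element age from substitution densities
#'
#' Age = density / k, reported in million years, separately for the CpG and
#' non-CpG site classes. A class with zero sites yields NA.
#'
#' @param cpg_density,noncpg_density Substitution densities in `[0, 1]`
#'   (counted substitutions / sites of the class).
#' @param clock A [clock_parameters()].
#' @return Named numeric vector `c(age_cpg, age_noncpg)` in My.
#' @export
estimate_age <- function(cpg_density, noncpg_density, clock = clock_parameters()) {
  stopifnot(is.na(cpg_density) || (cpg_density >= 0 && cpg_density <= 1),
            is.na(noncpg_density) || (noncpg_density >= 0 && noncpg_density <= 1))
  c(age_cpg = unname(cpg_density / clock$k_cpg / 1e6),
    age_noncpg = unname(noncpg_density / clock$k_noncpg / 1e6))
}

#' Percent divergence and age of an element against a consensus
#'
#' Trims the poly-A tail, globally aligns the element to the consensus
#' (consensus ends free), and reports percent divergence (substituted
#' columns / aligned non-gap columns x 100) together with the CpG/non-CpG
#' substitution breakdown and the two clock ages. Alignments covering less
#' than half the consensus are flagged low-confidence.
#'
#' @param element_seq Element sequence (tail trimmed internally).
#' @param consensus A [consensus_record()].
#' @param clock A [clock_parameters()].
#' @param trim_polyA Remove the 3' poly-A tail before aligning.
#' @param element_id Optional label for the output row.
#' @return One-row data.frame (class `divergence_result`): `element_id`,
#'   `subfamily`, `percent_divergence`, `aligned_columns`, `cpg_subs`,
#'   `cpg_sites`, `noncpg_subs`, `noncpg_sites`, `age_cpg`, `age_noncpg`,
#'   `low_confidence`.
#' @export
percent_divergence <- function(element_seq, consensus,
                               clock = clock_parameters(),
                               trim_polyA = TRUE,
                               element_id = NA_character_) {
  seq <- element_seq
  if (trim_polyA) {
    tail <- detect_polyA(seq)
    if (!is.null(tail)) seq <- seq_slice(seq, 0L, tail$interval[1])
  }
  pd <- pair_divergence(seq, consensus$seq, type = "global-local")
  counts <- count_cpg_substitutions(pd$aln, consensus)
  dens_cpg <- if (counts["cpg_sites"] > 0)
    counts["cpg_subs"] / counts["cpg_sites"] else NA_real_
  dens_ncpg <- if (counts["noncpg_sites"] > 0)
    counts["noncpg_subs"] / counts["noncpg_sites"] else NA_real_
  ages <- estimate_age(dens_cpg, dens_ncpg, clock)
  out <- data.frame(
    element_id = element_id, subfamily = consensus$subfamily,
    percent_divergence = pd$divergence, aligned_columns = pd$aligned_columns,
    cpg_subs = unname(counts["cpg_subs"]), cpg_sites = unname(counts["cpg_sites"]),
    noncpg_subs = unname(counts["noncpg_subs"]),
    noncpg_sites = unname(counts["noncpg_sites"]),
    age_cpg = unname(ages["age_cpg"]), age_noncpg = unname(ages["age_noncpg"]),
    low_confidence = pd$aligned_columns < 0.5 * nchar(consensus$seq),
    stringsAsFactors = FALSE
  )
  class(out) <- c("divergence_result", class(out))
  out
}

#' Permutation test of mean divergence against a background
#'
#' Draws `n_resamples` samples of size `n` with replacement from the
#' background divergence vector and reports
#' `p = Pr(resampled mean < observed_mean)` — the fraction of background
#' samples less diverged than the observed set.
#'
#' @param observed_mean Observed mean percent divergence.
#' @param background Numeric vector of background percent divergences.
#' @param n Sample size per resample.
#' @param n_resamples Number of resamples (>= 1).
#' @param seed Optional seed recorded in the result; when supplied the RNG
#'   state is set locally and restored on exit.
#' @return List of class `permutation_result`: `observed_mean`,
#'   `background_size`, `n`, `n_resamples`, `p_value`, `seed`.
#' @export
permutation_test <- function(observed_mean, background, n = 7L,
                             n_resamples = 1e6, seed = NULL) {
  stopifnot(length(background) >= 1, n >= 1)
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n_resamples <- as.numeric(n_resamples)
  hits <- 0
  done <- 0
  chunk <- 1e5
  while (done < n_resamples) {
    b <- min(chunk, n_resamples - done)
    m <- matrix(sample(background, n * b, replace = TRUE), nrow = n)
    hits <- hits + sum(.colMeans(m, n, b) < observed_mean)
    done <- done + b
  }
  structure(list(observed_mean = observed_mean,
                 background_size = length(background),
                 n = as.integer(n), n_resamples = n_resamples,
                 p_value = hits / n_resamples, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> p = %.6f (Pr(mean of %d < %.3f), %g resamples, background n = %d)\n",
    x$p_value, x$n, x$observed_mean, x$n_resamples, x$background_size))
  invisible(x)
}

#' Read a background divergence table
#'
#' Accepts either the classic repeat-annotation `.out` dialect (three header
#' lines then whitespace-separated columns, percent divergence in column 2)
#' or a plain TSV: a single unnamed column of percent divergences, or a
#' header naming one of `perc_div` / `percDiv` (used as-is) or `milliDiv`
#' (divided by 10).
#'
#' @param path File path.
#' @param format `"auto"`, `"rm_out"` or `"tsv"`.
#' @param repeat_filter Optional regex; keeps only `.out` rows whose repeat
#'   name matches (e.g. `"^AluS"`).
#' @return Numeric vector of percent divergences.
#' @export
read_background_divergence <- function(path, format = c("auto", "rm_out", "tsv"),
                                       repeat_filter = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (length(lines) >= 1 &&
                  grepl("^\\s*SW|^\\s*score", lines[1], ignore.case = TRUE))
      "rm_out" else "tsv"
  }
  if (format == "rm_out") {
    body <- lines[-seq_len(min(3L, length(lines)))]
    body <- body[nzchar(trimws(body))]
    fields <- strsplit(trimws(body), "\\s+")
    div <- vapply(fields, function(f) as.numeric(f[2]), numeric(1))
    if (!is.null(repeat_filter)) {
      rep_name <- vapply(fields, function(f) f[10], character(1))
      div <- div[grepl(repeat_filter, rep_name)]
    }
    return(div)
  }
  first <- strsplit(trimws(lines[1]), "\t")[[1]]
  if (suppressWarnings(!is.na(as.numeric(first[1])))) {
    return(as.numeric(vapply(strsplit(trimws(lines), "\t"), `[`, character(1), 1)))
  }
  df <- utils::read.delim(path, check.names = FALSE)
  if ("milliDiv" %in% names(df)) return(df$milliDiv / 10)
  for (nm in c("perc_div", "percDiv", "percent_divergence")) {
    if (nm %in% names(df)) return(as.numeric(df[[nm]]))
  }
  as.numeric(df[[1]])
}
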