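# Ground-truthed synthetic data: a 12-subfamily synthetic consensus registry,
# a CpG-elevated neutral mutation clock, per-mechanism locus generators, a
# 48-locus study-condition cohort, and a genome-background divergence
# generator. Everything is seeded and deterministic; every generated locus
# carries a truth record.

SYNTH_LEN <- 290L
ALU_S_LABELS <- c("AluSc", "AluSg", "AluSp", "AluSq", "AluSx", "AluSz")
ALU_Y_LABELS <- c("AluY", "AluYa5", "AluYa8", "AluYb8", "AluYb9", "AluYc1")

# fixed layout of the synthetic ancestral consensus (0-based half-open)
SYNTH_LAYOUT <- list(
  left_monomer = c(0L, 130L),
  a_rich_linker = c(130L, 150L),
  right_monomer = c(150L, 290L),
  A_box = c(6L, 17L),
  B_box = c(70L, 79L),
  SRP914_left_major = c(30L, 44L),
  SRP914_left_minor = c(96L, 106L),
  SRP914_right_major = c(190L, 202L),
  AC_dinucleotide_left = c(118L, 120L),
  AC_dinucleotide_right = c(230L, 232L)
)
SYNTH_KEY_POSITIONS <- list(
  SRP914_left_major = c(33L, 36L, 39L, 42L),
  SRP914_left_minor = c(98L, 101L, 103L),
  SRP914_right_major = c(193L, 196L, 199L)
)
SYNTH_STRICT_DIAG <- c(25L, 60L, 165L, 210L, 250L)       # 2 left + 3 right
SYNTH_RELAXED_DIAG <- c(50L, 90L, 125L, 160L, 220L, 260L, 280L)

alt_base <- function(b, step = 1L) {
  bases <- c("A", "C", "G", "T")
  bases[((match(b, bases) - 1L + step) %% 4L) + 1L]
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

set_chars <- function(seq, pos0, value) {
  # overwrite seq at 0-based position(s) with value (string or char vector)
  ch <- seq_chars(seq)
  v <- if (length(value) == 1L && nchar(value) > 1L) seq_chars(value) else value
  ch[pos0 + 1L] <- v
  paste(ch, collapse = "")
}

#' Synthetic 12-subfamily consensus set
#'
#' Builds a fixed synthetic ancestral Alu-like consensus (290 nt: left
#' monomer, A-rich linker, right monomer; A/B boxes, SRP9/14 sites and AC
#' dinucleotides at known coordinates) and derives six AluS-group and six
#' AluY-group subfamily consensuses from it: 5 strict diagnostic positions
#' (2 in the left monomer, 3 in the right) separate the groups, 7 relaxed
#' positions have one deviating member each, and every subfamily carries 8
#' private substitutions. The set is deterministic (internally seeded) and
#' stands in for licensed reference consensus sequences in all tests and
#' analyses; it is synthetic, not a reconstruction of any published
#' consensus.
#'
#' @return List with `sequences` (named character vector), `config` (the
#'   annotation-config list, see [load_registry()]), and `meta` (planted
#'   structure: diagnostic positions, motif layout, per-subfamily private
#'   substitution positions, mutable-position pools).
#' @export
synthetic_consensus_set <- function() {
  with_local_seed(20170424, {
    L <- SYNTH_LEN
    anc <- random_dna(L, gc = 0.55)
    anc <- set_chars(anc, 0L, "G")
    anc <- set_chars(anc, c(288L, 289L), "CC")
    anc <- set_chars(anc, SYNTH_LAYOUT$a_rich_linker[1] + 0:19,
                     "AAAATACAAAAATACAAAAA")
    motif_strings <- list(
      A_box = "TGGCTCACGCC",          # CpG at layout positions 13-14
      B_box = "GTTCGAAAC",            # CpG at 73-74
      SRP914_left_major = "GCTGTAATCCCAGC",
      SRP914_left_minor = "GGATTACAGG",
      SRP914_right_major = "GCTGAGATTGCA",
      AC_dinucleotide_left = "AC",
      AC_dinucleotide_right = "AC"
    )
    for (nm in names(motif_strings)) {
      anc <- set_chars(anc, SYNTH_LAYOUT[[nm]][1] + seq_len(nchar(motif_strings[[nm]])) - 1L,
                       motif_strings[[nm]])
    }
    # guard bases so planted motif mismatches stay in their designed CpG class
    anc <- set_chars(anc, 120L, "A")  # AC-left C stays non-CpG
    anc <- set_chars(anc, 17L, "T"); anc <- set_chars(anc, 79L, "T")
    diag_all <- c(SYNTH_STRICT_DIAG, SYNTH_RELAXED_DIAG)
    # keep diagnostic columns out of CpG context so they never interact with
    # the CpG clock
    for (p in diag_all) {
      if (substr(anc, p + 1L, p + 1L) %in% c("C", "G")) anc <- set_chars(anc, p, "T")
      if (p > 0 && substr(anc, p, p) == "C" && substr(anc, p + 1L, p + 1L) == "G")
        anc <- set_chars(anc, p, "A")
    }

    # enrich CpG density to realistic Alu levels (~24 CpG dinucleotides):
    # Alu elements are CpG-rich, which is what gives the CpG clock its power
    enrich_occupied <- unique(c(
      unlist(lapply(names(motif_strings), function(nm) {
        iv <- SYNTH_LAYOUT[[nm]]; iv[1]:(iv[2] - 1L)
      })),
      SYNTH_LAYOUT$a_rich_linker[1]:(SYNTH_LAYOUT$a_rich_linker[2] - 1L),
      diag_all, diag_all + 1L, diag_all - 1L, 0L, 288L, 289L))
    cand <- setdiff(1:286, enrich_occupied)
    chosen <- integer(0)
    for (p in sample(cand)) {
      if (length(chosen) >= 10L) break
      if (!(p + 1L) %in% cand) next
      if (length(chosen) && min(abs(chosen - p)) < 3L) next
      anc <- set_chars(anc, c(p, p + 1L), "CG")
      chosen <- c(chosen, p)
    }

    labels <- c(ALU_S_LABELS, ALU_Y_LABELS)
    seqs <- stats::setNames(rep(anc, length(labels)), labels)

    # strict diagnostic positions: AluS keeps the ancestral base, AluY shifts
    for (p in SYNTH_STRICT_DIAG) {
      yb <- alt_base(substr(anc, p + 1L, p + 1L))
      for (nm in ALU_Y_LABELS) seqs[[nm]] <- set_chars(seqs[[nm]], p, yb)
    }
    # relaxed positions: differing group majorities, one deviating member each
    relaxed_plan <- list(
      list(pos = 50L,  deviant = "AluSc",  dev_to = "y"),
      list(pos = 90L,  deviant = "AluYb8", dev_to = "s"),
      list(pos = 125L, deviant = "AluSg",  dev_to = "novel"),
      list(pos = 160L, deviant = "AluYa5", dev_to = "novel"),
      list(pos = 220L, deviant = "AluSz",  dev_to = "y"),
      list(pos = 260L, deviant = "AluSq",  dev_to = "novel"),
      list(pos = 280L, deviant = "AluYc1", dev_to = "novel")
    )
    for (rp in relaxed_plan) {
      p <- rp$pos
      sb <- substr(anc, p + 1L, p + 1L)
      yb <- alt_base(sb); nb <- alt_base(sb, 2L)
      for (nm in ALU_Y_LABELS) seqs[[nm]] <- set_chars(seqs[[nm]], p, yb)
      dv <- switch(rp$dev_to, y = yb, s = sb, novel = nb)
      seqs[[rp$deviant]] <- set_chars(seqs[[rp$deviant]], p, dv)
    }

    # private substitutions: 8 per subfamily at disjoint free positions
    motif_pos <- unlist(lapply(names(motif_strings), function(nm) {
      iv <- SYNTH_LAYOUT[[nm]]; iv[1]:(iv[2] - 1L)
    }))
    linker_pos <- SYNTH_LAYOUT$a_rich_linker[1]:(SYNTH_LAYOUT$a_rich_linker[2] - 1L)
    cpg_anc <- cpg_positions(anc)
    reserved <- unique(c(0L, 288L, 289L, motif_pos, linker_pos, diag_all,
                         cpg_anc, cpg_anc + 1L, cpg_anc - 1L))
    free_pool <- setdiff(0:(L - 1L), reserved)
    free_pool <- sample(free_pool)
    private <- list()
    idx <- 0L
    for (nm in labels) {
      pp <- sort(free_pool[idx + 1:8]); idx <- idx + 8L
      for (p in pp) {
        seqs[[nm]] <- set_chars(seqs[[nm]], p,
                                alt_base(substr(anc, p + 1L, p + 1L),
                                         1L + (match(nm, labels) %% 3L)))
      }
      private[[nm]] <- pp
    }
    remaining_pool <- sort(free_pool[-seq_len(idx)])

    motifs_cfg <- lapply(names(motif_strings), function(nm) {
      cfgnm <- if (nm %in% c("A_box", "B_box")) nm else nm
      list(name = cfgnm, interval = as.list(SYNTH_LAYOUT[[nm]]),
           consensus_seq = motif_strings[[nm]],
           key_positions = as.list(SYNTH_KEY_POSITIONS[[nm]] %||% integer(0)))
    })
    rec_cfg <- stats::setNames(lapply(labels, function(nm) {
      list(left_monomer = as.list(SYNTH_LAYOUT$left_monomer),
           a_rich_linker = as.list(SYNTH_LAYOUT$a_rich_linker),
           right_monomer = as.list(SYNTH_LAYOUT$right_monomer))
    }), labels)
    config <- list(anchor = "AluY", records = rec_cfg, motifs = motifs_cfg)
    meta <- list(ancestral = anc,
                 strict_diag = SYNTH_STRICT_DIAG, relaxed_diag = SYNTH_RELAXED_DIAG,
                 motif_positions = sort(unique(motif_pos)),
                 linker_positions = linker_pos,
                 private = private, free_pool = remaining_pool,
                 motif_strings = motif_strings, layout = SYNTH_LAYOUT)
    list(sequences = seqs, config = config, meta = meta)
  })
}

#' Write the synthetic consensus set and load it as a registry
#'
#' Writes FASTA + YAML config (exercising the registry IO path) and returns
#' the loaded `alu_registry` with the planted-structure metadata attached as
#' attribute `"synthetic_meta"`.
#'
#' @param dir Directory for the two files (created if needed).
#' @export
synthetic_registry <- function(dir = tempfile("synthetic_registry")) {
  cs <- synthetic_consensus_set()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "synthetic_consensus.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cs$sequences), fa)
  cfg <- file.path(dir, "synthetic_consensus.yaml")
  yaml::write_yaml(cs$config, cfg)
  reg <- load_registry(fa, cfg)
  attr(reg, "synthetic_meta") <- cs$meta
  reg
}

#' Simulation configuration
#'
#' Defaults are the study conditions: TSD lengths uniform on 10–21 bp,
#' poly-A tails 20–32 bp, non-Alu filler 2 bp–2 kb (log-uniform),
#' target-site deletions 0–14 bp, insertion ages 10–45 My, ancestral
#' (pre-deletion) insertions 35–60 My old, endonuclease sites at
#' consensus TTTT/AA.
#'
#' @param seed Optional integer seed applied by the cohort-level generators.
#' @param n_per_class Loci per mechanism class for [simulate_cohort()].
#' @param tsd_len_range,polyA_len_range,filler_range,target_site_deletion_range
#'   Inclusive integer supports.
#' @param trunc_5p_range 5' truncation support for TPRT loci.
#' @param age_range_My Insertion-age support (My).
#' @param ancestral_age_range_My Age support for fixed pre-deletion Alus.
#' @param flank_len Flank length per side (bp).
#' @param en_site_mode `"consensus"` (plant TTTT/AA) or `"degenerate"`
#'   (plant 1–2 mismatches).
#' @param clock [clock_parameters()].
#' @export
simulation_config <- function(seed = NULL, n_per_class = 20L,
                              tsd_len_range = c(10L, 21L),
                              polyA_len_range = c(20L, 32L),
                              filler_range = c(2L, 2000L),
                              target_site_deletion_range = c(0L, 14L),
                              trunc_5p_range = c(0L, 0L),
                              age_range_My = c(10, 45),
                              ancestral_age_range_My = c(35, 60),
                              flank_len = 150L,
                              en_site_mode = c("consensus", "degenerate"),
                              clock = clock_parameters()) {
  list(seed = seed, n_per_class = as.integer(n_per_class),
       tsd_len_range = tsd_len_range, polyA_len_range = polyA_len_range,
       filler_range = filler_range,
       target_site_deletion_range = target_site_deletion_range,
       trunc_5p_range = trunc_5p_range,
       age_range_My = age_range_My,
       ancestral_age_range_My = ancestral_age_range_My,
       flank_len = as.integer(flank_len),
       en_site_mode = match.arg(en_site_mode), clock = clock)
}

runif_int <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  sample(range[1]:range[2], 1L)
}

rlog_unif_int <- function(range) {
  as.integer(round(exp(stats::runif(1, log(range[1]), log(range[2])))))
}

#' Apply the CpG-elevated neutral mutation clock
#'
#' Each non-CpG site substitutes with probability `k_noncpg * T` (to a
#' uniformly random different base); each CpG site substitutes with
#' probability `k_cpg * T` as the deamination transition (C->T at the C,
#' G->A at the G) that the CpG clock is calibrated on. Probabilities use the
#' linear form p = kT, matching the linear density/k age inversion (for
#' T <= 60 My the difference from 1 - exp(-kT) is < 0.5%).
#'
#' @param seq Sequence to mutate.
#' @param age_My Age in million years.
#' @param clock [clock_parameters()].
#' @param cpg_sites CpG member positions (default: computed from `seq`).
#' @return List with `seq`, `n_cpg_subs`, `n_noncpg_subs`, and the mutated
#'   positions.
#' @export
apply_mutation_clock <- function(seq, age_My, clock = clock_parameters(),
                                 cpg_sites = cpg_positions(seq)) {
  if (age_My <= 0) {
    return(list(seq = seq, n_cpg_subs = 0L, n_noncpg_subs = 0L,
                cpg_positions_hit = integer(0), noncpg_positions_hit = integer(0)))
  }
  T_years <- age_My * 1e6
  ch <- seq_chars(seq)
  n <- length(ch)
  is_cpg <- (0:(n - 1L)) %in% cpg_sites
  p <- ifelse(is_cpg, clock$k_cpg * T_years, clock$k_noncpg * T_years)
  hit <- stats::runif(n) < p
  cpg_hit <- which(hit & is_cpg)
  ncpg_hit <- which(hit & !is_cpg)
  for (i in cpg_hit) {
    ch[i] <- if (ch[i] == "C") "T" else if (ch[i] == "G") "A" else alt_base(ch[i])
  }
  for (i in ncpg_hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  list(seq = paste(ch, collapse = ""),
       n_cpg_subs = length(cpg_hit), n_noncpg_subs = length(ncpg_hit),
       cpg_positions_hit = cpg_hit - 1L, noncpg_positions_hit = ncpg_hit - 1L)
}

# Draw an endonuclease site: returns list(flank_tail = 2 top-strand bases
# immediately 5' of the TSD, tsd_head = first 4 TSD bases, mismatches).
draw_en_site <- function(mode, n_mismatch = NULL) {
  top <- seq_chars("TTAAAA")  # top strand of the TTTT/AA negative-strand site
  m <- 0L
  if (mode == "degenerate") {
    m <- n_mismatch %||% sample(1:2, 1L)
    pos <- sample(1:6, m)
    for (i in pos) top[i] <- sample(setdiff(c("A", "C", "G", "T"), top[i]), 1L)
  }
  list(flank_tail = paste(top[1:2], collapse = ""),
       tsd_head = paste(top[3:6], collapse = ""), mismatches = m)
}

draw_tsd <- function(len, en, body_first) {
  for (try in 1:100) {
    rest <- random_dna(max(0L, len - 4L))
    tsd <- paste0(en$tsd_head, rest)
    tsd <- substr(tsd, 1L, len)
    last <- substr(tsd, len, len)
    fifth <- if (len >= 5L) substr(tsd, 5L, 5L) else "C"
    if (substr(tsd, 1L, 1L) != body_first && last != "A" && fifth != "A") return(tsd)
  }
  NULL  # irreconcilable with this element start; caller redraws the locus
}

draw_flank <- function(len, last_not = "A") {
  repeat {
    fl <- random_dna(len)
    if (!substr(fl, len, len) %in% last_not) return(fl)
  }
}

new_truth <- function(locus_id, mechanism, subfamily, category = NA_character_,
                      tsd_len = NA_integer_, polyA_len = NA_integer_,
                      trunc_5p = NA_integer_, trunc_3p = NA_integer_,
                      non_alu_3p = NA_integer_, target_site_deletion = NA_integer_,
                      age_My = NA_real_, en_mismatches = NA_integer_,
                      n_cpg_subs = NA_integer_, n_noncpg_subs = NA_integer_,
                      validated = TRUE) {
  data.frame(locus_id = locus_id, mechanism = mechanism, subfamily = subfamily,
             category = category, tsd_len = tsd_len, polyA_len = polyA_len,
             trunc_5p = trunc_5p, trunc_3p = trunc_3p, non_alu_3p = non_alu_3p,
             target_site_deletion = target_site_deletion, age_My = age_My,
             en_mismatches = en_mismatches, n_cpg_subs = n_cpg_subs,
             n_noncpg_subs = n_noncpg_subs, validated = validated,
             stringsAsFactors = FALSE)
}

#' Simulate a TPRT (or internal-priming) insertion locus
#'
#' Plants an endonuclease site in the 5' flank, inserts a (optionally
#' 5'-truncated) consensus copy with a poly-A tail, duplicates the target
#' site as a TSD, and applies the mutation clock for the drawn age. With
#' `with_tail = FALSE` the generator emits the internal-priming variant
#' (full-length, TSD-flanked, tail-less, no endonuclease site). Draws whose
#' flank or junction bases would make the indel placement ambiguous or the
#' tail/TSD parse degenerate are regenerated, so noiseless loci round-trip
#' exactly.
#'
#' @param registry `alu_registry` (synthetic or real).
#' @param cfg [simulation_config()].
#' @param subfamily Subfamily label (default: drawn from the AluS group).
#' @param age_My,tsd_len,polyA_len,trunc_5p Optional fixed values (otherwise
#'   drawn from `cfg`).
#' @param with_tail Plant a poly-A tail (FALSE = internal priming).
#' @param en_mode Override `cfg$en_site_mode`; internal priming always uses
#'   a random (non-consensus) site.
#' @param locus_id Label.
#' @param validated PCR-validation flag carried into the truth record.
#' @return List with `obs` ([locus_observation()]) and `truth` (one-row
#'   data.frame).
#' @export
simulate_tprt_locus <- function(registry, cfg = simulation_config(),
                                subfamily = NULL, age_My = NULL,
                                tsd_len = NULL, polyA_len = NULL,
                                trunc_5p = NULL, with_tail = TRUE,
                                en_mode = NULL, locus_id = "tprt_1",
                                validated = TRUE) {
  subfamily <- subfamily %||% sample(intersect(ALU_S_LABELS, registry_labels(registry)), 1L)
  cons <- registry$records[[subfamily]]
  age <- age_My %||% stats::runif(1, cfg$age_range_My[1], cfg$age_range_My[2])
  k <- tsd_len %||% runif_int(cfg$tsd_len_range)
  t <- if (with_tail) polyA_len %||% runif_int(cfg$polyA_len_range) else 0L
  for (try in 1:50) {
    tr5 <- trunc_5p %||% runif_int(cfg$trunc_5p_range)
    # element start must differ from the TSD head for a unique placement
    while (substr(cons$seq, tr5 + 1L, tr5 + 1L) == "A" && tr5 < nchar(cons$seq) - 60L)
      tr5 <- tr5 + 1L
    mut <- apply_mutation_clock(seq_slice(cons$seq, tr5, nchar(cons$seq)),
                                age, cfg$clock,
                                cpg_sites = cons$cpg_sites[cons$cpg_sites >= tr5] - tr5)
    body <- mut$seq
    en <- if (with_tail) draw_en_site(en_mode %||% cfg$en_site_mode)
          else draw_en_site("degenerate", n_mismatch = sample(3:6, 1L))
    tsd <- draw_tsd(k, en, substr(body, 1L, 1L))
    if (is.null(tsd)) next
    L <- paste0(draw_flank(cfg$flank_len - 2L), en$flank_tail)
    if (substr(L, nchar(L), nchar(L)) == "A") next
    R <- draw_flank(cfg$flank_len, last_not = character(0))
    X <- paste0(body, strrep("A", t))
    filled <- paste0(L, tsd, X, tsd, R)
    empty <- paste0(L, tsd, R)
    obs <- locus_observation(locus_id, filled, empty, annotated_alu = NULL,
                             subfamily_hint = subfamily, in_reference = FALSE,
                             validated = validated)
    # well-posedness: unique placement and exact tail/TSD parse
    f5 <- paste0(L, tsd); I <- paste0(X, tsd)
    if (substr(X, 1L, 1L) == substr(tsd, 1L, 1L)) next
    if (substr(X, 1L, 1L) == substr(R, 1L, 1L)) next
    got <- detect_tsd(f5, I, R, min_tsd = 6L)
    if (is.null(got) || got$length != k) next
    tail_got <- detect_polyA(seq_slice(I, 0L, nchar(I) - k))
    if (with_tail && (is.null(tail_got) || tail_got$length != t)) next
    if (!with_tail && !is.null(tail_got)) next
    truth <- new_truth(locus_id,
                       if (with_tail) "TPRT" else "INTERNAL_PRIMING",
                       subfamily, category = "ENTIRE+NONE",
                       tsd_len = k, polyA_len = if (with_tail) t else 0L,
                       trunc_5p = tr5, trunc_3p = 0L,
                       age_My = age, en_mismatches = en$mismatches,
                       n_cpg_subs = mut$n_cpg_subs,
                       n_noncpg_subs = mut$n_noncpg_subs,
                       validated = validated)
    return(list(obs = obs, truth = truth))
  }
  stop("simulate_tprt_locus: could not draw a well-posed locus in 50 tries")
}

#' Simulate an internal-priming insertion locus
#'
#' Convenience wrapper: [simulate_tprt_locus()] with `with_tail = FALSE`.
#' @inheritParams simulate_tprt_locus
#' @export
simulate_ip_locus <- function(registry, cfg = simulation_config(), ...,
                              locus_id = "ip_1") {
  simulate_tprt_locus(registry, cfg, ..., with_tail = FALSE, locus_id = locus_id)
}

#' Simulate a non-classical Alu insertion (NCAI) locus
#'
#' A doubly truncated consensus fragment with 3' non-Alu filler, no TSD, no
#' planted endonuclease site, and an optional target-site deletion. The
#' fragment appears as a reference-annotated Alu whose polymorphic span also
#' includes the 3' filler.
#'
#' @inheritParams simulate_tprt_locus
#' @param trunc_5p,trunc_3p Optional fixed truncations (>= 6 bp each; the
#'   fragment must keep >= 30 bp).
#' @param filler_len,target_site_deletion Optional fixed values.
#' @export
simulate_ncai_locus <- function(registry, cfg = simulation_config(),
                                subfamily = NULL, age_My = 0,
                                trunc_5p = NULL, trunc_3p = NULL,
                                filler_len = NULL, target_site_deletion = NULL,
                                locus_id = "ncai_1", validated = TRUE) {
  subfamily <- subfamily %||% sample(intersect(ALU_S_LABELS, registry_labels(registry)), 1L)
  cons <- registry$records[[subfamily]]
  Lc <- nchar(cons$seq)
  for (try in 1:100) {
    t5 <- trunc_5p %||% runif_int(c(20L, 120L))
    t3 <- trunc_3p %||% runif_int(c(20L, 120L))
    if (Lc - t5 - t3 < 30L) { if (!is.null(trunc_5p)) stop("fragment < 30 bp"); next }
    fl <- filler_len %||% rlog_unif_int(cfg$filler_range)
    dlen <- target_site_deletion %||% runif_int(cfg$target_site_deletion_range)
    mut <- apply_mutation_clock(cons$seq, age_My, cfg$clock, cons$cpg_sites)
    frag <- seq_slice(mut$seq, t5, Lc - t3)
    filler <- random_dna(fl)
    # filler must not extend the local alignment past the planted boundary,
    # must not end the insert ambiguously, and must not look like a tail
    nxt <- substr(cons$seq, Lc - t3 + 1L, Lc - t3 + 1L)
    if (fl >= 1L && substr(filler, 1L, 1L) == nxt) next
    if (grepl("AAAA$", filler) || (fl >= 6 && grepl("A{5}", filler))) next
    L <- draw_flank(cfg$flank_len)
    R <- draw_flank(cfg$flank_len, last_not = character(0))
    del_site <- if (dlen > 0L) random_dna(dlen) else ""
    X <- paste0(frag, filler)
    tail_x <- substr(X, nchar(X), nchar(X))
    if (dlen > 0L) {
      if (substr(del_site, 1L, 1L) == substr(X, 1L, 1L)) next
      if (substr(del_site, dlen, dlen) == tail_x) next
    } else {
      if (substr(R, 1L, 1L) == substr(X, 1L, 1L)) next
      if (substr(L, nchar(L), nchar(L)) == tail_x) next
    }
    filled <- paste0(L, X, R)
    empty <- paste0(L, del_site, R)
    # no chance duplication may mimic a TSD
    if (!is.null(detect_tsd(L, X, R, min_tsd = 6L))) next
    obs <- locus_observation(locus_id, filled, empty,
                             annotated_alu = c(nchar(L), nchar(L) + nchar(frag)),
                             subfamily_hint = subfamily, in_reference = TRUE,
                             validated = validated)
    truth <- new_truth(locus_id, "NCAI", subfamily,
                       category = "ENTIRE+THREE_PRIME",
                       tsd_len = 0L, polyA_len = 0L,
                       trunc_5p = t5, trunc_3p = t3, non_alu_3p = fl,
                       target_site_deletion = dlen, age_My = age_My,
                       n_cpg_subs = mut$n_cpg_subs,
                       n_noncpg_subs = mut$n_noncpg_subs,
                       validated = validated)
    return(list(obs = obs, truth = truth))
  }
  stop("simulate_ncai_locus: could not draw a well-posed locus in 100 tries")
}

DELETION_CATEGORIES <- c("PARTIAL_5P+NONE", "PARTIAL_3P+NONE",
                         "PARTIAL_INTERNAL+NONE", "PARTIAL_5P+FIVE_PRIME",
                         "PARTIAL_3P+THREE_PRIME", "ENTIRE+THREE_PRIME",
                         "ENTIRE+BOTH")

#' Simulate a deletion-polymorphism locus of a requested category
#'
#' Builds a fixed ancestral TPRT-style insertion (full-length element, tail,
#' TSDs, aged by the ancestral clock), then deletes a span matching the
#' requested post-deletion category. The filled allele is the ancestral
#' state; the empty allele is the post-deletion state.
#'
#' @inheritParams simulate_tprt_locus
#' @param category One of the seven post-deletion categories
#'   (`alupoly:::DELETION_CATEGORIES`).
#' @param tsd_len Ancestral TSD length.
#' @export
simulate_deletion_locus <- function(registry, cfg = simulation_config(),
                                    category = "PARTIAL_INTERNAL+NONE",
                                    subfamily = NULL, age_My = NULL,
                                    tsd_len = NULL, polyA_len = NULL,
                                    locus_id = "del_1", validated = TRUE) {
  stopifnot(category %in% DELETION_CATEGORIES)
  subfamily <- subfamily %||% sample(intersect(ALU_S_LABELS, registry_labels(registry)), 1L)
  cons <- registry$records[[subfamily]]
  age <- age_My %||% stats::runif(1, cfg$ancestral_age_range_My[1],
                                  cfg$ancestral_age_range_My[2])
  k <- tsd_len %||% runif_int(cfg$tsd_len_range)
  t <- polyA_len %||% runif_int(cfg$polyA_len_range)
  for (try in 1:100) {
    mut <- apply_mutation_clock(cons$seq, age, cfg$clock, cons$cpg_sites)
    body <- mut$seq
    en <- draw_en_site("consensus")
    tsd <- draw_tsd(k, en, substr(body, 1L, 1L))
    if (is.null(tsd)) next
    L <- paste0(draw_flank(cfg$flank_len - 2L), en$flank_tail)
    R <- draw_flank(cfg$flank_len, last_not = character(0))
    filled <- paste0(L, tsd, body, strrep("A", t), tsd, R)
    a <- nchar(L) + k                      # annotated Alu = element + tail
    b <- a + nchar(body) + t
    lb <- nchar(body)
    u <- runif_int(c(40L, lb - 40L)); v <- runif_int(c(u + 20L, lb - 20L))
    w5 <- runif_int(c(5L, k + 10L)); w3 <- runif_int(c(5L, 30L))
    span <- switch(category,
      "PARTIAL_5P+NONE"        = c(a, a + u),
      "PARTIAL_3P+NONE"        = c(a + u, b),
      "PARTIAL_INTERNAL+NONE"  = c(a + u, a + v),
      "PARTIAL_5P+FIVE_PRIME"  = c(a - w5, a + u),
      "PARTIAL_3P+THREE_PRIME" = c(a + u, b + w3),
      "ENTIRE+THREE_PRIME"     = c(a, b + w3),
      "ENTIRE+BOTH"            = c(a - w5, b + w3))
    s <- span[1]; e <- span[2]
    if (s < 1L || e > nchar(filled) - 1L) next
    # unique placement: block left and right shifts of the deleted span
    ch_at <- function(p) substr(filled, p + 1L, p + 1L)
    if (ch_at(s - 1L) == ch_at(e - 1L)) next
    if (ch_at(s) == ch_at(e)) next
    if (s < cfg$flank_len / 2 || nchar(filled) - e < cfg$flank_len / 2) next
    empty <- paste0(seq_slice(filled, 0L, s), seq_slice(filled, e, nchar(filled)))
    obs <- locus_observation(locus_id, filled, empty,
                             annotated_alu = c(a, b),
                             subfamily_hint = subfamily, in_reference = TRUE,
                             validated = validated)
    truth <- new_truth(locus_id, "DELETION_CANDIDATE", subfamily,
                       category = category, tsd_len = k, polyA_len = t,
                       trunc_5p = 0L, trunc_3p = 0L, age_My = age,
                       en_mismatches = en$mismatches,
                       n_cpg_subs = mut$n_cpg_subs,
                       n_noncpg_subs = mut$n_noncpg_subs,
                       validated = validated)
    return(list(obs = obs, truth = truth))
  }
  stop(sprintf("simulate_deletion_locus: no well-posed %s locus in 100 tries", category))
}

#' Simulate a cohort with every mechanism class
#'
#' `n_per_class` loci for each of TPRT, internal priming, NCAI, and deletion
#' polymorphisms (cycling through the requested post-deletion categories).
#'
#' @inheritParams simulate_tprt_locus
#' @param categories Deletion categories to cycle through.
#' @param age_My Age applied to all loci (default: drawn per locus).
#' @return List with `observations` (list of [locus_observation()]) and
#'   `truth` (data.frame).
#' @export
simulate_cohort <- function(registry, cfg = simulation_config(),
                            categories = DELETION_CATEGORIES,
                            age_My = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  obs <- list(); truth <- list()
  add <- function(x) { obs[[length(obs) + 1L]] <<- x$obs
                       truth[[length(truth) + 1L]] <<- x$truth }
  n <- cfg$n_per_class
  for (i in seq_len(n)) {
    add(simulate_tprt_locus(registry, cfg, age_My = age_My,
                            locus_id = sprintf("tprt_%03d", i)))
    add(simulate_ip_locus(registry, cfg, age_My = age_My,
                          locus_id = sprintf("ip_%03d", i)))
    add(simulate_ncai_locus(registry, cfg, age_My = age_My %||% 0,
                            locus_id = sprintf("ncai_%03d", i)))
  }
  for (i in seq_len(n)) {
    cat_i <- categories[((i - 1L) %% length(categories)) + 1L]
    add(simulate_deletion_locus(registry, cfg, category = cat_i,
                                age_My = age_My,
                                locus_id = sprintf("del_%03d", i)))
  }
  list(observations = obs, truth = do.call(rbind, truth))
}

#' Simulate a genome-background divergence distribution
#'
#' Seeded draws from a normal truncated at zero, emulating the percent
#' divergence of genome-annotated AluS elements from their subfamily
#' consensus.
#'
#' @param n Number of elements.
#' @param mean,sd Moments of the untruncated normal (percent).
#' @param seed Optional seed (RNG state restored on exit).
#' @return Numeric vector of percent divergences.
#' @export
simulate_background_divergences <- function(n, mean = 13.2, sd = 4.2, seed = NULL) {
  run <- function() {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
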