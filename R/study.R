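# The study-condition cohort: 48 polymorphic AluS loci whose composition and
# per-element feature profile reproduce the published cohort structure
# (37 deletion candidates, 2 NCAI, 1 internal priming, 7 validated + 1
# non-validated TPRT candidates), with substitution budgets planted per
# element so the divergence/age pipeline has known truth. All sequences are
# synthetic.

# Per-element profile of the seven validated TPRT candidates: subfamily,
# target CpG/non-CpG clock ages (My), TSD and tail lengths (bp), planted
# endonuclease-site mismatches, and planted motif mismatches (anchor
# coordinates on the synthetic consensus layout).
tprt_profile_table <- function() {
  list(
    list(id = "T1", subfamily = "AluSx", age_cpg = 14.4, age_noncpg = 25.4,
         tsd = 10L, tail = 20L, en_mm = 0L, cpg_plant = integer(0), noncpg_plant = c()),
    list(id = "T2", subfamily = "AluSx", age_cpg = 18.5, age_noncpg = 28.2,
         tsd = 12L, tail = 22L, en_mm = 0L, cpg_plant = integer(0), noncpg_plant = c()),
    list(id = "T3", subfamily = "AluSx", age_cpg = 22.6, age_noncpg = 31.0,
         tsd = 14L, tail = 25L, en_mm = 0L, cpg_plant = c(73L),
         noncpg_plant = c("119" = "T")),
    list(id = "T4", subfamily = "AluSg", age_cpg = 40.0, age_noncpg = 33.3,
         tsd = 15L, tail = 27L, en_mm = 1L, cpg_plant = c(13L, 73L),
         noncpg_plant = c()),
    list(id = "T5", subfamily = "AluSg", age_cpg = 40.0, age_noncpg = 36.1,
         tsd = 17L, tail = 29L, en_mm = 2L, cpg_plant = c(14L, 74L),
         noncpg_plant = c("199" = "C")),
    list(id = "T6", subfamily = "AluSp", age_cpg = 42.2, age_noncpg = 36.1,
         tsd = 19L, tail = 30L, en_mm = 0L, cpg_plant = c(74L),
         noncpg_plant = c()),
    list(id = "T7", subfamily = "AluSz", age_cpg = 37.7, age_noncpg = 37.0,
         tsd = 21L, tail = 32L, en_mm = 0L, cpg_plant = c(73L, 74L),
         noncpg_plant = c("77" = "G"))
  )
}

# Substitute a consensus copy with planted budgets: fixed motif mismatches
# first, then random CpG transitions and non-CpG substitutions outside
# motifs and diagnostic-panel columns until the target counts are met.
plant_profile <- function(cons, panel, age_cpg, age_noncpg,
                          clock = clock_parameters(),
                          cpg_plant = integer(0), noncpg_plant = c()) {
  Lc <- nchar(cons$seq)
  n_cpg <- length(cons$cpg_sites)
  n_ncpg <- Lc - n_cpg
  target_cpg <- round(age_cpg * 1e6 * clock$k_cpg * n_cpg)
  target_ncpg <- round(age_noncpg * 1e6 * clock$k_noncpg * n_ncpg)
  motif_pos <- unlist(lapply(cons$motifs, function(m) {
    iv <- m$interval_target %||% m$interval
    iv[1]:(iv[2] - 1L)
  })) %||% integer(0)
  diag_pos <- panel$anchor_pos[!is.na(panel$anchor_pos)]
  seq <- cons$seq
  used <- integer(0)
  sub_cpg <- function(seq, p) {
    b <- substr(seq, p + 1L, p + 1L)
    set_chars(seq, p, if (b == "C") "T" else "A")
  }
  for (p in cpg_plant) {
    stopifnot(p %in% cons$cpg_sites)
    seq <- sub_cpg(seq, p); used <- c(used, p)
  }
  if (length(noncpg_plant)) {
    for (nm in names(noncpg_plant)) {
      p <- as.integer(nm)
      stopifnot(!(p %in% cons$cpg_sites))
      seq <- set_chars(seq, p, noncpg_plant[[nm]]); used <- c(used, p)
    }
  }
  n_cpg_left <- target_cpg - length(cpg_plant)
  n_ncpg_left <- target_ncpg - length(noncpg_plant)
  stopifnot(n_cpg_left >= 0, n_ncpg_left >= 0)
  cpg_pool <- setdiff(cons$cpg_sites, c(motif_pos, used))
  pos <- sample(cpg_pool, n_cpg_left)
  for (p in pos) seq <- sub_cpg(seq, p)
  used <- c(used, pos)
  ncpg_pool <- setdiff(0:(Lc - 1L),
                       c(cons$cpg_sites, motif_pos, diag_pos, used,
                         0L, Lc - 2L, Lc - 1L))
  pos <- sample(ncpg_pool, n_ncpg_left)
  for (p in pos) {
    b <- substr(seq, p + 1L, p + 1L)
    seq <- set_chars(seq, p, sample(setdiff(c("C", "G", "T"), b), 1L))
  }
  list(seq = seq, n_cpg_subs = as.integer(target_cpg),
       n_noncpg_subs = as.integer(target_ncpg))
}

# Assemble a TPRT/IP locus around a pre-mutated body (shared well-posedness
# loop with the generic generator).
assemble_insertion_locus <- function(body, subfamily, cfg, tsd_len, tail_len,
                                     en_mm, locus_id, validated,
                                     n_cpg_subs, n_noncpg_subs, age_label) {
  with_tail <- tail_len > 0L
  for (try in 1:50) {
    en <- draw_en_site(if (en_mm == 0L) "consensus" else "degenerate",
                       n_mismatch = if (en_mm > 0L) en_mm else NULL)
    tsd <- draw_tsd(tsd_len, en, substr(body, 1L, 1L))
    if (is.null(tsd)) next
    L <- paste0(draw_flank(cfg$flank_len - 2L), en$flank_tail)
    if (substr(L, nchar(L), nchar(L)) == "A") next
    R <- draw_flank(cfg$flank_len, last_not = character(0))
    X <- paste0(body, strrep("A", tail_len))
    if (substr(X, 1L, 1L) == substr(R, 1L, 1L)) next
    if (substr(X, 1L, 1L) == substr(tsd, 1L, 1L)) next
    filled <- paste0(L, tsd, X, tsd, R)
    empty <- paste0(L, tsd, R)
    f5 <- paste0(L, tsd); I <- paste0(X, tsd)
    got <- detect_tsd(f5, I, R, min_tsd = 6L)
    if (is.null(got) || got$length != tsd_len) next
    tail_got <- detect_polyA(seq_slice(I, 0L, nchar(I) - tsd_len))
    if (with_tail && (is.null(tail_got) || tail_got$length != tail_len)) next
    if (!with_tail && !is.null(tail_got)) next
    obs <- locus_observation(locus_id, filled, empty, annotated_alu = NULL,
                             subfamily_hint = subfamily, in_reference = FALSE,
                             validated = validated)
    truth <- new_truth(locus_id, if (with_tail) "TPRT" else "INTERNAL_PRIMING",
                       subfamily, category = "ENTIRE+NONE",
                       tsd_len = tsd_len, polyA_len = tail_len,
                       trunc_5p = 0L, trunc_3p = 0L, age_My = age_label,
                       en_mismatches = en$mismatches,
                       n_cpg_subs = n_cpg_subs, n_noncpg_subs = n_noncpg_subs,
                       validated = validated)
    return(list(obs = obs, truth = truth))
  }
  stop("assemble_insertion_locus: no well-posed draw in 50 tries")
}

#' Simulate the study-condition cohort of 48 polymorphic AluS loci
#'
#' Generates the full cohort under the study conditions: 33 partial-Alu
#' deletion polymorphisms (over the five partial post-deletion categories),
#' 3 deletions spanning the entire Alu plus both flanks (ancestral TSDs 11,
#' 14 and 17 bp), 1 full-length AluSz deletion with 3' flanking sequence,
#' 2 NCAI (95 bp left-monomer fragment + 11 bp filler; 77 bp right-monomer
#' fragment + 21 bp filler + 14 bp target-site deletion), 1 internal-priming
#' AluSq insertion, 7 validated TPRT candidates with planted per-element
#' profiles (TSDs 10-21 bp, tails 20-32 bp, CpG/non-CpG substitution budgets
#' spanning CpG ages ~15-44 My and divergences ~5.5-11%), and 1 additional
#' TPRT candidate flagged not PCR-validated.
#'
#' @param registry The synthetic `alu_registry`.
#' @param seed Integer seed (fully determines the cohort).
#' @param panel Diagnostic panel (computed from the registry if missing).
#' @param cfg [simulation_config()].
#' @return List with `observations`, `truth`, and `tprt_ids`.
#' @export
simulate_study_cohort <- function(registry, seed = 1L,
                                  panel = find_diagnostic_positions(
                                    registry,
                                    intersect(ALU_S_LABELS, registry_labels(registry)),
                                    intersect(ALU_Y_LABELS, registry_labels(registry))),
                                  cfg = simulation_config()) {
  set.seed(child_seed(seed, 101))
  obs <- list(); truth <- list()
  add <- function(x) { obs[[length(obs) + 1L]] <<- x$obs
                       truth[[length(truth) + 1L]] <<- x$truth }

  # 33 partial-Alu deletion polymorphisms over the five partial categories
  partial_counts <- c("PARTIAL_5P+NONE" = 8L, "PARTIAL_3P+NONE" = 8L,
                      "PARTIAL_INTERNAL+NONE" = 7L,
                      "PARTIAL_5P+FIVE_PRIME" = 5L,
                      "PARTIAL_3P+THREE_PRIME" = 5L)
  subs <- rep(ALU_S_LABELS, length.out = 33L)
  i <- 0L
  for (cat in names(partial_counts)) {
    for (j in seq_len(partial_counts[[cat]])) {
      i <- i + 1L
      add(simulate_deletion_locus(registry, cfg, category = cat,
                                  subfamily = subs[i],
                                  locus_id = sprintf("del_%02d", i)))
    }
  }
  # 3 deletions of the entire Alu plus both flanks (ancestral TSDs 11-17 bp)
  for (j in seq_along(tsds <- c(11L, 14L, 17L))) {
    add(simulate_deletion_locus(registry, cfg, category = "ENTIRE+BOTH",
                                subfamily = ALU_S_LABELS[j], tsd_len = tsds[j],
                                locus_id = sprintf("del_both_%d", j)))
  }
  # 1 full-length AluSz deletion including 3' flanking sequence
  add(simulate_deletion_locus(registry, cfg, category = "ENTIRE+THREE_PRIME",
                              subfamily = "AluSz", locus_id = "del_3p_full"))
  # 2 NCAI
  add(simulate_ncai_locus(registry, cfg, subfamily = "AluSc",
                          trunc_5p = 40L, trunc_3p = 155L,
                          filler_len = 11L, target_site_deletion = 0L,
                          locus_id = "ncai_sc"))
  add(simulate_ncai_locus(registry, cfg, subfamily = "AluSq",
                          trunc_5p = 205L, trunc_3p = 8L,
                          filler_len = 21L, target_site_deletion = 14L,
                          locus_id = "ncai_sq"))
  # 1 internal-priming insertion (full-length, TSD, no tail)
  ip_body <- plant_profile(registry$records[["AluSq"]], panel,
                           age_cpg = 30, age_noncpg = 30)
  add(assemble_insertion_locus(ip_body$seq, "AluSq", cfg, tsd_len = 12L,
                               tail_len = 0L, en_mm = 4L, locus_id = "ip_sq",
                               validated = TRUE,
                               n_cpg_subs = ip_body$n_cpg_subs,
                               n_noncpg_subs = ip_body$n_noncpg_subs,
                               age_label = 30))
  # 7 validated TPRT candidates with planted profiles
  tprt_ids <- character(0)
  for (pr in tprt_profile_table()) {
    body <- plant_profile(registry$records[[pr$subfamily]], panel,
                          age_cpg = pr$age_cpg, age_noncpg = pr$age_noncpg,
                          cpg_plant = pr$cpg_plant, noncpg_plant = pr$noncpg_plant)
    id <- sprintf("tprt_%s", pr$id)
    tprt_ids <- c(tprt_ids, id)
    add(assemble_insertion_locus(body$seq, pr$subfamily, cfg,
                                 tsd_len = pr$tsd, tail_len = pr$tail,
                                 en_mm = pr$en_mm, locus_id = id,
                                 validated = TRUE,
                                 n_cpg_subs = body$n_cpg_subs,
                                 n_noncpg_subs = body$n_noncpg_subs,
                                 age_label = pr$age_cpg))
  }
  # 1 TPRT candidate that failed PCR validation (excluded from mechanism counts)
  nv_body <- plant_profile(registry$records[["AluSx"]], panel,
                           age_cpg = 30, age_noncpg = 30)
  add(assemble_insertion_locus(nv_body$seq, "AluSx", cfg, tsd_len = 13L,
                               tail_len = 24L, en_mm = 0L,
                               locus_id = "tprt_nonval", validated = FALSE,
                               n_cpg_subs = nv_body$n_cpg_subs,
                               n_noncpg_subs = nv_body$n_noncpg_subs,
                               age_label = 30))
  list(observations = obs, truth = do.call(rbind, truth), tprt_ids = tprt_ids)
}
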