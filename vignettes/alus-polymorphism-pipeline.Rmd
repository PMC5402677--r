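---
title: "Characterizing polymorphic AluS elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing polymorphic AluS elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Alu elements are ~300 bp primate SINE retrotransposons: two monomers
separated by an A-rich linker, ending in a poly-A tail. New copies insert by
target-primed reverse transcription (TPRT) using the L1 ORF2p machinery,
which prefers to nick the negative strand at 5'-TTTT/AA-3' sites. A TPRT
insertion leaves three hallmarks: an intact 3' end, a 3' poly-A tail, and
flanking target site duplications (TSDs). Most polymorphic Alu elements
belong to the young AluY subfamilies; polymorphisms involving the much older
AluS subfamilies can instead arise by imprecise deletion of a fixed element,
by endonuclease-independent repair of a double-strand break (non-classical
Alu insertion, NCAI), by internal priming (IP), or — more interestingly — by
genuine recent TPRT retrotransposition of a still-competent AluS source
element.

`alupoly` implements the full decision process that separates these
scenarios for a set of loci given as paired *filled* (Alu-containing) and
*empty* allele sequences, plus the downstream population of that decision:
divergence-based age estimation under a CpG-aware neutral clock, a
permutation test against the genome-background divergence distribution, and
conservation scoring of the sequence features retrotransposition requires.

## Pipeline

For each locus (`characterize_locus()`):

1. **Polymorphic span** (`compute_polymorphic_span()`): the single
   contiguous difference between the alleles, left-shifted to its leftmost
   equivalent placement (VCF convention). A replacement — empty-allele
   sequence absent from the filled allele — is recorded as a target-site
   deletion; differences that decompose into multiple disjoint blocks
   (detected as a shared 20-mer between the inserted and deleted segments)
   are surfaced as *complex* rather than force-classified.
2. **Subfamily** (`classify_subfamily()`): strand normalization, poly-A
   trimming, then alignment to every registry consensus (element fully
   aligned, consensus ends free); the best subfamily minimizes percent
   divergence. AluS-versus-AluY conflicts are resolved with a
   diagnostic-nucleotide panel (`find_diagnostic_positions()`): *strict*
   alignment columns are unanimous within each group and differ between
   groups; *relaxed* columns tolerate one deviating member per group with
   differing group majorities. An element is tallied per covered panel
   position as matching AluS only, AluY only, both (possible at relaxed
   positions), or neither; both/neither positions are uninformative and the
   family is decided by majority.
3. **Insertion annotation** (`annotate_insertion()`): at the *rightmost*
   equivalent placement the filled allele reads
   `flank5 · [body, tail, TSD-copy] · flank3`, the left TSD copy ending
   `flank5` — so the TSD is the longest common suffix (>= 6 bp) of `flank5`
   and the inserted segment, which automatically implements "TSD length
   maximized at the expense of poly-A tail length": adenines shared between
   the tail's end and the flank 5' of the duplication are absorbed into the
   duplication. The poly-A tail is then the longest suffix of the
   TSD-stripped insert that starts and ends with A, is >= 6 bp, has A
   fraction >= 0.9 and no non-A run > 1. Truncations and non-Alu sequence
   come from a local alignment of the remaining core to the consensus, and
   the L1 endonuclease site is scored as the 6 nt negative-strand window
   across the inferred nick (the TSD's 5' boundary), as a mismatch count
   against TTTT/AA rather than a binary.
4. **Mechanism** (`classify_mechanism()`): a total decision tree.
   Partial-Alu spans are deletion candidates. Spans covering the whole Alu
   plus flank are deletions when the element carries a tail at an intact 3'
   boundary, NCAI when doubly truncated without a TSD. Exact-element spans
   are TPRT (tail + TSD + intact 3' end; 5' truncation allowed, since
   premature termination of reverse transcription 5'-truncates TPRT
   products), IP (full-length + TSD, no tail), or NCAI (no TSD with
   truncation/non-Alu sequence). Everything else is UNRESOLVED with an
   evidence trail. The endonuclease site is reported as supporting evidence
   (<= 2 mismatches "supportive") but never decides a call.
5. **Age** (`percent_divergence()`): divergence is substituted columns over
   aligned non-gap columns (indel columns excluded from both counts), tail
   removed. Sites are classed by the consensus: positions inside consensus
   CpG dinucleotides are CpG sites, where only C-to-T and G-to-A changes are
   counted (the deamination signature); all other positions are non-CpG
   sites where every change counts. Ages are `density / k` with
   k = 1.5e-9 substitutions/site/year at non-CpG sites and a six-fold
   faster 9e-9 at CpG sites.
6. **Permutation test** (`permutation_test()`): p is the fraction of
   `n_resamples` with-replacement samples of size n from the background
   whose mean divergence falls below the observed mean.
7. **Motif conservation** (`score_conservation()`): the Pol III promoter
   A box (11 nt) and B box (9 nt), SRP9/14 binding sites (with their "most
   highly conserved" key positions), and the two AC dinucleotides are
   lifted from the anchor consensus onto each element through the pairwise
   alignment; reports carry per-element mismatch counts, fully conserved
   column counts, CpG flags for imperfect columns, and position frequency
   matrices with per-column information content (numeric logo data, not
   images, so every number is testable).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_tsd` | 6 bp | shortest accepted duplication; observed TSDs at real loci are 10–21 bp, 6 keeps sensitivity while bounding the chance-duplication rate (~4^-6 per junction offset) |
| poly-A rule | >= 6 bp, A fraction >= 0.9, non-A runs <= 1 | explicit, tunable definition of a tail; the literature reports only outcomes (20–32 bp tails) |
| `full_length_tol` | 5 bp | truncation still counted full-length; absorbs alignment-end fraying |
| EN supportive cutoff | <= 2 of 6 mismatches | evidence label only; sites are reported as mismatch counts |
| alignment scoring | match +1, mismatch −1, gap open 5, extend 1 | consensus sequences are >85% identical, so any sane scoring yields the same columns; echoed into reports |
| clock | 1.5e-9 and 9e-9 /site/yr | non-CpG and CpG neutral rates; their ratio (6) is what makes the two estimators independent checks on each other |

## The synthetic data generator

No public, licence-free locus set with known ground truth exists at this
scale, so every stage is exercised on generated loci
(`simulate_tprt_locus()`, `simulate_ncai_locus()`,
`simulate_deletion_locus()`, `simulate_study_cohort()`), each paired with a
truth record. The generator emulates the study conditions: TSDs uniform on
10–21 bp, tails 20–32 bp, NCAI filler 2 bp–2 kb (log-uniform), target-site
deletions 0–14 bp, insertion ages 10–45 My, ancestral (pre-deletion)
insertions 35–60 My (the AluS activity peak), endonuclease sites planted at
the TTTT/AA consensus or degenerate. The consensus registry itself is
synthetic: a 290 nt ancestral sequence with the two-monomer layout, enriched
to realistic Alu CpG density (~25 CpG dinucleotides), from which six
AluS-group and six AluY-group consensuses are derived with exactly 5 strict
diagnostic positions (2 left monomer, 3 right), 7 relaxed positions with one
deviating member each, and 8 private substitutions per subfamily. It is a
stand-in for licensed reference consensus sequences, not a reconstruction of
them.

The study cohort (`simulate_study_cohort()`) fixes the cohort composition
(33 partial-Alu deletions over five categories, 3 whole-Alu-plus-both-flank
deletions with ancestral TSDs 11–17 bp, 1 full-length deletion with 3'
flank, 2 NCAI with 95/77 bp fragments and 11/21 bp fillers, 1 IP, 7
validated TPRT candidates, 1 non-validated TPRT candidate) and plants
per-element substitution budgets — CpG transitions and non-CpG changes —
chosen so the seven TPRT candidates span divergences ~5.5–11% with CpG ages
~14–42 My and non-CpG ages ~25–37 My, and so the A/B-box mismatch tallies
(5 exact / 2 single-mismatch; {0,0,1,1,1,1,3}) and SRP/AC variation pattern
are realized exactly. Tests against this cohort therefore verify that the
pipeline *recovers* planted truth end to end, not that it can annotate any
particular natural locus; features of real data the generator does not
emulate — 5' inversions from twin priming, nested repeats occluding TSDs,
sequencing errors, alignment-breaking indel clusters — are out of its scope
and are surfaced by the pipeline as UNRESOLVED or complex rather than
guessed.

Two generator choices deserve a note. Substitution probabilities use the
linear form p = kT rather than 1 − exp(−kT), matching the linear
density-over-k inversion used for ages (difference < 0.5% for T <= 60 My).
And the whole CpG-site process is drawn as C-to-T/G-to-A transitions at rate
9e-9: that rate is calibrated on counted transitions, so splitting off a
random-substitution component would make the counting rule miss ~1/9 of CpG
events and bias the CpG age estimator downward by ~11% by construction.

## Numerical choices and degenerate inputs

* Indel placement is normalized leftmost for reporting, rightmost for TSD
  search (where the biological junction lives); both ends of the
  equivalence interval are carried in the span object.
* A poly-A suffix must *start* with A: without that constraint the rule
  would absorb one flanking non-A base into every tail >= 9 bp and
  systematically overshoot by one.
* On deletion-candidate spans the element's tail is internal to the span, so
  after a tail-less suffix parse the annotator rescans for an A-run at the
  element's aligned 3' boundary, tolerating up to 8 bp of alignment-end
  fraying on diverged elements.
* Ties in best-subfamily divergence return UNRESOLVED with the
  lexicographically smallest label as tie representative (determinism); the
  family may still be decided by the diagnostic tally.
* Identical alleles, alleles with multiple disjoint differences, and flanks
  shorter than 20 bp are rejected with informative errors, never guessed.
* Generators redraw degenerate draws (e.g. a flank base that would make the
  indel placement ambiguous, or a chance >= 6 bp duplication at an NCAI
  junction) so that noiseless round trips are exact for any seed; the
  arbitration behaviour those constraints avoid is exercised by dedicated
  A-terminal constructions in the tests.

## Problem sizes

The bundled analyses and tests run at desk scale, chosen as the smallest
sizes that exercise every code path with stable statistics: the 48-locus
study cohort; 20 loci per mechanism class for noiseless round trips; 200
replicates per planted age (10 and 30 My) for clock recovery; 500 null
trials of 10^4 resamples for permutation calibration; and one
genome-background-scale permutation (686,955 background values, 10^6
resamples of n = 7). The background distribution is drawn from a normal
truncated at zero with mean 13.2% and sd 4.2%, chosen once as realistic
genome-wide AluS divergence values.

## Known limitations

* The synthetic registry's diagnostic panel has a designed structure; on
  real consensus sequences the panel is recomputed from the supplied FASTA
  and may contain different counts of relaxed positions depending on the
  subfamilies included.
* Twin-priming/5'-inversion products and nested-repeat loci are not modeled;
  they surface as UNRESOLVED.
* The permutation test treats background divergences as exchangeable; no
  correction is made for subfamily composition differences between the
  candidate set and the background.
* `PARTIAL_BOTH_ENDS` exists in the category enum for completeness but no
  single contiguous span can realize it.

## Reproducing the analyses

```{r, eval = FALSE}
# from the repository root
Rscript analysis/01_build_registry.R
Rscript analysis/02_simulate_cohort.R
Rscript analysis/03_classify_subfamilies.R
Rscript analysis/04_annotate_mechanisms.R
Rscript analysis/05_divergence_age.R
Rscript analysis/06_motif_conservation.R
# headline quantities in JSON form:
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
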