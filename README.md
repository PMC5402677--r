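# alupoly

Annotation and mechanism classification of polymorphic Alu elements.

Alu elements are ~300 bp primate SINE retrotransposons. Polymorphic copies of
the evolutionarily old **AluS** subfamilies are scientifically interesting
precisely because they should not exist as insertions: the subfamily's peak
activity was tens of millions of years ago, so an AluS polymorphism is either
the scar of an imprecise **deletion** of a fixed element, a **non-classical
insertion** (NCAI, endonuclease-independent repair of a double-strand break),
an **internal-priming** (IP) product, or — the interesting case — a genuine
recent **TPRT** (target-primed reverse transcription) insertion by the L1
machinery, implying residual AluS retrotransposition activity.

Given each locus as a paired *filled* (Alu-containing) and *empty* allele
sequence, `alupoly` implements the complete decision process:

* **Subfamily confirmation** against a consensus registry; AluS-versus-AluY
  conflicts are resolved with a diagnostic-nucleotide panel derived from the
  inter-consensus alignment (strict positions: unanimous within each group
  and different between groups; relaxed positions tolerate one deviating
  member per group), with per-element tallies of positions matching AluS
  only, AluY only, both, or neither.
* **Polymorphic-span computation** with VCF-style leftmost normalization,
  overlay on the annotated Alu, and post-deletion category assignment
  (partial-element and element-plus-flank classes).
* **TPRT hallmark measurement**: target site duplications with the
  tail-versus-TSD arbitration rule (TSD length maximized at the expense of
  poly-A length), explicit poly-A tail rule, truncation extents and non-Alu
  sequence, target-site deletions, and the L1 ORF2p endonuclease site scored
  as a 6 nt negative-strand window against `5'-TTTT/AA-3'`.
* **Mechanism classification** by a total decision tree: deletion candidate,
  NCAI, internal priming, TPRT, or unresolved — each call with an evidence
  trail.
* **Divergence and age** under a two-rate neutral clock: age = substitution
  density / k, with k = 1.5×10⁻⁹ substitutions/site/year at non-CpG sites
  and 9×10⁻⁹ at CpG sites, where only C→T and G→A changes are counted.
* **Permutation testing** of the candidates' mean divergence against a
  genome-background divergence distribution (RepeatMasker-style `.out` or
  TSV input): p = Pr(mean of n background draws < observed mean).
* **Motif conservation** of the RNA polymerase III A/B boxes, SRP9/14
  binding sites and AC dinucleotides, reported as mismatch tallies and
  position frequency matrices (numeric logo data).
* **A ground-truthed synthetic-locus generator** covering every mechanism
  class plus a synthetic 12-subfamily consensus registry, so the entire
  pipeline is testable offline with planted truth.

## Worked example

```r
library(alupoly)

registry <- synthetic_registry()
panel <- find_diagnostic_positions(registry,
                                   c("AluSc","AluSg","AluSp","AluSq","AluSx","AluSz"),
                                   c("AluY","AluYa5","AluYa8","AluYb8","AluYb9","AluYc1"))
sum(panel$strict)
#> [1] 5

x <- simulate_tprt_locus(registry, simulation_config(), age_My = 0,
                         tsd_len = 14, polyA_len = 26, locus_id = "demo")
res <- characterize_locus(x$obs, registry, panel)
res$row[, c("mechanism", "subfamily", "tsd_len", "polyA_len",
            "en_window", "en_mismatches")]
#>   mechanism subfamily tsd_len polyA_len en_window en_mismatches
#> 1      TPRT     AluSc      14        26    TTTTAA             0
```

The element is called a classical TPRT insertion because it is 3'-intact
with a 26 bp poly-A tail, flanked by a 14 bp target site duplication, and
sits at a perfect L1 endonuclease site; the TSD and tail lengths recover the
planted truth exactly.

On the full 48-locus synthetic study cohort (`simulate_study_cohort()`), the
pipeline reports 77% deletion candidates (37/48), 4% NCAI (2/48), 2%
internal priming (1/48) and 15% TPRT candidates (7/48), with the seven TPRT
candidates carrying TSDs of 10–21 bp, tails of 20–32 bp, consensus
divergences of ~5.5–11% and CpG-clock ages of ~14–42 My — and their mean
divergence is significantly lower than a genome-scale background
distribution by permutation test (p ≈ 0.004 at 10⁶ resamples of n = 7).

The numbered scripts under `analysis/` run the whole workflow and write the
tables under `results/`; `vignettes/alus-polymorphism-pipeline.Rmd`
describes the methods, parameter choices and limitations.

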