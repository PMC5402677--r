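Package: alupoly
Title: Annotation and Mechanism Classification of Polymorphic Alu Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end characterization of polymorphic Alu (SINE) loci from
    paired filled/empty allele sequences: subfamily confirmation against a
    consensus registry with AluS-versus-AluY diagnostic nucleotides,
    measurement of the hallmarks of target-primed reverse transcription
    (target site duplications, 3' poly-A tails, L1 ORF2p endonuclease sites),
    classification of each locus as a deletion polymorphism, non-classical
    insertion, internal-priming insertion or classical TPRT insertion,
    CpG-aware divergence and age estimation under a two-rate neutral clock, a
    permutation test against a genome-background divergence distribution, and
    conservation scoring of retrotransposition-critical motifs (RNA polymerase
    III A/B boxes, SRP9/14 binding sites, AC dinucleotides). Includes a
    ground-truthed synthetic-locus generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
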