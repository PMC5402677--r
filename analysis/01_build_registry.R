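#!/usr/bin/env Rscript
# Build the synthetic 12-subfamily consensus registry, derive the
# AluS-versus-AluY diagnostic-nucleotide panel, and record both under
# results/. Later analysis steps reload the registry from these files.

suppressPackageStartupMessages(library(alupoly))

reg_dir <- "results/registry"
registry <- synthetic_registry(dir = reg_dir)
cat(sprintf("Wrote consensus FASTA + annotation config to %s\n", reg_dir))
print(registry)

panel <- find_diagnostic_positions(registry,
                                   alupoly:::ALU_S_LABELS,
                                   alupoly:::ALU_Y_LABELS)
left_end <- registry$records[[registry$anchor]]$left_monomer[2]
cat(sprintf(
  "Diagnostic panel: %d positions (%d strict: %d in the left monomer, %d in the right; %d relaxed)\n",
  nrow(panel), sum(panel$strict),
  sum(panel$strict & panel$anchor_pos < left_end),
  sum(panel$strict & panel$anchor_pos >= left_end),
  sum(!panel$strict)))

write_tsv_report(panel, "results/tables/diagnostic_panel.tsv",
                 params = registry$alignment_params)
cat("Panel written to results/tables/diagnostic_panel.tsv\n")
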