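#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study panel.
#
# Fabricates an NCI-60-like dataset: 2,000 proteins x 59 cell lines over
# 9 tissues, roughly log-normal CPC values, sparse detection with planted
# sporadically-detected proteins, a dominant glycolysis-like pathway, a
# reaction network with six planted branch points, and kinetic tables.
# Everything lands under results/synthetic/ together with manifest.json,
# the ground truth the later stages are checked against.

library(cpcnet)

seed <- as.integer(Sys.getenv("CPCNET_SEED", "1"))
out <- "results/synthetic"
s <- simulate_dataset(sim_config(seed = seed), out)

cat("Synthetic panel written to", out, "\n")
cat(sprintf("  %d proteins x %d cell lines, %d planted branch points\n",
            s$manifest$n_proteins, s$manifest$n_cell_lines,
            length(s$manifest$branches)))
cat(sprintf("  true metabolic share of total CPC: %.2f%%\n",
            s$manifest$true_metabolic_fraction_pct))
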