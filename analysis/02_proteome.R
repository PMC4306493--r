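#!/usr/bin/env Rscript
# Stage 2 — proteome partitioning.
#
# Loads the synthetic panel, removes proteins detected in only one sample
# or tissue, and quantifies how total protein mass splits between the
# metabolic and non-metabolic proteome and across pathways, plus the
# log-binned abundance distributions.

library(cpcnet)

m <- read_cpc_table("results/synthetic/cpc_matrix.tsv",
                    "results/synthetic/tissues.tsv")
pmap <- read_pathway_map("results/synthetic/pathway_map.tsv")

flt <- filter_rare_proteins(m)
fs <- filter_cpc_summary(m)
cat(sprintf("Filter: %d proteins removed (mean %.0f CPC) vs %d retained (mean %.0f CPC)\n",
            fs$n_removed, fs$removed_mean_cpc,
            fs$n_retained, fs$retained_mean_cpc))

met <- metabolic_fraction(flt$matrix, pmap)
cat(sprintf("Metabolic proteome: %.2f%% of total CPC (non-metabolic %.2f%%)\n",
            met, 100 - met))

pf <- pathway_fractions(flt$matrix, pmap)
write_tsv(pf$summary, "results/pathway_fractions.tsv")
top <- pf$summary[1, ]
cat(sprintf("Top pathway: %s, median %.2f%% of the proteome (max %.2f%%)\n",
            top$pathway_id, top$median_pct, top$max_pct))

vals <- flt$matrix$cpc[!is.na(flt$matrix$cpc) & flt$matrix$cpc > 0]
write_tsv(log_binned_pdf(vals, 0.3), "results/pdf_all.tsv")
met_vals <- flt$matrix$cpc[rownames(flt$matrix$cpc) %in%
                             unique(pmap$protein_id), ]
write_tsv(log_binned_pdf(met_vals[!is.na(met_vals) & met_vals > 0], 0.3),
          "results/pdf_metabolic.tsv")
write_tsv(data.frame(protein_id = flt$removed), "results/filter_report.tsv")
cat("Wrote pathway_fractions.tsv, pdf_all.tsv, pdf_metabolic.tsv, filter_report.tsv\n")
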