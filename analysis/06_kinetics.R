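#!/usr/bin/env Rscript
# Stage 6 — abundance vs kinetics vs thermodynamics.
#
# Aggregates replicate K_M measurements per enzyme (wild-type only,
# log-IQR outliers removed, geometric mean), joins the standard reaction
# Gibbs energies and mean CPC, correlates the three variables pairwise,
# and partitions the joined enzymes into the four kinetic groups.

library(cpcnet)

m <- read_cpc_table("results/synthetic/cpc_matrix.tsv",
                    "results/synthetic/tissues.tsv")
net <- read_reaction_network("results/synthetic/network_stoichiometry.tsv",
                             "results/synthetic/reaction_meta.tsv")
mf <- filter_rare_proteins(m)$matrix
km <- cpcnet:::read_tsv("results/synthetic/km_table.tsv")
thermo <- cpcnet:::read_tsv("results/synthetic/thermo.tsv")

filt <- filter_km(km)
cat(sprintf("K_M records: %d in, %d kept after wild-type + outlier filters\n",
            nrow(km), nrow(filt$records)))
agg <- aggregate_km(filt$records)

jc <- join_and_correlate(agg, thermo, mf, net)
write_tsv(jc$correlations, "results/correlations.tsv")
cat("Pairwise correlations (log10 CPC, log10 K_M, dG0):\n")
print(jc$correlations[, c("pair", "pearson_r", "spearman_rho", "n")],
      row.names = FALSE)

grouped <- assign_groups(jc$joined)
write_tsv(grouped, "results/kinetics_joined.tsv")
cat("Group sizes (1 = moderate, 2 = high CPC, 3 = extreme K_M, 4 = very low dG0):\n")
print(table(grouped$group))
cat("Wrote correlations.tsv, kinetics_joined.tsv\n")
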