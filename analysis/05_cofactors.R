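#!/usr/bin/env Rscript
# Stage 5 — cofactor usage.
#
# Classifies every enzyme whose reaction touches the NAD(H) or NADP(H)
# pools (either side, so reversible reactions count) or alpha-
# ketoglutarate (nitrogen assimilation), and ranks the classes by mean
# abundance.

library(cpcnet)

m <- read_cpc_table("results/synthetic/cpc_matrix.tsv",
                    "results/synthetic/tissues.tsv")
net <- read_reaction_network("results/synthetic/network_stoichiometry.tsv",
                             "results/synthetic/reaction_meta.tsv")
mf <- filter_rare_proteins(m)$matrix

redox <- classify_redox(net, mf)
amino <- classify_aminotransferases(net, mf)
write_tsv(redox, "results/redox_ranking.tsv")
write_tsv(amino, "results/aminotransferase_ranking.tsv")

cat(sprintf("%d NAD-linked, %d NADP-linked, %d aminotransferase enzymes\n",
            sum(redox$class == "NAD_linked"),
            sum(redox$class == "NADP_linked"), nrow(amino)))
if (nrow(redox))
  cat(sprintf("Most abundant redox enzyme: %s (%.0f mean CPC)\n",
              redox$enzyme_id[1], redox$mean_cpc[1]))

ct <- cofactor_usage_table(rbind(redox, amino))
write_tsv(ct$nodes, "results/cofactor_nodes.tsv")
write_tsv(ct$edges, "results/cofactor_edges.tsv")
cat("Wrote redox_ranking.tsv, aminotransferase_ranking.tsv, cofactor_{nodes,edges}.tsv\n")
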