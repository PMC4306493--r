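# cpcnet

Analysis of how absolute enzyme abundance is organized across a
metabolic network, for systems biologists working with deep proteome
panels (e.g. cancer cell-line collections quantified in cell protein
copies, CPC). The flux through a reaction is bounded by its enzyme's
concentration, so the distribution of absolute abundance over pathways
and over competing reactions is informative about network organization
even without flux measurements.

The pipeline:

1. **Proteome partitioning** — filter proteins detected in only one
   sample or tissue; compute the metabolic share of total protein mass,
   per-pathway percentages per cell line (multi-pathway proteins count
   fully in each pathway), and log-binned abundance distributions.
2. **Glycolysis profiling** — mean/min/max CPC along an ordered
   glucose-to-lactate chain, and branch-point enzymes compared against
   the core enzyme competing for the same substrate (ratio and
   per-cell-line exceedance counts).
3. **Branch-point analysis** — every metabolite consumed by ≥ 2
   reactions is a branch point; with competing routes ranked by mean
   CPC descending (C₁ ≥ C₂ ≥ C₃), the branch divergence scores are

   BD₂ = (C₁ − C₂) / C₁  ∈ [0, 1]
   BD₃ = (C₁ − C₂ − C₃) / C₁  ∈ [−1, 1]  (branches with ≥ 3 routes)

   Branches are *one-sided* when BD₂ > 0.8 and *equally distributed*
   when BD₂ < 0.2 or BD₃ < 0; pathway composition of the two classes is
   compared with Fisher's exact test.
4. **Cofactor usage** — enzymes whose reactions involve NAD⁺/NADH or
   NADP⁺/NADPH on either side (redox), or α-ketoglutarate (nitrogen
   assimilation), ranked by mean abundance.
5. **Kinetics integration** — per-enzyme K_M aggregation (wild-type
   records, log-scale IQR outlier removal, geometric mean), joined with
   standard reaction Gibbs energies ΔG° and mean CPC; pairwise Pearson
   and Spearman correlations and a reproducible four-group partition of
   the scaled (CPC, K_M, ΔG°) triples.

Real inputs of this shape are large external snapshots, so the package
includes a synthetic-data generator (`sim_config()`,
`simulate_dataset()`) that fabricates an NCI-60-like panel — log-normal
CPC, sparse detection, planted pathways, planted branch points with
chosen BD₂, kinetic tables with injected mutants and outliers — plus a
ground-truth manifest against which every stage is tested.

## Worked example

```r
library(cpcnet)

s   <- simulate_dataset(sim_config(seed = 1), "results/synthetic")
m   <- read_cpc_table("results/synthetic/cpc_matrix.tsv",
                      "results/synthetic/tissues.tsv")
pm  <- read_pathway_map("results/synthetic/pathway_map.tsv")
net <- read_reaction_network("results/synthetic/network_stoichiometry.tsv",
                             "results/synthetic/reaction_meta.tsv")

flt <- filter_rare_proteins(m)
filter_cpc_summary(m)[c("removed_mean_cpc", "retained_mean_cpc")]
#> $removed_mean_cpc
#> [1] 3454.732
#> $retained_mean_cpc
#> [1] 90452.03

metabolic_fraction(flt$matrix, pm)
#> [1] 18.80159

scored <- score_branches(
  dedupe_and_filter(extract_branch_points(net), net, flt$matrix),
  net, flt$matrix)
table(scored$class)
#> equally_distributed           one_sided        unclassified
#>                   2                   2                   2
```

The 100 removed proteins average ~3,500 CPC against ~90,000 CPC for the
1,900 retained — the sporadically-detected population the filter is for.
The metabolic proteome holds 18.8% of total protein mass (the planted
truth is recorded in `results/synthetic/manifest.json`), and the six
planted branch points come back with their planted divergence classes
(BD₂ targets 0.9/0.9 → one-sided, 0.1/0.1 → equally distributed,
0.5/0.5 → unclassified).

The numbered drivers under `analysis/` run the same stages end to end
(`Rscript analysis/01_simulate.R` … `06_kinetics.R`) and write their
tables under `results/`; `run_pipeline()` does it in one call with a
YAML-configurable parameter set and a machine-readable `summary.json`.

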