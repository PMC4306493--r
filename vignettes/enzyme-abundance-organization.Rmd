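---
title: "Organization of absolute enzyme abundance across a metabolic network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organization of absolute enzyme abundance across a metabolic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the quantities

For any enzymatic reaction, the attainable flux is bounded by the amount
of enzyme present. Absolute proteomics — here in the cell protein copy
(CPC) metric, an estimate of copies of a protein per cell — therefore
lets one ask structural questions about a metabolic network without
measuring flux at all: how much of the proteome is metabolic, how is
that mass divided across pathways, and when a metabolite can be consumed
by several reactions, is the available catalytic capacity concentrated
on one route or spread across them?

`cpcnet` implements that analysis as a pipeline over four inputs: a
protein-by-cell-line CPC matrix with a tissue label per cell line, a
many-to-many pathway-membership map, a stoichiometric reaction network
with reaction-to-enzyme and reaction-to-pathway maps, and kinetic tables
(replicate Michaelis constants `K_M` with wild-type flags, and standard
reaction Gibbs energies dG0). Because the real data of this kind are
large external downloads, the package ships a synthetic generator that
fabricates all four inputs with known ground truth; every stage is
tested by recovering what was planted.

## Detection filtering and proteome partitioning

An entry is *detected* when it is present and strictly positive. The
data this emulates mixes true missingness with zeros, and the
conservative reading is that neither is a detection; undetected entries
are written as empty fields, never as zeros, so the distinction
survives a round-trip. `filter_rare_proteins()` removes every protein
whose detections span fewer than two cell lines or fewer than two
tissues — sporadically detected proteins carry far lower average
abundance than the remainder and say little about network-level
organization.

The metabolic share is a mass fraction: with per-protein mean CPC
averaged across all cell lines (absent entries counting as zero by
default, so a protein seen in 3 of 59 lines is not credited a full-panel
abundance), the metabolic percentage is 100 times the mean-CPC mass of
pathway-mapped proteins over the mass of all proteins. Whether the
average should instead be taken over detecting lines only is genuinely
ambiguous; both modes are implemented (`absent = "zero"` / `"exclude"`)
and the default is the zero-filled mean. Pathway percentages are
computed per cell line against the line's total CPC (a flag switches the
denominator to the metabolic subset only), and a protein belonging to
several pathways counts fully in each — so pathway percentages do not
sum to 100 by construction. Pathways with no detected protein are
reported with a flag rather than dropped.

Abundance distributions are summarized as log-binned relative
frequencies: half-open bins `[10^(kw), 10^((k+1)w))` anchored at
`10^0`, with `w = 0.3` for the proteome-wide view and `w = 0.2` for
the finer pathway subset. The anchor is a choice (the bin width, not the
origin, is what the display convention fixes); an epsilon guard keeps
values lying exactly on an edge in their upper bin despite floating-point
log error.

## Core-pathway profiling

`glycolysis_core()` ships an editable 11-step reconstruction of the
glucose-to-lactate chain (hexokinase through lactate dehydrogenase, one
representative isoform per step), with the branch enzymes that compete
for each step's substrate — G6PD at glucose-6-phosphate, GFPT1 at
fructose-6-phosphate, GPD1 at dihydroxyacetone phosphate, PHGDH at
3-phosphoglycerate (the committed step of de novo serine synthesis), and
PC/PDHA1 at pyruvate. The exact membership of the canonical profile is
not machine-derivable, so the definition is packaged as data a user can
edit rather than hard-coded. Step statistics sum isoenzyme CPCs by
default (per-isoenzyme rows are also emitted); output order is purely
the pathway's, never abundance-driven. The branch-versus-core comparison
reports, per step, the ratio of branch to core mean CPC and the
exceedance count — in how many cell lines the diverting capacity is at
least the through-going capacity.

## Branch divergence scores

A branch point is a metabolite consumed as a reactant by at least two
distinct reactions. For reversible reactions only the declared reactant
side counts by default — the stoichiometric sign convention is taken at
face value — with `reversible_both_sides = TRUE` available since a
reversible consumer is also a potential producer. Currency metabolites
(ATP, water, and friends) dominate connectivity if left in; the default
is no exclusion, with a user-suppliable exclusion list.

Branches whose consuming-reaction sets coincide are collapsed to one
record, and a branch is scored only when every consuming reaction has a
mapped enzyme present in the filtered matrix — otherwise the ranking
below would be taken over an incomplete field. Each reaction's abundance
is the summed mean CPC of its mapped enzymes (a max option exists; the
choice matters only for isoenzyme-rich reactions), reactions are ranked
descending with ties broken lexicographically by lead enzyme id for
determinism, and with `C1 >= C2 >= C3` the scores are

* top-2: `BD2 = (C1 - C2) / C1`, in `[0, 1]`;
* top-3 (three or more routes): `BD3 = (C1 - C2 - C3) / C1`, in
  `[-1, 1]`, never above BD2.

Classification uses strict inequalities: one-sided above 0.8 on BD2,
equally distributed below 0.2 on BD2 *or* below 0 on BD3, otherwise
unclassified; scores landing exactly on a threshold stay unclassified.
The 0.8 rule is applied to BD2 (which score the threshold belongs to is
not pinned down; a flag admits BD3 as well). Histograms use 0.1-wide
lower-inclusive bins with the top bin closed so a score of exactly 1 is
counted.

For enrichment, each classified branch contributes its top-2 ranked
enzymes — top-3 when the BD3 rule settled the class — counted as unique
(branch, enzyme) pairs, mapped to pathways through their reactions. Per
pathway a 2x2 table (in-pathway vs not, one-sided vs equally
distributed) is tested with a two-sided Fisher's exact test; raw
p-values are compared against 0.05, with Benjamini–Hochberg adjustment
available behind a flag but off by default to match the raw-threshold
convention. Count ratios (one-sided over equally distributed) are
reported with division-by-zero flagged rather than silently dropped.

## Cofactor usage

An enzyme is NAD-linked (resp. NADP-linked) when any reaction it
catalyzes contains NAD+/NADH (resp. NADP+/NADPH) among its reactants
*or* products — both sides count so that reversible reactions are
covered — and an aminotransferase, for the purpose of tracing nitrogen
assimilation, when its reaction involves alpha-ketoglutarate. Matching
is by metabolite identity against a packaged, user-replaceable synonym
table; compartment tags (`nadh_c`, `nadh[m]`, ...) are collapsed into
one pool by default because compartmentation is not otherwise modelled,
with a flag to keep pools separate. Classification is a pure network
property; the mean-CPC ranking is layered on top and the direction
annotation (cofactor on reactant side, product side, or both) is
emitted without asserting physiological producer/consumer roles, which
stoichiometry alone cannot decide.

## Kinetics integration

Replicate `K_M` values are filtered to wild-type records, then per
enzyme to the log10 values inside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` — the
outlier rule has to live on the log scale because inter-laboratory
`K_M` scatter is multiplicative. The per-enzyme aggregate is the
geometric mean (arithmetic behind a flag) since the values span orders
of magnitude. Enzymes with all three of mean CPC, aggregated `K_M` and
dG0 are inner-joined — an enzyme catalyzing several reactions takes its
lexicographically first reaction's dG0 by default, expandable to one
row per pair — and Pearson and Spearman coefficients are reported for
all three pairs on log10(CPC), log10(K_M) and linear dG0 (which
coefficient the original visual claim of "no correlation" refers to is
unstated, so both are given).

For the joint view, each variable is min-max scaled to `[0, 1]` — CPC
and `K_M` on the log scale, dG0 linear. The four-group partition that
was originally drawn by eye is replaced by an explicit, reproducible
rule evaluated in priority order: group 3 when scaled `K_M >= 0.9`
(substrate must pile up before the reaction runs), group 4 when scaled
dG0 `<= 0.1` (effectively irreversible), group 2 when scaled CPC
`>= 0.9` with neither extreme (the highly-expressed glycolysis-like
regime), group 1 otherwise. Thresholds are configurable; the assignment
is exhaustive and mutually exclusive by construction.

## What the generator emulates — and what it does not

Defaults describe an NCI-60-like panel: 59 cell lines over 9 tissues;
independent entry-level log10 CPC draws from N(4, 0.9) (a roughly
log-normal copy-number distribution centred near 10^4); detection rate
0.85 with empty fields for misses; 12% of proteins metabolic, of which
a planted glycolysis-like pathway holds 32 proteins at 6-fold abundance
— these two numbers together put the expected metabolic share of total
CPC near 18.5% and the dominant pathway near 9% of the proteome, the
regime the analysis is meant to operate in; 5% of non-metabolic
proteins planted as sporadically detected (a single cell line) at 0.035
times ordinary abundance, which is the population the detection filter
exists to remove and reproduces the large removed-versus-retained mean
contrast of deep panels; a reaction network of six planted branch
points (BD2 targets 0.9, 0.9, 0.5, 0.5, 0.1, 0.1; two branches with
three routes) padded with linear chains whose reactions release
nadh/nadph/akg as secondary products so the cofactor stage has planted
truth; and kinetic tables with 6 replicates per enzyme, log10 scatter
0.15, 10% mutant-flagged records (shifted one decade up) and 5% gross
outliers (four decades up), with true `K_M` drawn around 10^-4 M and
dG0 around -10 +/- 15 kJ/mol, independent of abundance by default
(`kinetics_rho` plants a correlation when recovery of a dependence is
to be tested).

Planted branch abundances are realized exactly: enzyme means are fixed
analytically from the BD2 target (`C2 = C1 (1 - BD2)`, further routes
halving), per-cell-line log-normal noise is added, and the detected
entries are rescaled so the zero-filled mean equals the planted mean to
machine precision. A BD2 target of exactly 1 is rejected at
configuration time since it would require a zero abundance. Identical
seeds give byte-identical files, and the emitted manifest records only
quantities recomputable from the files themselves.

The generator does not emulate: mass-spectrometry rawness (peptides,
LFQ-to-CPC regression), protein-level abundance correlation across cell
lines beyond the planted structure, tissue-specific expression
programs, compartmentation, or realistic network topology (degree
distributions, currency-metabolite hubs). Passing recovery tests
therefore demonstrates correctness of the computations under the
stated generative assumptions — not robustness to everything real
panels do.

## Numerical choices and degenerate inputs

Problem sizes follow the desk-scale defaults above (2,000 x 59 panel;
recovery loops use 100 seeds of a 150 x 12 panel, correlation checks a
500-enzyme network), which keep the full test suite under a minute
while leaving sampling error far inside the asserted tolerances.
Degenerate inputs are errors with typed conditions rather than silent
results: empty matrices, constant variables under min-max scaling,
branches whose top-ranked abundance is zero, correlation requests with
fewer than three joined enzymes, enrichment with an empty class.
Ranking ties anywhere are broken lexicographically so reruns are
reproducible. The packaged glycolysis definition and the
currency/cofactor synonym lists are data, not code — editing them is
the supported way to change scope.

## Known limitations

Branch scores bound capacity, not flux: they say how catalytic
potential is distributed, not how matter flows. Enrichment counts
unique (branch, enzyme) pairs, one documented resolution of an
ambiguity (counting with multiplicity is the other). The four-group
rule is a surrogate for a judgment call and its thresholds are
conventions, not estimates. And absolute desk-scale counts (numbers of
branch points, pathway tallies) depend on the supplied network and
pathway snapshots; with synthetic inputs they characterize the
generator, and only with real snapshots do they characterize human
metabolism.
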