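# Synthetic-data generator: determinism, distributional structure,
# planted truths, and self-consistency of the manifest.

no_plants <- function(...) {
  sim_config(planted_pathways = NULL, planted_branches = NULL,
             rare_protein_fraction = 0,
             n_reactions = 4, n_metabolites = 8, ...)
}

test_that("identical seeds give identical outputs, different seeds differ", {
  cfg <- sim_config(n_proteins = 100, n_cell_lines = 8, seed = 42,
                    metabolic_fraction = 0.6,
                    n_reactions = 20, n_metabolites = 30)
  a <- generate_cpc_matrix(cfg)
  b <- generate_cpc_matrix(cfg)
  expect_identical(a, b)
  expect_identical(generate_pathway_map(cfg), generate_pathway_map(cfg))
  cfg2 <- sim_config(n_proteins = 100, n_cell_lines = 8, seed = 43,
                     metabolic_fraction = 0.6,
                     n_reactions = 20, n_metabolites = 30)
  expect_false(identical(a$cpc, generate_cpc_matrix(cfg2)$cpc))
})

test_that("written dataset files are byte-identical across runs", {
  cfg <- sim_config(n_proteins = 60, n_cell_lines = 6, seed = 9,
                    n_reactions = 16, n_metabolites = 26,
                    metabolic_fraction = 0.6)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  for (f in names(s1$paths))
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]),
                     info = f)
})

test_that("degenerate config (sigma = 0, full detection) gives constant 10^mu", {
  m <- generate_cpc_matrix(no_plants(
    n_proteins = 30, n_cell_lines = 4, lognormal_mu = 3,
    lognormal_sigma = 0, detection_rate = 1, metabolic_fraction = 0.5,
    seed = 1))
  expect_false(anyNA(m$cpc))
  expect_true(all(m$cpc == 1e3))
})

test_that("sample mean of log10 CPC lands within 3 SE of mu at large n", {
  cfg <- no_plants(n_proteins = 10000, n_cell_lines = 4, lognormal_mu = 4,
                   lognormal_sigma = 0.5, detection_rate = 1,
                   metabolic_fraction = 0.05, seed = 5)
  m <- generate_cpc_matrix(cfg)
  lg <- log10(m$cpc)
  se <- 0.5 / sqrt(length(lg))
  expect_lt(abs(mean(lg) - 4), 3 * se)
})

test_that("config validation rejects bad parameters", {
  expect_error(sim_config(lognormal_mu = NaN), class = "cpcnet_config_error")
  expect_error(sim_config(detection_rate = 1.2), class = "cpcnet_config_error")
  expect_error(sim_config(n_proteins = 0), class = "cpcnet_config_error")
  expect_error(sim_config(km_sigma = -1), class = "cpcnet_config_error")
  # a planted BD2 of exactly 1 would need a zero abundance
  expect_error(sim_config(planted_branches = data.frame(
    metabolite_id = "b", n_out_reactions = 2L, target_bd2 = 1)),
    class = "cpcnet_config_error")
  expect_error(sim_config(planted_branches = data.frame(
    metabolite_id = c("b", "b"), n_out_reactions = 2L,
    target_bd2 = c(0.5, 0.6))), class = "cpcnet_config_error")
})

test_that("pathway map honours planted sizes, overlap and the empty case", {
  one <- sim_config(n_proteins = 100, n_cell_lines = 6,
                    metabolic_fraction = 0.05, overlap_rate = 0,
                    planted_pathways = data.frame(
                      pathway_id = "pp", n_proteins = 5,
                      abundance_multiplier = 2),
                    planted_branches = NULL, n_reactions = 4,
                    n_metabolites = 8, seed = 2)
  pm <- generate_pathway_map(one)
  expect_identical(nrow(pm), 5L)
  expect_true(all(pm$pathway_id == "pp"))

  dflt <- sim_config(n_proteins = 400, n_cell_lines = 8, seed = 3)
  pm2 <- generate_pathway_map(dflt)
  expect_gt(max(table(pm2$protein_id)), 1)  # some multi-membership

  empty <- no_plants(n_proteins = 50, n_cell_lines = 4,
                     metabolic_fraction = 0, seed = 4)
  expect_identical(nrow(generate_pathway_map(empty)), 0L)
})

test_that("planted branches are realized exactly in the emitted matrix", {
  cfg <- sim_config(n_proteins = 300, n_cell_lines = 12,
                    metabolic_fraction = 0.4, seed = 11,
                    planted_branches = data.frame(
                      metabolite_id = c("x", "y", "z"),
                      n_out_reactions = c(2L, 3L, 2L),
                      target_bd2 = c(0, 0.7, 0.25)),
                    n_reactions = 12, n_metabolites = 20)
  s <- cpcnet:::simulate_all(cfg)
  means <- mean_cpc(s$cpc)
  for (b in s$manifest$branches) {
    expect_equal(unname(means[b$enzymes]), b$planted_means,
                 tolerance = 1e-12)
    got2 <- bd_top2(sort(means[b$enzymes], decreasing = TRUE))
    expect_equal(got2, b$bd2, tolerance = 1e-12)
  }
  # bd2 = 0 branch: the two routes tie exactly
  eq <- s$manifest$branches[[1]]
  expect_equal(means[eq$enzymes[1]], means[eq$enzymes[2]],
               ignore_attr = TRUE)
})

test_that("downstream extraction finds exactly the planted branches", {
  cfg <- sim_config(n_proteins = 200, n_cell_lines = 10,
                    metabolic_fraction = 0.5, seed = 13)
  s <- cpcnet:::simulate_all(cfg)
  found <- extract_branch_points(s$network)
  planted <- vapply(s$manifest$branches, `[[`, "", "metabolite_id")
  expect_setequal(found$metabolite_id,
                  c(planted, s$manifest$incidental_branches))
  # routes per planted branch match the config
  for (b in s$manifest$branches)
    expect_length(cpcnet:::split_ids(found$reactions[
      found$metabolite_id == b$metabolite_id]), length(b$reactions))
  # and the whole enumeration agrees with a brute-force scan
  bf <- bf_branches(s$network$stoichiometry, dedupe = FALSE)
  srt <- found[order(found$metabolite_id), , drop = FALSE]
  expect_identical(bf$metabolite_id, srt$metabolite_id)
  expect_identical(bf$reactions, srt$reactions)
})

test_that("kinetic tables recover truth at zero noise and flag mutants", {
  clean <- sim_config(n_proteins = 200, n_cell_lines = 8,
                      metabolic_fraction = 0.5, km_scatter_sd = 0,
                      outlier_rate = 0, mutant_rate = 0, seed = 21)
  s <- cpcnet:::simulate_all(clean)
  agg <- aggregate_km(filter_km(s$km_table)$records)
  truth <- unlist(s$manifest$true_km)[agg$enzyme_id]
  expect_equal(agg$km, unname(truth), tolerance = 1e-12)

  all_mut <- sim_config(n_proteins = 200, n_cell_lines = 8,
                        metabolic_fraction = 0.5, mutant_rate = 1, seed = 22)
  s2 <- cpcnet:::simulate_all(all_mut)
  expect_identical(nrow(filter_km(s2$km_table)$records), 0L)
  expect_setequal(filter_km(s2$km_table)$dropped_enzymes,
                  unique(s2$km_table$enzyme_id))
})

test_that("with scatter, filtered geometric means stay near manifest truth", {
  cfg <- sim_config(n_proteins = 200, n_cell_lines = 8,
                    metabolic_fraction = 0.5, km_scatter_sd = 0.15,
                    km_replicates = 8, outlier_rate = 0, mutant_rate = 0,
                    seed = 23)
  s <- cpcnet:::simulate_all(cfg)
  agg <- aggregate_km(filter_km(s$km_table)$records)
  truth <- unlist(s$manifest$true_km)[agg$enzyme_id]
  # replicate SE on log10 scale is 0.15/sqrt(8) ~ 0.053; allow ~4 SE
  expect_true(all(abs(log10(agg$km) - log10(truth)) < 0.22))
})

test_that("planted rare proteins are exactly what the detection filter removes", {
  cfg <- sim_config(n_proteins = 600, n_cell_lines = 20,
                    metabolic_fraction = 0.3, seed = 77)
  s <- cpcnet:::simulate_all(cfg)
  expect_length(s$manifest$rare_proteins, 30)
  flt <- filter_rare_proteins(s$cpc)
  expect_setequal(flt$removed, s$manifest$rare_proteins)
  fs <- filter_cpc_summary(s$cpc)
  # rare proteins sit ~1.5 decades below the detected remainder
  expect_lt(fs$removed_mean_cpc, fs$retained_mean_cpc / 5)
})

test_that("cpc table round-trips losslessly through TSV", {
  cfg <- sim_config(n_proteins = 80, n_cell_lines = 6, seed = 31,
                    metabolic_fraction = 0.6, n_reactions = 16,
                    n_metabolites = 26)
  d <- withr::local_tempdir()
  s <- simulate_dataset(cfg, d)
  back <- read_cpc_table(s$paths[["cpc"]], s$paths[["tissues"]])
  expect_equal(back$cpc, s$cpc$cpc, tolerance = 1e-12)
  expect_identical(is.na(back$cpc), is.na(s$cpc$cpc))
  expect_identical(back$tissue, s$cpc$tissue)
})
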