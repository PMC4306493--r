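# K_M filtering/aggregation, three-way correlation, scaling, grouping.

km_df <- function(values, wt = 1L, enzyme = "E1") {
  data.frame(enzyme_id = enzyme, km_value = values,
             wildtype = rep_len(wt, length(values)))
}

# One-enzyme-per-reaction scaffold for join tests.
kin_fixture <- function(n, seed = 1, km_fun = NULL, dg_fun = NULL) {
  set.seed(seed)
  enz <- sprintf("E%04d", seq_len(n))
  rxn <- sprintf("r%04d", seq_len(n))
  v <- matrix(10^stats::rnorm(n * 3, 3, 0.8), n, 3,
              dimnames = list(enz, c("L1", "L2", "L3")))
  m <- make_cpc(v, c(L1 = "ta", L2 = "tb", L3 = "tc"))
  net <- reaction_network(
    data.frame(reaction_id = rep(rxn, each = 2),
               metabolite_id = paste0(rep(rxn, each = 2), c("_s", "_p")),
               coefficient = rep(c(-1, 1), n)),
    data.frame(reaction_id = rxn, reversible = FALSE),
    data.frame(reaction_id = rxn, enzyme_id = enz),
    data.frame(reaction_id = rxn, pathway_id = "pw"))
  means <- mean_cpc(m)
  km <- if (is.null(km_fun)) 10^stats::rnorm(n, -4, 1) else km_fun(means[enz])
  dg <- if (is.null(dg_fun)) stats::rnorm(n, -10, 15) else dg_fun(means[enz])
  list(m = m, net = net,
       km_agg = data.frame(enzyme_id = enz, km = km, n_measurements = 1L),
       thermo = data.frame(reaction_id = rxn, dg0 = dg))
}

test_that("wild-type and IQR outlier filters behave as documented", {
  all_mut <- filter_km(km_df(c(1, 2, 3), wt = 0L))
  expect_identical(nrow(all_mut$records), 0L)
  expect_identical(all_mut$dropped_enzymes, "E1")

  with_outlier <- filter_km(km_df(c(1, 1.1, 0.9, 1000)))
  expect_setequal(with_outlier$records$km_value, c(1, 1.1, 0.9))

  zero_spread <- filter_km(km_df(c(1, 1, 1)))
  expect_identical(nrow(zero_spread$records), 3L)

  expect_error(filter_km(km_df(c(1, -2))), class = "cpcnet_config_error")
  # mutant rows never leak through even when numerically inlying
  mixed <- filter_km(rbind(km_df(c(1, 1.2, 0.8)), km_df(1.1, wt = 0L)))
  expect_identical(nrow(mixed$records), 3L)
})

test_that("aggregation takes the geometric mean and reports counts", {
  expect_equal(aggregate_km(km_df(5))$km, 5)
  expect_equal(aggregate_km(km_df(c(1, 100)))$km, 10)
  expect_equal(aggregate_km(km_df(c(2, 4, 8)))$km, 4)
  expect_equal(aggregate_km(km_df(c(2, 4, 8)), "arithmetic")$km, 14 / 3)
  expect_identical(aggregate_km(km_df(c(2, 4, 8)))$n_measurements, 3L)
})

test_that("filter + aggregation is invariant to record order", {
  set.seed(2)
  recs <- rbind(km_df(10^rnorm(8, 0, 0.5), enzyme = "A"),
                km_df(10^rnorm(5, -2, 0.5), enzyme = "B"),
                km_df(1e6, wt = 0L, enzyme = "A"))
  shuffled <- recs[sample(nrow(recs)), ]
  a <- aggregate_km(filter_km(recs)$records)
  b <- aggregate_km(filter_km(shuffled)$records)
  expect_equal(a, b)
})

test_that("independent variables show no correlation; coupled ones r = 1", {
  fx <- kin_fixture(500, seed = 10)
  jc <- join_and_correlate(fx$km_agg, fx$thermo, fx$m, fx$net)
  expect_identical(unique(jc$correlations$n), 500L)
  expect_true(all(abs(jc$correlations$pearson_r) < 0.15))

  coupled <- kin_fixture(500, seed = 11, km_fun = function(cpc) cpc * 1e-7)
  jc2 <- join_and_correlate(coupled$km_agg, coupled$thermo, coupled$m,
                            coupled$net)
  r <- jc2$correlations$pearson_r[jc2$correlations$pair == "cpc_vs_km"]
  expect_gt(r, 0.99)
})

test_that("a join without shared enzymes is an error", {
  fx <- kin_fixture(5, seed = 12)
  fx$km_agg$enzyme_id <- paste0("Z", fx$km_agg$enzyme_id)
  expect_error(join_and_correlate(fx$km_agg, fx$thermo, fx$m, fx$net),
               class = "cpcnet_undefined_correlation")
})

test_that("unit scaling is anchored, order preserving and idempotent", {
  expect_equal(scale_unit(c(10, 100, 1000), log10_first = TRUE),
               c(0, 0.5, 1))
  expect_equal(scale_unit(c(3, 9)), c(0, 1))
  set.seed(3)
  x <- rnorm(50)
  sc <- scale_unit(x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(order(sc), order(x))
  expect_equal(scale_unit(sc), sc)  # idempotent
  expect_error(scale_unit(rep(4, 3)), class = "cpcnet_undefined_scaling")
})

test_that("the four-group rule is exhaustive, exclusive and as specified", {
  expect_identical(kinetic_group(0.5, 0.95, 0.5), 3L)
  expect_identical(kinetic_group(0.95, 0.2, 0.5), 2L)
  expect_identical(kinetic_group(0.5, 0.5, 0.5), 1L)
  expect_identical(kinetic_group(0.5, 0.5, 0.05), 4L)
  # priority: extreme K_M wins over extreme dG0
  expect_identical(kinetic_group(0.5, 0.95, 0.05), 3L)
  grid <- expand.grid(c = seq(0, 1, 0.25), k = seq(0, 1, 0.25),
                      d = seq(0, 1, 0.25))
  g <- kinetic_group(grid$c, grid$k, grid$d)
  expect_true(all(g %in% 1:4))
  expect_identical(length(g), nrow(grid))
})

test_that("group assignment partitions the joined set", {
  fx <- kin_fixture(200, seed = 13)
  jc <- join_and_correlate(fx$km_agg, fx$thermo, fx$m, fx$net)
  grouped <- assign_groups(jc$joined)
  expect_false(anyNA(grouped$group))
  expect_true(all(grouped$group %in% 1:4))
  expect_identical(nrow(grouped), nrow(jc$joined))
  expect_true(all(grouped$scaled_cpc >= 0 & grouped$scaled_cpc <= 1))
  # every joined enzyme gets exactly one group
  expect_identical(anyDuplicated(grouped$enzyme_id), 0L)
})

test_that("multi-reaction enzymes use the primary reaction unless expanded", {
  fx <- kin_fixture(4, seed = 14)
  # give E0001 a second reaction
  extra <- data.frame(reaction_id = "r0999", metabolite_id = c("s9", "p9"),
                      coefficient = c(-1, 1))
  fx$net$stoichiometry <- rbind(fx$net$stoichiometry, extra)
  fx$net$reactions <- rbind(fx$net$reactions,
                            data.frame(reaction_id = "r0999",
                                       reversible = FALSE))
  fx$net$enzymes <- rbind(fx$net$enzymes,
                          data.frame(reaction_id = "r0999",
                                     enzyme_id = "E0001"))
  fx$thermo <- rbind(fx$thermo,
                     data.frame(reaction_id = "r0999", dg0 = -99))
  jc <- join_and_correlate(fx$km_agg, fx$thermo, fx$m, fx$net)
  expect_identical(nrow(jc$joined), 4L)  # primary reaction only
  expect_identical(jc$joined$reaction_id[jc$joined$enzyme_id == "E0001"],
                   "r0001")
  jc2 <- join_and_correlate(fx$km_agg, fx$thermo, fx$m, fx$net,
                            expand_reactions = TRUE)
  expect_identical(nrow(jc2$joined), 5L)
})
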