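# Synthetic-data generator. Fabricates every input the pipeline consumes
# — abundance matrix, tissue annotation, pathway map, reaction network,
# kinetic tables — with a ground-truth manifest, so each downstream stage
# can be tested for parameter recovery without any external download.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of an NCI-60-like panel: 59 cell
#' lines over 9 tissues; entry-level log10 CPC drawn from N(mu = 4,
#' sigma = 0.9) (a roughly log-normal copy-number distribution centred
#' near 10^4 copies/cell); 12% of proteins metabolic with a dominant
#' planted glycolysis-like pathway (32 proteins at 6x abundance), which
#' puts the metabolic share of total CPC near 18.5% and the dominant
#' pathway near 9% of the proteome; sparse detection at rate 0.85; a
#' small network with planted branch points spanning one-sided,
#' intermediate and equally-distributed divergence; and K_M/dG0 tables
#' with replicate scatter, injected mutant records and outliers.
#'
#' @param n_proteins,n_cell_lines panel dimensions.
#' @param tissues character vector of tissue labels; cell lines are
#'   assigned round-robin.
#' @param lognormal_mu,lognormal_sigma mean and sd of the log10 CPC entry
#'   distribution.
#' @param metabolic_fraction proportion of proteins that are metabolic
#'   (carry >= 1 pathway membership).
#' @param planted_pathways data frame (`pathway_id`, `n_proteins`,
#'   `abundance_multiplier`) of pathways planted with elevated (or
#'   suppressed) abundance.
#' @param n_background_pathways number of ordinary pathways the remaining
#'   metabolic proteins are spread over.
#' @param overlap_rate probability a metabolic protein receives a second
#'   pathway membership.
#' @param n_metabolites,n_reactions network size.
#' @param planted_branches data frame (`metabolite_id`,
#'   `n_out_reactions`, `target_bd2`) of branch points to plant;
#'   `target_bd2` must lie in `[0, 1)` — a target of exactly 1 would
#'   require a zero abundance and is rejected.
#' @param detection_rate probability an entry is detected (undetected
#'   entries are written as empty fields, i.e. absent, not zero).
#' @param rare_protein_fraction fraction of (non-metabolic) proteins
#'   planted as sporadically detected: seen in a single cell line only,
#'   at `rare_abundance_factor` times ordinary abundance. These are
#'   exactly the proteins the detection filter is meant to remove, and
#'   their low abundance mirrors the large removed-vs-retained mean
#'   contrast of deep proteome panels.
#' @param rare_abundance_factor abundance multiplier for rare proteins.
#' @param km_replicates,km_scatter_sd replicate K_M measurements per
#'   enzyme and their log10-scale scatter.
#' @param outlier_rate,mutant_rate injection rates for outlier
#'   measurements (shifted 4 decades) and mutant-flagged records.
#' @param km_mu,km_sigma log10 of true K_M (molar) distribution.
#' @param dg0_mu,dg0_sigma per-reaction standard Gibbs energy (kJ/mol)
#'   distribution.
#' @param kinetics_rho planted correlation between log10 K_M and log10
#'   mean CPC (0 = independent, 1 = perfectly coupled).
#' @param seed integer; identical seeds give bit-identical outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 2000,
                       n_cell_lines = 59,
                       tissues = c("breast", "cns", "colon", "leukemia",
                                   "melanoma", "nsclc", "ovarian",
                                   "prostate", "renal"),
                       lognormal_mu = 4,
                       lognormal_sigma = 0.9,
                       metabolic_fraction = 0.12,
                       planted_pathways = data.frame(
                         pathway_id = "glycolysis_like",
                         n_proteins = 32,
                         abundance_multiplier = 6),
                       n_background_pathways = 10,
                       overlap_rate = 0.15,
                       n_metabolites = 40,
                       n_reactions = 26,
                       planted_branches = data.frame(
                         metabolite_id = c("bm1", "bm2", "bm3", "bm4",
                                           "bm5", "bm6"),
                         n_out_reactions = c(2L, 3L, 2L, 2L, 3L, 2L),
                         target_bd2 = c(0.9, 0.9, 0.5, 0.5, 0.1, 0.1)),
                       detection_rate = 0.85,
                       rare_protein_fraction = 0.05,
                       rare_abundance_factor = 0.035,
                       km_replicates = 6,
                       km_scatter_sd = 0.15,
                       outlier_rate = 0.05,
                       mutant_rate = 0.1,
                       km_mu = -4,
                       km_sigma = 1,
                       dg0_mu = -10,
                       dg0_sigma = 15,
                       kinetics_rho = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$planted_pathways))
    cfg$planted_pathways <- data.frame(pathway_id = character(0),
                                       n_proteins = integer(0),
                                       abundance_multiplier = numeric(0))
  if (is.null(cfg$planted_branches))
    cfg$planted_branches <- data.frame(metabolite_id = character(0),
                                       n_out_reactions = integer(0),
                                       target_bd2 = numeric(0))
  counts <- c("n_proteins", "n_cell_lines", "n_background_pathways",
              "n_metabolites", "n_reactions", "km_replicates")
  for (f in counts)
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 1)
      stop_cpcnet(f, " must be >= 1", class = "cpcnet_config_error")
  if (!is.finite(cfg$rare_abundance_factor) || cfg$rare_abundance_factor <= 0)
    stop_cpcnet("rare_abundance_factor must be > 0",
                class = "cpcnet_config_error")
  for (f in c("metabolic_fraction", "detection_rate", "overlap_rate",
              "outlier_rate", "mutant_rate", "rare_protein_fraction"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_cpcnet(f, " must be in [0, 1]", class = "cpcnet_config_error")
  for (f in c("lognormal_mu", "lognormal_sigma", "km_mu", "km_sigma",
              "dg0_mu", "dg0_sigma", "km_scatter_sd"))
    if (!is.finite(cfg[[f]]))
      stop_cpcnet(f, " must be finite", class = "cpcnet_config_error")
  if (cfg$lognormal_sigma < 0 || cfg$km_sigma < 0 || cfg$km_scatter_sd < 0)
    stop_cpcnet("scale parameters must be >= 0", class = "cpcnet_config_error")
  if (abs(cfg$kinetics_rho) > 1)
    stop_cpcnet("kinetics_rho must be in [-1, 1]", class = "cpcnet_config_error")
  pb <- cfg$planted_branches
  if (nrow(pb)) {
    if (anyDuplicated(pb$metabolite_id))
      stop_cpcnet("planted branch metabolite ids must be unique",
                  class = "cpcnet_config_error")
    if (any(pb$n_out_reactions < 2))
      stop_cpcnet("planted branches need >= 2 outgoing reactions",
                  class = "cpcnet_config_error")
    if (any(pb$target_bd2 < 0 | pb$target_bd2 >= 1))
      stop_cpcnet("target_bd2 must lie in [0, 1): a target of 1 would need ",
                  "a zero abundance", class = "cpcnet_config_error")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Deterministically derives the whole synthetic dataset from a config.
# All generate_* accessors call this, so the pieces are mutually
# consistent (the network's enzymes exist in the matrix with the planted
# means, etc.).
simulate_all <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  nl <- config$n_cell_lines
  proteins <- sprintf("P%05d", seq_len(n))
  lines <- sprintf("CL%03d", seq_len(nl))
  tissue <- stats::setNames(rep_len(config$tissues, nl), lines)

  ## ---- pathway map -------------------------------------------------
  n_met <- round(config$metabolic_fraction * n)
  pp <- config$planted_pathways
  planted_total <- if (nrow(pp)) sum(pp$n_proteins) else 0L
  if (planted_total > n_met)
    stop_cpcnet("planted pathways need more proteins than the metabolic ",
                "fraction provides", class = "cpcnet_generation_error")
  met_prot <- proteins[seq_len(n_met)]
  pairs <- list()
  offset <- 0L
  mult <- rep(1, n)  # per-protein abundance multiplier
  names(mult) <- proteins
  for (i in seq_len(nrow(pp))) {
    block <- met_prot[offset + seq_len(pp$n_proteins[i])]
    pairs[[length(pairs) + 1L]] <-
      data.frame(pathway_id = pp$pathway_id[i], protein_id = block)
    mult[block] <- pp$abundance_multiplier[i]
    offset <- offset + pp$n_proteins[i]
  }
  background <- met_prot[seq.int(offset + 1L, length.out = n_met - offset)]
  bg_ids <- sprintf("pathway_%02d", seq_len(config$n_background_pathways))
  if (length(background))
    pairs[[length(pairs) + 1L]] <-
      data.frame(pathway_id = rep_len(bg_ids, length(background)),
                 protein_id = background)
  pmap <- do.call(rbind, pairs)
  if (is.null(pmap))
    pmap <- data.frame(pathway_id = character(0), protein_id = character(0))
  # second memberships, to exercise the multi-membership counting rule
  all_pw <- unique(pmap$pathway_id)
  extra <- met_prot[stats::runif(n_met) < config$overlap_rate]
  if (length(extra) && length(all_pw) > 1) {
    first_pw <- pmap$pathway_id[match(extra, pmap$protein_id)]
    second <- vapply(first_pw, function(p) sample(setdiff(all_pw, p), 1), "")
    pmap <- rbind(pmap, data.frame(pathway_id = second, protein_id = extra))
  }
  pmap <- unique(pmap[order(pmap$pathway_id, pmap$protein_id), ])
  rownames(pmap) <- NULL

  ## ---- reaction network skeleton -----------------------------------
  pb <- config$planted_branches
  n_routes <- if (nrow(pb)) sum(pb$n_out_reactions) else 0L
  n_chain <- config$n_reactions - n_routes
  if (n_chain < 0)
    stop_cpcnet("n_reactions is smaller than the planted branch routes",
                class = "cpcnet_generation_error")
  n_cmet <- config$n_metabolites - nrow(pb) - n_routes
  if (n_chain > 0 && n_cmet < n_chain + 1)
    stop_cpcnet("not enough metabolites for the linear chains",
                class = "cpcnet_generation_error")
  n_enzymes <- n_routes + n_chain
  # enzyme pool: tail of the metabolic set (never the planted blocks);
  # degenerate configs without enough metabolic proteins fall back to the
  # tail of the whole panel
  if (n_met - planted_total >= n_enzymes) {
    avail <- met_prot[seq.int(n_met - n_enzymes + 1L, length.out = n_enzymes)]
  } else if (n - planted_total >= n_enzymes) {
    avail <- proteins[seq.int(n - n_enzymes + 1L, length.out = n_enzymes)]
  } else {
    stop_cpcnet("not enough proteins to serve as reaction enzymes",
                class = "cpcnet_generation_error")
  }
  st <- list(); rx <- list(); enz_map <- list()
  enz_i <- 0L
  base_mean <- 3 * 10^config$lognormal_mu  # top-route planted mean CPC
  planted_mean <- stats::setNames(numeric(0), character(0))
  branch_truth <- list()
  for (i in seq_len(nrow(pb))) {
    k <- pb$n_out_reactions[i]
    t2 <- pb$target_bd2[i]
    # analytic means: m1 fixed, m2 = m1 (1 - bd2), further routes halve
    means_i <- base_mean * c(1, (1 - t2) * 0.5^(seq_len(k - 1) - 1))
    rids <- sprintf("R_%s_%d", pb$metabolite_id[i], seq_len(k))
    eids <- avail[enz_i + seq_len(k)]
    enz_i <- enz_i + k
    planted_mean[eids] <- means_i
    for (j in seq_len(k)) {
      st[[length(st) + 1L]] <- data.frame(
        reaction_id = rids[j],
        metabolite_id = c(pb$metabolite_id[i],
                          sprintf("%s_p%d", pb$metabolite_id[i], j)),
        coefficient = c(-1, 1))
      rx[[length(rx) + 1L]] <- data.frame(reaction_id = rids[j],
                                          reversible = FALSE)
      enz_map[[length(enz_map) + 1L]] <- data.frame(reaction_id = rids[j],
                                                    enzyme_id = eids[j])
    }
    bd3 <- if (k >= 3) (means_i[1] - means_i[2] - means_i[3]) / means_i[1]
           else NA_real_
    branch_truth[[i]] <- list(
      metabolite_id = pb$metabolite_id[i],
      reactions = rids, enzymes = eids,
      planted_means = unname(means_i),
      bd2 = t2, bd3 = bd3,
      class = classify_branch(t2, bd3))
  }
  cofactor_truth <- list(NAD_linked = character(0),
                         NADP_linked = character(0),
                         aminotransferase = character(0))
  if (n_chain > 0) {
    cmet <- sprintf("cm%03d", seq_len(n_cmet))
    extra_prod <- if (n_cmet > n_chain + 1)
      cmet[seq.int(n_chain + 2L, n_cmet)] else character(0)
    # every few chain reactions release a cofactor as a secondary product
    # (product side only, so no incidental branch points arise)
    cof_cycle <- c("nadh", "nadph", "akg", NA, NA)
    cof_class <- c(nadh = "NAD_linked", nadph = "NADP_linked",
                   akg = "aminotransferase")
    for (j in seq_len(n_chain)) {
      rid <- sprintf("R_chain_%02d", j)
      mets <- c(cmet[j], cmet[j + 1])
      co <- c(-1, 1)
      hook <- extra_prod[(seq_along(extra_prod) - 1L) %% n_chain + 1L == j]
      # spare metabolites ride along as secondary products
      if (length(hook)) { mets <- c(mets, hook); co <- c(co, rep(1, length(hook))) }
      cof <- cof_cycle[(j - 1L) %% length(cof_cycle) + 1L]
      if (!is.na(cof)) {
        mets <- c(mets, cof); co <- c(co, 1)
        cofactor_truth[[cof_class[[cof]]]] <-
          c(cofactor_truth[[cof_class[[cof]]]], avail[enz_i + j])
      }
      st[[length(st) + 1L]] <- data.frame(reaction_id = rid,
                                          metabolite_id = mets,
                                          coefficient = co)
      rx[[length(rx) + 1L]] <- data.frame(reaction_id = rid,
                                          reversible = j %% 2 == 0)
      enz_map[[length(enz_map) + 1L]] <-
        data.frame(reaction_id = rid, enzyme_id = avail[enz_i + j])
    }
    enz_i <- enz_i + n_chain
  }
  enzymes_df <- do.call(rbind, enz_map)
  pathways_df <- data.frame(
    reaction_id = enzymes_df$reaction_id,
    pathway_id = pmap$pathway_id[match(enzymes_df$enzyme_id,
                                       pmap$protein_id)])
  net <- reaction_network(do.call(rbind, st), do.call(rbind, rx),
                          enzymes_df, pathways_df)

  ## ---- CPC matrix ---------------------------------------------------
  lg <- matrix(stats::rnorm(n * nl, config$lognormal_mu,
                            config$lognormal_sigma), n, nl,
               dimnames = list(proteins, lines))
  vals <- 10^lg * mult
  det <- matrix(stats::runif(n * nl) < config$detection_rate, n, nl,
                dimnames = dimnames(vals))
  # Planted branch enzymes: overwrite with noise around the analytic
  # mean, then rescale the detected entries so the realized mean
  # (absent-as-0) equals the planted mean exactly — the realized BD
  # scores then hit their targets to machine precision.
  for (e in names(planted_mean)) {
    row <- planted_mean[e] * 10^stats::rnorm(nl, 0, 0.05)
    d <- det[e, ]
    if (sum(d) < 2) { d[1:2] <- TRUE; det[e, ] <- d }
    row[d] <- row[d] * (planted_mean[e] * nl / sum(row[d]))
    vals[e, ] <- row
  }
  # Sporadically detected low-abundance proteins: single-cell-line
  # detections drawn from the non-metabolic, non-enzyme pool. These are
  # the proteins the downstream detection filter removes.
  rare_pool <- setdiff(proteins, c(met_prot, avail))
  n_rare <- min(round(config$rare_protein_fraction * n), length(rare_pool))
  rare <- rare_pool[seq_len(n_rare)]
  for (p in rare) {
    keep <- sample.int(nl, 1)
    det[p, ] <- FALSE
    det[p, keep] <- TRUE
    vals[p, ] <- vals[p, ] * config$rare_abundance_factor
  }
  vals[!det] <- NA_real_
  m <- cpc_matrix(vals, tissue)

  ## ---- kinetic tables ----------------------------------------------
  enz_ids <- sort(unique(enzymes_df$enzyme_id))
  mm <- mean_cpc(m)[enz_ids]
  lg_mm <- log10(pmax(mm, .Machine$double.xmin))
  z_cpc <- if (stats::sd(lg_mm) > 0) as.numeric(scale(lg_mm))
           else rep(0, length(lg_mm))
  rho <- config$kinetics_rho
  z <- rho * z_cpc + sqrt(1 - rho^2) * stats::rnorm(length(enz_ids))
  true_km <- 10^(config$km_mu + config$km_sigma * z)
  names(true_km) <- enz_ids
  km_rows <- list()
  for (e in enz_ids) {
    v <- true_km[e] * 10^stats::rnorm(config$km_replicates, 0,
                                      config$km_scatter_sd)
    wt <- rep(1L, config$km_replicates)
    mut <- stats::runif(config$km_replicates) < config$mutant_rate
    v[mut] <- v[mut] * 10   # mutant assays biased high
    wt[mut] <- 0L
    out <- !mut & stats::runif(config$km_replicates) < config$outlier_rate
    v[out] <- v[out] * 1e4  # gross outliers, removable by the IQR rule
    km_rows[[length(km_rows) + 1L]] <-
      data.frame(enzyme_id = e, km_value = v, wildtype = wt)
  }
  km_table <- do.call(rbind, km_rows)
  rownames(km_table) <- NULL
  thermo <- data.frame(reaction_id = sort(unique(enzymes_df$reaction_id)),
                       dg0 = stats::rnorm(length(unique(enzymes_df$reaction_id)),
                                          config$dg0_mu, config$dg0_sigma))

  ## ---- manifest -----------------------------------------------------
  v0 <- vals; v0[is.na(v0)] <- 0
  pm <- rowMeans(v0)
  is_met <- proteins %in% metabolic_proteins(pmap)
  realized_frac <- 100 * sum(pm[is_met]) / sum(pm)
  manifest <- list(
    schema = "cpcnet_manifest_v1",
    seed = config$seed,
    n_proteins = n, n_cell_lines = nl,
    detection_rate = config$detection_rate,
    lognormal_mu = config$lognormal_mu,
    lognormal_sigma = config$lognormal_sigma,
    metabolic_proteins = met_prot,
    planted_pathways = pp,
    top_pathway = if (nrow(pp)) pp$pathway_id[which.max(
      pp$n_proteins * pp$abundance_multiplier)] else NA,
    true_metabolic_fraction_pct = realized_frac,
    branches = branch_truth,
    incidental_branches = character(0),
    cofactor_enzymes = cofactor_truth,
    rare_proteins = rare,
    true_km = as.list(true_km),
    kinetics_rho = rho)

  list(config = config, cpc = m, pathway_map = pmap, network = net,
       km_table = km_table, thermo = thermo, manifest = manifest)
}

#' Generate the synthetic CPC matrix
#'
#' @param config a [sim_config()].
#' @return a [cpc_matrix()] with undetected entries absent, planted
#'   pathway multipliers applied and planted branch-enzyme means realized
#'   exactly.
#' @export
generate_cpc_matrix <- function(config) simulate_all(config)$cpc

#' Generate the synthetic pathway membership map
#'
#' @param config a [sim_config()].
#' @return data frame of unique (`pathway_id`, `protein_id`) pairs; some
#'   proteins carry two memberships, non-metabolic proteins none.
#' @export
generate_pathway_map <- function(config) simulate_all(config)$pathway_map

#' Generate the synthetic reaction network
#'
#' @param config a [sim_config()].
#' @return a [reaction_network()] in which every planted branch
#'   metabolite is consumed by exactly its configured number of
#'   reactions, each reaction has one catalyzing enzyme present in the
#'   CPC matrix, and linear chains fill the remaining reactions.
#' @export
generate_reaction_network <- function(config) simulate_all(config)$network

#' Generate the synthetic kinetic tables
#'
#' @param config a [sim_config()].
#' @return list with `km_table` (`enzyme_id`, `km_value`, `wildtype`) and
#'   `thermo` (`reaction_id`, `dg0`).
#' @export
generate_kinetic_tables <- function(config) {
  s <- simulate_all(config)
  list(km_table = s$km_table, thermo = s$thermo)
}

#' Generate and write the full synthetic dataset
#'
#' Writes `cpc_matrix.tsv`, `tissues.tsv`, `pathway_map.tsv`,
#' `network_stoichiometry.tsv`, `reaction_meta.tsv`, `km_table.tsv`,
#' `thermo.tsv` and `manifest.json` into `dir`. Undetected abundance
#' entries are written as empty fields.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return the [simulate_all()] bundle (objects + manifest), invisibly,
#'   with a `paths` element.
#' @export
simulate_dataset <- function(config, dir) {
  s <- simulate_all(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_cpc_table(s$cpc, p("cpc_matrix.tsv"), p("tissues.tsv"))
  write_tsv(s$pathway_map, p("pathway_map.tsv"))
  write_reaction_network(s$network, p("network_stoichiometry.tsv"),
                         p("reaction_meta.tsv"))
  write_tsv(s$km_table, p("km_table.tsv"))
  write_tsv(s$thermo, p("thermo.tsv"))
  jsonlite::write_json(s$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  s$paths <- stats::setNames(
    vapply(c("cpc_matrix.tsv", "tissues.tsv", "pathway_map.tsv",
             "network_stoichiometry.tsv", "reaction_meta.tsv",
             "km_table.tsv", "thermo.tsv", "manifest.json"), p, ""),
    c("cpc", "tissues", "pathway_map", "stoichiometry", "reaction_meta",
      "km", "thermo", "manifest"))
  invisible(s)
}
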