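# End-to-end driver: simulate (or load) inputs, then run the proteome,
# glycolysis, branch, cofactor and kinetics stages, writing each stage's
# TSV outputs plus a machine-readable summary.json.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable at its default:
#' stage toggles, input paths (NULL = use the synthetic generator), the
#' detection/averaging modes, branch thresholds, currency-metabolite
#' exclusions, kinetic grouping thresholds and the simulation config.
#' A YAML or JSON file with any subset of these keys can be merged over
#' it via [run_pipeline()]'s `config` argument.
#'
#' @param seed integer seed forwarded to the simulation config.
#' @return named list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    stages = c("simulate", "proteome", "glycolysis", "branch", "cofactor",
               "kinetics"),
    inputs = list(cpc = NULL, tissues = NULL, pathway_map = NULL,
                  stoichiometry = NULL, reaction_meta = NULL,
                  km = NULL, thermo = NULL, core_pathway = NULL),
    absent_mean = "zero",           # absent entries count as 0 in means
    pathway_denominator = "total",  # per-line pathway % denominator
    pdf_width_exponent = 0.3,       # log-bin width for the global PDF
    glycolysis_pdf_width = 0.2,     # finer bins for the pathway subset
    currency_metabolites = character(0),
    reversible_both_sides = FALSE,
    reaction_cpc = "sum",
    bd_one_sided_min = 0.8,
    bd_equal_max = 0.2,
    enrichment_alpha = 0.05,
    enrichment_adjust = "none",
    collapse_compartments = TRUE,
    km_aggregate = "geometric",
    t_km = 0.9, t_dg = 0.1, t_cpc = 0.9,
    sim = list(seed = as.integer(seed)))
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), stage, ": ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order. When no input paths
#' are configured, the `simulate` stage generates the synthetic dataset
#' first; otherwise the supplied files are loaded. Every stage writes its
#' tables under `outdir` and contributes a section to `summary.json`
#' (counts, fractions, class tallies, correlations and the parameters
#' used). Log lines go to stderr so file/stdout output stays pipe-safe.
#'
#' @param config a list of overrides over [default_run_config()], or a
#'   path to a YAML/JSON file of such overrides.
#' @param outdir output directory.
#' @param seed convenience override of the simulation seed.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir, seed = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- merge_config(default_run_config(), config)
  if (!is.null(seed)) cfg$sim$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  stages <- cfg$stages
  summary <- list(schema = "cpcnet_summary_v1",
                  package_version = as.character(utils::packageVersion("cpcnet")),
                  parameters = cfg[setdiff(names(cfg), "inputs")])

  ## ---- inputs -------------------------------------------------------
  sim <- NULL
  if (is.null(cfg$inputs$cpc)) {
    if (!"simulate" %in% stages)
      stop_cpcnet("no input files configured and the simulate stage is off",
                  class = "cpcnet_dependency_error")
    log_stage("simulate", "generating synthetic dataset (seed ",
              cfg$sim$seed, ")")
    simdir <- p("synthetic")
    sim <- simulate_dataset(do.call(sim_config, cfg$sim), simdir)
    cfg$inputs <- as.list(sim$paths[c("cpc", "tissues", "pathway_map",
                                      "stoichiometry", "reaction_meta",
                                      "km", "thermo")])
    summary$simulate <- list(
      dir = simdir,
      n_proteins = sim$manifest$n_proteins,
      n_cell_lines = sim$manifest$n_cell_lines,
      n_planted_branches = length(sim$manifest$branches),
      true_metabolic_fraction_pct = sim$manifest$true_metabolic_fraction_pct)
  } else if ("simulate" %in% stages) {
    stages <- setdiff(stages, "simulate")
  }
  m <- read_cpc_table(cfg$inputs$cpc, cfg$inputs$tissues)
  pmap <- read_pathway_map(cfg$inputs$pathway_map)
  if ("simulate" %in% cfg$stages && identical(cfg$stages, "simulate")) {
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(summary))
  }

  ## ---- proteome -----------------------------------------------------
  flt <- filter_rare_proteins(m)
  mf <- flt$matrix
  if ("proteome" %in% stages) {
    log_stage("proteome", nrow(mf$cpc), " proteins retained, ",
              length(flt$removed), " removed by the detection filter")
    write_tsv(data.frame(protein_id = flt$removed), p("filter_report.tsv"))
    met_pct <- metabolic_fraction(mf, pmap, absent = cfg$absent_mean)
    pf <- pathway_fractions(mf, pmap, denominator = cfg$pathway_denominator)
    write_tsv(pf$summary, p("pathway_fractions.tsv"))
    vals <- mf$cpc[!is.na(mf$cpc) & mf$cpc > 0]
    pdf_all <- log_binned_pdf(vals, cfg$pdf_width_exponent)
    write_tsv(pdf_all, p("pdf_all.tsv"))
    met_vals <- mf$cpc[rownames(mf$cpc) %in% metabolic_proteins(pmap), ]
    met_vals <- met_vals[!is.na(met_vals) & met_vals > 0]
    pdf_met <- log_binned_pdf(met_vals, cfg$pdf_width_exponent)
    write_tsv(pdf_met, p("pdf_metabolic.tsv"))
    filt_stats <- filter_cpc_summary(m)
    summary$proteome <- list(
      n_proteins_in = nrow(m$cpc), n_removed = length(flt$removed),
      removed_mean_cpc = filt_stats$removed_mean_cpc,
      retained_mean_cpc = filt_stats$retained_mean_cpc,
      metabolic_fraction_pct = met_pct,
      non_metabolic_fraction_pct = 100 - met_pct,
      n_pathways = nrow(pf$summary),
      n_pathways_undetected = sum(!pf$summary$detected),
      top_pathway = pf$summary$pathway_id[1],
      top_pathway_median_pct = pf$summary$median_pct[1])
  }

  ## ---- glycolysis profile -------------------------------------------
  if ("glycolysis" %in% stages) {
    cp <- if (is.null(cfg$inputs$core_pathway)) glycolysis_core()
          else read_core_pathway(cfg$inputs$core_pathway)
    log_stage("glycolysis", "profiling ", nrow(cp), " steps")
    prof <- sequential_profile(cp, mf)
    write_tsv(prof, p("sequential_profile.tsv"))
    bvc <- branch_vs_core_comparison(cp, mf)
    write_tsv(bvc, p("branch_vs_core.tsv"))
    nt <- node_size_table(cp, mf)
    write_tsv(nt$nodes, p("nodes.tsv"))
    write_tsv(nt$edges, p("edges.tsv"))
    steps <- prof[prof$level == "step" & prof$present, ]
    summary$glycolysis <- list(
      n_steps = nrow(cp),
      n_steps_measured = nrow(steps),
      peak_step = if (nrow(steps)) steps$step_index[which.max(steps$mean_cpc)]
                  else NA)
  }

  ## ---- branch points ------------------------------------------------
  net <- NULL
  if (any(c("branch", "cofactor", "kinetics") %in% stages))
    net <- read_reaction_network(cfg$inputs$stoichiometry,
                                 cfg$inputs$reaction_meta)
  if ("branch" %in% stages) {
    raw <- extract_branch_points(net, cfg$currency_metabolites,
                                 cfg$reversible_both_sides)
    kept <- dedupe_and_filter(raw, net, mf)
    scored <- score_branches(kept, net, mf, reaction_cpc = cfg$reaction_cpc,
                             absent = cfg$absent_mean,
                             one_sided_min = cfg$bd_one_sided_min,
                             equal_max = cfg$bd_equal_max)
    log_stage("branch", nrow(raw), " raw branch points, ", nrow(scored),
              " scored")
    write_tsv(scored, p("branches.tsv"))
    write_tsv(bd_histogram(scored, "top2"), p("bd_hist_top2.tsv"))
    write_tsv(bd_histogram(scored, "top3"), p("bd_hist_top3.tsv"))
    tally <- table(factor(scored$class,
                          c("one_sided", "equally_distributed",
                            "unclassified")))
    enr <- tryCatch(
      pathway_enrichment(scored, net, alpha = cfg$enrichment_alpha,
                         adjust = cfg$enrichment_adjust),
      cpcnet_undefined_test = function(e) NULL)
    if (!is.null(enr)) write_tsv(enr, p("enrichment.tsv"))
    summary$branch <- list(
      n_raw = nrow(raw), n_scored = nrow(scored),
      n_with_three_routes = sum(scored$n_routes >= 3),
      class_counts = as.list(tally),
      n_enriched_pathways = if (is.null(enr)) NA else sum(enr$significant))
  }

  ## ---- cofactors ----------------------------------------------------
  if ("cofactor" %in% stages) {
    redox <- classify_redox(net, mf,
                            collapse_compartments = cfg$collapse_compartments)
    amino <- classify_aminotransferases(
      net, mf, collapse_compartments = cfg$collapse_compartments)
    log_stage("cofactor", nrow(redox), " redox, ", nrow(amino),
              " aminotransferase classifications")
    write_tsv(redox, p("redox_ranking.tsv"))
    write_tsv(amino, p("aminotransferase_ranking.tsv"))
    ct <- cofactor_usage_table(rbind(redox, amino))
    write_tsv(ct$nodes, p("cofactor_nodes.tsv"))
    write_tsv(ct$edges, p("cofactor_edges.tsv"))
    summary$cofactor <- list(
      n_nad_linked = sum(redox$class == "NAD_linked"),
      n_nadp_linked = sum(redox$class == "NADP_linked"),
      n_aminotransferase = nrow(amino),
      top_redox_enzyme = if (nrow(redox)) redox$enzyme_id[1] else NA,
      top_aminotransferase = if (nrow(amino)) amino$enzyme_id[1] else NA)
  }

  ## ---- kinetics -----------------------------------------------------
  if ("kinetics" %in% stages) {
    km_raw <- read_tsv(cfg$inputs$km)
    thermo <- read_tsv(cfg$inputs$thermo)
    filt <- filter_km(km_raw)
    agg <- aggregate_km(filt$records, method = cfg$km_aggregate)
    jc <- join_and_correlate(agg, thermo, mf, net)
    grouped <- assign_groups(jc$joined, t_km = cfg$t_km, t_dg = cfg$t_dg,
                             t_cpc = cfg$t_cpc)
    log_stage("kinetics", nrow(grouped), " enzymes with CPC, K_M and dG0")
    write_tsv(grouped, p("kinetics_joined.tsv"))
    write_tsv(jc$correlations, p("correlations.tsv"))
    summary$kinetics <- list(
      n_km_records_in = nrow(km_raw),
      n_km_records_kept = nrow(filt$records),
      n_enzymes_dropped = length(filt$dropped_enzymes),
      n_joined = nrow(grouped),
      group_counts = as.list(table(factor(grouped$group, 1:4))),
      correlations = stats::setNames(
        as.list(jc$correlations$pearson_r), jc$correlations$pair))
  }

  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
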