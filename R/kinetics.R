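# Integration of enzyme abundance with Michaelis constants and standard
# reaction Gibbs energies: wild-type and outlier filtering of K_M
# measurements, per-enzyme aggregation, correlation of the three
# variables, unit scaling and a reproducible four-group partition.

#' Filter K_M measurements (wild-type, then outliers)
#'
#' Drops every record not flagged wild-type (e.g. mutant-enzyme assays),
#' then removes per-enzyme outliers: log10 K_M values outside
#' `[Q1 - 1.5*IQR, Q3 + 1.5*IQR]` of that enzyme's log10 values. Robust on
#' the log scale because K_M scatter across experiments is multiplicative.
#' Enzymes left with no surviving record are reported, not silently lost.
#'
#' @param km data frame with columns `enzyme_id`, `km_value` (> 0,
#'   concentration units), `wildtype` (0/1 or logical).
#' @return list: `records` (surviving rows), `dropped_enzymes` (ids whose
#'   records were all removed).
#' @export
filter_km <- function(km) {
  if (any(km$km_value <= 0, na.rm = TRUE))
    stop_cpcnet("K_M values must be > 0", class = "cpcnet_config_error")
  all_ids <- unique(km$enzyme_id)
  wt <- km[as.logical(as.integer(km$wildtype)), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(wt)), wt$enzyme_id), function(idx) {
    lg <- log10(wt$km_value[idx])
    q <- stats::quantile(lg, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    idx[lg >= q[1] - 1.5 * iqr & lg <= q[2] + 1.5 * iqr]
  }), use.names = FALSE)
  rec <- wt[sort(keep), , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec,
       dropped_enzymes = setdiff(all_ids, unique(rec$enzyme_id)))
}

#' Aggregate K_M measurements per enzyme
#'
#' One K_M per enzyme as the geometric mean of the filtered replicate
#' values (arithmetic mean behind `method = "arithmetic"`), with the
#' number of contributing measurements.
#'
#' @param records filtered records (`$records` of [filter_km()]).
#' @param method `"geometric"` (default) or `"arithmetic"`.
#' @return data frame: `enzyme_id`, `km`, `n_measurements`.
#' @export
aggregate_km <- function(records, method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  agg <- if (method == "geometric") geomean else mean
  sp <- split(records$km_value, records$enzyme_id)
  out <- data.frame(enzyme_id = names(sp),
                    km = vapply(sp, agg, numeric(1)),
                    n_measurements = lengths(sp),
                    stringsAsFactors = FALSE)
  out <- out[order(out$enzyme_id), ]
  rownames(out) <- NULL
  out
}

#' Join abundance, K_M and reaction energy; correlate all pairs
#'
#' Inner-joins enzymes that have all three variables — mean CPC, an
#' aggregated K_M, and the standard Gibbs energy of a mapped reaction —
#' and reports Pearson and Spearman coefficients (with p-values and n)
#' for the three pairs on the analysis scales: log10(CPC), log10(K_M),
#' dG0 linear. An enzyme catalyzing several reactions takes the dG0 of
#' its primary (lexicographically first) reaction by default;
#' `expand_reactions = TRUE` keeps one row per enzyme-reaction pair.
#'
#' @param km_agg output of [aggregate_km()].
#' @param thermo data frame with columns `reaction_id`, `dg0` (kJ/mol).
#' @param m a [cpc_matrix()].
#' @param net a [reaction_network()] supplying the enzyme-to-reaction map.
#' @param expand_reactions keep all enzyme-reaction pairs (default FALSE).
#' @return list: `joined` (enzyme, reaction_id, mean_cpc, km, dg0,
#'   log10_cpc, log10_km), `correlations` (pair, pearson_r, pearson_p,
#'   spearman_rho, spearman_p, n).
#' @export
join_and_correlate <- function(km_agg, thermo, m, net,
                               expand_reactions = FALSE) {
  names(thermo)[1:2] <- c("reaction_id", "dg0")
  e2r <- net$enzymes[order(net$enzymes$enzyme_id, net$enzymes$reaction_id), ]
  if (!expand_reactions) e2r <- e2r[!duplicated(e2r$enzyme_id), ]
  j <- merge(km_agg, e2r, by = "enzyme_id")
  j <- merge(j, thermo, by = "reaction_id")
  means <- mean_cpc(m)
  j$mean_cpc <- means[j$enzyme_id]
  j <- j[!is.na(j$mean_cpc) & j$mean_cpc > 0 & !is.na(j$dg0), , drop = FALSE]
  if (nrow(j) < 3)
    stop_cpcnet("fewer than 3 enzymes with all of CPC, K_M and dG0",
                class = "cpcnet_undefined_correlation")
  j$log10_cpc <- log10(j$mean_cpc)
  j$log10_km <- log10(j$km)
  j <- j[order(j$enzyme_id, j$reaction_id),
         c("enzyme_id", "reaction_id", "mean_cpc", "km", "dg0",
           "log10_cpc", "log10_km")]
  rownames(j) <- NULL
  pairs <- list(cpc_vs_km = c("log10_cpc", "log10_km"),
                cpc_vs_dg0 = c("log10_cpc", "dg0"),
                km_vs_dg0 = c("log10_km", "dg0"))
  cors <- do.call(rbind, lapply(names(pairs), function(nm) {
    x <- j[[pairs[[nm]][1]]]; y <- j[[pairs[[nm]][2]]]
    pe <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    data.frame(pair = nm, pearson_r = unname(pe$estimate),
               pearson_p = pe$p.value,
               spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
               n = length(x), stringsAsFactors = FALSE)
  }))
  list(joined = j, correlations = cors)
}

#' Min-max scale a variable to [0, 1]
#'
#' Linear min-max scaling, optionally after a log10 transform (used for
#' CPC and K_M, which span orders of magnitude; dG0 is scaled on its
#' linear scale). Strictly order-preserving, and idempotent on already
#' scaled values.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param log10_first transform before scaling (default FALSE).
#' @return vector in `[0, 1]` with min at 0 and max at 1.
#' @export
scale_unit <- function(values, log10_first = FALSE) {
  if (log10_first) {
    if (any(values <= 0)) stop_cpcnet("log scaling requires positive values",
                                      class = "cpcnet_undefined_scaling")
    values <- log10(values)
  }
  rng <- range(values)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop_cpcnet("cannot min-max scale a constant variable",
                class = "cpcnet_undefined_scaling")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Assign the four-group kinetic partition
#'
#' Reproducible rule-based version of an otherwise manual visual
#' grouping of enzymes by scaled abundance, K_M and dG0. In priority
#' order: group 3 = extreme Michaelis constant (`scaled_km >= t_km`,
#' substrate must pile up before the reaction runs); group 4 = extreme
#' thermodynamic drive (`scaled_dg0 <= t_dg`, effectively irreversible);
#' group 2 = highly expressed with neither extreme (`scaled_cpc >=
#' t_cpc`, the glycolysis-like regime); group 1 = everything else
#' (moderate in all three variables). The assignment is exhaustive and
#' mutually exclusive.
#'
#' @param joined the `joined` table of [join_and_correlate()].
#' @param t_km,t_dg,t_cpc thresholds on the scaled variables (defaults
#'   0.9, 0.1, 0.9).
#' @return `joined` with `scaled_cpc`, `scaled_km`, `scaled_dg0` and
#'   integer `group` columns added.
#' @export
assign_groups <- function(joined, t_km = 0.9, t_dg = 0.1, t_cpc = 0.9) {
  joined$scaled_cpc <- scale_unit(joined$mean_cpc, log10_first = TRUE)
  joined$scaled_km <- scale_unit(joined$km, log10_first = TRUE)
  joined$scaled_dg0 <- scale_unit(joined$dg0)
  joined$group <- kinetic_group(joined$scaled_cpc, joined$scaled_km,
                                joined$scaled_dg0, t_km, t_dg, t_cpc)
  joined
}

#' Four-group rule on scaled kinetic triples
#'
#' The bare grouping rule of [assign_groups()], vectorized over scaled
#' `(cpc, km, dg0)` triples in `[0, 1]`.
#'
#' @param scaled_cpc,scaled_km,scaled_dg0 scaled values in `[0, 1]`.
#' @inheritParams assign_groups
#' @return integer vector of groups in `1:4`.
#' @export
kinetic_group <- function(scaled_cpc, scaled_km, scaled_dg0,
                          t_km = 0.9, t_dg = 0.1, t_cpc = 0.9) {
  ifelse(scaled_km >= t_km, 3L,
  ifelse(scaled_dg0 <= t_dg, 4L,
  ifelse(scaled_cpc >= t_cpc, 2L, 1L)))
}
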