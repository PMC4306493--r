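# Proteome-level accounting: detection filter, metabolic / pathway
# abundance fractions, and log-binned abundance distributions.

#' Remove proteins detected in only one sample or tissue
#'
#' A protein is kept only if its detected entries (present and > 0) span
#' at least two cell lines AND at least two distinct tissues. Proteins
#' detected nowhere, in a single cell line, or only within one tissue of
#' origin are removed. The filter is idempotent.
#'
#' @param m a [cpc_matrix()].
#' @return list with elements `matrix` (the filtered [cpc_matrix()]) and
#'   `removed` (character vector of removed protein ids).
#' @export
filter_rare_proteins <- function(m) {
  det <- detected(m)
  n_lines <- rowSums(det)
  n_tissues <- apply(det, 1, function(d) length(unique(m$tissue[d])))
  drop <- n_lines <= 1 | n_tissues <= 1
  kept <- m$cpc[!drop, , drop = FALSE]
  list(matrix = cpc_matrix(kept, tissue_of(m)),
       removed = rownames(m$cpc)[drop])
}

#' Mean CPC per protein across cell lines
#'
#' The per-protein average used throughout the pipeline. By default absent
#' entries count as zero (the mean is taken over all cell lines), so
#' proteins detected in few lines are not inflated; set
#' `absent = "exclude"` to average over detecting lines only.
#'
#' @param m a [cpc_matrix()].
#' @param absent `"zero"` (default) or `"exclude"`.
#' @return named numeric vector of mean CPC per protein.
#' @export
mean_cpc <- function(m, absent = c("zero", "exclude")) {
  absent <- match.arg(absent)
  v <- m$cpc
  if (absent == "zero") {
    v[is.na(v)] <- 0
    rowMeans(v)
  } else {
    out <- rowMeans(v, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    out
  }
}

#' Detection-filter summary statistic
#'
#' Applies [filter_rare_proteins()] and reports the mean CPC (average of
#' per-protein mean CPC, absent entries excluded from each protein's mean)
#' of the removed proteins and of the retained remainder — the headline
#' contrast between rarely-detected and reliably-detected proteins.
#'
#' @param m an unfiltered [cpc_matrix()].
#' @return list with `removed_mean_cpc`, `retained_mean_cpc`, `n_removed`,
#'   `n_retained`.
#' @export
filter_cpc_summary <- function(m) {
  flt <- filter_rare_proteins(m)
  means <- mean_cpc(m, absent = "exclude")
  removed <- means[flt$removed]
  retained <- means[rownames(flt$matrix$cpc)]
  list(removed_mean_cpc = mean(removed, na.rm = TRUE),
       retained_mean_cpc = mean(retained, na.rm = TRUE),
       n_removed = length(flt$removed),
       n_retained = nrow(flt$matrix$cpc))
}

#' Metabolic percentage of the proteome
#'
#' Share of total protein mass held by metabolic proteins (those with at
#' least one pathway membership):
#' `100 * sum(mean CPC of metabolic proteins) / sum(mean CPC of all
#' proteins)`, with per-protein means from [mean_cpc()]. The metabolic and
#' non-metabolic percentages sum to 100 exactly.
#'
#' @param m a filtered [cpc_matrix()].
#' @param pathway_map data frame as from [read_pathway_map()].
#' @param absent passed to [mean_cpc()].
#' @return percentage in `[0, 100]`.
#' @export
metabolic_fraction <- function(m, pathway_map, absent = "zero") {
  if (nrow(m$cpc) == 0)
    stop_cpcnet("empty CPC matrix", class = "cpcnet_undefined_input")
  means <- mean_cpc(m, absent = absent)
  is_met <- rownames(m$cpc) %in% metabolic_proteins(pathway_map)
  100 * sum(means[is_met]) / sum(means)
}

#' Per-pathway proteome percentages across cell lines
#'
#' For every pathway and cell line, the percentage of that cell line's
#' total CPC (detected entries) carried by the pathway's proteins. A
#' protein belonging to several pathways counts fully in each, so the
#' percentages need not sum to 100. Pathways none of whose proteins are in
#' the matrix are retained and flagged (`detected = FALSE`), never
#' silently dropped.
#'
#' @param m a filtered [cpc_matrix()].
#' @param pathway_map data frame of (`pathway_id`, `protein_id`) pairs.
#' @param denominator `"total"` (default: the cell line's whole proteome
#'   CPC) or `"metabolic"` (CPC of pathway-mapped proteins only).
#' @return list with `per_cell_line` (pathway x cell line percentage
#'   matrix) and `summary` (data frame: pathway, detected flag, n
#'   proteins, median/mean/sd/min/max percentage across cell lines,
#'   ordered by median descending).
#' @export
pathway_fractions <- function(m, pathway_map,
                              denominator = c("total", "metabolic")) {
  denominator <- match.arg(denominator)
  v <- m$cpc
  v[is.na(v)] <- 0
  denom <- if (denominator == "total") colSums(v) else
    colSums(v[rownames(v) %in% metabolic_proteins(pathway_map), , drop = FALSE])
  pathways <- sort(unique(pathway_map$pathway_id))
  pct <- matrix(NA_real_, length(pathways), ncol(v),
                dimnames = list(pathways, colnames(v)))
  n_prot <- integer(length(pathways))
  for (i in seq_along(pathways)) {
    prots <- pathway_map$protein_id[pathway_map$pathway_id == pathways[i]]
    prots <- intersect(prots, rownames(v))
    n_prot[i] <- length(prots)
    pct[i, ] <- if (length(prots))
      100 * colSums(v[prots, , drop = FALSE]) / denom else 0
  }
  has_detection <- n_prot > 0 &
    apply(pct, 1, function(p) any(p > 0))
  summ <- data.frame(
    pathway_id = pathways,
    detected = has_detection,
    n_proteins = n_prot,
    median_pct = apply(pct, 1, stats::median),
    mean_pct = rowMeans(pct),
    sd_pct = apply(pct, 1, stats::sd),
    min_pct = apply(pct, 1, min),
    max_pct = apply(pct, 1, max),
    stringsAsFactors = FALSE)
  summ <- summ[order(-summ$median_pct, summ$pathway_id), ]
  rownames(summ) <- NULL
  list(per_cell_line = pct, summary = summ)
}

#' Log-binned relative-frequency distribution
#'
#' Bins strictly positive CPC values into logarithmic bins
#' `[10^(k*w), 10^((k+1)*w))` anchored at `10^0`, where `w` is the bin
#' width exponent (`w = 0.3` for a bin difference of `10^0.3`), and
#' returns the relative frequency per bin. Frequencies sum to one.
#'
#' @param values positive numeric vector (zeros/absent must be excluded
#'   upstream).
#' @param width_exponent positive bin width on the log10 scale.
#' @return data frame with `bin_lo`, `bin_hi`, `bin_center` (geometric
#'   midpoint), `count`, `frequency`.
#' @export
log_binned_pdf <- function(values, width_exponent = 0.3) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop_cpcnet("no values to bin", class = "cpcnet_undefined_input")
  if (any(values <= 0))
    stop_cpcnet("log binning requires strictly positive values",
                class = "cpcnet_undefined_input")
  if (!is.finite(width_exponent) || width_exponent <= 0)
    stop_cpcnet("width_exponent must be > 0", class = "cpcnet_config_error")
  # Guard against values sitting exactly on an edge being pushed down a
  # bin by floating-point log error.
  k <- floor(log10(values) / width_exponent + 1e-9)
  kr <- seq(min(k), max(k))
  counts <- tabulate(k - min(k) + 1L, nbins = length(kr))
  data.frame(bin_lo = 10^(kr * width_exponent),
             bin_hi = 10^((kr + 1) * width_exponent),
             bin_center = 10^((kr + 0.5) * width_exponent),
             count = counts,
             frequency = counts / length(values))
}
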