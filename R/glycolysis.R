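# Sequential profiling of a core pathway (glucose -> lactate by default)
# and comparison of core enzymes with branch-point enzymes that compete
# for the same substrate.

#' Read a core-pathway definition
#'
#' A core pathway is an ordered list of steps, each converting a substrate
#' into the next step's substrate and naming the core enzyme(s) catalyzing
#' it plus any branch enzymes that divert the same substrate elsewhere.
#' Enzyme fields are ";"-separated. The packaged glucose-to-lactate
#' glycolysis definition (11 steps, with branch enzymes such as PHGDH at
#' 3-phosphoglycerate) is an editable best-effort reconstruction of the
#' canonical pathway; see [glycolysis_core()].
#'
#' @param path TSV with columns `step_index`, `substrate`, `product`,
#'   `core_enzymes`, `branch_enzymes`.
#' @return an object of class `core_pathway` (a data frame).
#' @export
read_core_pathway <- function(path) {
  df <- read_tsv(path)
  df <- df[order(df$step_index), , drop = FALSE]
  df$core_enzymes <- as.character(df$core_enzymes)
  df$branch_enzymes <- as.character(df$branch_enzymes)
  if (nrow(df) > 1 &&
      !all(df$product[-nrow(df)] == df$substrate[-1]))
    stop_cpcnet("core pathway is not a chain: each step's product must be ",
                "the next step's substrate", class = "cpcnet_format_error")
  if (any(!nzchar(df$core_enzymes) | is.na(df$core_enzymes)))
    stop_cpcnet("every step needs >= 1 core enzyme", class = "cpcnet_format_error")
  rownames(df) <- NULL
  structure(df, class = c("core_pathway", "data.frame"))
}

#' The packaged core glycolysis definition
#'
#' @return a `core_pathway` for the glucose-to-lactate chain.
#' @export
glycolysis_core <- function() {
  read_core_pathway(system.file("extdata", "glycolysis_core.tsv",
                                package = "cpcnet", mustWork = TRUE))
}

# Per-cell-line abundance of a step: sum of its enzymes' CPC (absent = 0).
step_cpc <- function(enzymes, m) {
  present <- intersect(enzymes, rownames(m$cpc))
  if (length(present) == 0) return(rep(NA_real_, ncol(m$cpc)))
  v <- m$cpc[present, , drop = FALSE]
  v[is.na(v)] <- 0
  colSums(v)
}

#' Sequential abundance profile along a core pathway
#'
#' Mean, min and max CPC across cell lines for every step, in pathway
#' order. The step statistic sums isoenzyme CPCs; per-isoenzyme rows are
#' also emitted (`level = "enzyme"`). Enzymes absent from the matrix are
#' reported as missing rows rather than dropped; ordering is purely the
#' pathway's, never abundance-driven.
#'
#' @param cp a `core_pathway`.
#' @param m a [cpc_matrix()].
#' @return data frame: `step_index`, `substrate`, `product`, `level`
#'   (`"step"` or `"enzyme"`), `enzyme` (the step's enzymes or one
#'   enzyme), `present`, `mean_cpc`, `min_cpc`, `max_cpc`.
#' @export
sequential_profile <- function(cp, m) {
  rows <- list()
  for (i in seq_len(nrow(cp))) {
    core <- split_ids(cp$core_enzymes[i])
    stat_row <- function(level, label, ids) {
      x <- step_cpc(ids, m)
      data.frame(step_index = cp$step_index[i], substrate = cp$substrate[i],
                 product = cp$product[i], level = level, enzyme = label,
                 present = any(ids %in% rownames(m$cpc)),
                 mean_cpc = mean(x), min_cpc = suppressWarnings(min(x)),
                 max_cpc = suppressWarnings(max(x)),
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <-
      stat_row("step", paste(core, collapse = ";"), core)
    for (e in core)
      rows[[length(rows) + 1L]] <- stat_row("enzyme", e, e)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Branch-point versus core enzyme comparison along a pathway
#'
#' For every step that has branch enzymes, compares the abundance diverted
#' off the pathway with the abundance continuing along it: the ratio of
#' branch to core mean CPC, and the exceedance count — the number of cell
#' lines in which the branch enzymes' CPC is at least the core enzymes'
#' CPC (how often the diversion is comparable to or higher than the main
#' route). A core mean of zero leaves the ratio undefined (`NA`,
#' `ratio_defined = FALSE`).
#'
#' @param cp a `core_pathway`.
#' @param m a [cpc_matrix()].
#' @return data frame: `step_index`, `substrate`, `core_enzymes`,
#'   `branch_enzymes`, `core_mean_cpc`, `branch_mean_cpc`, `ratio`,
#'   `ratio_defined`, `exceedance`, `n_cell_lines`.
#' @export
branch_vs_core_comparison <- function(cp, m) {
  has_branch <- !is.na(cp$branch_enzymes) & nzchar(cp$branch_enzymes)
  rows <- lapply(which(has_branch), function(i) {
    core <- step_cpc(split_ids(cp$core_enzymes[i]), m)
    branch <- split_ids(cp$branch_enzymes[i])
    br <- step_cpc(branch, m)
    if (all(is.na(br))) br <- rep(0, ncol(m$cpc))  # branch absent everywhere
    cm <- mean(core); bm <- mean(br)
    data.frame(step_index = cp$step_index[i], substrate = cp$substrate[i],
               core_enzymes = cp$core_enzymes[i],
               branch_enzymes = cp$branch_enzymes[i],
               core_mean_cpc = cm, branch_mean_cpc = bm,
               ratio = if (isTRUE(cm > 0)) bm / cm else NA_real_,
               ratio_defined = isTRUE(cm > 0),
               exceedance = sum(br >= core),
               n_cell_lines = ncol(m$cpc),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(step_index = integer(0), substrate = character(0),
                      core_enzymes = character(0), branch_enzymes = character(0),
                      core_mean_cpc = numeric(0), branch_mean_cpc = numeric(0),
                      ratio = numeric(0), ratio_defined = logical(0),
                      exceedance = integer(0), n_cell_lines = integer(0))
  rownames(out) <- NULL
  out
}

#' Node/edge attribute tables for a core-pathway diagram
#'
#' Exports the pathway as renderer-agnostic node and edge tables: one node
#' per metabolite (`type = "metabolite"`), per core enzyme
#' (`type = "enzyme"`) and per branch enzyme (`type = "branch"`), each
#' enzyme node carrying its mean CPC and a size attribute linear in mean
#' CPC (scaled so the largest enzyme node has size 100); edges run
#' substrate -> enzyme -> product and substrate -> branch enzyme.
#'
#' @param cp a `core_pathway`.
#' @param m a [cpc_matrix()].
#' @return list of data frames `nodes` (`id`, `type`, `mean_cpc`, `size`)
#'   and `edges` (`source`, `target`).
#' @export
node_size_table <- function(cp, m) {
  means <- mean_cpc(m)
  nodes <- list(); edges <- list()
  add_node <- function(id, type) {
    mc <- if (type == "metabolite") NA_real_ else
      if (id %in% names(means)) unname(means[id]) else 0
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = id, type = type, mean_cpc = mc, stringsAsFactors = FALSE)
  }
  add_edge <- function(s, t)
    edges[[length(edges) + 1L]] <<- data.frame(source = s, target = t,
                                               stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cp))) {
    add_node(cp$substrate[i], "metabolite")
    if (i == nrow(cp)) add_node(cp$product[i], "metabolite")
    for (e in split_ids(cp$core_enzymes[i])) {
      add_node(e, "enzyme")
      add_edge(cp$substrate[i], e)
      add_edge(e, cp$product[i])
    }
    for (b in split_ids(cp$branch_enzymes[i])) {
      add_node(b, "branch")
      add_edge(cp$substrate[i], b)
    }
  }
  nodes <- unique(do.call(rbind, nodes))
  top <- max(nodes$mean_cpc, na.rm = TRUE)
  nodes$size <- ifelse(is.na(nodes$mean_cpc), NA_real_,
                       if (top > 0) 100 * nodes$mean_cpc / top else 0)
  edges <- unique(do.call(rbind, edges))
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
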