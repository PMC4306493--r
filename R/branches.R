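# Branch-point extraction and branch-divergence (BD) scoring.
#
# A branch point is a metabolite consumed as a reactant by two or more
# distinct reactions. Ranking the competing enzymes by mean CPC
# (descending), the top-2 BD score (C1 - C2)/C1 and, where at least three
# routes exist, the top-3 score (C1 - C2 - C3)/C1 measure how strongly
# abundance is concentrated on one outgoing route.

#' Enumerate branch points in a reaction network
#'
#' Finds every metabolite that is a reactant (negative stoichiometric
#' coefficient) of at least two distinct reactions. For reversible
#' reactions only the declared reactant side counts by default; set
#' `reversible_both_sides = TRUE` to treat products of reversible
#' reactions as potential reactants too. Metabolites on
#' `exclude_metabolites` (e.g. a currency-metabolite list) are removed
#' before enumeration.
#'
#' @param net a [reaction_network()].
#' @param exclude_metabolites character vector of metabolite ids to skip.
#' @param reversible_both_sides logical.
#' @return data frame with `metabolite_id` and `reactions`
#'   (";"-separated consuming reaction ids, sorted), one row per branch.
#' @export
extract_branch_points <- function(net, exclude_metabolites = character(0),
                                  reversible_both_sides = FALSE) {
  st <- net$stoichiometry
  consumed <- st[st$coefficient < 0, c("reaction_id", "metabolite_id")]
  if (reversible_both_sides) {
    rev_ids <- net$reactions$reaction_id[net$reactions$reversible]
    back <- st[st$coefficient > 0 & st$reaction_id %in% rev_ids,
               c("reaction_id", "metabolite_id")]
    consumed <- unique(rbind(consumed, back))
  }
  consumed <- consumed[!(consumed$metabolite_id %in% exclude_metabolites), ]
  sets <- lapply(split(consumed$reaction_id, consumed$metabolite_id),
                 function(r) sort(unique(r)))
  sets <- sets[lengths(sets) >= 2]
  data.frame(metabolite_id = names(sets),
             reactions = vapply(sets, paste, "", collapse = ";"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Deduplicate branches and keep only fully measured ones
#'
#' Branches whose consuming-reaction sets are identical are collapsed to a
#' single record (the lexicographically first metabolite id is kept, the
#' others listed in `aliases`). A branch is then retained only if every
#' consuming reaction has at least one mapped enzyme and all of its mapped
#' enzymes are rows of the (filtered) CPC matrix.
#'
#' @param branches output of [extract_branch_points()].
#' @param net the [reaction_network()].
#' @param m the filtered [cpc_matrix()].
#' @return `branches` subset with an `aliases` column added.
#' @export
dedupe_and_filter <- function(branches, net, m) {
  if (nrow(branches) == 0) {
    branches$aliases <- character(0)
    return(branches)
  }
  branches <- branches[order(branches$metabolite_id), , drop = FALSE]
  first <- !duplicated(branches$reactions)
  alias <- vapply(branches$reactions[first], function(r) {
    others <- branches$metabolite_id[branches$reactions == r]
    paste(others[-1], collapse = ";")
  }, "")
  out <- branches[first, , drop = FALSE]
  out$aliases <- unname(alias)
  enz <- reaction_enzymes(net)
  measured <- rownames(m$cpc)
  keep <- vapply(out$reactions, function(r) {
    rids <- split_ids(r)
    all(rids %in% names(enz)) &&
      all(unlist(enz[rids]) %in% measured)
  }, logical(1))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-2 branch divergence score
#'
#' `(C1 - C2) / C1` over mean abundances ranked descending; 0 when the two
#' leading routes are equally expressed, approaching 1 when one route
#' dominates. Always in `[0, 1]`.
#'
#' @param cpc_ranked numeric vector of mean CPC values sorted descending
#'   (length >= 2).
#' @return score in `[0, 1]`.
#' @export
bd_top2 <- function(cpc_ranked) {
  if (length(cpc_ranked) < 2)
    stop_cpcnet("top-2 score needs >= 2 enzymes", class = "cpcnet_undefined_score")
  if (cpc_ranked[1] <= 0)
    stop_cpcnet("top-ranked abundance must be > 0", class = "cpcnet_undefined_score")
  unname((cpc_ranked[1] - cpc_ranked[2]) / cpc_ranked[1])
}

#' Top-3 branch divergence score
#'
#' `(C1 - C2 - C3) / C1` over mean abundances ranked descending; defined
#' for branches with at least three routes. May be negative (down to -1
#' when all three are equal); never exceeds the top-2 score.
#'
#' @param cpc_ranked numeric vector of mean CPC values sorted descending
#'   (length >= 3).
#' @return score in `[-1, 1]`.
#' @export
bd_top3 <- function(cpc_ranked) {
  if (length(cpc_ranked) < 3)
    stop_cpcnet("top-3 score needs >= 3 enzymes", class = "cpcnet_undefined_score")
  if (cpc_ranked[1] <= 0)
    stop_cpcnet("top-ranked abundance must be > 0", class = "cpcnet_undefined_score")
  unname((cpc_ranked[1] - cpc_ranked[2] - cpc_ranked[3]) / cpc_ranked[1])
}

#' Classify a branch from its BD scores
#'
#' `one_sided` when the top-2 score strictly exceeds `one_sided_min`
#' (default 0.8); `equally_distributed` when the top-2 score is strictly
#' below `equal_max` (default 0.2) or the top-3 score is strictly
#' negative; otherwise `unclassified`. Scores exactly on a threshold stay
#' unclassified.
#'
#' @param bd2 top-2 score.
#' @param bd3 top-3 score or `NA` for two-route branches.
#' @param one_sided_min,equal_max thresholds.
#' @return one of `"one_sided"`, `"equally_distributed"`, `"unclassified"`.
#' @export
classify_branch <- function(bd2, bd3 = NA_real_,
                            one_sided_min = 0.8, equal_max = 0.2) {
  if (bd2 > one_sided_min) return("one_sided")
  if (bd2 < equal_max || (!is.na(bd3) && bd3 < 0)) return("equally_distributed")
  "unclassified"
}

#' Score and classify branch points against a CPC matrix
#'
#' For each branch, each consuming reaction's abundance is the sum
#' (default; `reaction_cpc = "max"` for the maximum) of its mapped
#' enzymes' mean CPC; reactions are ranked by that abundance descending
#' with ties broken by lexicographic order of their lead enzyme id, and
#' the BD scores and class are computed. Rows where the top abundance is
#' zero are dropped with a warning (the score is undefined there).
#'
#' @param branches output of [dedupe_and_filter()].
#' @param net the [reaction_network()].
#' @param m the filtered [cpc_matrix()].
#' @param reaction_cpc `"sum"` or `"max"` over isoenzymes.
#' @param absent passed to [mean_cpc()].
#' @param one_sided_min,equal_max thresholds for [classify_branch()].
#' @return data frame: `metabolite_id`, `reactions` and `enzymes` (ranked,
#'   ";"-separated), `n_routes`, `bd2`, `bd3` (`NA` for two-route
#'   branches), `class`, and `score_used` (`"top2"`/`"top3"`, the score
#'   that settled the class — needed when picking contributing enzymes for
#'   enrichment).
#' @export
score_branches <- function(branches, net, m, reaction_cpc = c("sum", "max"),
                           absent = "zero",
                           one_sided_min = 0.8, equal_max = 0.2) {
  reaction_cpc <- match.arg(reaction_cpc)
  agg <- if (reaction_cpc == "sum") sum else max
  means <- mean_cpc(m, absent = absent)
  enz <- reaction_enzymes(net)
  res <- lapply(seq_len(nrow(branches)), function(i) {
    rids <- split_ids(branches$reactions[i])
    abund <- vapply(rids, function(r) agg(means[enz[[r]]]), numeric(1))
    lead_enz <- vapply(rids, function(r) min(enz[[r]]), "")
    ord <- order(-abund, lead_enz)
    abund <- abund[ord]; rids <- rids[ord]
    if (abund[1] <= 0) return(NULL)
    bd2 <- bd_top2(abund)
    bd3 <- if (length(abund) >= 3) bd_top3(abund) else NA_real_
    cls <- classify_branch(bd2, bd3, one_sided_min, equal_max)
    # Record which score settled the class: the top-3 score only decides
    # when the top-2 score alone would not have (bd2 in [equal_max, ...]).
    used <- if (cls == "equally_distributed" && bd2 >= equal_max &&
                !is.na(bd3) && bd3 < 0) "top3" else "top2"
    data.frame(metabolite_id = branches$metabolite_id[i],
               reactions = paste(rids, collapse = ";"),
               enzymes = paste(unlist(enz[rids]), collapse = ";"),
               n_routes = length(rids),
               bd2 = bd2, bd3 = bd3,
               class = cls, score_used = used,
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " branch(es) dropped: top-ranked abundance is zero")
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(metabolite_id = character(0), reactions = character(0),
                      enzymes = character(0), n_routes = integer(0),
                      bd2 = numeric(0), bd3 = numeric(0), class = character(0),
                      score_used = character(0))
  out
}

#' Histogram of BD scores
#'
#' Fixed-width bins of size 0.1, lower-end inclusive; the top-2 score is
#' binned over `[0, 1]` and the top-3 score over `[-1, 1]`, with the final
#' bin closed above so boundary scores of exactly 1 are counted.
#'
#' @param scored output of [score_branches()].
#' @param which `"top2"` or `"top3"`.
#' @param bin_width bin size (default 0.1).
#' @return data frame with `bin_lo`, `bin_hi`, `count`.
#' @export
bd_histogram <- function(scored, which = c("top2", "top3"), bin_width = 0.1) {
  which <- match.arg(which)
  if (which == "top2") {
    x <- scored$bd2
    lo <- 0
  } else {
    x <- scored$bd3[!is.na(scored$bd3)]
    lo <- -1
  }
  edges <- seq(lo, 1, by = bin_width)
  n_bins <- length(edges) - 1L
  idx <- pmin(floor((x - lo) / bin_width + 1e-9), n_bins - 1L) + 1L
  data.frame(bin_lo = edges[-length(edges)],
             bin_hi = edges[-1],
             count = tabulate(idx, nbins = n_bins))
}
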