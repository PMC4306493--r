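# Pathway enrichment between one-sided and equally-distributed branches.

#' Pathway enrichment of branch classes
#'
#' Compares which pathways the enzymes of one-sided branches fall into
#' versus those of equally-distributed branches. For each classified
#' branch the contributing enzymes are those of the top-2 ranked routes,
#' or the top-3 when the top-3 score settled the class; contributions are
#' counted as unique (branch, enzyme) pairs. Each enzyme's pathways come
#' from its reaction's pathway map. Per pathway a 2x2 table
#' (in-pathway vs not) x (one_sided vs equally_distributed) is tested with
#' a two-sided Fisher's exact test, and the count ratio
#' one_sided / equally_distributed is reported (infinite when the
#' equally-distributed count is zero, flagged in `ratio_defined`).
#'
#' @param scored output of [score_branches()].
#' @param net the [reaction_network()] (supplies reaction-to-enzyme and
#'   reaction-to-pathway maps).
#' @param alpha significance level for the `significant` flag (default
#'   0.05, on raw p-values).
#' @param adjust `"none"` (default) or `"BH"` to add
#'   Benjamini-Hochberg-adjusted p-values in `p_adj`.
#' @return data frame: `pathway_id`, `n_one_sided`, `n_equal`, `p_value`,
#'   `ratio`, `ratio_defined`, `significant`, ordered by p-value.
#' @export
pathway_enrichment <- function(scored, net, alpha = 0.05,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  enz <- reaction_enzymes(net)
  pw <- split(net$pathways$pathway_id, net$pathways$reaction_id)
  contrib <- function(rows) {
    out <- list()
    for (i in seq_len(nrow(rows))) {
      rids <- split_ids(rows$reactions[i])
      k <- if (rows$score_used[i] == "top3") 3L else 2L
      rids <- rids[seq_len(min(k, length(rids)))]
      for (r in rids) for (e in enz[[r]]) {
        out[[length(out) + 1L]] <- data.frame(
          branch = rows$metabolite_id[i], enzyme = e,
          pathway = if (is.null(pw[[r]])) NA_character_ else pw[[r]],
          stringsAsFactors = FALSE)
      }
    }
    unique(do.call(rbind, out))
  }
  ones <- scored[scored$class == "one_sided", , drop = FALSE]
  eqs <- scored[scored$class == "equally_distributed", , drop = FALSE]
  if (nrow(ones) == 0 || nrow(eqs) == 0)
    stop_cpcnet("both branch classes must be non-empty for enrichment",
                class = "cpcnet_undefined_test")
  co <- contrib(ones)
  ce <- contrib(eqs)
  n_one <- nrow(unique(co[, c("branch", "enzyme")]))
  n_eq <- nrow(unique(ce[, c("branch", "enzyme")]))
  pathways <- sort(unique(stats::na.omit(c(co$pathway, ce$pathway))))
  rows <- lapply(pathways, function(p) {
    a <- nrow(unique(co[!is.na(co$pathway) & co$pathway == p,
                        c("branch", "enzyme")]))
    b <- nrow(unique(ce[!is.na(ce$pathway) & ce$pathway == p,
                        c("branch", "enzyme")]))
    tab <- matrix(c(a, b, n_one - a, n_eq - b), nrow = 2)
    data.frame(pathway_id = p, n_one_sided = a, n_equal = b,
               p_value = stats::fisher.test(tab)$p.value,
               ratio = if (b == 0) Inf else a / b,
               ratio_defined = b > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$pathway_id), ]
  rownames(out) <- NULL
  out
}
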