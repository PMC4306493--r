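# Cofactor-usage classification: which enzymes touch the NAD(H)/NADP(H)
# redox pools, and which assimilate nitrogen through alpha-ketoglutarate,
# ranked by mean abundance.

#' Packaged cofactor synonym table
#'
#' Maps canonical cofactor metabolite ids (lower-cased) to their class:
#' NAD+/NADH to `NAD_linked`, NADP+/NADPH to `NADP_linked`, and
#' alpha-ketoglutarate synonyms to `aminotransferase`. Users may supply
#' their own table in the same two-column format.
#'
#' @param path optional custom synonyms TSV (`canonical_id`, `class`).
#' @return data frame with columns `canonical_id`, `class`.
#' @export
cofactor_synonyms <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cofactor_synonyms.tsv",
                                package = "cpcnet", mustWork = TRUE)
  df <- read_tsv(path)
  df$canonical_id <- tolower(df$canonical_id)
  if (anyDuplicated(df$canonical_id))
    stop_cpcnet("synonym table maps an id to more than one class",
                class = "cpcnet_config_error")
  df
}

# Collapse compartment tags: "nadh_c", "nadh[m]", "nadh(e)" -> "nadh".
strip_compartment <- function(ids) {
  tolower(sub("(_[a-z][a-z0-9]?|\\[[a-z][a-z0-9]?\\]|\\([a-z][a-z0-9]?\\))$",
              "", tolower(ids)))
}

cofactor_classify <- function(net, m, classes, synonyms = cofactor_synonyms(),
                              collapse_compartments = TRUE) {
  syn <- synonyms[synonyms$class %in% classes, , drop = FALSE]
  st <- net$stoichiometry
  met <- if (collapse_compartments) strip_compartment(st$metabolite_id) else
    tolower(st$metabolite_id)
  hit <- match(met, syn$canonical_id)
  if (all(is.na(hit))) {
    warning("no cofactor metabolite ids found in the network; ",
            "check the synonym table")
    return(data.frame(enzyme_id = character(0), class = character(0),
                      direction = character(0), mean_cpc = numeric(0),
                      rank = integer(0)))
  }
  st <- st[!is.na(hit), , drop = FALSE]
  st$class <- syn$class[hit[!is.na(hit)]]
  st$side <- ifelse(st$coefficient < 0, "reactant", "product")
  rec <- merge(st[, c("reaction_id", "class", "side")], net$enzymes,
               by = "reaction_id")
  if (nrow(rec) == 0)
    return(data.frame(enzyme_id = character(0), class = character(0),
                      direction = character(0), mean_cpc = numeric(0),
                      rank = integer(0)))
  means <- mean_cpc(m)
  agg <- lapply(split(rec, list(rec$enzyme_id, rec$class), drop = TRUE),
                function(g) {
                  sides <- unique(g$side)
                  data.frame(enzyme_id = g$enzyme_id[1], class = g$class[1],
                             direction = if (length(sides) == 2) "both" else sides,
                             mean_cpc = if (g$enzyme_id[1] %in% names(means))
                               unname(means[g$enzyme_id[1]]) else NA_real_,
                             stringsAsFactors = FALSE)
                })
  out <- do.call(rbind, agg)
  out <- out[order(-ifelse(is.na(out$mean_cpc), -Inf, out$mean_cpc),
                   out$enzyme_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify and rank redox (NAD(P)-linked) enzymes
#'
#' An enzyme is NAD-linked (resp. NADP-linked) if any reaction it
#' catalyzes has NAD+/NADH (resp. NADP+/NADPH) among its reactants or
#' products — both sides count, so reversible reactions are covered. The
#' direction annotation records which side(s) the cofactor sits on.
#' Classification is a pure network property; the ranking (mean CPC
#' descending) comes from the abundance matrix alone.
#'
#' @param net a [reaction_network()].
#' @param m a [cpc_matrix()].
#' @param synonyms synonym table, see [cofactor_synonyms()].
#' @param collapse_compartments collapse compartment-tagged metabolite ids
#'   (e.g. `nadh_c` vs `nadh_m`) into one pool (default TRUE).
#' @return data frame: `enzyme_id`, `class` (`NAD_linked` /
#'   `NADP_linked`), `direction` (`reactant`/`product`/`both`),
#'   `mean_cpc`, `rank`. An enzyme touching both pools gets one row per
#'   class.
#' @export
classify_redox <- function(net, m, synonyms = cofactor_synonyms(),
                           collapse_compartments = TRUE) {
  cofactor_classify(net, m, c("NAD_linked", "NADP_linked"), synonyms,
                    collapse_compartments)
}

#' Classify and rank aminotransferase (alpha-ketoglutarate) enzymes
#'
#' Same machinery as [classify_redox()] with alpha-ketoglutarate in place
#' of the NAD compounds, tracing nitrogen assimilation: every enzyme whose
#' reaction involves alpha-ketoglutarate on either side is classified and
#' ranked by mean CPC.
#'
#' @inheritParams classify_redox
#' @return data frame as in [classify_redox()] with
#'   `class = "aminotransferase"`.
#' @export
classify_aminotransferases <- function(net, m,
                                       synonyms = cofactor_synonyms(),
                                       collapse_compartments = TRUE) {
  cofactor_classify(net, m, "aminotransferase", synonyms,
                    collapse_compartments)
}

#' Node/edge attribute tables for a cofactor-usage diagram
#'
#' Bipartite rendering export: one node per classified enzyme (size
#' proportional to mean CPC) plus one hub node per cofactor class, and an
#' edge from every enzyme to each class it carries.
#'
#' @param classifications output of [classify_redox()] and/or
#'   [classify_aminotransferases()] (rows may be concatenated).
#' @return list of data frames `nodes` (`id`, `type`, `class`,
#'   `direction`, `mean_cpc`) and `edges` (`source`, `target`).
#' @export
cofactor_usage_table <- function(classifications) {
  if (nrow(classifications) == 0)
    return(list(nodes = data.frame(id = character(0), type = character(0),
                                   class = character(0),
                                   direction = character(0),
                                   mean_cpc = numeric(0)),
                edges = data.frame(source = character(0),
                                   target = character(0))))
  enz_nodes <- data.frame(id = classifications$enzyme_id, type = "enzyme",
                          class = classifications$class,
                          direction = classifications$direction,
                          mean_cpc = classifications$mean_cpc,
                          stringsAsFactors = FALSE)
  hub_nodes <- data.frame(id = unique(classifications$class), type = "cofactor",
                          class = unique(classifications$class),
                          direction = NA_character_, mean_cpc = NA_real_,
                          stringsAsFactors = FALSE)
  edges <- data.frame(source = classifications$enzyme_id,
                      target = classifications$class,
                      stringsAsFactors = FALSE)
  list(nodes = rbind(enz_nodes, hub_nodes), edges = unique(edges))
}
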