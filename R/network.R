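#' Reaction network container
#'
#' A stoichiometric metabolic network: reactions over metabolites with
#' signed coefficients (negative = consumed, positive = produced), a
#' reversibility flag per reaction, and reaction-to-enzyme and
#' reaction-to-pathway maps. The enzyme map may be partial — reactions
#' without a mapped enzyme are allowed and are excluded later by the
#' branch completeness filter.
#'
#' @param stoichiometry data frame with columns `reaction_id`,
#'   `metabolite_id`, `coefficient`.
#' @param reactions data frame with columns `reaction_id`, `reversible`
#'   (0/1 or logical).
#' @param enzymes data frame with columns `reaction_id`, `enzyme_id`
#'   (several rows per reaction = isoenzymes/complex subunits).
#' @param pathways data frame with columns `reaction_id`, `pathway_id`.
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(stoichiometry, reactions, enzymes, pathways) {
  names(stoichiometry)[1:3] <- c("reaction_id", "metabolite_id", "coefficient")
  names(reactions)[1:2] <- c("reaction_id", "reversible")
  reactions$reversible <- as.logical(as.integer(reactions$reversible))
  bad <- vapply(split(stoichiometry$coefficient, stoichiometry$reaction_id),
                function(s) !any(s < 0) || !any(s > 0), logical(1))
  if (any(bad))
    stop_cpcnet("reaction(s) without both a reactant and a product: ",
                paste(names(bad)[bad], collapse = ", "),
                class = "cpcnet_format_error")
  structure(list(stoichiometry = stoichiometry,
                 reactions = unique(reactions[, c("reaction_id", "reversible")]),
                 enzymes = unique(enzymes[, c("reaction_id", "enzyme_id")]),
                 pathways = unique(pathways[, c("reaction_id", "pathway_id")])),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d reactions, %d metabolites, %d enzyme links\n",
              nrow(x$reactions), length(unique(x$stoichiometry$metabolite_id)),
              nrow(x$enzymes)))
  invisible(x)
}

#' Read a reaction network from stoichiometry + metadata TSVs
#'
#' `stoich_path` holds (`reaction_id`, `metabolite_id`, `coefficient`)
#' triples with negative coefficients for consumed metabolites;
#' `meta_path` holds one row per (reaction, enzyme) with columns
#' `reaction_id`, `reversible`, `enzyme_id`, `pathway_id` (empty enzyme or
#' pathway fields allowed).
#'
#' @param stoich_path stoichiometry TSV.
#' @param meta_path reaction metadata TSV.
#' @return a [reaction_network()].
#' @export
read_reaction_network <- function(stoich_path, meta_path) {
  st <- read_tsv(stoich_path)
  meta <- read_tsv(meta_path)
  names(meta)[1:4] <- c("reaction_id", "reversible", "enzyme_id", "pathway_id")
  enz <- meta[!is.na(meta$enzyme_id), c("reaction_id", "enzyme_id")]
  pw <- meta[!is.na(meta$pathway_id), c("reaction_id", "pathway_id")]
  reaction_network(st, meta[, c("reaction_id", "reversible")], enz, pw)
}

#' Read a reaction network from an SBML subset
#'
#' Parses the SBML core a genome-scale reconstruction export needs:
#' `listOfSpecies`, `listOfReactions` with `listOfReactants` /
#' `listOfProducts` (`speciesReference` with `species` and optional
#' `stoichiometry`, default 1) and the `reversible` attribute. Enzyme and
#' pathway maps are not part of core SBML; supply them as data frames.
#'
#' @param path SBML file.
#' @param enzymes,pathways optional data frames as in [reaction_network()].
#' @return a [reaction_network()].
#' @export
read_sbml_network <- function(path, enzymes = NULL, pathways = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  rxns <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rxns) == 0)
    stop_cpcnet("no reactions found in ", path, class = "cpcnet_format_error")
  rows <- list()
  meta <- data.frame(reaction_id = character(0), reversible = logical(0))
  for (r in rxns) {
    rid <- xml2::xml_attr(r, "id")
    rev <- !identical(xml2::xml_attr(r, "reversible"), "false")
    side <- function(xp, sign) {
      sp <- xml2::xml_find_all(r, xp)
      if (length(sp) == 0) return(NULL)
      co <- as.numeric(xml2::xml_attr(sp, "stoichiometry"))
      co[is.na(co)] <- 1
      data.frame(reaction_id = rid,
                 metabolite_id = xml2::xml_attr(sp, "species"),
                 coefficient = sign * co)
    }
    rows[[length(rows) + 1L]] <- rbind(
      side(".//listOfReactants/speciesReference", -1),
      side(".//listOfProducts/speciesReference", +1))
    meta <- rbind(meta, data.frame(reaction_id = rid, reversible = rev))
  }
  empty <- data.frame(reaction_id = character(0), enzyme_id = character(0),
                      pathway_id = character(0))
  reaction_network(do.call(rbind, rows), meta,
                   enzymes %||% empty[, c(1, 2)],
                   pathways %||% empty[, c(1, 3)])
}

#' Write a reaction network as stoichiometry + metadata TSVs
#'
#' @param net a [reaction_network()].
#' @param stoich_path,meta_path output paths.
#' @return `stoich_path`, invisibly.
#' @export
write_reaction_network <- function(net, stoich_path, meta_path) {
  write_tsv(net$stoichiometry, stoich_path)
  enz <- merge(net$reactions, net$enzymes, by = "reaction_id", all.x = TRUE)
  meta <- merge(enz, net$pathways, by = "reaction_id", all.x = TRUE)
  meta$reversible <- as.integer(meta$reversible)
  meta <- meta[order(meta$reaction_id, meta$enzyme_id), ]
  write_tsv(meta, meta_path)
  invisible(stoich_path)
}

# Enzymes catalyzing each reaction, as a named list.
reaction_enzymes <- function(net) {
  split(net$enzymes$enzyme_id, net$enzymes$reaction_id)
}
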