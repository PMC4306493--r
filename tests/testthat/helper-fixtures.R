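# Shared fixtures and independent brute-force oracles.

# Small handmade abundance matrix.
make_cpc <- function(values, tissues = NULL) {
  if (is.null(tissues))
    tissues <- stats::setNames(paste0("t", seq_len(ncol(values))),
                               colnames(values))
  cpc_matrix(values, tissues)
}

# Matrix filled by row with explicit ids.
mat <- function(x, proteins, lines) {
  matrix(x, nrow = length(proteins), byrow = TRUE,
         dimnames = list(proteins, lines))
}

# Random toy reaction network: each reaction consumes 1-2 random
# metabolites and produces 1-2 others; every reaction gets one enzyme.
random_network <- function(n_met = 20, n_rxn = 15, seed = 1) {
  set.seed(seed)
  mets <- sprintf("m%02d", seq_len(n_met))
  st <- do.call(rbind, lapply(seq_len(n_rxn), function(j) {
    k_in <- sample(1:2, 1); k_out <- sample(1:2, 1)
    picked <- sample(mets, k_in + k_out)
    data.frame(reaction_id = sprintf("r%02d", j),
               metabolite_id = picked,
               coefficient = c(rep(-1, k_in), rep(1, k_out)))
  }))
  rxn <- data.frame(reaction_id = sprintf("r%02d", seq_len(n_rxn)),
                    reversible = sample(c(TRUE, FALSE), n_rxn, replace = TRUE))
  enz <- data.frame(reaction_id = rxn$reaction_id,
                    enzyme_id = sprintf("E%02d", seq_len(n_rxn)))
  pw <- data.frame(reaction_id = rxn$reaction_id,
                   pathway_id = sample(c("pwA", "pwB", "pwC"), n_rxn,
                                       replace = TRUE))
  reaction_network(st, rxn, enz, pw)
}

# CPC matrix covering every enzyme of a network, all detected.
network_cpc <- function(net, n_lines = 4, seed = 1) {
  set.seed(seed)
  enz <- sort(unique(net$enzymes$enzyme_id))
  v <- matrix(10^stats::rnorm(length(enz) * n_lines, 3, 0.5),
              length(enz), n_lines,
              dimnames = list(enz, paste0("L", seq_len(n_lines))))
  make_cpc(v, stats::setNames(rep(c("ta", "tb"), length.out = n_lines),
                              colnames(v)))
}

# Oracle: enumerate branch points straight from the stoichiometry table,
# including the duplicate-set collapse, without any package machinery.
bf_branches <- function(st, dedupe = TRUE) {
  cons <- st[st$coefficient < 0, ]
  tab <- tapply(cons$reaction_id, cons$metabolite_id,
                function(r) paste(sort(unique(r)), collapse = ";"))
  tab <- tab[vapply(strsplit(tab, ";"), length, 1L) >= 2]
  out <- data.frame(metabolite_id = names(tab), reactions = unname(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$metabolite_id), , drop = FALSE]
  if (dedupe) out <- out[!duplicated(out$reactions), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Oracle: naive O(n * bins) log-binned counting.
bf_log_counts <- function(values, w, edges_lo, edges_hi) {
  vapply(seq_along(edges_lo), function(b)
    sum(values >= edges_lo[b] & values < edges_hi[b]), integer(1))
}

# Oracle: two-sided Fisher exact p by full enumeration of all 2x2 tables
# with the observed margins, summing hypergeometric probabilities not
# exceeding the observed one.
bf_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- vapply(support, function(x)
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)),
    numeric(1))
  p_obs <- pr[support == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
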