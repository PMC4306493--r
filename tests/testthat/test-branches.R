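# Branch-point extraction, BD scores, classification, histograms.

chain_net <- function(triples) {
  st <- do.call(rbind, lapply(seq_along(triples), function(i)
    data.frame(reaction_id = names(triples)[i],
               metabolite_id = triples[[i]],
               coefficient = c(-1, 1))))
  rxn <- data.frame(reaction_id = names(triples), reversible = FALSE)
  enz <- data.frame(reaction_id = names(triples),
                    enzyme_id = paste0("E_", names(triples)))
  pw <- data.frame(reaction_id = names(triples), pathway_id = "pw")
  reaction_network(st, rxn, enz, pw)
}

test_that("branch extraction finds shared reactants and nothing else", {
  net <- chain_net(list(r1 = c("A", "B"), r2 = c("A", "C"), r3 = c("B", "D")))
  br <- extract_branch_points(net)
  expect_identical(br$metabolite_id, "A")
  expect_identical(br$reactions, "r1;r2")
  lin <- chain_net(list(r1 = c("A", "B"), r2 = c("B", "C")))
  expect_identical(nrow(extract_branch_points(lin)), 0L)
})

test_that("reversible reactions branch from the product side only when asked", {
  st <- data.frame(reaction_id = c("r1", "r1", "r2", "r2", "r3", "r3"),
                   metabolite_id = c("A", "B", "C", "B", "B", "D"),
                   coefficient = c(-1, 1, -1, 1, -1, 1))
  rxn <- data.frame(reaction_id = c("r1", "r2", "r3"),
                    reversible = c(TRUE, FALSE, FALSE))
  enz <- data.frame(reaction_id = c("r1", "r2", "r3"),
                    enzyme_id = c("E1", "E2", "E3"))
  net <- reaction_network(st, rxn, enz, enz[, 1, drop = FALSE] |>
                            transform(pathway_id = "pw"))
  # B is produced by r1 (reversible) and r2, consumed by r3 only
  expect_identical(nrow(extract_branch_points(net)), 0L)
  both <- extract_branch_points(net, reversible_both_sides = TRUE)
  expect_identical(both$metabolite_id, "B")  # r1's back-reaction counts
  expect_identical(both$reactions, "r1;r3")
})

test_that("currency metabolites can be excluded before enumeration", {
  net <- chain_net(list(r1 = c("atp", "B"), r2 = c("atp", "C"),
                        r3 = c("G", "H"), r4 = c("G", "I")))
  all_br <- extract_branch_points(net)
  expect_setequal(all_br$metabolite_id, c("atp", "G"))
  no_cur <- extract_branch_points(net, exclude_metabolites = "atp")
  expect_identical(no_cur$metabolite_id, "G")
})

test_that("extraction equals brute force on random networks", {
  for (seed in 1:20) {
    net <- random_network(n_met = sample(5:30, 1), n_rxn = sample(4:25, 1),
                          seed = seed)
    got <- extract_branch_points(net)
    got <- got[order(got$metabolite_id), , drop = FALSE]
    bf <- bf_branches(net$stoichiometry, dedupe = FALSE)
    expect_identical(bf$metabolite_id, got$metabolite_id)
    expect_identical(bf$reactions, got$reactions)
  }
})

test_that("dedupe collapses repeated reaction sets and enforces completeness", {
  # A and A2 are consumed by the same two reactions
  st <- data.frame(reaction_id = c("r1", "r1", "r1", "r2", "r2", "r2",
                                   "r3", "r3"),
                   metabolite_id = c("A", "A2", "B", "A", "A2", "C",
                                     "D", "E"),
                   coefficient = c(-1, -1, 1, -1, -1, 1, -1, 1))
  rxn <- data.frame(reaction_id = c("r1", "r2", "r3"), reversible = FALSE)
  enz <- data.frame(reaction_id = c("r1", "r2"), enzyme_id = c("E1", "E2"))
  net <- reaction_network(st, rxn, enz,
                          data.frame(reaction_id = "r1", pathway_id = "pw"))
  br <- extract_branch_points(net)
  expect_identical(nrow(br), 2L)
  m <- make_cpc(mat(c(1, 2, 3, 4), c("E1", "E2"), c("L1", "L2")),
                c(L1 = "ta", L2 = "tb"))
  kept <- dedupe_and_filter(br, net, m)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$metabolite_id, "A")   # lexicographically first
  expect_identical(kept$aliases, "A2")
  # no reaction repeated within the retained set
  expect_false(anyDuplicated(cpcnet:::split_ids(kept$reactions)) > 0)
  # unmeasured enzyme: drop the branch
  m2 <- make_cpc(mat(c(1, 2), "E1", c("L1", "L2")),
                 c(L1 = "ta", L2 = "tb"))
  expect_identical(nrow(dedupe_and_filter(br, net, m2)), 0L)
})

test_that("BD scores match direct evaluation of their formulas", {
  expect_equal(bd_top2(c(100, 100)), 0)
  expect_equal(bd_top2(c(100, 25)), 0.75)
  expect_equal(bd_top2(c(1000, 1)), 0.999)
  expect_error(bd_top2(c(0, 0)), class = "cpcnet_undefined_score")
  expect_error(bd_top2(5), class = "cpcnet_undefined_score")
  expect_equal(bd_top3(c(3, 3, 3)), -1)
  expect_equal(bd_top3(c(60, 30, 30)), 0)
  expect_equal(bd_top3(c(100, 10, 5)), 0.85)
  expect_error(bd_top3(c(1, 1)), class = "cpcnet_undefined_score")
})

test_that("BD score bounds, ordering and invariances hold on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    x <- sort(10^runif(sample(3:6, 1), -1, 5), decreasing = TRUE)
    b2 <- bd_top2(x); b3 <- bd_top3(x)
    expect_gte(b2, 0); expect_lte(b2, 1)
    expect_gte(b3, -1); expect_lte(b3, 1)
    expect_lte(b3, b2)
    # rescaling all abundances leaves both scores unchanged
    expect_equal(bd_top2(x * 123), b2)
    expect_equal(bd_top3(x * 123), b3)
    # strictly decreasing in C2 (and C3 for top-3)
    y <- x; y[2] <- min(y[2] * 1.01, y[1])
    expect_lte(bd_top2(y), b2)
    z <- x; z[3] <- min(z[3] * 1.01, z[2])
    expect_lte(bd_top3(z), b3)
  }
})

test_that("classification applies strict thresholds with the or-clause", {
  expect_identical(classify_branch(0.85), "one_sided")
  expect_identical(classify_branch(0.5, -0.1), "equally_distributed")
  expect_identical(classify_branch(0.8), "unclassified")     # boundary
  expect_identical(classify_branch(0.2), "unclassified")     # boundary
  expect_identical(classify_branch(0.19), "equally_distributed")
  expect_identical(classify_branch(0.5, 0), "unclassified")  # bd3 boundary
})

test_that("BD histograms are lower-inclusive with a closed top bin", {
  sc <- data.frame(bd2 = 1.0, bd3 = NA_real_)
  h <- bd_histogram(sc, "top2")
  expect_identical(h$count[10], 1L)
  expect_identical(sum(h$count), 1L)
  sc2 <- data.frame(bd2 = c(0.05, 0.15, 0.15), bd3 = NA_real_)
  h2 <- bd_histogram(sc2, "top2")
  expect_identical(h2$count[1:2], c(1L, 2L))
  # top3 covers [-1, 1]
  sc3 <- data.frame(bd2 = rep(0.5, 3), bd3 = c(-1, -0.05, 1))
  h3 <- bd_histogram(sc3, "top3")
  expect_identical(length(h3$count), 20L)
  expect_identical(h3$count[1], 1L)   # -1 in first bin
  expect_identical(h3$count[10], 1L)  # -0.05 in [-0.1, 0)
  expect_identical(h3$count[20], 1L)  # 1 in closed top bin
  # random scores match a counting oracle
  set.seed(4)
  scr <- data.frame(bd2 = runif(300), bd3 = runif(300, -1, 1))
  for (w in c("top2", "top3")) {
    hh <- bd_histogram(scr, w)
    x <- if (w == "top2") scr$bd2 else scr$bd3
    oracle <- vapply(seq_len(nrow(hh)), function(b) {
      top <- b == nrow(hh)
      sum(x >= hh$bin_lo[b] & (x < hh$bin_hi[b] | (top & x == hh$bin_hi[b])))
    }, integer(1))
    expect_identical(hh$count, oracle)
  }
})

test_that("scoring ranks by reaction abundance with documented tie-breaks", {
  net <- chain_net(list(r1 = c("A", "B"), r2 = c("A", "C"),
                        r3 = c("A", "D")))
  m <- make_cpc(mat(c(100, 100, 100, 100, 10, 10),
                    c("E_r1", "E_r2", "E_r3"), c("L1", "L2")),
                c(L1 = "ta", L2 = "tb"))
  br <- dedupe_and_filter(extract_branch_points(net), net, m)
  sc <- score_branches(br, net, m)
  expect_equal(sc$bd2, 0)        # tie at the top
  expect_equal(sc$bd3, (100 - 100 - 10) / 100)
  expect_identical(sc$class, "equally_distributed")
  expect_identical(sc$score_used, "top2")  # bd2 < 0.2 already decides
  # tie broken lexicographically by lead enzyme id
  expect_identical(cpcnet:::split_ids(sc$reactions)[1:2], c("r1", "r2"))
})
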