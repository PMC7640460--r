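test_that("final alignment score is the stated convex combination of T and B", {
  tm <- sim_matrix(matrix(c(0.0, 0.2), 1, 2, dimnames = list("a", c("x", "y"))),
                   "topological", normalized = TRUE)
  bm <- sim_matrix(matrix(c(1.0, 0.6), 1, 2, dimnames = list("a", c("x", "y"))),
                   "biological", normalized = TRUE)
  a <- alignment_scores(tm, bm, alpha = 0.1)
  expect_equal(a["a", "x"], 0.9)   # biological contributes 90% at alpha = 0.1
  expect_equal(alignment_scores(tm, bm, alpha = 1.0)["a", "y"], 0.2) # A = T
  expect_equal(alignment_scores(tm, bm, alpha = 0.5)["a", "y"],
               0.5 * 0.2 + 0.5 * 0.6)                                 # = 0.4
  expect_error(alignment_scores(tm, bm, alpha = -0.1), "alpha")

  # union of pairs: a component missing from one matrix counts as 0
  bm2 <- sim_matrix(matrix(0.8, 1, 1, dimnames = list("a", "z")),
                    "biological", normalized = TRUE)
  a2 <- alignment_scores(tm, bm2, alpha = 0.5)
  expect_equal(a2["a", "z"], 0.4)
  expect_equal(a2["a", "x"], 0.0)
  expect_true(all(unclass(a2) >= 0 & unclass(a2) <= 1))
})

test_that("greedy alignment handles the trivial and hand-enumerated cases", {
  n1 <- ppi_network(nodes = "a")
  n2 <- ppi_network(nodes = "x")
  A <- sim_matrix(matrix(0.5, 1, 1, dimnames = list("a", "x")),
                  "alignment", normalized = TRUE)
  al <- greedy_align(A, n1, n2)
  expect_equal(alignment_mapping(al), c(a = "x"))

  # seed (a,x) = 0.9; frontier then contains only (b,y) -> {a->x, b->y},
  # even though picking b first would prefer neither
  n1 <- ppi_network(rbind(c("a", "b")))
  n2 <- ppi_network(rbind(c("x", "y")))
  A <- sim_matrix(matrix(c(0.9, 0.1, 0.1, 0.8), 2, 2, byrow = TRUE,
                         dimnames = list(c("a", "b"), c("x", "y"))),
                  "alignment", normalized = TRUE)
  al <- greedy_align(A, n1, n2)
  expect_equal(al$node1, c("a", "b"))
  expect_equal(al$node2, c("x", "y"))
  expect_equal(al$score, c(0.9, 0.8))
})

test_that("self-alignment with a dominant diagonal recovers the identity", {
  pair <- make_paired_networks(40, edge_p = 0.1, seed = 2L)
  net <- pair$net1
  ident <- setNames(net$nodes, net$nodes)
  A <- planted_scores(net$nodes, net$nodes, ident, seed = 2L)
  al <- greedy_align(A, net, ppi_network(net$edges, nodes = net$nodes,
                                         name = "copy"))
  expect_equal(recovery_rate(al, ident), 1.0)
})

test_that("greedy output is injective and exhausts the smaller network on dense scores", {
  for (seed in 1:5) {
    p <- make_paired_networks(25, edge_p = 0.12, seed = seed)
    extra <- ppi_network(p$net2$edges,
                         nodes = c(p$net2$nodes, "b_extra1", "b_extra2"),
                         name = "larger")
    A <- dense_scores(p$net1$nodes, extra$nodes, seed = seed)
    al <- greedy_align(A, p$net1, extra)
    expect_equal(nrow(al), 25L)
    expect_false(anyDuplicated(al$node1) > 0)
    expect_false(anyDuplicated(al$node2) > 0)
    expect_true(all(al$node1 %in% p$net1$nodes))
    expect_true(all(al$node2 %in% extra$nodes))
  }
})

test_that("greedy alignment is invariant under consistent relabeling", {
  p <- make_paired_networks(15, edge_p = 0.2, seed = 4L)
  A <- dense_scores(p$net1$nodes, p$net2$nodes, seed = 4L)
  al <- greedy_align(A, p$net1, p$net2)

  # relabel both networks with an order-preserving map (keeps tie-breaks)
  rl1 <- setNames(paste0("x", p$net1$nodes), p$net1$nodes)
  rl2 <- setNames(paste0("y", p$net2$nodes), p$net2$nodes)
  net1r <- ppi_network(cbind(rl1[p$net1$edges[, 1]], rl1[p$net1$edges[, 2]]),
                       nodes = rl1, name = "net1")
  net2r <- ppi_network(cbind(rl2[p$net2$edges[, 1]], rl2[p$net2$edges[, 2]]),
                       nodes = rl2, name = "net2")
  m <- unclass(A)
  dimnames(m) <- list(rl1[rownames(m)], rl2[colnames(m)])
  alr <- greedy_align(sim_matrix(m, "alignment", normalized = TRUE),
                      net1r, net2r)
  expect_equal(unname(rl2[al$node2]), alr$node2)
  expect_equal(unname(rl1[al$node1]), alr$node1)
})

test_that("top-n candidate selection equals sort-and-slice", {
  A <- sim_matrix(matrix(c(0.9, 0.5, 0.1), 1, 3,
                         dimnames = list("a", c("x", "y", "z"))),
                  "alignment", normalized = TRUE)
  cands <- topn_candidates(A, "a", c("x", "y", "z"), n_top = 2)
  expect_equal(cands$nodes, c("x", "y"))
  expect_equal(cands$score, c(0.9, 0.5))
  # n_top beyond the candidate count returns everything
  expect_equal(length(topn_candidates(A, "a", c("x", "y", "z"), 10)$nodes), 3L)
  # aligned partners are excluded before the top-n cut
  expect_equal(topn_candidates(A, "a", c("y", "z"), 1)$nodes, "y")
  # no scored candidates -> empty set
  expect_equal(length(topn_candidates(A, "a", character(0), 3)$nodes), 0L)

  set.seed(8)
  for (i in 1:10) {
    s <- runif(12)
    ids <- sprintf("c%02d", sample(100, 12))
    m <- sim_matrix(matrix(s, 1, 12, dimnames = list("u", ids)),
                    "alignment", normalized = TRUE)
    got <- topn_candidates(m, "u", ids, 5)
    want <- sort(s[order(ids)], decreasing = TRUE)[1:5]
    expect_equal(got$score, want)
  }
})

test_that("candidate score normalization divides by the score sum", {
  cands <- topn_candidates(
    sim_matrix(matrix(c(0.9, 0.5, 0.1), 1, 3,
                      dimnames = list("a", c("x", "y", "z"))),
               "alignment", normalized = TRUE),
    "a", c("x", "y", "z"), 3)
  ns <- normalize_topn(cands)$ns
  expect_equal(ns, c(0.9, 0.5, 0.1) / 1.5)
  expect_equal(sum(ns), 1, tolerance = 1e-9)

  one <- normalize_topn(topn_candidates(
    sim_matrix(matrix(0.4, 1, 1, dimnames = list("a", "x")),
               "alignment", normalized = TRUE), "a", "x", 1))
  expect_equal(one$ns, 1.0)

  eq <- structure(list(nodes = c("x", "y", "z"), score = c(0.2, 0.2, 0.2),
                       ns = NULL, prob = NULL), class = "candidate_set")
  expect_equal(normalize_topn(eq)$ns, rep(1 / 3, 3))

  zero <- structure(list(nodes = c("x", "y"), score = c(0, 0),
                         ns = NULL, prob = NULL), class = "candidate_set")
  expect_message(zs <- normalize_topn(zero), "uniform")
  expect_equal(zs$ns, c(0.5, 0.5))
})

test_that("Boltzmann probabilities match independent exponential arithmetic", {
  mk <- function(ns) structure(list(nodes = paste0("c", seq_along(ns)),
                                    score = ns, ns = ns, prob = NULL),
                               class = "candidate_set")
  # worked case NS = [0.6, 0.4], kT = 0.1
  p <- mc_probabilities(mk(c(0.6, 0.4)), kT = 0.1)$prob
  expect_equal(p, c(exp(0), exp(-2)) / (exp(0) + exp(-2)), tolerance = 1e-12)
  expect_equal(p, c(0.8808, 0.1192), tolerance = 1e-4)
  expect_equal(sum(p), 1, tolerance = 1e-9)

  # equal normalized scores -> uniform
  expect_equal(mc_probabilities(mk(rep(0.25, 4)), 0.1)$prob, rep(0.25, 4))

  # kT -> 0+ concentrates on the best candidate
  p_cold <- mc_probabilities(mk(c(0.6, 0.4)), kT = 1e-4)$prob
  expect_gt(p_cold[1], 1 - 1e-10)

  # shift invariance: adding a constant to all NS leaves Prob unchanged
  expect_equal(mc_probabilities(mk(c(0.6, 0.4) + 0.3), 0.1)$prob,
               mc_probabilities(mk(c(0.6, 0.4)), 0.1)$prob)

  # monotone: larger NS never gets smaller probability
  set.seed(3)
  ns <- sort(runif(6), decreasing = TRUE)
  pr <- mc_probabilities(mk(ns), 0.1)$prob
  expect_true(all(diff(pr) <= 1e-12))
})

test_that("MC alignment is seed-reproducible and reduces to greedy at n_top = 1", {
  for (seed in 1:20) {
    p <- make_paired_networks(12, edge_p = 0.25, seed = seed)
    A <- dense_scores(p$net1$nodes, p$net2$nodes, seed = seed)
    g <- greedy_align(A, p$net1, p$net2)
    m1 <- mc_align(A, p$net1, p$net2,
                   salign_params(n_top = 1, seed = seed))
    expect_identical(m1$node1, g$node1)
    expect_identical(m1$node2, g$node2)
  }

  p <- make_paired_networks(20, edge_p = 0.2, seed = 33L)
  A <- dense_scores(p$net1$nodes, p$net2$nodes, seed = 33L)
  pars <- salign_params(n_top = 5, seed = 99L)
  r1 <- mc_align(A, p$net1, p$net2, pars)
  r2 <- mc_align(A, p$net1, p$net2, pars)
  expect_identical(r1, r2)
  r3 <- mc_align(A, p$net1, p$net2, salign_params(n_top = 5, seed = 100L))
  expect_false(identical(r1$node2, r3$node2))
  # injectivity under sampling
  expect_false(anyDuplicated(r3$node2) > 0)
})

test_that("MC first-pick frequencies follow the Boltzmann probabilities", {
  # 1-node network vs 3 isolated candidates: the first (only) selection
  # samples directly from the Eq.-style probabilities
  n1 <- ppi_network(nodes = "u")
  n2 <- ppi_network(nodes = c("x", "y", "z"))
  A <- sim_matrix(matrix(c(0.5, 0.3, 0.2), 1, 3,
                         dimnames = list("u", c("x", "y", "z"))),
                  "alignment", normalized = TRUE)
  cands <- mc_probabilities(normalize_topn(topn_candidates(A, "u",
                                                           c("x", "y", "z"),
                                                           3)), kT = 0.1)
  n_draws <- 10000L
  picks <- vapply(seq_len(n_draws), function(s) {
    mc_align(A, n1, n2, salign_params(n_top = 3, seed = s))$node2[1]
  }, character(1))
  freq <- as.vector(table(factor(picks, levels = cands$nodes))) / n_draws
  se <- sqrt(cands$prob * (1 - cands$prob) / n_draws)
  expect_true(all(abs(freq - cands$prob) <= 3 * se))
})
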