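#' Alignment parameters
#'
#' Bundles the tunables of the aligner with their defaults: `alpha = 0.1`
#' (weight of the topological score in the final alignment score; the
#' biological score then contributes 90%), `beta = 0.7` (weight of sequence
#' vs structure inside the biological score; use `beta = 0.9` when few
#' proteins have resolved structures), `d = 10` (degree threshold of the
#' minimum-degree reduction), `n_top = 10` (candidate pool size of the
#' Monte Carlo variant), `kT = 0.1` (constant Boltzmann temperature
#' product), and the random `seed`.
#'
#' @param alpha trade-off between topological and biological score, in `[0,1]`.
#' @param beta trade-off between sequence and structure score, in `[0,1]`.
#' @param d positive integer degree threshold.
#' @param n_top number of top candidates sampled by the Monte Carlo variant.
#' @param kT positive Boltzmann temperature product.
#' @param seed integer random seed for the Monte Carlo variant.
#' @return object of class `salign_params`.
#' @export
salign_params <- function(alpha = 0.1, beta = 0.7, d = 10L, n_top = 10L,
                          kT = 0.1, seed = 1L) {
  assert_unit_interval(alpha, "alpha")
  assert_unit_interval(beta, "beta")
  d <- as.integer(d); n_top <- as.integer(n_top)
  if (is.na(d) || d < 1L) stopf("`d` must be a positive integer")
  if (is.na(n_top) || n_top < 1L) stopf("`n_top` must be a positive integer")
  if (!is.numeric(kT) || kT <= 0) stopf("`kT` must be positive")
  structure(list(alpha = alpha, beta = beta, d = d, n_top = n_top,
                 kT = kT, seed = as.integer(seed)),
            class = "salign_params")
}

#' @export
print.salign_params <- function(x, ...) {
  cat(sprintf(
    "<salign_params alpha=%g beta=%g d=%d n_top=%d kT=%g seed=%d>\n",
    x$alpha, x$beta, x$d, x$n_top, x$kT, x$seed))
  invisible(x)
}

#' Final alignment score matrix
#'
#' Convex combination `A = alpha * T + (1 - alpha) * B` of the topological
#' and biological similarity matrices, defined on the union of pairs present
#' in either input (a missing component counts as 0). With `alpha = 0.1`
#' the biological score contributes 90% of the final score.
#'
#' @param topo_sim [sim_matrix()] with role `"topological"`, entries in `[0,1]`.
#' @param bio_sim [sim_matrix()] with role `"biological"`, entries in `[0,1]`.
#' @param alpha weight of the topological score, in `[0,1]`.
#' @return a normalized [sim_matrix()] with role `"alignment"`.
#' @export
alignment_scores <- function(topo_sim, bio_sim, alpha = 0.1) {
  assert_unit_interval(alpha, "alpha")
  stopifnot(inherits(topo_sim, "sim_matrix"), inherits(bio_sim, "sim_matrix"))
  if (!sim_normalized(topo_sim) || !sim_normalized(bio_sim)) {
    stopf("both score matrices must be normalized to [0,1]")
  }
  rows <- sort(unique(c(rownames(topo_sim), rownames(bio_sim))))
  cols <- sort(unique(c(colnames(topo_sim), colnames(bio_sim))))
  expand <- function(sim) {
    m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
    if (nrow(sim)) {
      tmp <- unclass(sim)
      tmp[is.na(tmp)] <- 0
      m[rownames(sim), colnames(sim)] <- tmp
    }
    m
  }
  a <- alpha * expand(topo_sim) + (1 - alpha) * expand(bio_sim)
  sim_matrix(a, role = "alignment", normalized = TRUE)
}

# orient the score matrix so rows index the smaller network; returns
# list(A, small, large, swapped)
orient_scores <- function(A, net1, net2) {
  ord <- order_networks(net1, net2)
  m <- unclass(A)
  if (ord$swapped) m <- t(m)
  full <- matrix(NA_real_, n_nodes(ord$small), n_nodes(ord$large),
                 dimnames = list(ord$small$nodes, ord$large$nodes))
  common_r <- intersect(rownames(m), ord$small$nodes)
  common_c <- intersect(colnames(m), ord$large$nodes)
  full[common_r, common_c] <- m[common_r, common_c]
  list(A = full, small = ord$small, large = ord$large, swapped = ord$swapped)
}

# greedy/MC shared step: pick the maximum available pair from `mask`
# (ties: larger score, then lexicographic row name, then column name);
# rows/cols of A are sorted, so smallest indices = lexicographic order
pick_max_pair <- function(A, mask) {
  idx <- which(mask, arr.ind = TRUE, useNames = FALSE)
  if (nrow(idx) == 0L) return(NULL)
  vals <- A[idx]
  best <- max(vals)
  sub <- idx[vals == best, , drop = FALSE]
  sub <- sub[order(sub[, 1L], sub[, 2L]), , drop = FALSE]
  c(sub[1L, 1L], sub[1L, 2L])
}

# core seed-and-extend loop shared by the greedy and Monte Carlo aligners.
# choose_partner(u_idx, partner_idx) -> selected column index; the greedy
# aligner passes NULL and takes the greedy pair directly.
align_loop <- function(A, small, large, choose_partner = NULL) {
  n1 <- nrow(A); n2 <- ncol(A)
  scored <- !is.na(A)
  A0 <- A
  A0[!scored] <- -Inf
  adj1 <- adjacency_list(small)
  adj2 <- adjacency_list(large)
  rn <- rownames(A); cn <- colnames(A)
  ridx <- stats::setNames(seq_len(n1), rn)
  cidx <- stats::setNames(seq_len(n2), cn)
  avail1 <- rep(TRUE, n1); avail2 <- rep(TRUE, n2)
  frontier <- matrix(FALSE, n1, n2)
  out1 <- character(0); out2 <- character(0); outs <- numeric(0)

  repeat {
    if (!any(avail1)) break
    live <- outer(avail1, avail2, `&`) & scored
    fr_live <- frontier & live
    seeding <- !any(fr_live)
    pick <- pick_max_pair(A0, if (seeding) live else fr_live)
    if (is.null(pick)) break
    ui <- pick[1L]; vi <- pick[2L]
    if (!is.null(choose_partner)) {
      partners <- which(if (seeding) live[ui, ] else fr_live[ui, ])
      vi <- choose_partner(ui, partners)
    }
    u <- rn[ui]; v <- cn[vi]
    out1 <- c(out1, u); out2 <- c(out2, v); outs <- c(outs, A[ui, vi])
    avail1[ui] <- FALSE; avail2[vi] <- FALSE
    nb1 <- ridx[adj1[[u]]]; nb2 <- cidx[adj2[[v]]]
    nb1 <- nb1[avail1[nb1]]; nb2 <- nb2[avail2[nb2]]
    if (length(nb1) && length(nb2)) frontier[nb1, nb2] <- TRUE
  }
  ppi_alignment(out1, out2, outs)
}

#' Greedy seed-and-extend global alignment
#'
#' Seeds with the globally maximum-scoring unaligned pair, then repeatedly
#' aligns the maximum-scoring frontier pair, where the frontier contains
#' pairs `(u, v)` such that `u` is an unaligned neighbour (in the smaller
#' network) of an already aligned node `u'` and `v` an unaligned neighbour
#' (in the larger network) of its partner `g(u')` — neighbours of aligned
#' nodes are prioritized, keeping the alignment topologically consistent.
#' When the frontier empties while scored candidates remain, the alignment
#' re-seeds from the best remaining global pair, so all (or the maximum
#' possible number) of the smaller network's nodes get aligned. Ties break
#' by larger score, then lexicographic node identifiers; the result is
#' deterministic.
#'
#' @param A [sim_matrix()] of final alignment scores (role `"alignment"`).
#' @param net1,net2 the two [ppi_network()]s; the smaller one (auto-detected,
#'   see [order_networks()]) becomes the mapping's domain.
#' @return a [ppi_alignment()] in alignment (seed-and-extend) order.
#' @export
greedy_align <- function(A, net1, net2) {
  stopifnot(inherits(A, "sim_matrix"))
  o <- orient_scores(A, net1, net2)
  align_loop(o$A, o$small, o$large)
}

#' Top-n candidate partners for one node
#'
#' The up-to-`n_top` highest-scoring unaligned partners of `u`, sorted by
#' score descending with lexicographic tie-break.
#'
#' @param A [sim_matrix()] of alignment scores, rows = smaller network.
#' @param u a smaller-network node identifier (row of `A`).
#' @param unaligned character vector of currently unaligned larger-network
#'   nodes to consider.
#' @param n_top maximum number of candidates.
#' @return object of class `candidate_set`: list with `nodes`, `score`, and
#'   (once computed) `ns` (normalized scores) and `prob` (selection
#'   probabilities). Empty when `u` has no scored unaligned candidate.
#' @export
topn_candidates <- function(A, u, unaligned, n_top = 10L) {
  n_top <- as.integer(n_top)
  if (is.na(n_top) || n_top < 1L) stopf("`n_top` must be >= 1")
  stopifnot(u %in% rownames(A))
  unaligned <- intersect(unaligned, colnames(A))
  m <- unclass(A)[u, unaligned, drop = FALSE]
  s <- stats::setNames(as.vector(m), colnames(m))
  s <- s[!is.na(s)]
  if (length(s) == 0L) {
    return(structure(list(nodes = character(0), score = numeric(0),
                          ns = NULL, prob = NULL), class = "candidate_set"))
  }
  o <- order(-s, names(s))
  o <- o[seq_len(min(n_top, length(o)))]
  structure(list(nodes = names(s)[o], score = unname(s[o]),
                 ns = NULL, prob = NULL), class = "candidate_set")
}

#' Normalize candidate scores to selection weights
#'
#' `NS_i = n_i / s`, where `s` is the sum of the top-n candidates' alignment
#' scores, so the normalized scores sum to 1. When all candidate scores are
#' zero the normalized scores are uniform (the symmetric completion of the
#' 0/0 case).
#'
#' @param cands a `candidate_set` from [topn_candidates()].
#' @return the `candidate_set` with its `ns` field filled.
#' @export
normalize_topn <- function(cands) {
  stopifnot(inherits(cands, "candidate_set"))
  if (length(cands$score) == 0L) stopf("empty candidate set")
  s <- sum(cands$score)
  if (s == 0) {
    message("all candidate scores zero; using uniform normalized scores")
    cands$ns <- rep(1 / length(cands$score), length(cands$score))
  } else {
    cands$ns <- cands$score / s
  }
  cands
}

#' Boltzmann selection probabilities over candidates
#'
#' `Prob_i = exp(-(best - NS_i) / kT) / sum_j exp(-(best - NS_j) / kT)`,
#' where `best` is the maximum normalized score. Probabilities sum to 1,
#' are invariant to adding a constant to all normalized scores, and
#' concentrate on the best candidate as `kT -> 0`.
#'
#' @param cands a `candidate_set` with normalized scores (see
#'   [normalize_topn()]).
#' @param kT positive temperature product.
#' @return the `candidate_set` with its `prob` field filled.
#' @export
mc_probabilities <- function(cands, kT = 0.1) {
  stopifnot(inherits(cands, "candidate_set"))
  if (is.null(cands$ns)) stopf("normalize the candidate set first")
  if (!is.numeric(kT) || kT <= 0) stopf("`kT` must be positive")
  w <- exp(-(max(cands$ns) - cands$ns) / kT)
  cands$prob <- w / sum(w)
  cands
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set: %d candidates>\n", length(x$nodes)))
  if (length(x$nodes)) {
    print(data.frame(node = x$nodes, score = x$score,
                     ns = x$ns %||% NA, prob = x$prob %||% NA))
  }
  invisible(x)
}

#' Monte Carlo (semi-greedy) global alignment
#'
#' Follows exactly the seed-and-extend node-visit order of
#' [greedy_align()], but instead of taking the single best partner it draws
#' the partner of each visited node from the Boltzmann probabilities
#' ([mc_probabilities()]) over its top-`n_top` currently unaligned
#' candidates ([topn_candidates()], [normalize_topn()]). With `n_top = 1`
#' the draw is deterministic and the output reduces to the greedy
#' alignment. Identical seeds give identical alignments; different seeds
#' generally give alternate alignments of similar quality.
#'
#' @param A [sim_matrix()] of final alignment scores (role `"alignment"`).
#' @param net1,net2 the two [ppi_network()]s.
#' @param params a [salign_params()]; uses `n_top`, `kT` and `seed`.
#' @return a [ppi_alignment()].
#' @export
mc_align <- function(A, net1, net2, params = salign_params()) {
  stopifnot(inherits(A, "sim_matrix"), inherits(params, "salign_params"))
  o <- orient_scores(A, net1, net2)
  Af <- o$A
  cn <- colnames(Af)
  sim <- sim_matrix(Af, role = "alignment",
                    normalized = sim_normalized(A))
  choose <- function(ui, partner_idx) {
    u <- rownames(Af)[ui]
    cands <- topn_candidates(sim, u, cn[partner_idx], params$n_top)
    cands <- mc_probabilities(suppressMessages(normalize_topn(cands)),
                              params$kT)
    pick <- if (length(cands$nodes) == 1L) cands$nodes else {
      sample(cands$nodes, 1L, prob = cands$prob)
    }
    which(cn == pick)
  }
  with_seed(params$seed, align_loop(Af, o$small, o$large, choose))
}
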