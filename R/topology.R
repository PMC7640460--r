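#' Node importance by iterative minimum-degree reduction
#'
#' Computes a global topological importance for every node by repeatedly
#' deleting the current minimum-degree node (lowest degrees first) and
#' transferring its accumulated weight to its neighbourhood, until every
#' remaining node has degree greater than the threshold `d`. Node weights
#' start at 0 and edge weights at 1. The transfer rules concentrate weight
#' on hubs and bottlenecks:
#'
#' * degree 0: nothing transfers;
#' * degree 1 with neighbour `u`: `w(u) += w(v) + w(v,u)`;
#' * degree `k >= 2`: for every unordered neighbour pair `(u,z)`,
#'   `w(u,z) += (w(v) + w(v,u) + w(v,z)) / choose(k,2)`, creating the
#'   "skeleton" edge `(u,z)` with weight 0 first when absent. Skeleton
#'   edges participate in subsequent degrees and in importance sums.
#'
#' The importance of a removed node is its node weight frozen at removal
#' time; the importance of a surviving node is its node weight plus the sum
#' of its surviving incident edge weights. Ties in the removal order are
#' broken by lexicographically smallest node identifier, making the result
#' deterministic.
#'
#' @param net a [ppi_network()].
#' @param d positive integer degree threshold; nodes are removed while their
#'   current degree is at most `d`.
#' @return object of class `topo_weights`: list with named numeric vectors
#'   `importance` and `node_weight` over all nodes, `edge_weight` over
#'   surviving edges (named by `from\tto` key), the threshold `d`, and
#'   `removed`, the removal order.
#' @export
min_degree_reduce <- function(net, d = 10L) {
  stopifnot(inherits(net, "ppi_network"))
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stopf("`d` must be a positive integer")
  nodes <- net$nodes
  nn <- length(nodes)
  out <- structure(list(importance = stats::setNames(numeric(0), character(0)),
                        node_weight = stats::setNames(numeric(0), character(0)),
                        edge_weight = numeric(0), d = d, removed = character(0)),
                   class = "topo_weights")
  if (nn == 0L) return(out)

  nw <- stats::setNames(numeric(nn), nodes)
  adj <- adjacency_list(net)
  ew <- new.env(parent = emptyenv())
  if (n_edges(net) > 0L) {
    for (k in edge_key(net$edges[, 1L], net$edges[, 2L])) assign(k, 1.0, ew)
  }
  active <- stats::setNames(rep(TRUE, nn), nodes)
  importance <- stats::setNames(rep(NA_real_, nn), nodes)
  removed <- character(0)

  repeat {
    act <- names(active)[active]
    if (length(act) == 0L) break
    deg <- lengths(adj[act])
    elig <- act[deg <= d]
    if (length(elig) == 0L) break
    dmin <- min(deg[elig])
    cand <- elig[deg[elig] == dmin]
    v <- sort(cand)[1L]                       # lexicographic tie-break
    nbrs <- adj[[v]]
    k <- length(nbrs)
    if (k == 1L) {
      u <- nbrs
      nw[u] <- nw[u] + nw[v] + get(edge_key(v, u), ew)
    } else if (k >= 2L) {
      denom <- choose(k, 2)
      inc <- vapply(nbrs, function(u) get(edge_key(v, u), ew), numeric(1))
      for (i in seq_len(k - 1L)) {
        for (j in (i + 1L):k) {
          key <- edge_key(nbrs[i], nbrs[j])
          old <- if (exists(key, ew, inherits = FALSE)) get(key, ew) else {
            # new skeleton edge joins the surviving graph with weight 0
            adj[[nbrs[i]]] <- sort(c(adj[[nbrs[i]]], nbrs[j]))
            adj[[nbrs[j]]] <- sort(c(adj[[nbrs[j]]], nbrs[i]))
            0
          }
          assign(key, old + (nw[v] + inc[i] + inc[j]) / denom, ew)
        }
      }
    }
    importance[v] <- nw[v]                    # frozen at removal time
    for (u in nbrs) {
      adj[[u]] <- adj[[u]][adj[[u]] != v]
      rm(list = edge_key(v, u), envir = ew)
    }
    adj[[v]] <- character(0)
    active[v] <- FALSE
    removed <- c(removed, v)
  }

  surviving <- names(active)[active]
  for (u in surviving) {
    inc <- if (length(adj[[u]])) {
      sum(vapply(adj[[u]], function(z) get(edge_key(u, z), ew), numeric(1)))
    } else 0
    importance[u] <- nw[u] + inc
  }
  ewk <- ls(ew)
  out$importance <- importance
  out$node_weight <- nw
  out$edge_weight <- stats::setNames(
    vapply(ewk, function(k) get(k, ew), numeric(1)), ewk)
  out$removed <- removed
  out
}

#' @export
print.topo_weights <- function(x, ...) {
  cat(sprintf("<topo_weights: %d nodes, d = %d, %d removed>\n",
              length(x$importance), x$d, length(x$removed)))
  invisible(x)
}

#' Write topological weights as a TSV (debug dump)
#'
#' @param tw a `topo_weights` object from [min_degree_reduce()].
#' @param path output path; columns node, node_weight, importance.
#' @return `path`, invisibly.
#' @export
write_topo_weights <- function(tw, path) {
  stopifnot(inherits(tw, "topo_weights"))
  nodes <- sort(names(tw$importance))
  writeLines(paste(nodes,
                   format(tw$node_weight[nodes], digits = 15, trim = TRUE),
                   format(tw$importance[nodes], digits = 15, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Topological similarity matrix between two reduced networks
#'
#' Combines per-node importances `S` from two networks into the topological
#' similarity `T(i,j) = min(S(i), S(j)) / max(S(i), S(j))` (0 when the
#' maximum is 0), so that `T` lies in `[0,1]`, equals 1 exactly for equal
#' positive importances, and is symmetric under swapping the two networks'
#' roles.
#'
#' @param tw1,tw2 `topo_weights` for the two networks, computed with the
#'   same threshold `d`.
#' @return a [sim_matrix()] with role `"topological"`, rows indexed by the
#'   first network's nodes and columns by the second's.
#' @export
topo_similarity <- function(tw1, tw2) {
  stopifnot(inherits(tw1, "topo_weights"), inherits(tw2, "topo_weights"))
  if (tw1$d != tw2$d) stopf("topo_weights computed with different `d` (%d vs %d)",
                            tw1$d, tw2$d)
  s1 <- tw1$importance[sort(names(tw1$importance))]
  s2 <- tw2$importance[sort(names(tw2$importance))]
  lo <- outer(s1, s2, pmin)
  hi <- outer(s1, s2, pmax)
  tm <- ifelse(hi > 0, lo / hi, 0)
  dimnames(tm) <- list(names(s1), names(s2))
  sim_matrix(tm, role = "topological", normalized = TRUE)
}
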