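# shared fixture builders (everything generated in code; no stored data)

# dense strictly positive alignment-score matrix over two node sets
dense_scores <- function(nodes1, nodes2, seed = 1L) {
  m <- matrix(NA_real_, length(nodes1), length(nodes2),
              dimnames = list(sort(nodes1), sort(nodes2)))
  set.seed(seed)
  m[] <- runif(length(m), min = 0.01, max = 0.99)
  sim_matrix(m, role = "alignment", normalized = TRUE)
}

# identity-favouring score matrix: 1 on the planted pairs, < 1 elsewhere
planted_scores <- function(nodes1, nodes2, mapping, seed = 1L) {
  m <- unclass(dense_scores(nodes1, nodes2, seed)) * 0.9
  m[cbind(names(mapping), unname(mapping))] <- 1
  sim_matrix(m, role = "alignment", normalized = TRUE)
}

# small two-namespace DAG: per namespace a root with two internal nodes and
# four leaves, used by ontology tests
toy_dag <- function() {
  terms <- c("GO:1", "GO:2", "GO:3", "GO:4", "GO:5", "GO:6", "GO:7",
             "GO:8", "GO:9")
  ns <- c("MF", "MF", "MF", "MF", "MF", "MF", "MF", "BP", "BP")
  names(ns) <- terms
  parents <- list(
    "GO:2" = data.frame(parent = "GO:1", rel = "is_a"),
    "GO:3" = data.frame(parent = "GO:1", rel = "is_a"),
    "GO:4" = data.frame(parent = "GO:2", rel = "is_a"),
    "GO:5" = data.frame(parent = "GO:2", rel = "is_a"),
    "GO:6" = data.frame(parent = "GO:3", rel = "part_of"),
    "GO:7" = data.frame(parent = "GO:3", rel = "is_a"),
    "GO:9" = data.frame(parent = "GO:8", rel = "is_a"))
  go_dag(terms, ns, parents)
}

# independent step-by-step simulator of the minimum-degree reduction,
# written directly from the stated transfer rules with no shared code path
reference_min_degree <- function(net, d) {
  nodes <- net$nodes
  nw <- setNames(numeric(length(nodes)), nodes)
  ew <- list()
  ekey <- function(u, v) paste(min(u, v), max(u, v), sep = "|")
  for (i in seq_len(nrow(net$edges))) {
    ew[[ekey(net$edges[i, 1], net$edges[i, 2])]] <- 1
  }
  nbrs <- function(v, alive) {
    out <- character(0)
    for (k in names(ew)) {
      uv <- strsplit(k, "|", fixed = TRUE)[[1]]
      if (uv[1] == v) out <- c(out, uv[2])
      if (uv[2] == v) out <- c(out, uv[1])
    }
    intersect(out, alive)
  }
  alive <- nodes
  imp <- setNames(rep(NA_real_, length(nodes)), nodes)
  repeat {
    if (length(alive) == 0) break
    degs <- vapply(alive, function(v) length(nbrs(v, alive)), numeric(1))
    elig <- alive[degs <= d]
    if (length(elig) == 0) break
    dm <- min(degs[elig])
    v <- sort(elig[degs[elig] == dm])[1]
    nb <- nbrs(v, alive)
    k <- length(nb)
    if (k == 1) {
      nw[nb] <- nw[nb] + nw[v] + ew[[ekey(v, nb)]]
    } else if (k >= 2) {
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        key <- ekey(nb[i], nb[j])
        add <- (nw[v] + ew[[ekey(v, nb[i])]] + ew[[ekey(v, nb[j])]]) /
          choose(k, 2)
        ew[[key]] <- (if (is.null(ew[[key]])) 0 else ew[[key]]) + add
      }
    }
    imp[v] <- nw[v]
    for (u in nb) ew[[ekey(v, u)]] <- NULL
    alive <- setdiff(alive, v)
  }
  for (u in alive) {
    inc <- 0
    for (k in names(ew)) {
      uv <- strsplit(k, "|", fixed = TRUE)[[1]]
      if (u %in% uv) inc <- inc + ew[[k]]
    }
    imp[u] <- nw[u] + inc
  }
  imp
}

# random tree on n labelled nodes (random Prufer-style attachment)
random_tree <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("t%02d", seq_len(n))
  edges <- cbind(ids[2:n], ids[sapply(2:n, function(i) sample(i - 1, 1))])
  ppi_network(edges, name = sprintf("tree%d", seed))
}
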