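#' Generate a pair of networks with a planted node correspondence
#'
#' The first network is an Erdos-Renyi draw (or a preferential-attachment
#' graph) on `n_nodes` nodes; the second is a relabeled copy in which a
#' fraction of edges is rewired to random endpoints. The returned
#' `true_mapping` records the relabeling, so at `rewire_fraction = 0` the
#' two networks are isomorphic under it.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param edge_p edge probability of the Erdos-Renyi draw, in `(0,1)`.
#' @param rewire_fraction fraction of the second network's edges replaced by
#'   uniformly random node pairs, in `[0,1]`.
#' @param seed integer seed; identical seeds give identical pairs.
#' @param model `"erdos_renyi"` (default) or `"preferential_attachment"`.
#' @return list with `net1`, `net2` ([ppi_network()]s) and `true_mapping`
#'   (named character vector, net1 node -> net2 node).
#' @export
make_paired_networks <- function(n_nodes, edge_p = 0.05, rewire_fraction = 0,
                                 seed = 1L,
                                 model = c("erdos_renyi",
                                           "preferential_attachment")) {
  model <- match.arg(model)
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 3L) stopf("`n_nodes` must be >= 3")
  if (!is.numeric(edge_p) || edge_p <= 0 || edge_p >= 1) {
    stopf("`edge_p` must be in (0, 1)")
  }
  assert_unit_interval(rewire_fraction, "rewire_fraction")
  wd <- nchar(as.character(n_nodes))
  nodes1 <- sprintf("a%0*d", wd, seq_len(n_nodes))
  nodes2 <- sprintf("b%0*d", wd, seq_len(n_nodes))
  with_seed(seed, {
    pairs <- t(utils::combn(nodes1, 2L))
    edges1 <- if (model == "erdos_renyi") {
      pairs[stats::runif(nrow(pairs)) < edge_p, , drop = FALSE]
    } else {
      # Barabasi-Albert style: each new node attaches to m existing nodes
      # picked proportionally to degree (+1)
      m <- max(1L, round(edge_p * n_nodes / 2))
      deg <- stats::setNames(numeric(n_nodes), nodes1)
      el <- matrix(character(), ncol = 2L)
      for (i in 2:n_nodes) {
        prev <- nodes1[seq_len(i - 1L)]
        k <- min(m, i - 1L)
        tgt <- sample(prev, k, prob = deg[prev] + 1)
        el <- rbind(el, cbind(rep(nodes1[i], k), tgt))
        deg[nodes1[i]] <- deg[nodes1[i]] + k
        deg[tgt] <- deg[tgt] + 1
      }
      el
    }
    if (nrow(edges1) == 0L) {
      # guarantee at least one edge so downstream modules have work to do
      edges1 <- pairs[sample(nrow(pairs), 1L), , drop = FALSE]
    }
    perm <- sample(n_nodes)
    true_mapping <- stats::setNames(nodes2[perm], nodes1)
    edges2 <- cbind(true_mapping[edges1[, 1L]], true_mapping[edges1[, 2L]])
    n_rewire <- floor(rewire_fraction * nrow(edges2))
    if (n_rewire > 0L) {
      # replacements avoid self-loops and existing edges, so rewiring
      # preserves the edge count exactly
      keys <- new.env(parent = emptyenv())
      for (k in edge_key(edges2[, 1L], edges2[, 2L])) assign(k, TRUE, keys)
      idx <- sample(nrow(edges2), n_rewire)
      for (k in idx) {
        rm(list = edge_key(edges2[k, 1L], edges2[k, 2L]), envir = keys)
        repeat {
          cand <- sample(nodes2, 2L)
          ck <- edge_key(cand[1L], cand[2L])
          if (cand[1L] != cand[2L] && !exists(ck, keys, inherits = FALSE)) break
        }
        assign(ck, TRUE, keys)
        edges2[k, ] <- cand
      }
    }
    list(net1 = ppi_network(edges1, nodes = nodes1, name = "net1"),
         net2 = suppressMessages(
           ppi_network(edges2, nodes = nodes2, name = "net2")),
         true_mapping = true_mapping)
  })
}

#' Generate sequence and structure similarity matrices with planted signal
#'
#' True pairs (under `true_mapping`) draw raw scores from a normal
#' distribution with mean `base_mean + signal_mean`; all other pairs from
#' mean `base_mean`; both use standard deviation `noise_sd` and are clipped
#' at 0. The structure matrix omits every pair involving a designated
#' `missing_struct_fraction` of each network's proteins (missing entries,
#' not zeros), emulating proteins without resolved 3D structures.
#'
#' @param true_mapping named character vector (net1 node -> net2 node).
#' @param nodes1,nodes2 node sets of the two networks.
#' @param signal_mean expected raw-score excess of true pairs over non-pairs.
#' @param noise_sd standard deviation of the score noise; 0 separates the
#'   two score populations completely.
#' @param missing_struct_fraction fraction of proteins (in each network)
#'   without structure information, in `[0,1]`.
#' @param seed integer seed.
#' @param base_mean raw-score mean of non-true pairs.
#' @return list with `seq_sim` and `struct_sim`, both unnormalized
#'   [sim_matrix()] objects (`struct_sim` has `NA` for structure-less pairs).
#' @export
make_similarity <- function(true_mapping, nodes1, nodes2, signal_mean = 2,
                            noise_sd = 0.5, missing_struct_fraction = 0.3,
                            seed = 1L, base_mean = 1) {
  assert_unit_interval(missing_struct_fraction, "missing_struct_fraction")
  if (signal_mean <= 0) stopf("`signal_mean` must be positive")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  nodes1 <- sort(nodes1); nodes2 <- sort(nodes2)
  mu <- matrix(base_mean, length(nodes1), length(nodes2),
               dimnames = list(nodes1, nodes2))
  tm <- true_mapping[names(true_mapping) %in% nodes1]
  tm <- tm[tm %in% nodes2]
  mu[cbind(names(tm), unname(tm))] <- base_mean + signal_mean
  with_seed(seed, {
    draw <- function() {
      m <- matrix(pmax(0, stats::rnorm(length(mu), mean = mu, sd = noise_sd)),
                  nrow(mu), ncol(mu), dimnames = dimnames(mu))
      m
    }
    seq_m <- draw()
    struct_m <- draw()
    n_miss1 <- floor(missing_struct_fraction * length(nodes1))
    n_miss2 <- floor(missing_struct_fraction * length(nodes2))
    if (missing_struct_fraction >= 1) {
      n_miss1 <- length(nodes1); n_miss2 <- length(nodes2)
    }
    miss1 <- sample(nodes1, n_miss1)
    miss2 <- sample(nodes2, n_miss2)
    struct_m[miss1, ] <- NA_real_
    struct_m[, miss2] <- NA_real_
    list(seq_sim = sim_matrix(seq_m, role = "sequence"),
         struct_sim = sim_matrix(struct_m, role = "structure"))
  })
}

#' Generate a toy GO DAG with annotations for two protein sets
#'
#' Builds one rooted tree of `is_a` edges per namespace (MF and BP), with
#' the given branching factor and roughly `n_terms` terms each, plus a
#' minority (~10%) of extra `part_of` edges to shallower terms so both edge
#' types occur. Every protein receives `terms_per_protein` terms per
#' namespace; the partner of a true pair shares a `shared_fraction` of its
#' terms (rounded), drawing the rest independently, so `shared_fraction = 1`
#' gives identical term sets and an AFS of exactly 1 under the true mapping.
#'
#' @param n_terms approximate number of terms per namespace (>= 3).
#' @param branching tree branching factor.
#' @param n_proteins number of proteins per set (ignored when `nodes1` is
#'   supplied).
#' @param shared_fraction fraction of each true pair's terms that the two
#'   partners share, in `[0,1]`.
#' @param seed integer seed.
#' @param nodes1,nodes2 optional explicit protein identifiers.
#' @param true_mapping optional named character vector (nodes1 -> nodes2);
#'   defaults to positional pairing.
#' @param terms_per_protein annotations per protein and namespace.
#' @return list with `dag` ([go_dag()]), `ann1`, `ann2`
#'   ([annotation_set()]s).
#' @export
make_toy_ontology <- function(n_terms = 30L, branching = 3L,
                              n_proteins = 10L, shared_fraction = 0.8,
                              seed = 1L, nodes1 = NULL, nodes2 = NULL,
                              true_mapping = NULL, terms_per_protein = 3L) {
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 3L) stopf("`n_terms` must be >= 3")
  assert_unit_interval(shared_fraction, "shared_fraction")
  if (is.null(nodes1)) nodes1 <- sprintf("p%03d", seq_len(n_proteins))
  if (is.null(nodes2)) nodes2 <- sprintf("q%03d", seq_len(length(nodes1)))
  if (is.null(true_mapping)) {
    true_mapping <- stats::setNames(nodes2[seq_len(min(length(nodes1),
                                                       length(nodes2)))],
                                    nodes1[seq_len(min(length(nodes1),
                                                       length(nodes2)))])
  }
  with_seed(seed, {
    terms <- character(0); namespace <- character(0); parents <- list()
    offs <- 0L
    for (ns in c("MF", "BP")) {
      ids <- sprintf("GO:%07d", offs + seq_len(n_terms))
      offs <- offs + n_terms
      terms <- c(terms, ids)
      namespace[ids] <- ns
      for (i in 2:n_terms) {
        parent <- ids[max(1L, ceiling((i - 1L) / branching))]
        parents[[ids[i]]] <- data.frame(parent = parent, rel = "is_a",
                                        stringsAsFactors = FALSE)
      }
      # minority of part_of edges toward strictly shallower terms
      n_po <- max(1L, floor(0.1 * n_terms))
      cand <- sample(3:n_terms, min(n_po, n_terms - 2L))
      for (i in cand) {
        tgt <- ids[sample(max(1L, ceiling((i - 1L) / branching) - 1L), 1L)]
        if (!tgt %in% parents[[ids[i]]]$parent) {
          parents[[ids[i]]] <- rbind(parents[[ids[i]]],
                                     data.frame(parent = tgt, rel = "part_of",
                                                stringsAsFactors = FALSE))
        }
      }
    }
    dag <- go_dag(terms, namespace, parents)
    pick_terms <- function(ns) {
      pool <- terms[namespace[terms] == ns]
      sample(pool, terms_per_protein)
    }
    ann1 <- list(MF = list(), BP = list())
    ann2 <- list(MF = list(), BP = list())
    n_shared <- round(shared_fraction * terms_per_protein)
    for (ns in c("MF", "BP")) {
      pool <- terms[namespace[terms] == ns]
      for (u in nodes1) ann1[[ns]][[u]] <- pick_terms(ns)
      for (v in nodes2) {
        u <- names(true_mapping)[true_mapping == v]
        if (length(u) == 1L) {
          shared <- if (n_shared > 0L) {
            sample(ann1[[ns]][[u]], n_shared)
          } else character(0)
          fresh <- sample(setdiff(pool, ann1[[ns]][[u]]),
                          terms_per_protein - n_shared)
          ann2[[ns]][[v]] <- c(shared, fresh)
        } else {
          ann2[[ns]][[v]] <- sample(pool, terms_per_protein)
        }
      }
    }
    list(dag = dag,
         ann1 = annotation_set(mf = ann1$MF, bp = ann1$BP),
         ann2 = annotation_set(mf = ann2$MF, bp = ann2$BP))
  })
}

#' Write a GO DAG as an OBO 1.2 flat file
#'
#' @param dag a [go_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  ns_long <- c(MF = "molecular_function", BP = "biological_process",
               CC = "cellular_component")
  out <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: term ", t),
             paste0("namespace: ", ns_long[[dag$namespace[[t]]]]))
    ps <- dag$parents[[t]]
    if (!is.null(ps)) {
      for (k in seq_len(nrow(ps))) {
        out <- c(out, if (ps$rel[k] == "is_a") {
          paste0("is_a: ", ps$parent[k])
        } else {
          paste0("relationship: part_of ", ps$parent[k])
        })
      }
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write an annotation set as a GAF 2.2 file
#'
#' @param ann an [annotation_set()].
#' @param path output file path.
#' @param db database label for column 1.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(ann, path, db = "SYN") {
  stopifnot(inherits(ann, "annotation_set"))
  rows <- character(0)
  for (ns in c("MF", "BP")) {
    aspect <- c(MF = "F", BP = "P")[[ns]]
    for (p in names(ann[[ns]])) {
      for (t in ann[[ns]][[p]]) {
        rows <- c(rows, paste(db, p, p, "", t, "SYN:0000001", "IEA", "",
                              aspect, "", "", "protein", "taxon:0000", "20200101",
                              db, "", "", sep = "\t"))
      }
    }
  }
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' Generate a complete synthetic benchmark bundle
#'
#' Assembles everything the pipeline consumes: paired networks with a
#' planted correspondence, sequence/structure similarity matrices whose
#' true pairs score higher on average, and a toy GO DAG with annotations
#' shared by true pairs. Identical seeds and parameters give identical
#' bundles.
#'
#' @inheritParams make_paired_networks
#' @inheritParams make_similarity
#' @inheritParams make_toy_ontology
#' @return object of class `salign_bundle`: list with `net1`, `net2`,
#'   `true_mapping`, `seq_sim`, `struct_sim`, `dag`, `ann1`, `ann2` and
#'   `params` (the generation parameters).
#' @export
make_bundle <- function(n_nodes = 100L, edge_p = 0.05, rewire_fraction = 0.1,
                        signal_mean = 2, noise_sd = 0.5,
                        missing_struct_fraction = 0.3, n_terms = 30L,
                        branching = 3L, shared_fraction = 0.8, seed = 1L) {
  nets <- make_paired_networks(n_nodes, edge_p, rewire_fraction, seed = seed)
  sims <- make_similarity(nets$true_mapping, nets$net1$nodes, nets$net2$nodes,
                          signal_mean = signal_mean, noise_sd = noise_sd,
                          missing_struct_fraction = missing_struct_fraction,
                          seed = seed + 1L)
  onto <- make_toy_ontology(n_terms = n_terms, branching = branching,
                            shared_fraction = shared_fraction,
                            seed = seed + 2L,
                            nodes1 = nets$net1$nodes,
                            nodes2 = nets$net2$nodes,
                            true_mapping = nets$true_mapping)
  structure(c(nets, sims, onto,
              list(params = list(n_nodes = n_nodes, edge_p = edge_p,
                                 rewire_fraction = rewire_fraction,
                                 signal_mean = signal_mean,
                                 noise_sd = noise_sd,
                                 missing_struct_fraction = missing_struct_fraction,
                                 n_terms = n_terms, branching = branching,
                                 shared_fraction = shared_fraction,
                                 seed = seed))),
            class = "salign_bundle")
}

#' Write a synthetic bundle to a fixture directory
#'
#' Writes the eight files the command-line interface consumes: `net1.tsv`,
#' `net2.tsv`, `truth.tsv`, `seqsim.tsv`, `structsim.tsv`, `toy.obo`,
#' `ann1.gaf`, `ann2.gaf`.
#'
#' @param bundle a `salign_bundle` from [make_bundle()].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "salign_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(dir, x)
  write_edgelist(bundle$net1, f("net1.tsv"))
  write_edgelist(bundle$net2, f("net2.tsv"))
  writeLines(paste(names(bundle$true_mapping), bundle$true_mapping, "1",
                   sep = "\t"), f("truth.tsv"))
  write_similarity_tsv(bundle$seq_sim, f("seqsim.tsv"))
  write_similarity_tsv(bundle$struct_sim, f("structsim.tsv"))
  write_obo(bundle$dag, f("toy.obo"))
  write_gaf(bundle$ann1, f("ann1.gaf"))
  write_gaf(bundle$ann2, f("ann2.gaf"))
  invisible(file.path(dir, c("net1.tsv", "net2.tsv", "truth.tsv",
                             "seqsim.tsv", "structsim.tsv", "toy.obo",
                             "ann1.gaf", "ann2.gaf")))
}

#' Fraction of the planted correspondence recovered by an alignment
#'
#' @param alignment a [ppi_alignment()].
#' @param true_mapping named character vector (net1 node -> net2 node).
#' @return fraction in `[0,1]` of true pairs present in the alignment.
#' @export
recovery_rate <- function(alignment, true_mapping) {
  stopifnot(inherits(alignment, "ppi_alignment"))
  if (length(true_mapping) == 0L) return(NA_real_)
  g <- alignment_mapping(alignment)
  hits <- sum(g[names(true_mapping)] == true_mapping, na.rm = TRUE)
  hits / length(true_mapping)
}
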