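#' Run the full alignment pipeline
#'
#' Computes per-node topological importances for both networks
#' ([min_degree_reduce()]), the topological similarity matrix
#' ([topo_similarity()]), the normalized biological matrix
#' ([normalize_sim()], [combine_bio()]), fuses them into the final
#' alignment score ([alignment_scores()]) and aligns the networks by the
#' greedy or Monte Carlo algorithm. With `method = "mc"` and
#' `mc_runs = k`, k alignments are produced with seeds `seed, seed + 1,
#' ..., seed + k - 1`, giving reproducible alternate alignments.
#'
#' @param net1,net2 [ppi_network()] objects or paths to edge-list files.
#' @param seq_sim [sim_matrix()] (role `"sequence"`) or path to a 3-column
#'   similarity TSV of raw sequence scores.
#' @param struct_sim optional [sim_matrix()] (role `"structure"`) or path;
#'   `NULL` when no structure information is available.
#' @param params a [salign_params()].
#' @param method `"greedy"` or `"mc"`.
#' @param mc_runs number of Monte Carlo alignments (only with
#'   `method = "mc"`).
#' @return object of class `salign_result`: list with `alignments` (list of
#'   [ppi_alignment()]s; length 1 for greedy), `scores` (the fused
#'   [sim_matrix()]), `topo` (list of the two `topo_weights`), `params`,
#'   `method` and `seeds`.
#' @export
salign_align <- function(net1, net2, seq_sim, struct_sim = NULL,
                         params = salign_params(),
                         method = c("greedy", "mc"), mc_runs = 1L) {
  method <- match.arg(method)
  mc_runs <- as.integer(mc_runs)
  if (is.na(mc_runs) || mc_runs < 1L) stopf("`mc_runs` must be >= 1")
  if (mc_runs > 1L && method != "mc") {
    stopf("`mc_runs` > 1 requires method = \"mc\"")
  }
  stopifnot(inherits(params, "salign_params"))
  if (is.character(net1)) net1 <- read_edgelist(net1)
  if (is.character(net2)) net2 <- read_edgelist(net2)
  if (is.character(seq_sim)) {
    seq_sim <- read_similarity_tsv(seq_sim, role = "sequence")
  }
  if (is.character(struct_sim)) {
    struct_sim <- read_similarity_tsv(struct_sim, role = "structure")
  }

  tw1 <- min_degree_reduce(net1, d = params$d)
  tw2 <- min_degree_reduce(net2, d = params$d)
  topo <- topo_similarity(tw1, tw2)
  seq_n <- if (sim_normalized(seq_sim)) seq_sim else normalize_sim(seq_sim)
  struct_n <- if (is.null(struct_sim) || all(is.na(struct_sim))) {
    NULL
  } else if (sim_normalized(struct_sim)) {
    struct_sim
  } else {
    normalize_sim(struct_sim)
  }
  bio <- combine_bio(seq_n, struct_n, beta = params$beta)
  scores <- alignment_scores(topo, bio, alpha = params$alpha)

  if (method == "greedy") {
    alignments <- list(greedy_align(scores, net1, net2))
    seeds <- integer(0)
  } else {
    seeds <- params$seed + seq_len(mc_runs) - 1L
    alignments <- lapply(seeds, function(s) {
      p <- params
      p$seed <- s
      mc_align(scores, net1, net2, p)
    })
  }
  structure(list(alignments = alignments, scores = scores,
                 topo = list(tw1, tw2), params = params, method = method,
                 seeds = seeds),
            class = "salign_result")
}

#' @export
print.salign_result <- function(x, ...) {
  cat(sprintf("<salign_result: %s, %d alignment(s) of %s pairs>\n",
              x$method, length(x$alignments),
              paste(vapply(x$alignments, nrow, integer(1)), collapse = "/")))
  invisible(x)
}

#' Evaluate one or more alignments against GO annotations
#'
#' Computes the Average Functional Similarity and percentage of aligned
#' nodes per namespace for every alignment, plus the across-run mean and
#' standard deviation of the AFS when several alignments are supplied
#' (e.g. Monte Carlo runs).
#'
#' @param alignments a [ppi_alignment()] or list of them (or paths to
#'   alignment TSVs).
#' @param dag a [go_dag()] or path to an OBO file.
#' @param ann1,ann2 [annotation_set()]s or paths to GAF files, for the
#'   smaller and larger network respectively.
#' @param namespaces character vector among `"MF"`, `"BP"`.
#' @param nodes1 optional smaller-network node universe for the percentage
#'   denominator (see [afs()]).
#' @return object of class `salign_evaluation`: list with `reports` (per
#'   alignment, per namespace [afs()] reports) and `summary` (data.frame
#'   with namespace, mean AFS, sd AFS across runs, mean pct aligned).
#' @export
salign_evaluate <- function(alignments, dag, ann1, ann2,
                            namespaces = c("MF", "BP"), nodes1 = NULL) {
  if (inherits(alignments, "ppi_alignment")) alignments <- list(alignments)
  alignments <- lapply(alignments, function(a) {
    if (is.character(a)) read_alignment(a) else a
  })
  if (is.character(dag)) dag <- parse_obo(dag)
  if (is.character(ann1)) ann1 <- parse_gaf(ann1, dag)
  if (is.character(ann2)) ann2 <- parse_gaf(ann2, dag)
  namespaces <- match.arg(namespaces, several.ok = TRUE)

  reports <- lapply(alignments, function(al) {
    stats::setNames(lapply(namespaces, function(ns) {
      afs(al, ann1, ann2, dag, namespace = ns, nodes1 = nodes1)
    }), namespaces)
  })
  summary <- do.call(rbind, lapply(namespaces, function(ns) {
    vals <- vapply(reports, function(r) r[[ns]]$afs, numeric(1))
    pcts <- vapply(reports, function(r) r[[ns]]$pct_aligned_nodes, numeric(1))
    data.frame(namespace = ns,
               afs_mean = mean(vals),
               afs_sd = if (length(vals) > 1L) stats::sd(vals) else 0,
               pct_aligned_mean = mean(pcts),
               n_runs = length(vals),
               stringsAsFactors = FALSE)
  }))
  structure(list(reports = reports, summary = summary),
            class = "salign_evaluation")
}

#' @export
print.salign_evaluation <- function(x, ...) {
  cat("<salign_evaluation>\n")
  print(x$summary)
  invisible(x)
}
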