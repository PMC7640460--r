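#' Construct a PPI network
#'
#' A `ppi_network` is a simple undirected graph: protein identifiers as nodes
#' (opaque, case-sensitive strings) and unordered node pairs as edges.
#' Self-loops are dropped and duplicate edges collapse to a single edge;
#' both removals are reported via [message()]. Node weights default to 0 and
#' edge weights to 1, the initial state required by the minimum-degree
#' reduction (see [min_degree_reduce()]).
#'
#' @param edges a two-column character matrix or data.frame of node pairs
#'   (one row per interaction), or `NULL` for an edgeless network.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node identifiers; isolated nodes are retained as alignable.
#' @param name label for the network.
#' @return an object of class `ppi_network` with fields `name`, `nodes`
#'   (sorted character vector) and `edges` (two-column character matrix with
#'   `from < to` lexicographically, deduplicated).
#' @seealso [read_edgelist()], [write_edgelist()]
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, name = "network") {
  if (is.null(edges)) {
    em <- matrix(character(), ncol = 2L, dimnames = list(NULL, c("from", "to")))
  } else {
    em <- as.matrix(edges)
    if (ncol(em) < 2L) stopf("`edges` must have at least two columns")
    em <- cbind(as.character(em[, 1L]), as.character(em[, 2L]))
    loops <- em[, 1L] == em[, 2L]
    if (any(loops)) {
      message(sum(loops), " self-loop(s) dropped")
      em <- em[!loops, , drop = FALSE]
    }
    em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
    dup <- duplicated(edge_key(em[, 1L], em[, 2L]))
    if (any(dup)) {
      message(sum(dup), " duplicate edge(s) collapsed")
      em <- em[!dup, , drop = FALSE]
    }
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
    colnames(em) <- c("from", "to")
  }
  all_nodes <- sort(unique(c(as.character(nodes), as.vector(em))))
  structure(list(name = name, nodes = all_nodes, edges = em),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network '%s': %d nodes, %d edges>\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

# adjacency list: node -> sorted character vector of neighbours
adjacency_list <- function(net) {
  adj <- lapply(stats::setNames(vector("list", n_nodes(net)), net$nodes),
                function(x) character())
  if (n_edges(net) > 0L) {
    fr <- split(net$edges[, 2L], net$edges[, 1L])
    to <- split(net$edges[, 1L], net$edges[, 2L])
    for (u in names(fr)) adj[[u]] <- c(adj[[u]], fr[[u]])
    for (u in names(to)) adj[[u]] <- c(adj[[u]], to[[u]])
    adj <- lapply(adj, function(v) sort(unique(v)))
  }
  adj
}

#' Read a PPI network from a tab-separated edge list
#'
#' Each non-comment line carries at least two tab-separated fields: the two
#' interacting protein identifiers (extra columns are ignored). An optional
#' single header line (e.g. `Uniprot_A<TAB>Uniprot_B`) is auto-detected and
#' skipped: the first line counts as a header when both lead fields are
#' purely alphabetic/underscore tokens that occur nowhere else in the file
#' as a node. Duplicate edges and self-loops are removed as in
#' [ppi_network()].
#'
#' @param path path to the edge-list file.
#' @param comment_prefix lines starting with this character are ignored.
#' @param name network label; defaults to the file name.
#' @return a [ppi_network()].
#' @export
read_edgelist <- function(path, comment_prefix = "#", name = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, comment_prefix) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("no edges in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, function(f) length(f) < 2L ||
                        !nzchar(f[1L]) || !nzchar(f[2L]), logical(1)))
  if (length(bad)) {
    stopf("malformed line %d in %s: need >= 2 tab-separated fields",
          lineno[bad[1L]], path)
  }
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  if (length(a) >= 1L) {
    word <- grepl("^[A-Za-z_]+$", a[1L]) && grepl("^[A-Za-z_]+$", b[1L])
    reappears <- a[1L] %in% c(a[-1L], b[-1L]) || b[1L] %in% c(a[-1L], b[-1L])
    if (word && !reappears && length(a) > 1L) {
      a <- a[-1L]
      b <- b[-1L]
    }
  }
  if (length(a) == 0L) stopf("no edges in %s", path)
  ppi_network(cbind(a, b), name = name %||% basename(path))
}

#' Write a network as a tab-separated edge list
#'
#' @param net a [ppi_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Construct an alignment object
#'
#' An alignment is an injective (one-to-one) mapping from nodes of the
#' smaller network into nodes of the larger network, with the final
#' alignment score attached to each pair.
#'
#' @param node1 character vector of smaller-network nodes.
#' @param node2 character vector of larger-network partners (same length).
#' @param score numeric vector of per-pair alignment scores.
#' @return object of class `ppi_alignment`: a data.frame with columns
#'   `node1`, `node2`, `score`, in construction order, plus a named-vector
#'   `mapping` attribute (`node1 -> node2`).
#' @export
ppi_alignment <- function(node1 = character(), node2 = character(),
                          score = numeric()) {
  node1 <- as.character(node1)
  node2 <- as.character(node2)
  score <- as.numeric(score)
  stopifnot(length(node1) == length(node2), length(node1) == length(score))
  if (anyDuplicated(node1) || anyDuplicated(node2)) {
    stopf("alignment must be one-to-one: duplicated node in mapping")
  }
  out <- data.frame(node1 = node1, node2 = node2, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "mapping") <- stats::setNames(node2, node1)
  class(out) <- c("ppi_alignment", "data.frame")
  out
}

#' Extract the node mapping of an alignment
#'
#' @param alignment a [ppi_alignment()].
#' @return named character vector: names are smaller-network nodes, values
#'   their aligned partners.
#' @export
alignment_mapping <- function(alignment) {
  stopifnot(inherits(alignment, "ppi_alignment"))
  stats::setNames(alignment$node2, alignment$node1)
}

#' Write an alignment to a 3-column TSV
#'
#' Columns `node_g1 <TAB> node_g2 <TAB> score`, no header, rows ordered by
#' the smaller-network node identifier. An empty alignment produces an
#' empty file.
#'
#' @param alignment a [ppi_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "ppi_alignment"))
  o <- order(alignment$node1)
  writeLines(paste(alignment$node1[o], alignment$node2[o],
                   format(alignment$score[o], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   sep = "\t"),
             path)
  invisible(path)
}

#' Read an alignment written by [write_alignment()]
#'
#' @param path path to a 3-column TSV (node1, node2, score), no header.
#' @return a [ppi_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(ppi_alignment())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad)) stopf("malformed alignment line %d in %s", bad[1L], path)
  ppi_alignment(vapply(fields, `[`, character(1), 1L),
                vapply(fields, `[`, character(1), 2L),
                as.numeric(vapply(fields, `[`, character(1), 3L)))
}

#' Order two networks as (smaller, larger)
#'
#' The smaller network is always the domain of the alignment mapping. Ties
#' on node count are broken by edge count, then by name.
#'
#' @param net1,net2 two [ppi_network()] objects.
#' @return list with elements `small`, `large` and logical `swapped`
#'   (`TRUE` when `net2` is the smaller network).
#' @export
order_networks <- function(net1, net2) {
  key <- function(n) c(n_nodes(n), n_edges(n))
  k1 <- key(net1); k2 <- key(net2)
  swapped <- if (k1[1L] != k2[1L]) {
    k1[1L] > k2[1L]
  } else if (k1[2L] != k2[2L]) {
    k1[2L] > k2[2L]
  } else {
    net1$name > net2$name
  }
  if (swapped) list(small = net2, large = net1, swapped = TRUE)
  else list(small = net1, large = net2, swapped = FALSE)
}
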