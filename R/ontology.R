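#' Construct a GO DAG
#'
#' Holds the term graph used by the Wang semantic similarity: terms, typed
#' parent edges (`is_a`, `part_of`), and the namespace of each term
#' (`MF`, `BP`, `CC`). Cross-namespace parent edges are dropped with a
#' message; a cycle in the parent graph is an error.
#'
#' @param terms character vector of term identifiers.
#' @param namespace named character vector mapping each term to `"MF"`,
#'   `"BP"` or `"CC"`.
#' @param parents named list: for each term, a data.frame with columns
#'   `parent` and `rel` (`"is_a"` or `"part_of"`). Terms without parents may
#'   be omitted.
#' @param alt_map named character vector mapping alternative/obsolete term
#'   identifiers to their primary replacements (may be empty).
#' @return object of class `go_dag`.
#' @export
go_dag <- function(terms, namespace, parents = list(),
                   alt_map = character()) {
  terms <- unique(as.character(terms))
  if (!all(terms %in% names(namespace))) {
    stopf("every term needs a namespace")
  }
  namespace <- namespace[terms]
  if (!all(namespace %in% c("MF", "BP", "CC"))) {
    stopf("namespace values must be MF, BP or CC")
  }
  parents <- parents[intersect(names(parents), terms)]
  dropped <- 0L
  for (t in names(parents)) {
    p <- parents[[t]]
    keep <- p$parent %in% terms & namespace[p$parent] == namespace[t]
    dropped <- dropped + sum(!keep)
    p <- p[keep & !duplicated(p$parent), , drop = FALSE]
    rownames(p) <- NULL
    parents[[t]] <- p
  }
  if (dropped > 0L) {
    message(dropped, " unknown or cross-namespace parent edge(s) dropped")
  }
  parents <- parents[vapply(parents, nrow, integer(1)) > 0L]
  dag <- structure(list(terms = terms, namespace = namespace,
                        parents = parents, alt_map = alt_map),
                   class = "go_dag")
  cyc <- find_cycle_member(dag)
  if (!is.null(cyc)) stopf("parent graph is cyclic (involves term %s)", cyc)
  dag
}

# returns a term on a cycle, or NULL if the parent graph is acyclic
find_cycle_member <- function(dag) {
  state <- stats::setNames(integer(length(dag$terms)), dag$terms) # 0/1/2
  for (start in dag$terms) {
    if (state[start] != 0L) next
    stack <- list(c(start, 0L))  # term, next-parent cursor handled below
    path <- character(0)
    visit <- function(t) {
      state[t] <<- 1L
      path <<- c(path, t)
      ps <- dag$parents[[t]]
      if (!is.null(ps)) {
        for (p in ps$parent) {
          if (state[p] == 1L) return(p)
          if (state[p] == 0L) {
            r <- visit(p)
            if (!is.null(r)) return(r)
          }
        }
      }
      state[t] <<- 2L
      path <<- path[-length(path)]
      NULL
    }
    r <- visit(start)
    if (!is.null(r)) return(r)
  }
  NULL
}

#' @export
print.go_dag <- function(x, ...) {
  ns <- table(factor(x$namespace, levels = c("MF", "BP", "CC")))
  cat(sprintf("<go_dag: %d terms (MF %d, BP %d, CC %d), %d with parents>\n",
              length(x$terms), ns[["MF"]], ns[["BP"]], ns[["CC"]],
              length(x$parents)))
  invisible(x)
}

#' Parse an OBO 1.2 flat file into a GO DAG
#'
#' Reads `[Term]` stanzas, keeping `is_a` and `relationship: part_of`
#' edges. Obsolete terms are excluded from the DAG; their `replaced_by`
#' targets and all `alt_id`s are recorded so annotations can be mapped up
#' to primary identifiers. Namespaces are mapped to `MF`/`BP`/`CC`.
#'
#' @param path path to the OBO file.
#' @return a [go_dag()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  # strip trailing comments (" ! ...") and whitespace
  lines <- sub("\\s*!.*$", "", lines)
  breaks <- c(grep("^\\[", lines), length(lines) + 1L)
  ns_map <- c(molecular_function = "MF", biological_process = "BP",
              cellular_component = "CC")
  terms <- character(0); namespace <- character(0)
  parents <- list(); alt_map <- character(0)
  for (i in seq_along(breaks[-length(breaks)])) {
    s <- breaks[i]; e <- breaks[i + 1L] - 1L
    if (lines[s] != "[Term]") next
    body <- lines[(s + 1L):e]
    val <- function(tag) {
      hits <- body[startsWith(body, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", hits))
    }
    id <- val("id")[1L]
    if (is.na(id)) next
    obsolete <- any(val("is_obsolete") == "true")
    alts <- val("alt_id")
    if (obsolete) {
      rep_by <- val("replaced_by")
      if (length(rep_by)) alt_map[id] <- rep_by[1L]
      next
    }
    ns <- ns_map[val("namespace")[1L]]
    if (is.na(ns)) next
    isa <- vapply(strsplit(val("is_a"), "\\s+"), `[`, character(1), 1L)
    rel <- val("relationship")
    po <- character(0)
    if (length(rel)) {
      relf <- strsplit(rel, "\\s+")
      po <- vapply(relf[vapply(relf, `[`, character(1), 1L) == "part_of"],
                   `[`, character(1), 2L)
    }
    terms <- c(terms, id)
    namespace[id] <- ns
    if (length(alts)) alt_map[alts] <- id
    if (length(isa) + length(po)) {
      parents[[id]] <- data.frame(
        parent = c(isa, po),
        rel = c(rep("is_a", length(isa)), rep("part_of", length(po))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(terms) == 0L) stopf("no usable [Term] stanzas in %s", path)
  go_dag(terms, namespace, parents, alt_map)
}

#' Construct an annotation set
#'
#' @param mf,bp named lists: protein id -> character vector of term ids in
#'   the MF / BP namespace.
#' @return object of class `annotation_set` with elements `MF` and `BP`.
#' @export
annotation_set <- function(mf = list(), bp = list()) {
  clean <- function(x) lapply(x, function(v) sort(unique(as.character(v))))
  structure(list(MF = clean(mf), BP = clean(bp)), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d proteins MF, %d proteins BP>\n",
              length(x$MF), length(x$BP)))
  invisible(x)
}

#' Parse a GAF 2.x annotation file
#'
#' Keeps protein identifier (column 2), GO term (column 5) and aspect
#' (column 9: `F` -> MF, `P` -> BP; `C` dropped). Rows with a `NOT`
#' qualifier are dropped. Terms unknown to the DAG are dropped (after
#' mapping alternative/obsolete ids up to their replacements); malformed
#' rows are skipped with a message. All evidence codes are accepted.
#'
#' @param path path to the GAF file (`!`-prefixed comment lines ignored).
#' @param dag a [go_dag()] used to validate and remap terms.
#' @return an [annotation_set()].
#' @export
parse_gaf <- function(path, dag) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  stopifnot(inherits(dag, "go_dag"))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("no annotation rows in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 9L
  if (any(!ok)) message(sum(!ok), " malformed GAF row(s) skipped")
  fields <- fields[ok]
  if (length(fields) == 0L) stopf("zero usable annotation rows in %s", path)
  protein <- vapply(fields, `[`, character(1), 2L)
  qualifier <- vapply(fields, `[`, character(1), 4L)
  term <- vapply(fields, `[`, character(1), 5L)
  aspect <- vapply(fields, `[`, character(1), 9L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier) & aspect %in% c("F", "P")
  protein <- protein[keep]; term <- term[keep]; aspect <- aspect[keep]
  # map alt/obsolete ids up to primary ids where the OBO provides them
  mapped <- term %in% names(dag$alt_map)
  term[mapped] <- dag$alt_map[term[mapped]]
  known <- term %in% dag$terms
  if (any(!known)) message(sum(!known), " annotation(s) to unknown terms dropped")
  protein <- protein[known]; term <- term[known]; aspect <- aspect[known]
  if (length(protein) == 0L) stopf("zero usable annotation rows in %s", path)
  grab <- function(a) {
    sel <- aspect == a
    if (!any(sel)) return(list())
    split(term[sel], protein[sel])
  }
  annotation_set(mf = grab("F"), bp = grab("P"))
}

# Wang S-values: semantic contribution of every ancestor of `term`
# (including itself), propagated multiplicatively along the best path with
# per-relation contribution factors.
wang_sv <- function(dag, term,
                    weights = c(is_a = 0.8, part_of = 0.6)) {
  sv <- stats::setNames(1.0, term)
  queue <- term
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    ps <- dag$parents[[t]]
    if (is.null(ps)) next
    for (k in seq_len(nrow(ps))) {
      p <- ps$parent[k]
      cand <- unname(weights[ps$rel[k]]) * sv[[t]]
      if (is.na(sv[p]) || cand > sv[[p]]) {
        sv[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  sv
}

#' Wang graph-based semantic similarity of two GO terms
#'
#' Each term's semantics are the S-values of its ancestor closure: the term
#' itself contributes 1, and each ancestor contributes the maximum product
#' of edge factors (0.8 per `is_a`, 0.6 per `part_of` edge) along a path
#' down to the term. The similarity is the summed S-values of the shared
#' ancestors (from both sides) divided by the two terms' total semantic
#' values, giving a score in `[0,1]` that is 1 for identical terms and 0
#' for terms sharing no ancestor.
#'
#' @param dag a [go_dag()].
#' @param a,b term identifiers in the same namespace.
#' @param weights per-relation contribution factors.
#' @return similarity in `[0,1]`.
#' @export
wang_term_similarity <- function(dag, a, b,
                                 weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(inherits(dag, "go_dag"))
  if (!a %in% dag$terms) stopf("term not in DAG: %s", a)
  if (!b %in% dag$terms) stopf("term not in DAG: %s", b)
  if (dag$namespace[[a]] != dag$namespace[[b]]) {
    stopf("namespace mismatch: %s (%s) vs %s (%s)", a, dag$namespace[[a]],
          b, dag$namespace[[b]])
  }
  sa <- wang_sv(dag, a, weights)
  sb <- wang_sv(dag, b, weights)
  common <- intersect(names(sa), names(sb))
  if (length(common) == 0L) return(0)
  (sum(sa[common]) + sum(sb[common])) / (sum(sa) + sum(sb))
}

#' Best-Match-Average similarity of two term sets
#'
#' Symmetric BMA: the mean of (i) the average over terms of `termsA` of
#' their best match in `termsB` and (ii) the average over `termsB` of their
#' best match in `termsA`.
#'
#' @param dag a [go_dag()].
#' @param termsA,termsB non-empty character vectors of term ids in the same
#'   namespace.
#' @param weights per-relation contribution factors for
#'   [wang_term_similarity()].
#' @return similarity in `[0,1]`.
#' @export
bma_similarity <- function(dag, termsA, termsB,
                           weights = c(is_a = 0.8, part_of = 0.6)) {
  termsA <- unique(as.character(termsA))
  termsB <- unique(as.character(termsB))
  if (length(termsA) == 0L || length(termsB) == 0L) {
    stopf("BMA is undefined for empty term sets")
  }
  m <- matrix(0, length(termsA), length(termsB))
  for (i in seq_along(termsA)) {
    for (j in seq_along(termsB)) {
      m[i, j] <- wang_term_similarity(dag, termsA[i], termsB[j], weights)
    }
  }
  mean(c(mean(apply(m, 1L, max)), mean(apply(m, 2L, max))))
}

#' Average Functional Similarity of an alignment
#'
#' For every aligned pair where both proteins carry at least one annotation
#' in the namespace, the pair's semantic similarity is the BMA of its two
#' term sets; the AFS is the mean over those scored pairs. Pairs where
#' either protein lacks annotations are excluded from the mean (missing
#' knowledge is not dissimilarity). The percentage of aligned nodes is
#' `100 * scored pairs / annotated smaller-network nodes` for the namespace.
#'
#' @param alignment a [ppi_alignment()].
#' @param ann1,ann2 [annotation_set()]s for the smaller and larger network.
#' @param dag a [go_dag()].
#' @param namespace `"MF"` or `"BP"`.
#' @param nodes1 optional character vector: the smaller network's node set,
#'   used as the universe for the percentage denominator. Defaults to the
#'   proteins annotated in `ann1` for the namespace.
#' @return object of class `afs_report`: list with `namespace`, `afs` (`NA`
#'   when no pair is scorable), `pct_aligned_nodes`, `n_pairs_scored`,
#'   `n_annotated` and `per_pair` (data.frame `node1`, `node2`, `sim`).
#' @export
afs <- function(alignment, ann1, ann2, dag, namespace = c("MF", "BP"),
                nodes1 = NULL) {
  namespace <- match.arg(namespace)
  stopifnot(inherits(alignment, "ppi_alignment"),
            inherits(ann1, "annotation_set"),
            inherits(ann2, "annotation_set"),
            inherits(dag, "go_dag"))
  a1 <- ann1[[namespace]]; a2 <- ann2[[namespace]]
  annotated <- names(a1)[lengths(a1) > 0L]
  if (!is.null(nodes1)) annotated <- intersect(annotated, nodes1)
  sims <- numeric(0); p1 <- character(0); p2 <- character(0)
  for (k in seq_len(nrow(alignment))) {
    u <- alignment$node1[k]; v <- alignment$node2[k]
    t1 <- a1[[u]]; t2 <- a2[[v]]
    if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2)) next
    sims <- c(sims, bma_similarity(dag, t1, t2))
    p1 <- c(p1, u); p2 <- c(p2, v)
  }
  structure(list(
    namespace = namespace,
    afs = if (length(sims)) mean(sims) else NA_real_,
    pct_aligned_nodes = if (length(annotated)) {
      100 * length(sims) / length(annotated)
    } else NA_real_,
    n_pairs_scored = length(sims),
    n_annotated = length(annotated),
    per_pair = data.frame(node1 = p1, node2 = p2, sim = sims,
                          stringsAsFactors = FALSE)),
    class = "afs_report")
}

#' @export
print.afs_report <- function(x, ...) {
  cat(sprintf("<afs_report %s: AFS=%s over %d pairs, %.1f%% of %d annotated nodes>\n",
              x$namespace,
              if (is.na(x$afs)) "NA" else sprintf("%.4f", x$afs),
              x$n_pairs_scored,
              if (is.na(x$pct_aligned_nodes)) NA else x$pct_aligned_nodes,
              x$n_annotated))
  invisible(x)
}

#' Write an AFS report as TSV
#'
#' Per-pair rows (`node1`, `node2`, `sim`) followed by a `#`-prefixed
#' summary block (namespace, AFS, percentage, counts).
#'
#' @param report an `afs_report` from [afs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_afs_report <- function(report, path) {
  stopifnot(inherits(report, "afs_report"))
  body <- if (nrow(report$per_pair)) {
    paste(report$per_pair$node1, report$per_pair$node2,
          format(report$per_pair$sim, digits = 15, trim = TRUE), sep = "\t")
  } else character(0)
  summary_block <- c(
    sprintf("# namespace\t%s", report$namespace),
    sprintf("# AFS\t%s", format(report$afs, digits = 15)),
    sprintf("# pct_aligned_nodes\t%s",
            format(report$pct_aligned_nodes, digits = 15)),
    sprintf("# n_pairs_scored\t%d", report$n_pairs_scored),
    sprintf("# n_annotated\t%d", report$n_annotated))
  writeLines(c(body, summary_block), path)
  invisible(path)
}
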