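#' Construct a cross-network similarity matrix
#'
#' A `sim_matrix` stores pairwise scores between nodes of two networks as a
#' dense numeric matrix (rows: first network, columns: second network).
#' `NA` marks a missing entry. For the `sequence`, `topological`,
#' `biological` and `alignment` roles a missing entry is semantically 0;
#' for the `structure` role it means "no structure available for at least
#' one member of the pair" and is distinguishable from an explicit 0.
#'
#' @param entries numeric matrix with dimnames (node ids).
#' @param role one of `"sequence"`, `"structure"`, `"biological"`,
#'   `"topological"`, `"alignment"`.
#' @param normalized logical: are all non-missing entries already in `[0,1]`?
#' @return object of class `sim_matrix`.
#' @export
sim_matrix <- function(entries, role, normalized = FALSE) {
  role <- match.arg(role, c("sequence", "structure", "biological",
                            "topological", "alignment"))
  entries <- as.matrix(entries)
  if (is.null(rownames(entries)) || is.null(colnames(entries))) {
    stopf("sim_matrix entries must have row and column names")
  }
  entries <- entries[order(rownames(entries)), order(colnames(entries)),
                     drop = FALSE]
  if (any(entries < 0, na.rm = TRUE)) stopf("similarity scores must be >= 0")
  if (normalized && any(entries > 1, na.rm = TRUE)) {
    stopf("normalized sim_matrix has entries > 1")
  }
  structure(entries, class = c("sim_matrix", "matrix", "array"),
            role = role, normalized = normalized)
}

sim_role <- function(sim) attr(sim, "role")
sim_normalized <- function(sim) isTRUE(attr(sim, "normalized"))

#' @export
print.sim_matrix <- function(x, ...) {
  cat(sprintf("<sim_matrix role=%s %dx%d normalized=%s (%d entries)>\n",
              sim_role(x), nrow(x), ncol(x), sim_normalized(x),
              sum(!is.na(x))))
  invisible(x)
}

#' Read a 3-column similarity TSV
#'
#' Format: `id1 <TAB> id2 <TAB> score`, no header, `#`-prefixed comment
#' lines allowed. Duplicate `(id1, id2)` rows keep the maximum score (a
#' message reports how many were collapsed).
#'
#' @param path input file path.
#' @param role role tag for the resulting matrix (see [sim_matrix()]).
#' @return an unnormalized [sim_matrix()]; pairs absent from the file are
#'   `NA` (missing).
#' @export
read_similarity_tsv <- function(path, role = "sequence") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("no similarity entries in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad)) {
    stopf("malformed row at line %d in %s: need id1, id2, score",
          lineno[bad[1L]], path)
  }
  id1 <- vapply(fields, `[`, character(1), 1L)
  id2 <- vapply(fields, `[`, character(1), 2L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(score)) {
    stopf("malformed score at line %d in %s", lineno[which(is.na(score))[1L]],
          path)
  }
  if (any(score < 0)) {
    stopf("negative score at line %d in %s", lineno[which(score < 0)[1L]], path)
  }
  ndup <- 0L
  if (anyDuplicated(paste(id1, id2, sep = "\t"))) {
    key <- paste(id1, id2, sep = "\t")
    agg <- tapply(score, key, max)
    ndup <- length(key) - length(agg)
    message(ndup, " duplicate pair(s) collapsed to their maximum score")
    parts <- strsplit(names(agg), "\t", fixed = TRUE)
    id1 <- vapply(parts, `[`, character(1), 1L)
    id2 <- vapply(parts, `[`, character(1), 2L)
    score <- as.numeric(agg)
  }
  rows <- sort(unique(id1)); cols <- sort(unique(id2))
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(id1, id2)] <- score
  sim_matrix(m, role = role, normalized = FALSE)
}

#' Write a similarity matrix as a 3-column TSV
#'
#' Only non-missing entries are written, ordered by id1 then id2.
#'
#' @param sim a [sim_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "sim_matrix"))
  idx <- which(!is.na(sim), arr.ind = TRUE)
  idx <- idx[order(rownames(sim)[idx[, 1L]], colnames(sim)[idx[, 2L]]), ,
             drop = FALSE]
  writeLines(paste(rownames(sim)[idx[, 1L]], colnames(sim)[idx[, 2L]],
                   format(sim[idx], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}

#' Normalize a similarity matrix to [0, 1] by its global maximum
#'
#' Every entry is divided by the maximum entry, so the ranking of entries is
#' unchanged and at least one entry equals 1. An all-zero matrix is returned
#' unchanged (with a warning) but flagged normalized.
#'
#' @param sim a [sim_matrix()] with at least one non-missing entry.
#' @return the normalized [sim_matrix()].
#' @export
normalize_sim <- function(sim) {
  stopifnot(inherits(sim, "sim_matrix"))
  if (all(is.na(sim))) stopf("cannot normalize: no entries")
  mx <- max(sim, na.rm = TRUE)
  if (mx == 0) {
    warning("all similarity entries are zero; returned unchanged", call. = FALSE)
    return(sim_matrix(unclass(sim), role = sim_role(sim), normalized = TRUE))
  }
  sim_matrix(unclass(sim) / mx, role = sim_role(sim), normalized = TRUE)
}

#' Combine sequence and structure similarity into the biological score
#'
#' For every node pair, the biological score is the convex combination
#' `B = (1 - beta) * SS + beta * SQ` of the normalized structure (`SS`) and
#' sequence (`SQ`) similarities; `beta = 0.7` gives sequence 70% of the
#' weight and structure 30%. Pairs with no structure entry (no resolved
#' structure for at least one member) fall back to `B = SQ`, i.e. full
#' weight on sequence, rather than being penalized with a zero structure
#' score. A missing sequence entry counts as 0.
#'
#' @param seq_sim normalized [sim_matrix()] with role `"sequence"`.
#' @param struct_sim normalized [sim_matrix()] with role `"structure"`, or
#'   `NULL` when no structure information is available at all.
#' @param beta weight of the sequence score, in `[0,1]`.
#' @return a normalized [sim_matrix()] with role `"biological"`, defined on
#'   the union of pairs present in either input.
#' @export
combine_bio <- function(seq_sim, struct_sim = NULL, beta = 0.7) {
  assert_unit_interval(beta, "beta")
  stopifnot(inherits(seq_sim, "sim_matrix"))
  if (!sim_normalized(seq_sim)) stopf("`seq_sim` must be normalized first")
  if (!is.null(struct_sim)) {
    stopifnot(inherits(struct_sim, "sim_matrix"))
    if (!sim_normalized(struct_sim)) stopf("`struct_sim` must be normalized first")
  }
  rows <- sort(unique(c(rownames(seq_sim), rownames(struct_sim))))
  cols <- sort(unique(c(colnames(seq_sim), colnames(struct_sim))))
  sq <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(seq_sim)) {
    tmp <- unclass(seq_sim)
    tmp[is.na(tmp)] <- 0
    sq[rownames(seq_sim), colnames(seq_sim)] <- tmp
  }
  b <- beta * sq
  has_ss <- matrix(FALSE, length(rows), length(cols),
                   dimnames = list(rows, cols))
  if (!is.null(struct_sim) && nrow(struct_sim)) {
    ssm <- matrix(NA_real_, length(rows), length(cols),
                  dimnames = list(rows, cols))
    ssm[rownames(struct_sim), colnames(struct_sim)] <- unclass(struct_sim)
    has_ss <- !is.na(ssm)
    b[has_ss] <- (1 - beta) * ssm[has_ss] + beta * sq[has_ss]
  }
  b[!has_ss] <- sq[!has_ss]   # structure missing: full weight to sequence
  sim_matrix(b, role = "biological", normalized = TRUE)
}

#' Import BLAST tabular output as a sequence similarity matrix
#'
#' Accepts `-outfmt 6`-style tabular output: either a 3-column file
#' `qseqid sseqid bitscore` or the standard 12-column format (bit score in
#' the last column). Multiple HSPs for a pair keep the maximum bit score.
#'
#' @param path path to the BLAST tabular file.
#' @return an unnormalized [sim_matrix()] with role `"sequence"`.
#' @export
import_blast_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("no BLAST hits in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  sc <- function(f) as.numeric(f[length(f)])
  if (any(nf < 3L)) stopf("malformed BLAST tabular line in %s", path)
  id1 <- vapply(fields, `[`, character(1), 1L)
  id2 <- vapply(fields, `[`, character(1), 2L)
  score <- vapply(fields, sc, numeric(1))
  key <- paste(id1, id2, sep = "\t")
  agg <- tapply(score, key, max)
  parts <- strsplit(names(agg), "\t", fixed = TRUE)
  id1 <- vapply(parts, `[`, character(1), 1L)
  id2 <- vapply(parts, `[`, character(1), 2L)
  rows <- sort(unique(id1)); cols <- sort(unique(id2))
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  m[cbind(id1, id2)] <- as.numeric(agg)
  sim_matrix(m, role = "sequence", normalized = FALSE)
}

#' All-vs-all blastp wrapper producing a sequence similarity matrix
#'
#' Runs `blastp` with the second FASTA as subject and captures bit scores
#' (`-outfmt "6 qseqid sseqid bitscore"`). FASTA identifiers must match the
#' network node identifiers. Absent hits are missing entries.
#'
#' @param fasta1,fasta2 FASTA files for the two networks' proteins.
#' @param blastp_exe path to the `blastp` executable.
#' @return an unnormalized [sim_matrix()] with role `"sequence"`.
#' @export
run_blastp_pairs <- function(fasta1, fasta2, blastp_exe = "blastp") {
  if (!file.exists(fasta1) || file.size(fasta1) == 0L) {
    stopf("empty or missing FASTA: %s", fasta1)
  }
  if (!file.exists(fasta2) || file.size(fasta2) == 0L) {
    stopf("empty or missing FASTA: %s", fasta2)
  }
  exe <- Sys.which(blastp_exe)
  if (!nzchar(exe)) {
    stopf(paste("blastp executable not found (%s); run BLAST yourself and",
                "provide its tabular output via import_blast_tsv() or a",
                "precomputed TSV via read_similarity_tsv()"), blastp_exe)
  }
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out))
  status <- system2(exe, c("-query", shQuote(fasta1), "-subject",
                           shQuote(fasta2), "-outfmt",
                           shQuote("6 qseqid sseqid bitscore"),
                           "-out", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stopf("blastp exited with status %d", status)
  if (!file.exists(out) || file.size(out) == 0L) {
    stopf("blastp produced no hits")
  }
  import_blast_tsv(out)
}

#' Parse saved TM-align stdout into TM-scores
#'
#' Extracts the TM-scores from the text TM-align prints; when both
#' normalizations are reported, the larger (i.e. the score normalized by the
#' shorter chain) is kept.
#'
#' @param text character vector: lines of TM-align standard output for one
#'   structure pair.
#' @return a single TM-score in `(0, 1]`.
#' @export
parse_tmalign_output <- function(text) {
  hits <- regmatches(text, regexpr("TM-score\\s*=\\s*[0-9.]+", text))
  if (length(hits) == 0L) stopf("no TM-score found in TM-align output")
  scores <- as.numeric(sub("TM-score\\s*=\\s*", "", hits))
  max(scores)
}

#' All-vs-all TM-align wrapper producing a structure similarity matrix
#'
#' Runs TM-align on every pair of PDB files (named `<node_id>.pdb`) across
#' the two directories; pairs involving a protein without a structure file
#' are missing entries, not zeros. When a protein has several structure
#' files (`<node_id>*.pdb`), the maximum TM-score over them is kept.
#'
#' @param pdb_dir1,pdb_dir2 directories of PDB files for the two networks.
#' @param tmalign_exe path to the TM-align executable.
#' @return an unnormalized [sim_matrix()] with role `"structure"`.
#' @export
run_tmalign_pairs <- function(pdb_dir1, pdb_dir2, tmalign_exe = "TMalign") {
  exe <- Sys.which(tmalign_exe)
  if (!nzchar(exe)) {
    stopf(paste("TM-align executable not found (%s); run TM-align yourself",
                "and provide a precomputed TSV via read_similarity_tsv()"),
          tmalign_exe)
  }
  list_pdb <- function(dir) {
    files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
    if (length(files) == 0L) stopf("no PDB files in %s", dir)
    split(files, sub("\\.pdb$", "", sub("_[^_]*$", "", basename(files))))
  }
  p1 <- list_pdb(pdb_dir1); p2 <- list_pdb(pdb_dir2)
  rows <- sort(names(p1)); cols <- sort(names(p2))
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  for (i in rows) for (j in cols) {
    best <- NA_real_
    for (f1 in p1[[i]]) for (f2 in p2[[j]]) {
      txt <- suppressWarnings(system2(exe, c(shQuote(f1), shQuote(f2)),
                                      stdout = TRUE, stderr = FALSE))
      s <- tryCatch(parse_tmalign_output(txt), error = function(e) NA_real_)
      if (!is.na(s) && (is.na(best) || s > best)) best <- s
    }
    m[i, j] <- best
  }
  sim_matrix(m, role = "structure", normalized = FALSE)
}
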