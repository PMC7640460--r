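test_that("OBO parsing keeps is_a/part_of edges and drops obsolete terms", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: mid",
    "namespace: molecular_function", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf",
    "namespace: molecular_function", "alt_id: GO:0000033",
    "relationship: part_of GO:0000002", "",
    "[Term]", "id: GO:0000004", "name: gone",
    "namespace: molecular_function", "is_obsolete: true",
    "replaced_by: GO:0000002", "",
    "[Typedef]", "id: part_of"), f)
  dag <- parse_obo(f)
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(dag$parents[["GO:0000002"]]$rel, "is_a")
  expect_equal(dag$parents[["GO:0000003"]]$rel, "part_of")
  expect_equal(unname(dag$alt_map[c("GO:0000033", "GO:0000004")]),
               c("GO:0000003", "GO:0000002"))
})

test_that("cyclic parent graphs are rejected naming a cycle member", {
  expect_error(
    go_dag(c("A", "B"), c(A = "MF", B = "MF"),
           list(A = data.frame(parent = "B", rel = "is_a"),
                B = data.frame(parent = "A", rel = "is_a"))),
    "cyclic")
})

test_that("cross-namespace parent edges are dropped with a message", {
  expect_message(
    dag <- go_dag(c("A", "B"), c(A = "MF", B = "BP"),
                  list(B = data.frame(parent = "A", rel = "is_a"))),
    "cross-namespace")
  expect_null(dag$parents[["B"]])
})

test_that("GAF parsing honours aspect, NOT qualifiers and unknown-term filtering", {
  dag <- toy_dag()
  f <- withr::local_tempfile(fileext = ".gaf")
  row <- function(protein, qual, term, aspect) {
    paste("DB", protein, protein, qual, term, "REF", "IEA", "", aspect,
          "", "", "protein", "taxon:1", "20200101", "DB", "", "", sep = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               row("P1", "", "GO:4", "F"),
               row("P1", "NOT", "GO:5", "F"),
               row("P2", "enables", "GO:9", "P"),
               row("P3", "", "GO:404", "F"),
               "bad row"), f)
  suppressMessages(ann <- parse_gaf(f, dag))
  expect_equal(ann$MF, list(P1 = "GO:4"))
  expect_equal(ann$BP, list(P2 = "GO:9"))
  writeLines("!gaf-version: 2.2", f)
  expect_error(parse_gaf(f, dag), "no annotation rows")
})

test_that("Wang similarity matches the hand-computed toy chain", {
  dag <- go_dag(c("root", "x", "a", "b"),
                c(root = "MF", x = "MF", a = "MF", b = "MF"),
                list(x = data.frame(parent = "root", rel = "is_a"),
                     a = data.frame(parent = "x", rel = "is_a"),
                     b = data.frame(parent = "x", rel = "is_a")))
  # S_a = {a:1, x:0.8, root:0.64}; SV = 2.44; shared {x, root}
  expect_equal(wang_term_similarity(dag, "a", "b"), 2.88 / 4.88,
               tolerance = 1e-9)
  expect_equal(wang_term_similarity(dag, "a", "b"), 0.5902, tolerance = 1e-4)
  expect_equal(wang_term_similarity(dag, "a", "a"), 1.0)
  expect_equal(wang_term_similarity(dag, "a", "b"),
               wang_term_similarity(dag, "b", "a"))
})

test_that("Wang similarity is 0 for disjoint components and errors on misuse", {
  dag <- toy_dag()
  # GO:8/GO:9 (BP) are disjoint from nothing in their own namespace; build
  # a disjoint MF pair instead
  dag2 <- go_dag(c("r1", "r2", "c1", "c2"),
                 c(r1 = "MF", r2 = "MF", c1 = "MF", c2 = "MF"),
                 list(c1 = data.frame(parent = "r1", rel = "is_a"),
                      c2 = data.frame(parent = "r2", rel = "is_a")))
  expect_equal(wang_term_similarity(dag2, "c1", "c2"), 0)
  expect_error(wang_term_similarity(dag, "GO:4", "GO:9"), "namespace")
  expect_error(wang_term_similarity(dag, "GO:4", "GO:404"), "not in DAG")
})

test_that("deeper shared ancestry increases Wang similarity", {
  dag <- toy_dag()
  # GO:4 and GO:5 are siblings under GO:2; GO:7 sits in the other branch
  expect_gt(wang_term_similarity(dag, "GO:4", "GO:5"),
            wang_term_similarity(dag, "GO:4", "GO:7"))
  # a term is closer to its parent than to an unrelated term
  expect_gt(wang_term_similarity(dag, "GO:4", "GO:2"),
            wang_term_similarity(dag, "GO:4", "GO:7"))
})

test_that("part_of edges contribute with their smaller factor", {
  dag <- toy_dag()
  # GO:6 reaches GO:3 via part_of (0.6), GO:7 via is_a (0.8): the is_a
  # child is semantically closer to their shared parent
  expect_gt(wang_term_similarity(dag, "GO:7", "GO:3"),
            wang_term_similarity(dag, "GO:6", "GO:3"))
})

test_that("BMA equals the exhaustive double loop and its reductions", {
  dag <- toy_dag()
  mf_terms <- c("GO:1", "GO:2", "GO:3", "GO:4", "GO:5", "GO:6", "GO:7")
  set.seed(21)
  for (i in 1:10) {
    A <- sample(mf_terms, 3)
    B <- sample(mf_terms, 3)
    ref_m <- outer(A, B, Vectorize(function(a, b)
      wang_term_similarity(dag, a, b)))
    ref <- mean(c(mean(apply(ref_m, 1, max)), mean(apply(ref_m, 2, max))))
    expect_equal(bma_similarity(dag, A, B), ref, tolerance = 1e-12)
    expect_equal(bma_similarity(dag, A, B), bma_similarity(dag, B, A))
  }
  expect_equal(bma_similarity(dag, mf_terms[1:3], mf_terms[1:3]), 1.0)
  expect_equal(bma_similarity(dag, "GO:4", "GO:5"),
               wang_term_similarity(dag, "GO:4", "GO:5"))
  expect_error(bma_similarity(dag, character(0), "GO:4"), "empty")
})

test_that("AFS is the mean of per-pair BMA over annotated pairs", {
  dag <- toy_dag()
  ann1 <- annotation_set(mf = list(u1 = c("GO:4", "GO:5"), u2 = "GO:6",
                                   u3 = "GO:7"),
                         bp = list(u1 = "GO:9"))
  ann2 <- annotation_set(mf = list(v1 = c("GO:4", "GO:5"), v2 = "GO:7"),
                         bp = list(v1 = "GO:9"))
  al <- ppi_alignment(c("u1", "u2", "u3"), c("v1", "v2", "v3"), c(1, 1, 1))

  rep_mf <- afs(al, ann1, ann2, dag, "MF")
  # u3 -> v3 is unannotated on the v side: excluded, not scored 0
  expect_equal(rep_mf$n_pairs_scored, 2L)
  expect_equal(rep_mf$afs,
               mean(c(bma_similarity(dag, c("GO:4", "GO:5"), c("GO:4", "GO:5")),
                      bma_similarity(dag, "GO:6", "GO:7"))))
  expect_equal(rep_mf$pct_aligned_nodes, 100 * 2 / 3)

  # identical annotation sets give AFS exactly 1
  rep_bp <- afs(al, ann1, ann2, dag, "BP")
  expect_equal(rep_bp$afs, 1.0)
  expect_equal(rep_bp$n_pairs_scored, 1L)

  # two pairs with known scores average as stated
  ann1b <- annotation_set(mf = list(u1 = "GO:4", u2 = "GO:4"))
  ann2b <- annotation_set(mf = list(v1 = "GO:4", v2 = "GO:5"))
  r <- afs(ppi_alignment(c("u1", "u2"), c("v1", "v2"), c(1, 1)),
           ann1b, ann2b, dag, "MF")
  expect_equal(r$afs, mean(c(1, wang_term_similarity(dag, "GO:4", "GO:5"))))

  # no scorable pair: AFS reported as NA, not 0
  r_na <- afs(ppi_alignment("u9", "v9", 1), ann1, ann2, dag, "MF")
  expect_true(is.na(r_na$afs))
  expect_equal(r_na$n_pairs_scored, 0L)
})

test_that("AFS percentage denominator honours an explicit node universe", {
  dag <- toy_dag()
  ann1 <- annotation_set(mf = list(u1 = "GO:4", u2 = "GO:5", zz = "GO:6"))
  ann2 <- annotation_set(mf = list(v1 = "GO:4"))
  al <- ppi_alignment("u1", "v1", 1)
  # without a universe: 3 annotated proteins in ann1
  expect_equal(afs(al, ann1, ann2, dag, "MF")$pct_aligned_nodes, 100 / 3)
  # restricted to the network's own nodes: zz does not count
  expect_equal(afs(al, ann1, ann2, dag, "MF",
                   nodes1 = c("u1", "u2"))$pct_aligned_nodes, 50)
})

test_that("self-alignment under identity annotations yields AFS 1 in both namespaces", {
  onto <- make_toy_ontology(n_terms = 20, n_proteins = 8,
                            shared_fraction = 1, seed = 6L)
  nodes1 <- names(onto$ann1$MF)
  nodes2 <- names(onto$ann2$MF)
  al <- ppi_alignment(nodes1, nodes2[seq_along(nodes1)], rep(1, length(nodes1)))
  for (ns in c("MF", "BP")) {
    r <- afs(al, onto$ann1, onto$ann2, onto$dag, ns)
    expect_equal(r$afs, 1.0)
    expect_equal(r$pct_aligned_nodes, 100)
  }
})

test_that("AFS reports serialize with their summary block", {
  dag <- toy_dag()
  ann1 <- annotation_set(mf = list(u1 = "GO:4"))
  ann2 <- annotation_set(mf = list(v1 = "GO:4"))
  r <- afs(ppi_alignment("u1", "v1", 1), ann1, ann2, dag, "MF")
  f <- withr::local_tempfile()
  write_afs_report(r, f)
  lines <- readLines(f)
  expect_equal(lines[1], "u1\tv1\t1")
  expect_true(any(grepl("^# AFS\t1$", lines)))
})
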