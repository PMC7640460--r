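Package: salignr
Title: Structure-Aware Global Alignment of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global pairwise alignment of protein-protein interaction (PPI)
    networks that fuses a minimum-degree-heuristic topological score with
    sequence (BLAST bit score) and structure (TM-score) similarity into a
    single alignment score, produces one-to-one node mappings by a greedy
    seed-and-extend algorithm or a Monte Carlo semi-greedy variant that
    samples partners from Boltzmann probabilities over the top candidates,
    and evaluates alignments by Average Functional Similarity using the Wang
    graph-based Gene Ontology semantic similarity measure with best-match
    averaging. Includes a synthetic benchmark generator (paired networks with
    a planted node correspondence, similarity matrices with controllable
    signal and noise, and a toy ontology with annotations) so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
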