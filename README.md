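# salignr

Structure-aware global alignment of protein–protein interaction (PPI)
networks in R.

## What problem this solves

Comparing the PPI networks of two species highlights evolutionarily
conserved interactions and lets annotations transfer across organisms. A
*global* network alignment is an injective mapping `g` of the smaller
network's proteins into the larger network's proteins. Most aligners score
candidate pairs from topology and sequence alone; `salignr` additionally
uses protein *structure* similarity, which tracks function better than
sequence, and fuses the three signals:

```
B(i,j) = (1 − β)·SS(i,j) + β·SQ(i,j)      biological score
A(i,j) = α·T(i,j) + (1 − α)·B(i,j)        final alignment score
```

* `T` — topological similarity: per-node importances from an iterative
  minimum-degree reduction (low-degree nodes are deleted first, their weight
  flowing onto neighbours and "skeleton" edges, so hubs and bottlenecks
  accumulate mass), combined as `min(S_i,S_j)/max(S_i,S_j)`.
* `SQ` — normalized BLAST bit scores; `SS` — normalized TM-scores. Pairs
  without structure data fall back to `B = SQ` instead of being zero-filled.
* Defaults `α = 0.1`, `β = 0.7` (use `β = 0.9` when few proteins have
  resolved structures), degree threshold `d = 10`.

Alignments are built by a deterministic greedy seed-and-extend pass that
prioritizes neighbours of already-aligned pairs, or by a Monte Carlo
semi-greedy variant that draws each partner from Boltzmann probabilities
`Prob_i ∝ exp(−(best − NS_i)/kT)` over the top-`n` candidates
(`n = 10`, `kT = 0.1`), producing reproducible *alternate* alignments under
different seeds. Alignment quality is evaluated as Average Functional
Similarity (AFS): the mean Wang graph-based GO semantic similarity of
aligned pairs, with term sets combined by Best-Match-Average, reported
separately for the Molecular Function and Biological Process namespaces
together with the percentage of annotated nodes aligned.

A synthetic benchmark generator (paired networks with a planted node
correspondence, similarity matrices with controllable signal/noise/
missingness, toy GO DAG with shareable annotations) makes the whole pipeline
testable without any database downloads.

## Worked example

```r
library(salignr)

b <- make_bundle(n_nodes = 60, rewire_fraction = 0.1, noise_sd = 0.5, seed = 1)
res <- salign_align(b$net1, b$net2, b$seq_sim, b$struct_sim,
                    params = salign_params(alpha = 0.1, beta = 0.7))
res
#> <salign_result: greedy, 1 alignment(s) of 60 pairs>
head(res$alignments[[1]], 3)
#>   node1 node2     score
#> 1   a44   b55 0.8886716
#> 2   a45   b01 0.7374174
#> 3   a40   b34 0.7351191

recovery_rate(res$alignments[[1]], b$true_mapping)
#> [1] 1

ev <- salign_evaluate(res$alignments[[1]], b$dag, b$ann1, b$ann2,
                      nodes1 = b$net1$nodes)
ev$summary
#>   namespace  afs_mean afs_sd pct_aligned_mean n_runs
#> 1        MF 0.8376090      0              100      1
#> 2        BP 0.8302493      0              100      1
```

All 60 planted pairs are recovered (`recovery_rate = 1`); the AFS of about
0.84 in both namespaces reflects the bundle's annotation-sharing level
(true pairs share 80% of their GO terms by default), and 100% of annotated
smaller-network nodes were aligned and scored.

Real data enter as plain text: tab-separated edge lists
(`read_edgelist()`), 3-column similarity TSVs (`read_similarity_tsv()`,
with `run_blastp_pairs()` / `import_blast_tsv()` and `run_tmalign_pairs()` /
`parse_tmalign_output()` to produce them), OBO ontologies (`parse_obo()`)
and GAF annotations (`parse_gaf()`). A command-line interface wrapping the
same functions ships in `inst/cli/salign.R` with `align`, `evaluate` and
`simulate` subcommands.

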