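---
title: "Structure-aware global PPI network alignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware global PPI network alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salignr)
```

## The problem

Two protein–protein interaction (PPI) networks from different species share
evolutionarily conserved subnetworks. A *global* network alignment is an
injective mapping `g` from the nodes of the smaller network into the nodes of
the larger one that pairs as many functionally related proteins as possible.
`salignr` scores candidate pairs by fusing three signals — network topology,
sequence similarity and structure similarity — and then builds the mapping
with a greedy seed-and-extend pass or a Monte Carlo semi-greedy variant that
can produce alternate alignments of similar quality.

## Topological score: minimum-degree reduction

Node importance is computed globally, not from the bare degree. All node
weights start at 0 and all edge weights at 1. The reduction repeatedly
deletes the node with the *lowest* current degree (ties broken by
lexicographic identifier, making the whole procedure deterministic) while
that degree is at most the threshold `d`, transferring accumulated weight
toward the survivors:

* a degree-1 node `v` with neighbour `u` transfers `w(v) + w(v,u)` onto `u`;
* a degree-`k` node (`k >= 2`) spreads `w(v) + w(v,u) + w(v,z)` over every
  unordered neighbour pair `(u,z)`, divided by `choose(k, 2)`, creating a
  weight-0 "skeleton" edge `(u,z)` when none exists. Skeleton edges count in
  later degrees and in the final importance sums, which is what keeps the
  mass flowing toward hubs and bottlenecks.

A removed node freezes its node weight as its importance; a surviving node's
importance is its node weight plus its incident (possibly skeleton) edge
weights. On a tree every step is a leaf removal, so total mass is conserved
and the last survivor collects exactly the initial edge mass — one of the
package's standing property tests. On a star, the hub collects one unit per
leaf, so hubs strictly dominate peripheral nodes.

The cross-network topological similarity is the ratio
`T(i,j) = min(S_i, S_j) / max(S_i, S_j)` (0 when the maximum is 0). This is
a deliberate design choice: it is parameter-free, lands in `[0, 1]` so it
composes with the convex combinations below, equals 1 exactly when two
nodes are equally important, and is scale-aware (multiplying one network's
importances by a constant changes the matrix). The default `d = 10` follows
the established practice for this heuristic; smaller values leave more of
the periphery unreduced, larger values push more mass onto fewer hubs.

## Biological score

Raw sequence scores (BLAST bit scores; bit scores rather than e-values
because they are positive, additive-scale and database-size independent) and
raw structure scores (TM-scores, taking the normalization by the shorter
chain when TM-align reports two) are each normalized by their own global
maximum — a monotone, parameter-free map to `[0, 1]` that preserves all
rankings. They are then fused per pair:

> `B = (1 - beta) * SS + beta * SQ`

with `beta = 0.7` by default: sequence gets 70% of the weight and structure
30%. When a pair has no structure entry (at least one member lacks a
resolved 3D structure) the package sets `B = SQ` — full weight on sequence —
rather than imputing `SS = 0`. Zero-filling would systematically punish
unresolved proteins for missing knowledge rather than for dissimilarity;
the fallback keeps them competitive, and `beta = 0.9` is the recommended
preset when structure coverage is poor. Missing entries are first-class in
the structure matrix (distinguishable from an explicit 0); in every other
role a missing entry simply means 0.

## Final score and alignment

The alignment score is the convex combination

> `A = alpha * T + (1 - alpha) * B`

with `alpha = 0.1` by default, i.e. the biological signal contributes 90%.
The greedy aligner seeds with the globally best pair, then repeatedly takes
the best pair from the *frontier* — pairs whose members neighbour an
already-aligned pair on both sides — so neighbours of aligned nodes are
prioritized and the mapping stays topologically consistent. When the
frontier empties while unaligned scored pairs remain, it re-seeds from the
best remaining global pair; re-seeding is this package's choice for
guaranteeing that all (or the maximum possible number) of the smaller
network's nodes are aligned rather than stopping at the first exhausted
component. All ties break by score, then lexicographic identifiers, so
repeated runs are bit-identical.

The Monte Carlo variant visits nodes in exactly the greedy order but draws
each partner from the Boltzmann distribution over the visited node's top-`n`
currently unaligned candidates: candidate scores are normalized to
`NS_i = n_i / s` (`s` the top-`n` score sum; a zero sum falls back to a
uniform draw, the symmetric completion of 0/0), and

> `Prob_i = exp(-(best - NS_i)/kT) / sum_j exp(-(best - NS_j)/kT)`

with `best` the maximum normalized score. Defaults are `n_top = 10` and a
constant temperature product `kT = 0.1` (no annealing schedule). Already
aligned partners are removed *before* the top-`n` cut so the pool always
holds up to `n` live options. Candidates are restricted to the frontier
partners of the visited node (or to all unaligned scored partners when
re-seeding), which makes `n_top = 1` reduce exactly to the greedy
alignment. The seed fixes the draw: same seed, same alignment; consecutive
seeds give reproducible alternate alignments.

## Evaluation: Wang similarity, BMA, AFS

Alignments are evaluated per Gene Ontology namespace (MF, BP) with the Wang
graph-based semantic similarity: each term's semantics are S-values over its
ancestor closure, propagated multiplicatively along the best path with
contribution factors 0.8 per `is_a` and 0.6 per `part_of` edge (the
measure's canonical constants); the similarity of two terms is the summed
S-values of their shared ancestors divided by their total semantic values.
Protein pairs combine their term sets by symmetric Best-Match-Average, and
the Average Functional Similarity (AFS) of an alignment is the plain mean of
the per-pair scores.

Two conventions are worth stating because the choice was genuinely open:

* Pairs where either protein has no annotation in the namespace are
  *excluded* from the AFS mean, not scored 0 — absence of annotation is
  missing knowledge, not evidence of dissimilarity.
* The "percentage of aligned nodes" is reported per namespace as
  `100 * scored pairs / annotated smaller-network nodes`; this makes the
  metric namespace-dependent and complements the AFS (which, by excluding
  unannotated pairs, would otherwise reward small confident alignments).

All GAF evidence codes (including IEA) are accepted, the common tool
default, to maximize coverage.

## The synthetic benchmark

Because quantitative results on public PPI databases depend on the database
release, the BLAST/TM-align runs and the GO version, the package's own
empirical claims are made on a fully self-contained generator:

* **Networks**: an Erdős–Rényi draw (preferential attachment available as an
  option; both extremes are useful for falsifying the hub-dominance
  property) with a relabeled copy whose edges are partially rewired.
  Rewiring preserves the edge count (replacements avoid self-loops and
  existing edges), and the planted relabeling is returned as ground truth.
* **Similarities**: true pairs draw raw scores from `N(base + signal, sd)`,
  non-pairs from `N(base, sd)`, clipped at 0 — a two-parameter truncated
  normal is the simplest shape that controls overlap directly. Defaults
  `base = 1`, `signal = 2`, `sd = 0.5` give strong but not saturated
  separation; a configurable fraction of proteins per network carries no
  structure entries at all, emulating unresolved structures.
* **Ontology**: one rooted `is_a` tree per namespace with a ~10% minority of
  `part_of` edges; partners of true pairs share a configurable fraction of
  their terms.

What the generator does *not* emulate: the heavy-tailed degree
distributions, interaction noise biases and annotation-depth biases of real
interactomes, or realistic sequence/structure score distributions. Passing
tests on these fixtures therefore demonstrate correctness of the algorithms
and the expected qualitative responses (recovery decays with noise;
biological weighting beats pure topology), not performance on any real
species pair.

## Problem sizes and numerical choices

The package's verification runs use 200-node bundles for the exact
noise-free recovery check and 100-node bundles averaged over 10–20 seeds for
the noise sweeps — large enough that every module (reduction, frontier
bookkeeping, sampling, evaluation) operates far from its trivial regime,
small enough that the full suite runs in about a minute. Probability sums
are checked to `1e-9`; score ties everywhere resolve by lexicographic node
identifier; degenerate inputs (empty graphs, all-zero matrices, empty
candidate sets, unannotated pairs) each have a defined, tested behaviour
rather than an error where the convention is safe (uniform sampling for
all-zero candidates, `NA` — never 0 — for an AFS with no scorable pair).

## Worked example

```{r example}
b <- make_bundle(n_nodes = 60, rewire_fraction = 0.1, noise_sd = 0.5,
                 seed = 1)
res <- salign_align(b$net1, b$net2, b$seq_sim, b$struct_sim,
                    params = salign_params(alpha = 0.1, beta = 0.7))
al <- res$alignments[[1]]
recovery_rate(al, b$true_mapping)

ev <- salign_evaluate(al, b$dag, b$ann1, b$ann2, nodes1 = b$net1$nodes)
ev$summary
```

## Known limitations

* The min-degree weight-transfer rules are this package's concrete
  formulation (in the HubAlign lineage) of the reduction heuristic;
  alternative transfer rules would change the absolute importances, though
  not the properties tested — conservation, hub dominance, determinism.
* Max-normalization couples every score to the single largest entry; one
  extreme outlier (e.g. a very long protein's self-hit bit score)
  compresses the rest of the matrix.
* The greedy pass is a heuristic, not an optimal assignment; with adversarial
  score matrices it can be arbitrarily far from the maximum-weight matching.
* AFS values depend on annotation depth; comparing AFS across datasets with
  different annotation coverage is not meaningful.
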