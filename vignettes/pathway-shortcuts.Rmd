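---
title: "Predicting pathway-consistent missing edges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pathway-consistent missing edges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathshortcuts)
```

## The model

A signaling pathway is modeled as information flow through a directed,
confidence-weighted interactome from a set of sources $S$ (upstream
sensors) to a set of targets $T$ (downstream transcription factors). Every
edge carries a confidence $w \in [0,1]$ and is traversed at cost $1 - w$,
so a path's cost is low exactly when all of its edges are well supported.
The working assumption is that missing true interactions reveal themselves
as detours: if the database lacked an edge that the cell uses, the
observed source-to-target distances are longer than they should be, and
the candidate edges whose addition shortens many source-target routes at
once are the best guesses for those missing interactions.

Four objectives formalize "shortens the routes". With $d(s,t)$ the
shortest-path cost and $d_X(s,t)$ its restriction to paths of at most $X$
edges:

| variant          | objective                                                  |
|------------------|------------------------------------------------------------|
| `shortcuts`      | $\sum_{s \in S}\sum_{t \in T} d(s,t)$                      |
| `shortcuts-x`    | $\sum_{s \in S}\sum_{t \in T} d_X(s,t)$                    |
| `shortcuts-ss`   | $\sum_{t \in T} \min_{s \in S} d(s,t)$                     |
| `shortcuts-x-ss` | $\sum_{t \in T} \min_{s \in S} d_X(s,t)$                   |

The hop-restricted variants encode the biological prior that signaling
cascades are short — curated pathway maps typically place about five edges
between a target and its closest source, hence the default $X = 5$. The
single-source (`-ss`) variants model each target as regulated by one
closest source rather than by all of them.

Exact edge-addition under any of these objectives is a hard combinatorial
problem, so the predictor is greedy: at each of $k$ steps it adds the one
candidate edge that most reduces the objective, recomputes, and repeats.
The interesting part is evaluating millions of candidates cheaply. After
precomputing distances from every source (forward) and to every target (on
the edge-reversed graph), a candidate $(u, v)$ with weight $w'$ changes a
pair distance only if the new route passes through it, so

$$d_{new}(s,t) = \min\!\big(d(s,t),\; d(s,u) + w' + d(v,t)\big),$$

a constant-time lookup per pair. Under a hop bound the new edge consumes
one hop and the remaining budget must be split across the two legs:

$$d_{X,new}(s,t) = \min\!\Big(d_X(s,t),\; \min_{a = 0..X-1}
  d_a(s,u) + w' + d_{X-1-a}(v,t)\Big),$$

with $d_0(x,y) = 0$ iff $x = y$ and unreachable otherwise. For $X = 5$
this enumerates exactly six cases: three interior splits, the two
endpoint cases ($u = s$, $v = t$), and the unchanged old distance.
`naive_best_edge()` implements the quadratically slower full
recomputation; the test suite holds the incremental rule to it within
$10^{-9}$ across all variants.

## Distance kernels

Unrestricted single-source distances use Dijkstra's algorithm (via
`igraph`); all costs are nonnegative, and zero-cost edges (the default
candidate weight) are legal without modification. Hop-bounded tables use
a Bellman-Ford variant written for exact hop semantics: round $k$ is
computed only from round $k-1$ (double buffering), so row $k$ of the table
is precisely "cheapest path using at most $k$ edges" even when zero-cost
edges would otherwise let a value leak across rounds. Unreachability is
represented by `Inf` inside every kernel — a true sentinel, never a large
number — and converted to a finite penalty only when an objective is
reduced to a scalar.

## Tunable parameters

* **Hop bound `hops`** (edges; default 5): the maximum path length for
  `-x` variants. Smaller values enforce more direct regulation and make
  more pairs unreachable.
* **Penalty** (cost units; default = node count $n$): substituted for
  unreachable pair distances. Any simple path costs at most $n - 1$ and
  any hop-bounded path at most $X$, so the default strictly exceeds every
  achievable distance: the greedy step always prefers connecting a
  disconnected pair over shaving cost off a connected one, which is the
  finite-arithmetic reading of "unreachable = infinite". A penalty that
  fails to exceed the achievable maximum triggers a warning.
* **Candidate cost** (default 0): a hypothesized edge with no evidence is
  added at zero cost to maximally encourage its use; when predicting from
  a reference set of weighted associations, candidates instead cost
  $1 - \text{confidence}$, making well-supported candidates cheaper to
  route through.
* **Budget `k`**: the CLI defaults to 15 predictions for the multi-source
  objectives and 10 for the single-source ones, the depths at which the
  greedy objective is typically driven to near zero on study-scale
  networks.

## Numerical choices and degenerate inputs

Objective values are compared with absolute tolerance $10^{-12}$: scores
within it are exact ties, collected and sampled uniformly with the run's
seeded generator, so identical seeds give identical prediction lists and
different seeds can differ only at steps whose recorded `tie_count`
exceeds 1. The greedy loop stops early — with a recorded reason — when the
pool is exhausted or no candidate strictly reduces the objective, rather
than padding the list with useless edges. An added candidate's reverse
orientation remains a legal future candidate, and candidate pools always
include reverse orientations of existing edges, since an oriented input
network can carry edges pointing the wrong way. `objective_before` at each
step is recomputed from fresh tables on the grown graph rather than copied
from the previous step's incremental value; the two agree to rounding, and
tests assert the replayed cost curve matches the recorded trajectory to
$10^{-9}$. Duplicate rows in edge inputs keep the maximum confidence
(best evidence, deterministically); self-loops are dropped with a warning.

## Baseline design choices

The comparison predictors involved three genuinely open readings, pinned
as follows (and by the tests):

* **Betweenness** counts, per candidate, the source-target pairs (targets,
  for `-ss` variants) whose distance it *strictly* reduces. "Lies on a
  shortest path" and "helps reduce the distance" diverge when ties exist;
  strict reduction is adopted for both multi-source and single-source
  variants for consistency and determinism, with non-strict counting
  available via `strict = FALSE`.
* **Weighted Jaccard** uses undirected neighborhoods (union of in- and
  out-neighbors; a doubly-adjacent neighbor contributes its
  maximum-confidence incidence once) and the score
  $|C| \cdot \sum_{x \in C}(c(u,x) + c(v,x)) \,/\,
  (\sum_{x \in N(u)} c(u,x) + \sum_{x \in N(v)} c(v,x))$ with
  $C = N(u) \cap N(v)$: shared neighbor mass normalized by total
  neighborhood mass, biased toward pairs with more common neighbors.
  Emitted edges are oriented lexicographically; evaluation ignores
  direction, so orientation cannot affect accuracy.
* **Short-Path** uses the *directed* distance $d(u,v)$ over ordered
  non-adjacent pairs; unreachable pairs are ineligible.

The global methods (Jaccard, Short-Path) never read $S$ or $T$ —
relabeling endpoints provably leaves their picks unchanged — which is
exactly why they serve as pathway-agnostic controls.

## Evaluation protocol

`cost_curve()` replays a prediction list on the original graph,
recomputing the objective from scratch per rank and reporting percent of
original cost (warning when the original is penalty-dominated).
`accuracy_at_k()` matches directed predictions against undirected
reference pairs ignoring direction — reference databases are undirected —
optionally filtered to pathway-member nodes; the denominator is the number
of evaluated predictions (relevant when early stopping truncates a run).
`cross_validate()` partitions held-out edges into seeded folds, re-offers
removed edges as candidates in the reduced graph, and counts
direction-agnostic recoveries among the top $k$; folds that receive no
edges (more folds than edges) are skipped and contribute nothing to either
numerator or denominator. `overlap_enrichment()` is the hypergeometric
upper tail, identical to a one-sided Fisher's exact test, with no
multiple-testing correction applied (single planned comparisons).

## The synthetic generator

`generate_pathway_network()` emulates the *shape* of an oriented
interactome restricted to a pathway's neighborhood: sources feed layered
intermediates feeding targets, edge confidences are Beta(8, 2)-distributed
(high-confidence skew, like curated physical interactions), and every
source-target pair is reachable within $L + 1$ hops (chains are completed
where sampling left gaps). Defaults — 5 sources, 11 targets, 4 layers of
32 nodes ($n = 144$), forward edge probability 0.15 — give the endpoint
counts of the motivating yeast system, canonical 5-hop source-target
routes matching the default hop bound, and a sparse graph of a few
hundred edges.

Planted shortcuts are the benchmark's "true missing edges": high
confidence ($\ge 0.95$), spanning at least two layers, and placed
sequentially at the missing pair whose addition most reduces the total
source-target cost. An earlier draft placed them between degree-ranked
hubs, but that often left them off the objective-optimal routes; direct
placement implements the intended property — an edge lying on many
source-target routes — literally, which is what makes hiding-and-recovery
a meaningful test.

What the generator does **not** emulate: STRING-style evidence channels,
scale-free degree structure, co-complex cliques, feedback loops (edges
all point forward), or correlated confidences. Passing the planted-edge
benchmarks therefore shows the machinery is correct and that
objective-relevant hidden edges are recoverable far above chance; it does
not certify real-database accuracy, which in the motivating study
depended on a curated interactome and an orientation step that are out of
scope here (pre-oriented networks are consumed as input).

## Problem sizes in the test suite

Property tests run at the scale where their oracles are exact and fast:
brute-force path enumeration on graphs of up to 12 nodes, incremental vs
naive candidate evaluation on 200 random instances of up to 12 nodes
across all four variants and $X \in \{2, 3, 5\}$, and recovery benchmarks
on 50 constructed dominant-shortcut instances plus 20 generator-default
(144-node) instances. These sizes are the package's choice of
exhaustively checkable regimes; the kernels themselves are the same code
at any scale, with the greedy step vectorized over all $O(n^2)$
candidates at once.

## Known limitations

* Greedy is a heuristic for NP-hard objectives: no approximation
  guarantee is claimed, and the recorded per-step deltas are conditional
  on earlier picks.
* Each greedy step recomputes all distance tables from scratch
  (correctness over micro-optimization); very large networks would want
  incremental table maintenance.
* Already-added edges are never re-weighted, and node identifiers are
  opaque case-sensitive text — no gene-symbol normalization is attempted.
* How to score an instance where every source-target pair is unreachable
  is a convention (penalty substitution), and percent-of-original curves
  on such instances mostly measure the penalty.
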