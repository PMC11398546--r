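---
title: "Methods: from synchrony to fibration-symmetric connectome repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from synchrony to fibration-symmetric connectome repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, the choices behind
them, and what the test suite does and does not establish. It states no
empirical numbers beyond what the tests and `scripts/acceptance.R`
themselves compute.

## The model in one page

A directed graph `G = (V, E)` carries a **balanced coloring** (equitable
partition) `𝒮 = {C_1, …, C_K}` when every node of `C_k` receives the same
number of edges from `C_j`, for all `k, j`. The clusters are the **fibers**
of a graph fibration onto a quotient **base graph**; nodes in one fiber
have isomorphic **input trees** (layered trees of iterated
in-neighbourhoods). For any *admissible* ODE system — one whose coupling
terms are dictated by the edges,
`dx_i/dt = F(x_i, t) + Σ_j A_ij H(x_i, x_j, t)` — equality of input trees
forces within-fiber trajectory equality: fibers are the wiring's prediction
of cluster synchrony.

The package's question is the converse: given synchrony clusters measured
from activity, what is the *cheapest* modification of a measured connectome
that makes those clusters an exact (and, ideally, coarsest) balanced
coloring? That is a mixed-integer linear program over binary removal
indicators `r_ij` (existing edges) and addition indicators `a_ij`
(candidate non-edges), minimising `α Σ r + β Σ a` subject to linear balance
equalities, optionally augmented by big-M *unbalancing* constraints with
indicator variables `s_pq^R` that force distinct clusters to receive
distinct in-counts from some cluster `R`.

## Synchrony metrics

* **LoS** `= (1/T) Σ_t exp(−Δ²/2σ²)` with bandwidth `σ` (dimensionless,
  same units as the DF/F0-style traces). It is 1 only for pointwise equal
  signals, always positive, and non-decreasing in `σ`; `σ` is swept over
  the fixed grid 0.01–0.20 in 0.005 steps (39 values), spanning "only
  near-identical signals count" to "most signals count".
* **Correlation family**: Pearson, Spearman, Kendall τ-b (tie-corrected,
  the standard default), distance correlation (the biased Székely sample
  estimator on 1-D series — the canonical definition, since the measure
  alone does not fix an estimator), covariance with the unbiased 1/(T−1)
  denominator (the convention is pinned by a frozen hand-computed test
  value, 2/3 for `x = (0,1,0,1)`, `y = (0,2,0,2)`). Covariance is left
  unnormalised by default; a correlation-like rescale would change
  thresholding and is deliberately not silently applied.
* Zero-variance series make correlations undefined; the package records 0
  with a warning rather than propagating NaN, so downstream matrices stay
  total without fabricating association.
* Cohort averages divide each pair by the number of animals containing
  both neurons; pairs never co-observed stay `NA` with count 0. The same
  per-pair denominator is reused for the consensus matrix, so missing
  neurons are handled identically at both levels.

## Functional networks and clustering

The thresholding step of functional-connectivity pipelines admits two
readings, and both are implemented and recorded in the output:

* `node-max` (default): keep all pairs at least as strong as the weakest
  node's strongest link (`τ = min_k max_j w_kj`). Parameter-free,
  guarantees every neuron keeps its best edge, reproducible.
* `percolation`: add pairs in decreasing weight until the graph is one
  connected component; ties are broken lexicographically on the label pair
  so the result is deterministic.

Clique synchronization accepts a fully connected clique of size `N` when
its total internal weight is ≥ `N(N−1)/2` times every edge leaving it, for
every member. The sweep order (decreasing size, then decreasing internal
weight, then lexicographic; accepted cliques retire their nodes) is a
package choice — the criterion alone does not determine a unique partition.
Every emitted clique is re-verified post hoc in the tests.

Louvain is run `nRuns` times (pipeline default 1000) under derived seeds;
the winner is scored by the package's own direct modularity evaluation
`Q = (1/2m) Σ_ij (A_ij − k_i k_j/2m) δ(c_i, c_j)`, not by the community
backend, and that evaluation is cross-checked against an independent
implementation in the tests. Since the functional network is weighted,
weighted modularity is the default (binary available).

## Consensus

All (metric × method) partitions — duplicates included, so frequent
partitions weigh more — are fused into co-assignment fractions `X`, with
per-pair denominators as above. Ward linkage is applied to `1 − X` directly
via the Lance–Williams update (`hclust` method `ward.D`), i.e. the
"Ward-on-dissimilarity" convention rather than embedding `1 − X` first;
this matches common hierarchical-clustering practice on precomputed
dissimilarities and is recorded in the linkage object. Leaves are arranged
by exact optimal leaf ordering (dynamic programme over subtree
orientations) for display only — cuts do not depend on it. "Cut at `h`"
keeps merges of height ≤ `h`; lowering `h` only refines, which the tests
check as a property. The pipeline's default cutoff ladder
(2.5, 2, 1.5, 1, 0.75, 0.5, 0.25) spans the Ward height range that a
consensus matrix over a few dozen nodes produces, from one cluster down to
near-singletons; distinct cuts are deduplicated before testing.

## The repair MILP

Balance is imposed as chained equalities (member `t_1` vs `t_2`, `t_2` vs
`t_3`, …) per (receiving cluster, source cluster) pair — equivalent to all
pairwise equalities with fewer rows. Because balance forces all members of
a cluster to share one in-profile, the unbalancing constraints are
instantiated on a single representative node per cluster; this leaves the
optimum unchanged and shrinks the model substantially. The big-M
coefficient is `n = |V|`, an upper bound on any in-count difference. An
optional constraint keeps every node's post-repair in-degree ≥ 1 (off by
default; whether it was active in published runs of such pipelines is
rarely stated, so it is exposed and flagged rather than assumed).

Candidate additions default to *all* ordered non-self-loop non-edges;
excluding candidates into rigid singleton clusters is available as a
model-size reduction. Forbidden removals/additions express biological hard
constraints.

Three modes:

* `none` — balance only.
* `relaxed` — adds, per cluster pair, indicators `s_pq^R` with
  `indeg_R(p) − indeg_R(q) ≥ s_pq^R − n·s_qp^R` (and the mirrored form),
  mutual exclusion `s_pq^R + s_qp^R ≤ 1`, and "some `R` distinguishes the
  pair". These conditions are necessary for the target to be the coarsest
  balanced coloring, but not sufficient: a repaired graph can satisfy them
  while its coarsest coloring still merges clusters (two mutually fed
  singletons are the smallest example).
* `strict` — the stronger variant requires, for both orientations of each
  cluster pair, distinction by a *third* cluster or a signed within-pair
  combination; it excludes more non-minimal repairs but can also exclude
  genuinely minimal ones (and is always infeasible at `K = 2`).

Because neither variant is sufficient, `solveRepair` in strict mode wraps
the solver in a **verify-and-cut loop**: every incumbent is re-verified by
the package's own refinement machinery (coarsest balanced coloring of the
repaired graph, rigid clusters pre-split, compared to the target as a set
partition). A non-minimal incumbent reveals a *collapse pattern* `B*` — a
strictly coarser balanced coloring merging some target clusters. Since
every balanced coloring refines the coarsest one, no repair whose coarsest
coloring equals the target can be balanced under `B*`; the loop therefore
adds a cut demanding that some pair of co-merged clusters differ in their
summed in-count from some `B*` group (fresh big-M indicators, forced
disjunction) and re-solves. Each cut eliminates an entire collapse pattern
at once — a combinatorial-Benders-style scheme that converges in a handful
of iterations where one-assignment no-good cuts would enumerate
exponentially many equally cheap non-minimal optima (no-good cuts remain as
the fallback representation). The strict variant is tried first and
accepted when its verified optimum matches the relaxed variant's objective
(a certified lower bound); otherwise the relaxed model with cuts — whose
feasible set provably contains every minimal repair — resolves the exact
optimum. The returned objective in strict mode is therefore the true
minimum over repairs whose coarsest balanced coloring equals the target,
which is what the exhaustive-search battery in the acceptance tests
checks. Solver ties among equally cheap edge sets are backend-dependent;
the objective, not the particular edge set, is the contract.

Edge semantics: the MILP sees binary topology. Balance verification uses
binary counts for repaired graphs (matching the edge indicators), while
general fibration machinery reads integer weights as parallel-edge
multiplicities (`mode = "weight"`), with binary available — the collapsed
connectome convention. Modification percentages divide by the original
edge count; the weighted cost mode charges removals their pre-binarisation
(summed left/right) weight, mirroring the bilateral-collapse bookkeeping.

The solver backend is `scipy.optimize.milp` (HiGHS branch-and-bound, MIP
gap 0) through a batched subprocess bridge: all models of a solve round
cross the process boundary in one JSON payload, which keeps permutation
tests (hundreds of solves) cheap. HiGHS is exact and single-threaded
deterministic; determinism of the surrounding pipeline comes from derived
seeds.

## Permutation significance

Null partitions shuffle labels among non-rigid clusters, preserving the
cluster-size multiset and rigid (interneuron-singleton) membership. The
p-value is the fraction of permutations whose optimal modification *count*
(unit costs, matching the objective at α = β = 1) is ≤ the observed one;
denominators: the fixed permutation number (default) or the number of
permutations with a valid minimally-colored solution — both are exposed
because the convention genuinely varies. Counting is exact but lazy: one
relaxed solve per permutation certifies a lower bound on its strict
objective, and only permutations whose bound does not already exceed the
observed count get the full verify-and-cut resolution; recorded per-
permutation objectives are exact for those, certified lower bounds for the
rest. Degenerate targets (one non-rigid cluster, or all-singleton) are
invariant under shuffling and return p = 1 without solving. No pseudocount
floor is applied — a zero count reports p = 0 and should be read as
"p < 1/n". Selecting the minimum-p cutoff across several cuts is done, as
is conventional in this workflow, without multiple-testing correction;
ties are broken by the lower modification percentage.

## The synthetic cohort: what it emulates, and what not

`generateFiberedGraph` draws a random base multigraph, deterministically
perturbs it until its coarsest balanced coloring is discrete (so the
planted fibers are exactly the lift's coarsest coloring — fibers are
*distinguishable*), then lifts it with the lifting property by
construction. `simulateDynamics` integrates an admissible system with
Euler–Maruyama:

* default `saturating-coupling`:
  `dx_i/dt = −x_i + tanh(Σ_j A_ij x_j) + u_f(t)` + white noise, where
  `u_f` is a slow square wave shared within fiber `f` (period `8 + 3k`,
  amplitude `0.4 + 0.1k`, staggered phases) — a stand-in for discrete
  command states driving a motor periphery. The admissibility requirement
  constrains the coupling to the edges; the concrete `F`, `H` and drive
  are package choices (contracting, cheap, synchrony provable), not a
  reconstruction of any particular biological dynamics.
* `kuramoto`: phase oscillators with the same per-fiber drive as a
  frequency offset.

Coupling sums add their terms in value-sorted order, so equal input
multisets produce bit-identical sums: zero-noise shared-IC runs have
*exactly* zero within-fiber spread, and a lifted graph reproduces its base
graph's trajectories to floating-point identity — both are asserted
exactly in the tests, not with tolerances.

The standard study conditions are 7 fibers over 21 neurons (sizes 2–4,
base density 0.5), 8 animals, 20 % of neurons missing per animal, noise
sd 0.05, duration 60 at dt 0.1 (600 samples), matching the scale of a
multi-animal backward-circuit recording campaign. What the generator does
**not** emulate: bleach/motion artefacts, heavy-tailed noise, slow drifts,
behavioural-state structure beyond the square-wave commands, inter-animal
wiring variability (all animals share one graph), and inhibitory or
multi-type synapses. Passing the end-to-end test therefore shows the
pipeline is correct and coherent under its own assumptions — not that it
is robust to everything real recordings do.

## Numerical and degenerate-input conventions

Refinement is the iterative split-by-input-profile algorithm (worst case
`O(n² m)`; graphs here have at most a few hundred nodes, so asymptotically
faster partition refinement is a non-goal). Input-tree isomorphism is
tested by level-wise canonical signatures, avoiding the exponential
explicit trees. Ties everywhere (cluster naming, clique sweeps,
percolation, leaf order reconstruction) are broken lexicographically or by
first occurrence, for determinism. All derived seeds stay below 2³¹.
LoS is strictly positive in exact arithmetic, but at the smallest
bandwidths the Gaussian kernel of order-one differences underflows double
precision to exactly zero; property tests therefore draw series at the
trace scale the metric is meant for.
Empty series, zero-length cliques, all-`NA` matrices, self-loops in
collapses, overlapping bilateral pairs, duplicate edges and negative
weights raise immediate, named errors.

## Problem sizes used by the checks

The exhaustive repair oracle enumerates modification subsets in increasing
count on digraphs of ≤ 5 nodes (battery of 200 instances in the tests,
100 in the acceptance script), capped at 6 (script: 5) modifications: at
that size enumeration is complete and fast while still exercising every
constraint family. The end-to-end study runs the full 44-metric bank on
the 7-fiber cohort with 200 permutations per tested cut — large enough for
a p < 0.05 reading at the observed zero-modification optimum, small enough
to re-run routinely.

## Known limitations

* Strict-mode exactness relies on the verify-and-cut loop; pathological
  instances could need many cuts (capped, then reported `suboptimal` —
  never silently accepted).
* The MILP treats balance in binary topology; weighted balance (equal
  *summed weight* per cluster) is a different, harder model and a
  non-goal.
* Distance correlation on long recordings is O(T²) memory per neuron pair
  batch; fine at hundreds of time points, not designed for hours of
  high-rate data.
* p-values from 200–1000 permutations have Monte-Carlo noise of a few
  hundredths; conclusions near the 0.05 boundary deserve more
  permutations.
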