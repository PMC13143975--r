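---
title: "Tiered constraint-based causal discovery with tierpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered constraint-based causal discovery with tierpc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierpc)
```

## The problem and the model

tierpc learns a causal network from a single observational table of mixed
ordinal/continuous variables in which every variable carries a *time
epoque* — an integer tier (1..8) recording when in the subjects' lives it
was measured or presumed to act. The motivating setting is longitudinal
developmental cohorts: on the order of a thousand subjects, a few hundred
variables spanning demographics, perinatal history, environment, behaviour
and administrative records, and a designated outcome measured in the last
wave.

The inferential machinery is constraint-based discovery under the causal
Markov and faithfulness conditions: if the data are generated by a causal
DAG and the distribution is faithful to it, conditional independencies in
the data identify non-adjacencies in the graph, and the pattern of
*colliders* (A → C ← B with A, B non-adjacent) identifies a portion of the
edge directions — up to the Markov equivalence class. Temporal tiers
sharpen this considerably: a causal edge can never point from a later
epoque into an earlier one, so every cross-tier adjacency is oriented for
free, and the data-driven rules only have to resolve within-tier edges.

The pipeline, in the order `build_global_network()` executes it:

1. **Local discovery** (`gll_pc()`): for each variable, a semi-interleaved
   HITON-PC search over candidates ranked by marginal association,
   eliminating any candidate that becomes independent of the target given
   some subset (size ≤ `max_k`) of the other tentative members. The
   separating set of every eliminated candidate is recorded.
2. **Symmetry correction** (`symmetry_correct()`): an edge survives only if
   each endpoint recovered the other (AND rule).
3. **Skeleton assembly** (`assemble_skeleton()`), then orientation:
   temporal tiers first (`orient_temporal()`), sepset colliders second
   (`orient_colliders()`), Meek propagation last (`orient_meek()`). Earlier
   phases take precedence; a later rule firing against an existing
   orientation is skipped and logged, never overwritten.
4. **Local causal model** (`extract_markov_boundary()`): the outcome's
   direct causes, direct effects and spouses, with unresolved (undirected)
   neighbours reported separately but retained — an undirected edge may
   hide either a parent or a child, so dropping it would understate the
   boundary.
5. **Pathways and impact** (`enumerate_paths()`, `impact_ranking()`): all
   directed simple paths of ≤ 4 edges into the outcome, and each upstream
   variable ranked by the fraction of those paths that its deletion
   severs.

Two safeguards accompany the point estimates: `tie_star_multiplicity()`
probes whether the outcome admits *several* Markov boundaries
(an information-equivalence/faithfulness violation), and
`bootstrap_stability()` reports how often each adjacency is redetected
across 100 row-resamples.

## Conditional-independence testing

The default test for any type mix is a Fisher-z test of the partial
correlation computed on *midranks*. Replacing each involved column by its
ranks makes the test invariant to strictly monotone transforms, which is
the right behaviour for survey-style ordinal scores, and lets one uniform
test serve cardinal, ordinal and binary columns. When all involved
variables are discrete with few levels, a G² likelihood-ratio test
(`g2_test()`) is available.

Missing values are handled by **test-wise deletion**: each test uses
exactly the rows complete for the variables it involves, and its degrees
of freedom are adjusted to that effective sample size — `n_eff` enters the
Fisher-z denominator `sqrt(n_eff − |S| − 3)` and the G² cell counts. This
is unbiased under MCAR missingness, which is also the only regime the
simulator generates.

Tests that *cannot* be computed — fewer than `|S| + 4` complete rows, or a
zero-variance column after deletion — are reported as non-rejections
("independent by insufficiency") and flagged in the result's `reason`
field. This is the conservative PC-family convention: an uncomputable test
never creates an edge, and the decision is auditable rather than silent.

`alpha` is fixed at 0.05 with no multiple-testing correction; error
control in this family comes from the bounded conditioning size and the
AND rule, not from p-value adjustment. `max_k = 3` bounds the conditioning
set; raising it buys separating power at a steep cost in tests and in the
effective sample each test retains.

## The synthetic cohort generator

Because the motivating data are access-restricted, every stage is
validated against a synthetic generator (`sim_config()`, `sample_model()`,
`sample_data()`) whose defaults are fixed once to emulate the study
conditions: 1,053 subjects × 252 variables over 8 epoques; edge density
0.026, which puts the expected edge count (~820) at the scale reported for
such cohorts; 5% MCAR missingness; and a 50/40/10 mix of cardinal,
4-level-ordinal and binary variables, a realistic profile for longitudinal
survey data. Mechanisms are linear-Gaussian — each node a weighted sum of
its parents plus unit noise, weights drawn from ±[0.3, 1.0] so no
dependency sits near zero — with ordinal/binary columns produced by
monotone quantile discretization of the continuous value. Children are
driven by the continuous latent, so the graphical independence structure
is exact and `d_separated()` provides ground truth for every CI query.

What the generator deliberately does **not** emulate: MAR/MNAR
missingness, nonlinear or interaction effects, latent confounders, and
measurement error. Passing the simulation benchmarks therefore
demonstrates correctness of the algorithms under the model's own
assumptions — not robustness of those assumptions on real cohort data.

Duplicate columns (`n_duplicates`) are exact deterministic copies of
randomly chosen sources. They are generated *outside* the structural
equations, which is why `d_separated()` refuses queries naming a
duplicate: graphically they are the same node as their source.

## Numerical and design choices

* **Determinism.** Candidate admission is ordered by p-value, then
  |statistic|, then name; triples and Meek sweeps run in lexicographic
  order; bootstrap replicates draw from substreams derived once from the
  master seed. Two runs with the same data, config and seed are
  byte-identical, including serialized outputs.
* **Collider conflicts.** Finite-sample sepsets can disagree (two triples
  demanding opposite directions, or a direction against time order). The
  first rule to fire — in lexicographic triple order, with temporal
  orientations immovable — wins; every skipped attempt is logged in the
  orientation report's conflict table rather than resolved silently.
* **Meek propagation** applies rules R1–R4 to a fixed point, and every
  candidate orientation is additionally guarded by an explicit
  no-directed-cycle and no-new-unshielded-collider check. The test suite
  verifies against exhaustive enumeration of consistent DAG extensions (on
  small graphs) that the propagated orientations are exactly the compelled
  ones.
* **One-sided vs symmetric discovery.** Raw HITON-PC retains a known class
  of false positives — descendants reachable through spouse colliders that
  no subset of the target's own neighbourhood separates. The AND rule
  removes exactly these, and the suite asserts it removes nothing else
  under the oracle. The *multiplicity* test, by contrast, runs on the
  one-sided local inducer (`local_markov_boundary()`, with an IAMB-style
  backward minimality pass): with an exact duplicate the AND rule deletes
  the target edges of *both* copies — each side separates via the other —
  so only the one-sided route can surface the equivalent boundaries the
  test exists to find.
* **Multiplicity criterion.** The reduced TIE*-style search hides every
  subset (≤ `max_subset`, default 2) of the union of boundaries found so
  far and re-runs discovery; a candidate boundary is accepted when every
  base-boundary member outside it is independent of the target given it.
  The full generative TIE* admits many equivalence criteria; this one is
  explicit and configurable, and iterating over the growing union is what
  lets chains of equivalent variables (triplicates and beyond) all
  surface.
* **Path semantics.** "Four path-lengths" is read as ≤ 4 *edges*
  (configurable). Paths traverse directed edges only by default: walking
  an unoriented edge would count routes whose causal direction is
  unresolved. Deleting a node removes its incident edges, so the paths it
  eliminates are exactly those containing it; the ranking reports that
  fraction per node.
* **Stability matching** is orientation-agnostic by default, since
  orientation provenance legitimately varies across resamples while the
  adjacency itself is the replicable claim. Note that bootstrap stability
  of a *null* edge is not bounded by alpha: replicates centre on the
  observed correlation of the data at hand, so a sample that happens to
  sit near the significance threshold reappears in a large share of its
  own replicates. Null-edge stability is only controlled on average over
  datasets (empirically ≈ 20% at n = 1000, alpha = .05).

## Problem sizes used in the shipped analyses

The analysis series under `analysis/` and the acceptance script run the
pipeline at a reduced scale chosen to keep a full reproduction inside a
few minutes on one CPU while preserving the qualitative regime (sample
size 1,053, average degree ≈ 6.5, 8 epoques, mixed types, 5% MCAR): a
40-variable cohort for the network/boundary/path analyses, a 12-variable
subproblem for the 100-replicate bootstrap, 30 variables × 20 seeds for
finite-sample recovery benchmarking, and ≤ 15-node graphs for the oracle
exactness sweeps. These sizes are the package's own benchmarking choices;
nothing in the method is specific to them.

## A worked miniature

```{r worked}
cfg <- sim_config(n_vars = 12, n_rows = 600, edge_density = 0.2,
                  missing_rate = 0.05, seed = 21)
model <- sample_model(cfg)
sim <- sample_data(model, seed = 22)

net <- build_global_network(sim$dataset, sim$table)
net$report

target <- model$topo_order[length(model$topo_order)]
extract_markov_boundary(net$graph, target)

paths <- enumerate_paths(net$graph, target, max_len = 4)
impact_ranking(paths)
```

## Known limitations

* Constraint-based discovery inherits every caveat of the faithfulness
  assumption; near-cancelling pathways produce unstable edges, which is
  precisely what the bootstrap report is for.
* Hidden (unmeasured) common causes are out of scope: an edge here means
  "directly dependent given the measured variables", and confounding from
  outside the variable set can masquerade as causation.
* The G² path treats its conditioning strata as fixed; with many strata
  and modest n it degrades to the insufficiency path and abstains.
* Orientation within a tier is only identified up to the Markov
  equivalence class; edges the data cannot compel stay undirected and are
  reported as such rather than guessed.
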