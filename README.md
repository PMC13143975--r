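# tierpc — tiered constraint-based causal discovery

`tierpc` learns causal network models from observational cohort tables in
which every variable carries a **time epoque** — an integer tier (1..8)
recording when in the subjects' lives it was measured or presumed to act.
It is built for longitudinal developmental studies: on the order of a
thousand subjects, a few hundred mixed ordinal/continuous variables with
missing values, and a designated outcome in the last wave. The package
answers three questions about such a table: *which variables directly
cause or are caused by the outcome* (its Markov boundary), *how stable is
each learned relation under resampling*, and *which upstream variables sit
on the largest share of causal pathways into the outcome*.

## The method

Under the causal Markov and faithfulness conditions, conditional
independencies identify the skeleton of the generating DAG, and collider
patterns (A → C ← B with A, B non-adjacent) identify part of its
orientation. `tierpc` implements the constraint-based pipeline:

1. **Local discovery** — semi-interleaved HITON-PC per variable: candidates
   ranked by marginal association enter a tentative set and are eliminated
   (with their separating set recorded) whenever some conditioning set
   *S*, |*S*| ≤ `max_k` = 3, makes them independent of the target at
   `alpha` = .05.
2. **AND-rule symmetry** — an edge survives only if each endpoint
   recovered the other.
3. **Orientation** — temporal tiers first (an edge between epoques *i* <
   *j* always points forward in time), then sepset colliders, then Meek
   rules R1–R4 to a fixed point; earlier phases are never overwritten and
   conflicts are logged.
4. **Markov boundary** — direct causes ∪ direct effects ∪ spouses of the
   outcome, with unresolved undirected neighbours retained and flagged.
5. **Safeguards** — TIE*-style multiplicity testing (are there several
   information-equivalent boundaries?), 100-replicate bootstrap edge
   stability, and test-wise deletion with degree-of-freedom adjustment for
   missing data.
6. **Impact ranking** — all directed paths of ≤ 4 edges into the outcome;
   each upstream node is scored by the fraction of paths its deletion
   eliminates.

Conditional independence is tested by Fisher-z on midrank partial
correlations (monotone-invariant, uniform across cardinal/ordinal/binary
columns), with a G² likelihood-ratio test available for all-discrete
queries. A linear-Gaussian tiered-DAG simulator and an exact d-separation
oracle make every stage testable without access to restricted cohort data.

## Worked example

```r
library(tierpc)

cfg   <- sim_config(n_vars = 12, n_rows = 600, edge_density = 0.2,
                    missing_rate = 0.05, seed = 21)
model <- sample_model(cfg)
sim   <- sample_data(model, seed = 22)

net <- build_global_network(sim$dataset, sim$table)
net$report
#> Orientation report: 11 edges
#>   temporal       9 (81.8%)
#>   collider       2 (18.2%)
#>   meek           0 (0.0%)
#>   unoriented     0 (0.0%)

target <- model$topo_order[length(model$topo_order)]  # "V007"
extract_markov_boundary(net$graph, target)
#> Markov boundary of V007: 2 variable(s)
#>   direct causes:         V001, V003
#>   direct effects:
#>   spouses:
#>   undirected neighbours:

impact_ranking(enumerate_paths(net$graph, target, max_len = 4))
#> Intervention-impact ranking over 5 path(s) into V007
#>   node n_paths eliminated_fraction
#> 1 V001       4                 0.8
#> 2 V010       2                 0.4
#> 3 V002       1                 0.2
#> 4 V003       1                 0.2
#> 5 V008       1                 0.2
```

Of the 11 learned edges, 9 were compelled by time order alone and 2 by
colliders; the outcome's boundary contains its two direct causes, and
deleting `V001` severs 80% of the causal pathways into it.

The `analysis/` directory carries the same workflow as a numbered script
series over a simulated 1,053-subject cohort — `01_simulate.R` through
`05_bootstrap_stability.R` — each writing its tables under `results/`.

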