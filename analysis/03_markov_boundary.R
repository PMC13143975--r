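#!/usr/bin/env Rscript

# Step 3 — the local causal model of the designated outcome.
#
# Picks the outcome variable the way the study design intends — the
# latest-epoque variable with the largest discovered neighbourhood — then
# extracts its Markov boundary (direct causes, direct effects, spouses,
# unresolved neighbours) from the step-2 network and tests the boundary for
# multiplicity (information-equivalent alternatives) on the cohort data.

suppressMessages(library(tierpc))

tab <- read_variable_table("results/variable_table.csv")
ds <- read_dataset("results/cohort.csv", tab)
g <- read_network("results/global_network.tsv")

ep <- g$epoque
late <- sort(names(ep)[ep == max(ep)])
deg <- vapply(late, function(v) length(pdg_parents(g, v)) +
                length(pdg_children(g, v)) +
                length(pdg_undirected_neighbors(g, v)), 0L)
target <- late[order(-deg, late)][1L]
message("Designated outcome variable: ", target,
        " (epoque ", ep[[target]], ")")

mb <- extract_markov_boundary(g, target)
print(mb)
write_network(mb$local_graph, "results/local_network.tsv", "edge_list_tsv")

mult <- tie_star_multiplicity(ds, tab, target, alpha = 0.05, max_k = 3L)
print(mult)

jsonlite::write_json(
  list(target = target,
       direct_causes = mb$direct_causes,
       direct_effects = mb$direct_effects,
       spouses = mb$spouses,
       undirected_neighbors = mb$undirected_neighbors,
       multiplicity = mult$verdict,
       n_boundaries = length(mult$boundaries)),
  "results/markov_boundary.json", pretty = TRUE)
message("Wrote results/local_network.tsv, results/markov_boundary.json")
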