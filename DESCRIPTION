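Package: tierpc
Title: Tiered Constraint-Based Causal Discovery with Markov Boundaries and
    Edge Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based causal network discovery for longitudinal
    observational studies in which every variable carries a time epoque
    (measurement tier). Implements semi-interleaved HITON-PC local discovery
    with bounded conditioning-set size, global skeleton assembly with
    AND-rule symmetry correction, edge orientation by temporal tiers,
    sepset-based collider detection and Meek propagation, Markov-boundary
    extraction with a multiplicity (information-equivalence) test, bootstrap
    edge-stability estimation, and path-based intervention-impact ranking.
    Includes conditional-independence tests for mixed ordinal/continuous
    data with test-wise deletion of missing values, a linear-Gaussian
    tiered-DAG simulator, and an exact d-separation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
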