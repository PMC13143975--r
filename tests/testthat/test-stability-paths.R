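worked_example <- function() {
  g <- pdg(c("A", "B", "T"))
  g <- pdg_add_edge(g, "A", "B", "directed")
  g <- pdg_add_edge(g, "B", "T", "directed")
  g <- pdg_add_edge(g, "A", "T", "directed")
  g
}

test_that("path enumeration matches hand counts and honours the length cap", {
  g <- worked_example()
  pp <- enumerate_paths(g, "T")
  expect_length(pp$paths, 3L)
  expect_setequal(vapply(pp$paths, paste, "", collapse = ">"),
                  c("A>T", "B>T", "A>B>T"))

  # a 5-edge chain into T: the full path is excluded, its 4-edge suffix kept
  nodes <- c("N1", "N2", "N3", "N4", "N5", "T")
  gc <- pdg(nodes)
  for (i in 1:5) {
    gc <- pdg_add_edge(gc, nodes[i], nodes[i + 1L], "directed")
  }
  pc <- enumerate_paths(gc, "T", max_len = 4L)
  lens <- vapply(pc$paths, length, 0L) - 1L
  expect_equal(sort(lens), 1:4)
  expect_false(any(vapply(pc$paths, function(p) "N1" %in% p, TRUE)))

  # undirected edges are excluded by default, traversable on request
  gu <- pdg(c("U", "T"))
  gu <- pdg_add_edge(gu, "U", "T")
  expect_length(enumerate_paths(gu, "T")$paths, 0L)
  expect_length(enumerate_paths(gu, "T", traverse_undirected = TRUE)$paths, 1L)

  expect_error(enumerate_paths(g, "Z"), "not in graph")
})

test_that("path enumeration agrees with the igraph exhaustive oracle", {
  for (s in 1:25) {
    m <- random_test_model(s + 900, n_vars = 10, density = 0.3, epoques = 4)
    net <- build_global_network(model = m, backend_kind = "oracle",
                                table = model_variable_table(m))
    target <- m$nodes[5L]
    for (L in c(2L, 4L)) {
      mine <- enumerate_paths(net$graph, target, max_len = L)
      oracle <- igraph_paths_to_target(net$graph, target, L)
      key <- function(p) paste(p, collapse = ">")
      expect_setequal(vapply(mine$paths, key, ""),
                      vapply(oracle, key, ""))
    }
  }
})

test_that("impact fractions match hand counts and the delete-and-recount oracle", {
  pp <- enumerate_paths(worked_example(), "T")
  rk <- impact_ranking(pp)$ranking
  expect_equal(rk$eliminated_fraction[rk$node == "A"], 2 / 3)
  expect_equal(rk$eliminated_fraction[rk$node == "B"], 2 / 3)
  # ties broken lexicographically
  expect_equal(rk$node, c("A", "B"))

  # a node on every path scores 1
  gc <- pdg(c("X", "M", "T"))
  gc <- pdg_add_edge(gc, "X", "M", "directed")
  gc <- pdg_add_edge(gc, "M", "T", "directed")
  rk2 <- impact_ranking(enumerate_paths(gc, "T"))$ranking
  expect_equal(rk2$eliminated_fraction[rk2$node == "M"], 1)

  # delete-and-recount oracle on random graphs
  for (s in 1:15) {
    m <- random_test_model(s + 950, n_vars = 9, density = 0.3)
    net <- build_global_network(model = m, backend_kind = "oracle",
                                table = model_variable_table(m))
    target <- m$nodes[4L]
    pp <- enumerate_paths(net$graph, target, max_len = 4L)
    if (length(pp$paths) == 0L) next
    rk <- impact_ranking(pp)$ranking
    for (i in seq_len(nrow(rk))) {
      v <- rk$node[i]
      # physically remove v and recount
      g2 <- net$graph
      keep <- g2$edges$u != v & g2$edges$v != v
      g2$edges <- g2$edges[keep, , drop = FALSE]
      g2$nodes <- setdiff(g2$nodes, v)
      g2$sepsets <- list()
      left <- length(enumerate_paths(g2, target, max_len = 4L)$paths)
      expect_equal(rk$n_paths[i], length(pp$paths) - left,
                   info = sprintf("seed %d node %s", s + 950, v))
    }
    # conservation: counts never exceed the total
    expect_true(all(rk$n_paths <= length(pp$paths)))
  }

  # zero paths: empty ranking with a warning
  gi <- pdg(c("T", "X"))
  expect_warning(rk0 <- impact_ranking(enumerate_paths(gi, "T")), "no paths")
  expect_equal(nrow(rk0$ranking), 0L)
})

test_that("oracle-backed stability is invariant to resampling", {
  m <- random_test_model(1001, n_vars = 7, density = 0.35)
  tab <- model_variable_table(m)
  st <- bootstrap_stability(table = tab, B = 20L, seed = 3,
                            backend_kind = "oracle", model = m)
  expect_true(all(st$edges$percent == 100))
  expect_true(all(st$edges$in_full_graph))
})

test_that("bootstrap stability is seed-deterministic and bounded for null pairs", {
  set.seed(11)
  d <- cbind(a = rnorm(400), b = rnorm(400))
  tab <- variable_table(c("a", "b"), c("cardinal", "cardinal"), c(1, 1))
  s1 <- bootstrap_stability(d, tab, B = 30L, seed = 5)
  s2 <- bootstrap_stability(d, tab, B = 30L, seed = 5)
  expect_identical(s1$edges, s2$edges)

  # a by-construction independent pair is rarely detected
  set.seed(21)
  dd <- cbind(a = rnorm(1000), b = rnorm(1000))
  st <- bootstrap_stability(dd, tab, B = 100L, seed = 9)
  null_pct <- if (nrow(st$edges) == 0L) 0 else max(st$edges$percent)
  expect_lte(null_pct, 25)
})

test_that("full-graph edges dominate spurious edges in stability", {
  m <- manual_model(list(X = character(), T = "X", Z = character()),
                    weights = list(X = numeric(), T = c(X = 0.9),
                                   Z = numeric()))
  sd_ <- sample_data(m, n_rows = 800, missing_rate = 0, seed = 13)
  st <- bootstrap_stability(sd_$dataset, sd_$table, B = 50L, seed = 13)
  e <- st$edges
  is_true_edge <- (e$u == "T" & e$v == "X") | (e$u == "X" & e$v == "T")
  strong <- e$percent[is_true_edge]
  expect_length(strong, 1L)
  expect_gte(strong, 90)
  expect_true(all(e$percent[!is_true_edge] <= strong))
})
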