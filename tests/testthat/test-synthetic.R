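test_that("sampled models respect epoque order, density and determinism", {
  cfg0 <- sim_config(n_vars = 10, n_rows = 50, edge_density = 0, seed = 4)
  expect_warning(m0 <- sample_model(cfg0), "no edges")
  expect_equal(sum(lengths(m0$parents)), 0L)

  for (s in 1:20) {
    m <- random_test_model(s, n_vars = 12, epoques = 4)
    ed <- model_edges(m)
    # constructive invariant: no edge from a later epoque to an earlier one
    expect_true(all(m$epoque[ed$from] <= m$epoque[ed$to]))
    # weights bounded away from zero
    w <- unlist(m$weights, use.names = FALSE)
    if (length(w) > 0L) expect_true(all(abs(w) >= 0.3 & abs(w) <= 1.0))
  }

  cfg <- sim_config(n_vars = 15, n_rows = 30, edge_density = 0.2, seed = 99)
  expect_identical(sample_model(cfg), sample_model(cfg))
})

test_that("sampled data honour missingness, duplicates and seed determinism", {
  cfg <- sim_config(n_vars = 20, n_rows = 10000, edge_density = 0.1,
                    missing_rate = 0.1, seed = 5)
  m <- sample_model(cfg)
  sd_ <- sample_data(m, seed = 5)
  frac <- mean(is.na(sd_$dataset$values))
  # binomial 3-sd band around 0.1 at 200k cells is well inside +-0.01
  expect_lt(abs(frac - 0.1), 0.01)

  sd0 <- sample_data(m, missing_rate = 0, seed = 5)
  expect_equal(sum(is.na(sd0$dataset$values)), 0L)
  expect_identical(sample_data(m, seed = 5), sample_data(m, seed = 5))

  cfgd <- sim_config(n_vars = 8, n_rows = 500, edge_density = 0.2,
                     missing_rate = 0.2, n_duplicates = 2, seed = 6)
  md <- sample_model(cfgd)
  expect_length(md$duplicates, 2L)
  sdd <- sample_data(md, seed = 6)
  for (dup in names(md$duplicates)) {
    src <- md$duplicates[[dup]]
    a <- sdd$dataset$values[, dup]
    b <- sdd$dataset$values[, src]
    ok <- !is.na(a) & !is.na(b)
    expect_identical(a[ok], b[ok])  # identity recoding on observed rows
  }
  # table covers duplicates with the source's epoque and type
  expect_true(all(names(md$duplicates) %in% sdd$table$name))
})

test_that("discretized columns are integer-coded with the requested levels", {
  cfg <- sim_config(n_vars = 30, n_rows = 400, edge_density = 0.1, seed = 8,
                    missing_rate = 0,
                    vtype_probs = c(cardinal = 0.3, ordinal = 0.4, binary = 0.3),
                    ordinal_levels = 4)
  m <- sample_model(cfg)
  sd_ <- sample_data(m, seed = 8)
  for (v in m$nodes) {
    x <- sd_$dataset$values[, v]
    if (m$vtype[[v]] == "binary") expect_setequal(unique(x), 0:1)
    if (m$vtype[[v]] == "ordinal") {
      expect_true(all(x == round(x)))
      expect_lte(length(unique(x)), 4L)
    }
  }
})

test_that("d-separation follows the textbook blocking rules", {
  chain <- manual_model(list(A = character(), B = "A", C = "B"))
  expect_false(d_separated(chain, "A", "C"))
  expect_true(d_separated(chain, "A", "C", "B"))  # conditioning on B blocks

  collider <- manual_model(list(A = character(), B = character(), C = c("A", "B")))
  expect_true(d_separated(collider, "A", "B"))
  expect_false(d_separated(collider, "A", "B", "C"))  # conditioning opens

  # collider descendant also opens the path
  desc <- manual_model(list(A = character(), B = character(),
                            C = c("A", "B"), D = "C"))
  expect_false(d_separated(desc, "A", "B", "D"))

  expect_error(d_separated(chain, "A", "Z"), "unknown")
  expect_error(d_separated(chain, "A", "A"), "differ")
  expect_error(d_separated(chain, "A", "B", "A"), "not be in S")
})

test_that("d-separation agrees with the moralization oracle on random DAGs", {
  set.seed(42)
  for (s in 1:12) {
    m <- random_test_model(s, n_vars = 8, density = 0.3)
    nodes <- m$nodes
    prs <- utils::combn(nodes, 2L, simplify = FALSE)
    for (p in prs) {
      others <- setdiff(nodes, p)
      subsets <- c(list(character()),
                   lapply(others, identity),
                   utils::combn(others, 2L, simplify = FALSE),
                   utils::combn(others, 3L, simplify = FALSE))
      # exercise a deterministic thinning to keep runtime modest
      subsets <- subsets[seq(1L, length(subsets), by = 3L)]
      for (S in subsets) {
        expect_identical(d_separated(m, p[1L], p[2L], S),
                         msep_moral(m, p[1L], p[2L], S),
                         info = sprintf("seed %d: %s _||_ %s | {%s}", s,
                                        p[1L], p[2L], paste(S, collapse = ",")))
      }
    }
  }
})

test_that("implied vanishing partial correlations vanish in large samples", {
  m <- random_test_model(31, n_vars = 10, density = 0.25)
  sd_ <- sample_data(m, n_rows = 50000, missing_rate = 0, seed = 31)
  vals <- sd_$dataset$values[, m$nodes]
  checked <- 0L
  prs <- utils::combn(m$nodes, 2L, simplify = FALSE)
  for (p in prs) {
    if (checked >= 25L) break
    for (S in c(list(character()),
                lapply(setdiff(m$nodes, p), identity))) {
      if (d_separated(m, p[1L], p[2L], S)) {
        sub <- vals[, c(p, S), drop = FALSE]
        if (length(S) == 0L) {
          r <- stats::cor(sub[, 1L], sub[, 2L])
        } else {
          rx <- stats::resid(stats::lm.fit(cbind(1, sub[, -(1:2), drop = FALSE]), sub[, 1L]))
          ry <- stats::resid(stats::lm.fit(cbind(1, sub[, -(1:2), drop = FALSE]), sub[, 2L]))
          r <- stats::cor(rx, ry)
        }
        expect_lt(abs(r), 0.03)
        checked <- checked + 1L
        break
      }
    }
  }
  expect_gt(checked, 5L)  # the property was actually exercised
})
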