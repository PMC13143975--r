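test_that("fisher-z flags a duplicated column as overwhelmingly dependent", {
  set.seed(1)
  x <- rnorm(200)
  d <- cbind(x = x, y = x)
  res <- fisher_z_test(d, "x", "y")
  expect_lt(res$p_value, 1e-15)
  expect_false(res$independent)
  expect_equal(res$n_effective, 200L)
})

test_that("fisher-z is symmetric and invariant to monotone transforms", {
  set.seed(2)
  n <- 300
  z <- rnorm(n)
  d <- cbind(a = z + rnorm(n), b = z + rnorm(n), c = z, e = rnorm(n))
  r1 <- fisher_z_test(d, "a", "b", "c")
  r2 <- fisher_z_test(d, "b", "a", "c")
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)

  # strictly monotone transforms of x and y leave the ranked test unchanged
  d2 <- d
  d2[, "a"] <- exp(d2[, "a"])
  d2[, "b"] <- d2[, "b"]^3
  r3 <- fisher_z_test(d2, "a", "b", "c")
  expect_equal(r3$p_value, r1$p_value, tolerance = 1e-12)
})

test_that("test-wise deletion ignores missingness in unrelated columns", {
  set.seed(3)
  n <- 250
  d <- cbind(x = rnorm(n), y = rnorm(n), s = rnorm(n), junk = rnorm(n))
  base <- fisher_z_test(d, "x", "y", "s")
  d2 <- d
  d2[sample(n, 100), "junk"] <- NA  # unrelated column
  after <- fisher_z_test(d2, "x", "y", "s")
  expect_identical(base[c("statistic", "p_value", "n_effective")],
                   after[c("statistic", "p_value", "n_effective")])

  # missingness in an involved column shrinks the effective sample size
  d3 <- d
  d3[1:50, "x"] <- NA
  expect_equal(fisher_z_test(d3, "x", "y", "s")$n_effective, n - 50L)
})

test_that("uncomputable tests come back as independent-by-insufficiency", {
  d <- cbind(x = c(1, 2, 3, NA, NA), y = c(2, 1, NA, 1, 2),
             s = c(1, NA, 2, 3, 4))
  res <- fisher_z_test(d, "x", "y", "s")
  expect_true(res$independent)
  expect_equal(res$p_value, 1)
  expect_match(res$reason, "insufficient")

  # zero-variance column after deletion takes the same path
  d2 <- cbind(x = c(rep(5, 30)), y = rnorm(30))
  res2 <- fisher_z_test(d2, "x", "y")
  expect_true(res2$independent)
  expect_match(res2$reason, "zero-variance")
})

test_that("fisher-z p-value tracks a residual-permutation oracle", {
  set.seed(7)
  n <- 30
  s1 <- rnorm(n); s2 <- rnorm(n)
  d <- cbind(x = 0.5 * s1 + rnorm(n), y = 0.4 * s1 - 0.3 * s2 + rnorm(n),
             s1 = s1, s2 = s2)
  res <- fisher_z_test(d, "x", "y", c("s1", "s2"))

  # oracle: permute x's residuals against y's residuals, 20,000 draws
  rk <- apply(d, 2L, rank)
  X <- cbind(1, rk[, c("s1", "s2")])
  qx <- qr(X)
  rx <- qr.resid(qx, rk[, "x"])
  ry <- qr.resid(qx, rk[, "y"])
  r_obs <- abs(cor(rx, ry))
  set.seed(8)
  B <- 20000
  r_perm <- vapply(seq_len(B), function(i) abs(cor(sample(rx), ry)), 0)
  p_perm <- (1 + sum(r_perm >= r_obs)) / (B + 1)
  # Monte-Carlo error plus the normal approximation at n = 30
  expect_lt(abs(res$p_value - p_perm), 0.05)
})

test_that("G-squared matches hand-computed tables and degrees of freedom", {
  # balanced 2x2 table: exact independence
  d <- cbind(x = rep(0:1, each = 50), y = rep(rep(0:1, 2), each = 25))
  res <- g2_test(d, "x", "y")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1L)

  # association table [[30,10],[10,30]], margins all 40/80 so e = 20:
  # G2 = 2 sum o ln(o/e) = 2*(2*30*ln(3/2) + 2*10*ln(1/2)) = 20.93 (2 dp)
  x <- c(rep(0, 40), rep(1, 40))
  y <- c(rep(0, 30), rep(1, 10), rep(0, 10), rep(1, 30))
  res2 <- g2_test(cbind(x = x, y = y), "x", "y")
  expect_equal(res2$statistic,
               2 * (2 * 30 * log(30 / 20) + 2 * 10 * log(10 / 20)),
               tolerance = 1e-12)
  expect_equal(round(res2$statistic, 2), 20.93)
  expect_equal(res2$df, 1L)
  expect_false(res2$independent)

  # binary x,y given one 3-level stratifier: df = (2-1)(2-1)*3 = 3
  set.seed(9)
  s <- sample(0:2, 600, replace = TRUE)
  xx <- rbinom(600, 1, 0.5); yy <- rbinom(600, 1, 0.5)
  res3 <- g2_test(cbind(x = xx, y = yy, s = s), "x", "y", "s")
  expect_equal(res3$df, 3L)

  # degenerate table: single-level column cannot be tested
  res4 <- g2_test(cbind(x = rep(1, 20), y = rep(0:1, 10)), "x", "y")
  expect_true(res4$independent)
  expect_match(res4$reason, "degenerate")

  expect_error(g2_test(cbind(x = c(0.5, 1.2), y = c(0, 1)), "x", "y"),
               "discrete")
})

test_that("the oracle test mirrors d-separation exactly", {
  chain <- manual_model(list(A = character(), B = "A", C = "B"))
  expect_true(oracle_test(chain, "A", "C", "B")$independent)
  expect_false(oracle_test(chain, "A", "C")$independent)
  # adjacency is never separable, whatever the conditioning set
  expect_false(oracle_test(chain, "A", "B", "C")$independent)

  set.seed(10)
  m <- random_test_model(3, n_vars = 8, density = 0.3)
  for (i in 1:200) {
    p <- sample(m$nodes, 2L)
    S <- sample(setdiff(m$nodes, p), sample(0:3, 1L))
    res <- oracle_test(m, p[1L], p[2L], S)
    expect_identical(res$independent, d_separated(m, p[1L], p[2L], S))
    expect_identical(res$p_value, as.numeric(res$independent))
  }
})

test_that("backend memoization returns identical results across query order", {
  set.seed(11)
  d <- matrix(rnorm(400), ncol = 4,
              dimnames = list(NULL, c("a", "b", "c", "e")))
  bk <- ci_backend("fisher_z", data = d, alpha = 0.05)
  r1 <- bk$test("a", "b", c("c"))
  r2 <- bk$test("b", "a", c("c"))
  expect_identical(r1, r2)  # symmetric key hits the cache
  expect_identical(r1[c("p_value", "statistic")],
                   fisher_z_test(d, "a", "b", "c")[c("p_value", "statistic")])
})
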