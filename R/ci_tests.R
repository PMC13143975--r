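#' @title Conditional-independence testing with test-wise deletion
#' @description The atoms of constraint-based discovery. All tests use
#'   test-wise deletion for missing data: each test is computed on the rows
#'   complete for exactly the variables involved, with the effective sample
#'   size (and hence degrees of freedom) adjusted accordingly. Tests that
#'   cannot be computed (too few complete rows, or a zero-variance column
#'   after deletion) are reported as non-rejections ("independent by
#'   insufficiency") and flagged via the `reason` field, never silently
#'   dropped — the standard conservative convention in PC-family algorithms.
#' @name ci_tests
NULL

ci_result <- function(x, y, S, statistic, p_value, n_effective, alpha,
                      method, reason = "ok") {
  structure(
    list(x = x, y = y, S = sort(as.character(S)), statistic = statistic,
         p_value = p_value, n_effective = n_effective,
         independent = p_value > alpha, alpha = alpha, method = method,
         reason = reason),
    class = "tierpc_ci_result"
  )
}

#' @export
print.tierpc_ci_result <- function(x, ...) {
  cat(sprintf("CI test [%s]: %s _||_ %s | {%s}\n", x$method, x$x, x$y,
              paste(x$S, collapse = ",")))
  cat(sprintf("  stat = %.4g, p = %.4g, n_eff = %s -> %s%s\n",
              x$statistic, x$p_value, format(x$n_effective),
              if (x$independent) "independent" else "dependent",
              if (x$reason != "ok") paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

insufficiency_result <- function(x, y, S, n_eff, alpha, method, reason) {
  ci_result(x, y, S, statistic = 0, p_value = 1, n_effective = n_eff,
            alpha = alpha, method = method, reason = reason)
}

# midranks of a numeric vector, NA preserved
midrank <- function(v) {
  r <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  r[ok] <- rank(v[ok], ties.method = "average")
  r
}

# partial correlation of cols 1 and 2 of matrix m (complete rows, midranked)
# given the remaining columns; qr-based so rank deficiency (duplicated
# conditioning variables) degrades gracefully to residual correlation.
partial_cor_ranked <- function(m) {
  rk <- apply(m, 2L, function(col) rank(col, ties.method = "average"))
  if (ncol(m) == 2L) {
    sx <- stats::sd(rk[, 1L]); sy <- stats::sd(rk[, 2L])
    if (sx == 0 || sy == 0) return(NA_real_)
    return(stats::cor(rk[, 1L], rk[, 2L]))
  }
  X <- cbind(1, rk[, -(1:2), drop = FALSE])
  qx <- qr(X)
  rx <- qr.resid(qx, rk[, 1L])
  ry <- qr.resid(qx, rk[, 2L])
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  tol <- 1e-8 * nrow(m)
  if (sx < tol && sy < tol) return(NA_real_)
  if (sx < tol || sy < tol) return(0)  # fully explained by S: independent given S
  sum(rx * ry) / (sx * sy)
}

#' Fisher-z partial-correlation test on midranked data
#'
#' Computes the partial correlation of `x` and `y` given `S` on the rows
#' complete for `{x, y} ∪ S`, after replacing each involved column by its
#' midranks (so the test is invariant to strictly monotone transforms and
#' applies uniformly to cardinal, ordinal and binary columns). The statistic
#' is `sqrt(n_eff - |S| - 3) * |atanh(r)|` with a two-sided normal p-value.
#'
#' @param data a `tierpc_dataset`, matrix or data frame with named columns.
#' @param x,y variable names.
#' @param S conditioning set (character vector, default empty).
#' @param alpha significance threshold (default 0.05); `independent` is
#'   `p_value > alpha`.
#' @return a `tierpc_ci_result` with fields `x`, `y`, `S`, `statistic`,
#'   `p_value`, `n_effective`, `independent`, `reason`.
#' @examples
#' set.seed(1)
#' d <- cbind(a = rnorm(200), b = rnorm(200))
#' fisher_z_test(d, "a", "b")$independent
#' @export
fisher_z_test <- function(data, x, y, S = character(), alpha = 0.05) {
  vals <- dataset_values(data)
  for (v in c(x, y, S)) {
    if (!v %in% colnames(vals)) stop("unknown variable '", v, "'", call. = FALSE)
  }
  sub <- vals[, c(x, y, S), drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  n_eff <- nrow(sub)
  k <- length(S)
  if (n_eff < k + 4L) {
    return(insufficiency_result(x, y, S, n_eff, alpha, "fisher_z",
                                "insufficient complete cases"))
  }
  r <- partial_cor_ranked(sub)
  if (is.na(r)) {
    return(insufficiency_result(x, y, S, n_eff, alpha, "fisher_z",
                                "zero-variance column after deletion"))
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  stat <- sqrt(n_eff - k - 3) * abs(atanh(r))
  p <- 2 * stats::pnorm(-stat)
  ci_result(x, y, S, statistic = stat, p_value = p, n_effective = n_eff,
            alpha = alpha, method = "fisher_z")
}

#' G-squared (likelihood-ratio) test for discrete variables
#'
#' `G² = 2 Σ o·ln(o/e)` summed over the cells of the `x` by `y` table within
#' each stratum of `S`, with expected counts from the stratum margins. The
#' degrees of freedom are `(r_x - 1)(r_y - 1) Π_s r_s` using the level counts
#' observed in the complete-case data; strata with no observations contribute
#' nothing. Requires all involved variables discrete (binary/ordinal).
#'
#' @inheritParams fisher_z_test
#' @return a `tierpc_ci_result`.
#' @examples
#' d <- cbind(x = rep(0:1, each = 50), y = rep(rep(0:1, 2), each = 25))
#' g2_test(d, "x", "y")  # balanced 2x2 table: G2 = 0, p = 1
#' @export
g2_test <- function(data, x, y, S = character(), alpha = 0.05) {
  vals <- dataset_values(data)
  for (v in c(x, y, S)) {
    if (!v %in% colnames(vals)) stop("unknown variable '", v, "'", call. = FALSE)
  }
  sub <- vals[, c(x, y, S), drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  n_eff <- nrow(sub)
  if (n_eff == 0L) {
    return(insufficiency_result(x, y, S, n_eff, alpha, "g2",
                                "insufficient complete cases"))
  }
  if (any(sub != round(sub))) {
    stop("g2_test requires discrete (integer-coded) variables", call. = FALSE)
  }
  rx <- length(unique(sub[, 1L]))
  ry <- length(unique(sub[, 2L]))
  rs <- if (length(S) > 0L) {
    vapply(seq_along(S) + 2L, function(j) length(unique(sub[, j])), 0L)
  } else integer()
  df <- (rx - 1L) * (ry - 1L) * prod(rs)
  if (df <= 0L) {
    return(insufficiency_result(x, y, S, n_eff, alpha, "g2",
                                "degenerate table (df <= 0)"))
  }
  strata <- if (length(S) > 0L) {
    apply(sub[, -(1:2), drop = FALSE], 1L, paste, collapse = "\r")
  } else rep("", n_eff)
  g2 <- 0
  for (s in unique(strata)) {
    idx <- strata == s
    tabl <- table(sub[idx, 1L], sub[idx, 2L])
    tot <- sum(tabl)
    if (tot == 0L) next
    e <- outer(rowSums(tabl), colSums(tabl)) / tot
    o <- as.numeric(tabl); e <- as.numeric(e)
    nz <- o > 0
    g2 <- g2 + 2 * sum(o[nz] * log(o[nz] / e[nz]))
  }
  p <- stats::pchisq(g2, df = df, lower.tail = FALSE)
  res <- ci_result(x, y, S, statistic = g2, p_value = p, n_effective = n_eff,
                   alpha = alpha, method = "g2")
  res$df <- df
  res
}

#' Oracle conditional-independence test from a ground-truth model
#'
#' Embodies perfect faithfulness: returns `p = 1` when `x` and `y` are
#' d-separated given `S` in the model's DAG and `p = 0` otherwise. Used to
#' validate the discovery algorithms independently of finite-sample effects.
#'
#' @param model a `tierpc_model`.
#' @param x,y,S as in [fisher_z_test()].
#' @param alpha recorded threshold (default 0.05).
#' @return a `tierpc_ci_result` with `n_effective = Inf`.
#' @export
oracle_test <- function(model, x, y, S = character(), alpha = 0.05) {
  sep <- d_separated(model, x, y, S)
  ci_result(x, y, S, statistic = if (sep) 0 else Inf,
            p_value = if (sep) 1 else 0, n_effective = Inf,
            alpha = alpha, method = "oracle")
}

#' Build a conditional-independence backend
#'
#' Packages a data source and test family into the callable backend consumed
#' by [gll_pc()] and [build_global_network()]. Results are memoized across
#' queries (tests are symmetric in `x`, `y`), which matters when local
#' discovery is run for every variable of a dataset.
#'
#' @param kind `"fisher_z"`, `"g2"` or `"oracle"`.
#' @param data dataset (for the data-driven kinds).
#' @param model a `tierpc_model` (for `kind = "oracle"`).
#' @param alpha significance threshold recorded into every result.
#' @return a `tierpc_ci_backend`: list with `test(x, y, S)`, `vars`, `alpha`,
#'   `kind`, `n_rows`.
#' @export
ci_backend <- function(kind = c("fisher_z", "g2", "oracle"), data = NULL,
                       model = NULL, alpha = 0.05) {
  kind <- match.arg(kind)
  cache <- new.env(parent = emptyenv())
  if (kind == "oracle") {
    if (is.null(model)) stop("oracle backend needs a model", call. = FALSE)
    model <- model_with_children_cache(model)
    vars <- model$nodes
    n_rows <- Inf
    raw_test <- function(x, y, S) oracle_test(model, x, y, S, alpha)
  } else {
    if (is.null(data)) stop("data backend needs data", call. = FALSE)
    vals <- dataset_values(data)
    vars <- colnames(vals)
    n_rows <- nrow(vals)
    fun <- if (kind == "fisher_z") fisher_z_test else g2_test
    raw_test <- function(x, y, S) fun(vals, x, y, S, alpha)
  }
  test <- function(x, y, S = character()) {
    xy <- sort(c(x, y))
    key <- paste(xy[1L], xy[2L], paste(sort(S), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- raw_test(xy[1L], xy[2L], S)
    assign(key, res, envir = cache)
    res
  }
  structure(list(test = test, vars = vars, alpha = alpha, kind = kind,
                 n_rows = n_rows, cache = cache),
            class = "tierpc_ci_backend")
}
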