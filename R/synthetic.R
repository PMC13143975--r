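#' Simulation configuration for the tiered-DAG generator
#'
#' Defaults emulate a longitudinal child-development study: 1,053 subjects by
#' 252 variables spread over eight time epoques, with an edge density chosen
#' so the expected edge count (~820) matches the scale of causal networks
#' reported for such cohorts, a modest MCAR missingness rate, and a mixed
#' variable-type profile (half continuous scores, 40% 4-level ordinal survey
#' items, 10% binary indicators).
#'
#' @param n_vars number of structural variables (default 252).
#' @param n_rows number of subjects (default 1053).
#' @param epoque_count number of time tiers (default 8).
#' @param edge_density probability of an edge between each epoque-admissible
#'   ordered pair (default 0.026).
#' @param missing_rate MCAR per-cell missingness probability in `[0, 0.9]`
#'   (default 0.05).
#' @param n_duplicates number of information-equivalent duplicate columns to
#'   append (default 0); each duplicate is a deterministic copy of a randomly
#'   chosen source variable, used to exercise multiplicity testing.
#' @param max_in_degree cap on the number of parents per node (default
#'   `Inf`); when the sampled parent set is larger, only the first
#'   `max_in_degree` draws are kept. A cap of 3 matches the conditioning
#'   depth `max_k = 3` of the discovery step, guaranteeing every false
#'   adjacency is separable with the default settings.
#' @param min_weight,max_weight absolute bounds for structural edge weights;
#'   weights are drawn uniformly from `±[min_weight, max_weight]`. The
#'   default lower bound 0.3 keeps dependencies bounded away from zero so
#'   faithfulness holds away from cancellations.
#' @param vtype_probs named numeric probabilities for assigning each variable
#'   a numeric type; names `cardinal`, `ordinal`, `binary`.
#' @param ordinal_levels number of levels for ordinal variables (default 4).
#' @param seed integer RNG seed.
#' @return a `tierpc_simconfig` list.
#' @export
sim_config <- function(n_vars = 252L, n_rows = 1053L, epoque_count = 8L,
                       edge_density = 0.026, missing_rate = 0.05,
                       n_duplicates = 0L, max_in_degree = Inf,
                       min_weight = 0.3, max_weight = 1.0,
                       vtype_probs = c(cardinal = 0.5, ordinal = 0.4,
                                       binary = 0.1),
                       ordinal_levels = 4L, seed = 1L) {
  cfg <- list(n_vars = as.integer(n_vars), n_rows = as.integer(n_rows),
              epoque_count = as.integer(epoque_count),
              edge_density = edge_density, missing_rate = missing_rate,
              n_duplicates = as.integer(n_duplicates),
              max_in_degree = max_in_degree,
              min_weight = min_weight, max_weight = max_weight,
              vtype_probs = vtype_probs,
              ordinal_levels = as.integer(ordinal_levels),
              seed = as.integer(seed))
  if (cfg$n_vars < 2L) stop("n_vars must be >= 2", call. = FALSE)
  if (cfg$n_rows < 1L) stop("n_rows must be >= 1", call. = FALSE)
  if (cfg$epoque_count < 1L || cfg$epoque_count > 8L) {
    stop("epoque_count must be in 1..8", call. = FALSE)
  }
  if (cfg$edge_density < 0 || cfg$edge_density > 1) {
    stop("edge_density must be in [0,1]", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.9) {
    stop("missing_rate must be in [0, 0.9]", call. = FALSE)
  }
  if (cfg$min_weight <= 0 || cfg$max_weight < cfg$min_weight) {
    stop("need 0 < min_weight <= max_weight", call. = FALSE)
  }
  if (cfg$n_duplicates < 0L || cfg$n_duplicates > cfg$n_vars) {
    stop("n_duplicates must be in 0..n_vars", call. = FALSE)
  }
  if (cfg$max_in_degree < 1) {
    stop("max_in_degree must be >= 1", call. = FALSE)
  }
  miss_p <- setdiff(c("cardinal", "ordinal", "binary"), names(vtype_probs))
  if (length(miss_p) > 0L || abs(sum(vtype_probs) - 1) > 1e-8) {
    stop("vtype_probs must name cardinal, ordinal, binary and sum to 1",
         call. = FALSE)
  }
  structure(cfg, class = "tierpc_simconfig")
}

#' Sample a ground-truth tiered structural model
#'
#' Variables are assigned uniformly to epoques; a random topological order is
#' drawn within the epoque ordering, and each admissible ordered pair
#' (earlier or equal epoque to later) receives a directed edge independently
#' with probability `edge_density`. Edges therefore never point from a later
#' epoque into an earlier one. Mechanisms are linear-Gaussian: each node is a
#' weighted sum of its parents plus unit-variance noise, with weights drawn
#' uniformly from `±[min_weight, max_weight]`; ordinal and binary variables
#' are produced at sampling time by monotone quantile discretization of the
#' continuous value. Optional duplicate variables are exact copies of their
#' source, emulating information-equivalent measurements.
#'
#' @param cfg a [sim_config()].
#' @return a `tierpc_model`: nodes, per-node epoque/vtype, parent lists and
#'   weights, topological order, duplicate map, and the generating config.
#' @export
sample_model <- function(cfg) {
  stopifnot(inherits(cfg, "tierpc_simconfig"))
  set.seed(cfg$seed)
  n <- cfg$n_vars
  nodes <- sprintf("V%03d", seq_len(n))
  epoque <- sample.int(cfg$epoque_count, n, replace = TRUE)
  names(epoque) <- nodes
  # random topological order consistent with epoques
  topo <- nodes[order(epoque, sample.int(n))]
  parents <- stats::setNames(vector("list", n), nodes)
  weights <- stats::setNames(vector("list", n), nodes)
  n_edges <- 0L
  for (j in seq_along(topo)) {
    if (j == 1L) { parents[[topo[j]]] <- character(); next }
    cand <- topo[seq_len(j - 1L)]
    sel <- cand[stats::runif(length(cand)) < cfg$edge_density]
    if (length(sel) > cfg$max_in_degree) {
      sel <- sel[seq_len(cfg$max_in_degree)]
    }
    parents[[topo[j]]] <- sel
    if (length(sel) > 0L) {
      w <- stats::runif(length(sel), cfg$min_weight, cfg$max_weight) *
        sample(c(-1, 1), length(sel), replace = TRUE)
      weights[[topo[j]]] <- stats::setNames(w, sel)
      n_edges <- n_edges + length(sel)
    } else {
      weights[[topo[j]]] <- stats::setNames(numeric(), character())
    }
  }
  if (n_edges == 0L) {
    warning("sampled model has no edges (edge_density too low)",
            call. = FALSE)
  }
  vtype <- sample(names(cfg$vtype_probs), n, replace = TRUE,
                  prob = cfg$vtype_probs)
  names(vtype) <- nodes
  duplicates <- character()
  if (cfg$n_duplicates > 0L) {
    src <- sample(nodes, cfg$n_duplicates)
    duplicates <- stats::setNames(src, paste0(src, "_dup"))
  }
  structure(
    list(nodes = nodes, epoque = epoque, vtype = vtype,
         parents = parents, weights = weights, noise_sd = 1,
         topo_order = topo, duplicates = duplicates, cfg = cfg),
    class = "tierpc_model"
  )
}

#' @export
print.tierpc_model <- function(x, ...) {
  cat(sprintf("Ground-truth tiered model: %d nodes, %d edges, %d epoques, %d duplicate column(s)\n",
              length(x$nodes), sum(lengths(x$parents)),
              x$cfg$epoque_count, length(x$duplicates)))
  invisible(x)
}

#' True edge list of a ground-truth model
#' @param model a `tierpc_model`.
#' @return data frame with columns `from`, `to`.
#' @export
model_edges <- function(model) {
  from <- unlist(model$parents, use.names = FALSE)
  to <- rep(names(model$parents), lengths(model$parents))
  data.frame(from = as.character(from), to = to, stringsAsFactors = FALSE)
}

#' Variable table of a ground-truth model (including duplicates)
#' @param model a `tierpc_model`.
#' @return a [variable_table()].
#' @export
model_variable_table <- function(model) {
  nm <- c(model$nodes, names(model$duplicates))
  vt <- c(model$vtype, model$vtype[model$duplicates])
  ep <- c(model$epoque, model$epoque[model$duplicates])
  variable_table(nm, as.character(vt), as.integer(ep))
}

#' Sample data from a ground-truth model
#'
#' Rows are drawn i.i.d. from the structural equations in topological order;
#' ordinal/binary variables are monotone quantile discretizations of the
#' underlying continuous value (children are driven by the continuous
#' latent). Duplicate columns are computed from their source's observed
#' values after discretization, then an MCAR mask is applied uniformly per
#' cell.
#'
#' @param model a `tierpc_model`.
#' @param n_rows number of rows (default from the model's config).
#' @param missing_rate MCAR rate (default from the model's config).
#' @param seed RNG seed for the draw.
#' @return list with elements `dataset` (a `tierpc_dataset`) and `table`
#'   (its [variable_table()]).
#' @export
sample_data <- function(model, n_rows = model$cfg$n_rows,
                        missing_rate = model$cfg$missing_rate,
                        seed = model$cfg$seed) {
  stopifnot(inherits(model, "tierpc_model"))
  if (missing_rate < 0 || missing_rate > 0.9) {
    stop("missing_rate must be in [0, 0.9]", call. = FALSE)
  }
  set.seed(seed)
  n <- as.integer(n_rows)
  latent <- matrix(0, nrow = n, ncol = length(model$nodes),
                   dimnames = list(NULL, model$nodes))
  for (v in model$topo_order) {
    x <- stats::rnorm(n, sd = model$noise_sd)
    w <- model$weights[[v]]
    if (length(w) > 0L) {
      x <- x + latent[, names(w), drop = FALSE] %*% w
    }
    latent[, v] <- x
  }
  obs <- latent
  for (v in model$nodes) {
    k <- switch(model$vtype[[v]], binary = 2L,
                ordinal = model$cfg$ordinal_levels, 0L)
    if (k >= 2L) {
      br <- stats::quantile(latent[, v], probs = seq_len(k - 1L) / k,
                            names = FALSE)
      obs[, v] <- findInterval(latent[, v], br)  # integer codes 0..k-1
    }
  }
  if (length(model$duplicates) > 0L) {
    dup <- obs[, model$duplicates, drop = FALSE]
    colnames(dup) <- names(model$duplicates)
    obs <- cbind(obs, dup)
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(obs)) < missing_rate, nrow = n)
    obs[mask] <- NA_real_
  }
  tab <- model_variable_table(model)
  list(dataset = dataset(obs, tab), table = tab)
}
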