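#' Exact d-separation in a ground-truth model
#'
#' Decides whether `x` and `y` are d-separated given the conditioning set `S`
#' in the model's DAG, using the standard blocking rules: a path is blocked
#' when it passes through a conditioned chain or fork node, or through a
#' collider whose node (and all of whose descendants) is unconditioned.
#' Implemented as reachability over (node, travel-direction) states, which
#' is exact and linear in the graph size per query.
#'
#' Queries are defined over the structural nodes only; duplicate columns are
#' deterministic copies outside the structural equations and raise a lookup
#' error.
#'
#' @param model a `tierpc_model`.
#' @param x,y distinct node names, neither contained in `S`.
#' @param S character vector of conditioning node names (possibly empty).
#' @return `TRUE` if `x` and `y` are d-separated given `S`.
#' @examples
#' # chain A -> B -> C: conditioning on B separates A from C
#' cfg <- sim_config(n_vars = 3, n_rows = 10, edge_density = 0, seed = 1)
#' m <- sample_model(cfg)
#' m$parents <- list(V001 = character(), V002 = "V001", V003 = "V002")
#' d_separated(m, "V001", "V003", "V002")  # TRUE
#' @export
d_separated <- function(model, x, y, S = character()) {
  stopifnot(inherits(model, "tierpc_model"))
  S <- as.character(S)
  for (v in c(x, y, S)) {
    if (!v %in% model$nodes) stop("unknown variable '", v, "'", call. = FALSE)
  }
  if (x == y) stop("x and y must differ", call. = FALSE)
  if (x %in% S || y %in% S) stop("x and y must not be in S", call. = FALSE)

  parents <- model$parents
  children <- model$children_cache
  if (is.null(children)) {
    children <- stats::setNames(
      lapply(model$nodes, function(v) character()), model$nodes)
    for (v in model$nodes) {
      for (p in parents[[v]]) children[[p]] <- c(children[[p]], v)
    }
  }

  # ancestors of S (including S): nodes from which S is reachable
  in_S <- stats::setNames(rep(FALSE, length(model$nodes)), model$nodes)
  in_S[S] <- TRUE
  an_S <- in_S
  frontier <- S
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(parents[frontier], use.names = FALSE))
    nxt <- nxt[!an_S[nxt]]
    an_S[nxt] <- TRUE
    frontier <- nxt
  }

  # reachability over states (node, direction); direction "up" = arrived from
  # a child (moving against arrows), "down" = arrived from a parent
  seen_up <- stats::setNames(rep(FALSE, length(model$nodes)), model$nodes)
  seen_down <- seen_up
  queue_node <- x
  queue_dir <- "up"
  while (length(queue_node) > 0L) {
    v <- queue_node[1L]; d <- queue_dir[1L]
    queue_node <- queue_node[-1L]; queue_dir <- queue_dir[-1L]
    if (d == "up") {
      if (seen_up[[v]]) next
      seen_up[[v]] <- TRUE
    } else {
      if (seen_down[[v]]) next
      seen_down[[v]] <- TRUE
    }
    if (v == y) return(FALSE)
    if (d == "up" && !in_S[[v]]) {
      for (p in parents[[v]]) { queue_node <- c(queue_node, p); queue_dir <- c(queue_dir, "up") }
      for (ch in children[[v]]) { queue_node <- c(queue_node, ch); queue_dir <- c(queue_dir, "down") }
    } else if (d == "down") {
      if (!in_S[[v]]) {
        for (ch in children[[v]]) { queue_node <- c(queue_node, ch); queue_dir <- c(queue_dir, "down") }
      }
      if (an_S[[v]]) {  # open collider: v is in S or an ancestor of S
        for (p in parents[[v]]) { queue_node <- c(queue_node, p); queue_dir <- c(queue_dir, "up") }
      }
    }
  }
  TRUE
}

# Precompute and cache the children map on a model (speeds up repeated
# oracle queries during discovery).
model_with_children_cache <- function(model) {
  if (!is.null(model$children_cache)) return(model)
  children <- stats::setNames(
    lapply(model$nodes, function(v) character()), model$nodes)
  for (v in model$nodes) {
    for (p in model$parents[[v]]) children[[p]] <- c(children[[p]], v)
  }
  model$children_cache <- children
  model
}
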