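#' Bootstrap edge-stability estimation
#'
#' Resamples the rows of the dataset with replacement `B` times, rebuilds
#' the full global network on every replicate, and reports for each
#' adjacency the percentage of bootstrap networks in which it was detected
#' — for every edge of the full-data graph plus any edge seen in at least
#' one replicate. Detection is orientation-agnostic by default, since
#' orientation provenance varies across resamples. Each replicate draws its
#' rows from an independent deterministic substream of the master seed, so
#' results do not depend on execution order.
#'
#' @param data dataset (matrix, data frame or `tierpc_dataset`).
#' @param table a [variable_table()].
#' @param alpha,max_k discovery parameters, as in [build_global_network()].
#' @param B number of bootstrap replicates (default 100).
#' @param seed master RNG seed.
#' @param backend_kind CI backend; the oracle backend ignores the resampled
#'   rows, so every true edge scores 100%.
#' @param model ground-truth model for the oracle backend.
#' @param orientation_aware if `TRUE`, a replicate detects an edge only with
#'   matching orientation status (default `FALSE`).
#' @return a `tierpc_stability`: data frame `edges` with columns `u`, `v`,
#'   `percent`, `in_full_graph`, plus `B`, `seed` and the full-data network.
#' @export
bootstrap_stability <- function(data = NULL, table, alpha = 0.05, max_k = 3L,
                                B = 100L, seed = 1L,
                                backend_kind = c("fisher_z", "g2", "oracle"),
                                model = NULL, orientation_aware = FALSE) {
  backend_kind <- match.arg(backend_kind)
  B <- as.integer(B)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  full <- build_global_network(data, table, alpha = alpha, max_k = max_k,
                               backend_kind = backend_kind, model = model)
  edge_keys <- function(g) {
    if (nrow(g$edges) == 0L) return(character())
    if (orientation_aware) {
      paste(g$edges$u, g$edges$v, g$edges$orientation, sep = "||")
    } else {
      paste(g$edges$u, g$edges$v, sep = "||")
    }
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, B)
  vals <- if (backend_kind == "oracle") NULL else dataset_values(data)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    set.seed(sub_seeds[b])
    if (is.null(vals)) {
      gb <- build_global_network(table = table, alpha = alpha, max_k = max_k,
                                 backend_kind = backend_kind, model = model)
    } else {
      rows <- sample.int(nrow(vals), nrow(vals), replace = TRUE)
      gb <- build_global_network(vals[rows, , drop = FALSE], table,
                                 alpha = alpha, max_k = max_k,
                                 backend_kind = backend_kind, model = model)
    }
    for (k in edge_keys(gb$graph)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  full_keys <- edge_keys(full$graph)
  all_keys <- sort(union(full_keys, ls(counts)))
  if (length(all_keys) > 0L) {
    parts <- strsplit(all_keys, "||", fixed = TRUE)
    tab <- data.frame(
      u = vapply(parts, `[`, "", 1L),
      v = vapply(parts, `[`, "", 2L),
      percent = vapply(all_keys, function(k) {
        100 * (if (is.null(counts[[k]])) 0L else counts[[k]]) / B
      }, 0, USE.NAMES = FALSE),
      in_full_graph = all_keys %in% full_keys,
      stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(u = character(), v = character(), percent = numeric(),
                      in_full_graph = logical(), stringsAsFactors = FALSE)
  }
  structure(
    list(edges = tab, B = B, seed = seed, full_network = full,
         orientation_aware = orientation_aware),
    class = "tierpc_stability"
  )
}

#' @export
print.tierpc_stability <- function(x, ...) {
  cat(sprintf("Edge stability over %d bootstrap replicates (seed %d)\n",
              x$B, x$seed))
  infull <- x$edges[x$edges$in_full_graph, , drop = FALSE]
  if (nrow(infull) > 0L) {
    cat(sprintf("  %d full-graph edges, median stability %.0f%%, %d below 30%%\n",
                nrow(infull), stats::median(infull$percent),
                sum(infull$percent < 30)))
  }
  invisible(x)
}

#' Enumerate directed simple paths into a target
#'
#' All directed simple paths with 1..`max_len` edges that end at the target,
#' found by exact backward depth-first search (no sampling). Undirected
#' edges are excluded by default — traversing them would count routes whose
#' causal direction is unresolved — but can be allowed in both directions.
#'
#' @param g a `tierpc_pdg` or `tierpc_global_network`.
#' @param target node name.
#' @param max_len maximum number of edges per path (default 4, excluding
#'   more distal influences).
#' @param traverse_undirected if `TRUE`, undirected edges are walkable both
#'   ways (default `FALSE`).
#' @return a `tierpc_paths`: `target`, `max_len`, and `paths` — a list of
#'   node-name vectors, each starting at the path's origin and ending at
#'   the target, in deterministic lexicographic order.
#' @examples
#' g <- pdg(c("A", "B", "T"))
#' g <- pdg_add_edge(g, "A", "B", "directed")
#' g <- pdg_add_edge(g, "B", "T", "directed")
#' g <- pdg_add_edge(g, "A", "T", "directed")
#' length(enumerate_paths(g, "T")$paths)  # 3
#' @export
enumerate_paths <- function(g, target, max_len = 4L,
                            traverse_undirected = FALSE) {
  if (inherits(g, "tierpc_global_network")) g <- g$graph
  stopifnot(inherits(g, "tierpc_pdg"))
  if (!target %in% g$nodes) {
    stop("target '", target, "' not in graph", call. = FALSE)
  }
  max_len <- as.integer(max_len)
  if (max_len < 1L) stop("max_len must be >= 1", call. = FALSE)
  preds <- function(v) {
    p <- pdg_parents(g, v)
    if (traverse_undirected) p <- union(p, pdg_undirected_neighbors(g, v))
    sort(p)
  }
  paths <- list()
  walk <- function(suffix) {
    # suffix runs from current head to target; extend backwards
    if (length(suffix) - 1L >= max_len) return()
    for (p in preds(suffix[1L])) {
      if (p %in% suffix) next  # simple paths only
      paths[[length(paths) + 1L]] <<- c(p, suffix)
      walk(c(p, suffix))
    }
  }
  walk(target)
  keys <- vapply(paths, paste, "", collapse = "\r")
  paths <- paths[order(keys)]
  structure(list(target = target, max_len = max_len, paths = paths,
                 traverse_undirected = traverse_undirected),
            class = "tierpc_paths")
}

#' @export
print.tierpc_paths <- function(x, ...) {
  cat(sprintf("%d directed path(s) of <= %d edge(s) into %s\n",
              length(x$paths), x$max_len, x$target))
  for (p in utils::head(x$paths, 10L)) {
    cat(" ", paste(p, collapse = " -> "), "\n")
  }
  if (length(x$paths) > 10L) cat(sprintf("  ... and %d more\n",
                                         length(x$paths) - 10L))
  invisible(x)
}

#' Rank nodes by the fraction of target paths their deletion eliminates
#'
#' Deleting a node removes it and all incident edges, so the paths it
#' eliminates are exactly the enumerated paths containing it. Each
#' non-target node appearing on at least one path gets
#' `eliminated_fraction = paths containing it / total paths`; nodes are
#' ranked descending, ties broken lexicographically.
#'
#' @param paths a `tierpc_paths` from [enumerate_paths()].
#' @return a `tierpc_impact`: data frame `ranking` with columns `node`,
#'   `n_paths`, `eliminated_fraction`, plus `n_paths_total`. Zero paths
#'   yield an empty ranking with a warning.
#' @examples
#' g <- pdg(c("A", "B", "T"))
#' g <- pdg_add_edge(g, "A", "B", "directed")
#' g <- pdg_add_edge(g, "B", "T", "directed")
#' g <- pdg_add_edge(g, "A", "T", "directed")
#' impact_ranking(enumerate_paths(g, "T"))$ranking  # A and B both 2/3
#' @export
impact_ranking <- function(paths) {
  stopifnot(inherits(paths, "tierpc_paths"))
  n_total <- length(paths$paths)
  if (n_total == 0L) {
    warning("no paths into target; empty ranking", call. = FALSE)
    return(structure(
      list(ranking = data.frame(node = character(), n_paths = integer(),
                                eliminated_fraction = numeric(),
                                stringsAsFactors = FALSE),
           n_paths_total = 0L, target = paths$target),
      class = "tierpc_impact"))
  }
  nodes <- setdiff(unique(unlist(paths$paths)), paths$target)
  cnt <- vapply(nodes, function(v) {
    sum(vapply(paths$paths, function(p) v %in% p, TRUE))
  }, 0L)
  rk <- data.frame(node = nodes, n_paths = cnt,
                   eliminated_fraction = cnt / n_total,
                   stringsAsFactors = FALSE)
  rk <- rk[order(-rk$eliminated_fraction, rk$node), , drop = FALSE]
  rownames(rk) <- NULL
  structure(list(ranking = rk, n_paths_total = n_total,
                 target = paths$target),
            class = "tierpc_impact")
}

#' @export
print.tierpc_impact <- function(x, ...) {
  cat(sprintf("Intervention-impact ranking over %d path(s) into %s\n",
              x$n_paths_total, x$target))
  print(utils::head(x$ranking, 10L))
  invisible(x)
}
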