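#' Extract the Markov boundary of a target from a global network
#'
#' The Markov boundary — the minimal variable set rendering the target
#' conditionally independent of everything else, and the local causal model
#' around it — comprises the target's direct causes (parents), direct
#' effects (children) and spouses (direct causes of direct effects).
#' Neighbours joined by an edge the pipeline could not orient are reported
#' separately as `undirected_neighbors` and retained in the boundary as a
#' conservative superset, since an undirected edge may hide either a parent
#' or a child.
#'
#' @param g a `tierpc_pdg` or `tierpc_global_network`.
#' @param target node name.
#' @return a `tierpc_mb_report`: `target`, `direct_causes`, `direct_effects`,
#'   `spouses`, `undirected_neighbors` (pairwise disjoint, excluding the
#'   target), `boundary` (their union), and `local_graph` (the induced
#'   subgraph on the boundary plus target).
#' @examples
#' g <- pdg(c("A", "T", "B", "C"))
#' g <- pdg_add_edge(g, "A", "T", "directed")
#' g <- pdg_add_edge(g, "T", "B", "directed")
#' g <- pdg_add_edge(g, "C", "B", "directed")
#' extract_markov_boundary(g, "T")$boundary  # A (cause), B (effect), C (spouse)
#' @export
extract_markov_boundary <- function(g, target) {
  if (inherits(g, "tierpc_global_network")) g <- g$graph
  stopifnot(inherits(g, "tierpc_pdg"))
  if (!target %in% g$nodes) {
    stop("target '", target, "' not in graph", call. = FALSE)
  }
  causes <- pdg_parents(g, target)
  effects <- pdg_children(g, target)
  und <- pdg_undirected_neighbors(g, target)
  spouses <- character()
  for (ch in effects) {
    spouses <- union(spouses, setdiff(pdg_parents(g, ch), target))
  }
  spouses <- sort(setdiff(spouses, c(causes, effects, und)))
  boundary <- sort(unique(c(causes, effects, spouses, und)))
  local_nodes <- c(target, boundary)
  lg <- pdg(local_nodes,
            if (!is.null(g$epoque)) g$epoque[local_nodes] else NULL)
  e <- g$edges
  keep <- e$u %in% local_nodes & e$v %in% local_nodes
  lg$edges <- e[keep, , drop = FALSE]
  rownames(lg$edges) <- NULL
  structure(
    list(target = target, direct_causes = causes, direct_effects = effects,
         spouses = spouses, undirected_neighbors = und,
         boundary = boundary, local_graph = lg),
    class = "tierpc_mb_report"
  )
}

#' @export
print.tierpc_mb_report <- function(x, ...) {
  cat(sprintf("Markov boundary of %s: %d variable(s)\n", x$target,
              length(x$boundary)))
  cat("  direct causes:        ", paste(x$direct_causes, collapse = ", "), "\n")
  cat("  direct effects:       ", paste(x$direct_effects, collapse = ", "), "\n")
  cat("  spouses:              ", paste(x$spouses, collapse = ", "), "\n")
  cat("  undirected neighbours:", paste(x$undirected_neighbors, collapse = ", "), "\n")
  if (!is.null(x$multiplicity)) {
    cat(sprintf("  multiplicity: %s (%d boundary/ies)\n",
                x$multiplicity$verdict, length(x$multiplicity$boundaries)))
  }
  invisible(x)
}

#' Local (one-sided) Markov-boundary discovery
#'
#' HITON-MB-style composition: the target's parents-and-children set from
#' [gll_pc()], plus spouse detection — for every other member `s` of a
#' child-candidate's PC set, `s` joins the boundary if the target becomes
#' dependent on `s` once the candidate is added to their separating set
#' (the collider signature). Deliberately one-sided: no AND-rule symmetry
#' correction is applied, so information-equivalent variables (duplicates)
#' remain recoverable — under faithfulness violations the symmetric global
#' route can silently drop both copies, which is exactly the failure mode
#' multiplicity testing probes.
#'
#' @param backend a [ci_backend()].
#' @param target variable name.
#' @param alpha,max_k as in [gll_pc()].
#' @param vars candidate variables (default: all backend variables).
#' @return list with `target`, `pc` (parents/children candidates),
#'   `spouses`, and `boundary` (their sorted union).
#' @export
local_markov_boundary <- function(backend, target, alpha = backend$alpha,
                                  max_k = 3L, vars = backend$vars) {
  pcT <- gll_pc(backend, target, alpha, max_k, vars)
  mb <- pcT$members
  spouses <- character()
  for (ch in pcT$members) {
    pcc <- gll_pc(backend, ch, alpha, max_k, vars)
    for (s in setdiff(pcc$members, c(target, mb, spouses))) {
      sep <- pcT$sepsets[[pair_key(target, s)]]
      if (is.null(sep)) sep <- character()
      res <- backend$test(target, s, union(sep, ch))
      if (!res$independent) spouses <- c(spouses, s)
    }
  }
  boundary <- sort(unique(c(pcT$members, spouses)))
  # backward minimality pass: one-sided composition can retain redundant
  # members (e.g. descendants through spouse colliders); a true boundary
  # member is never independent of the target given the rest
  repeat {
    dropped <- FALSE
    for (v in boundary) {
      res <- backend$test(target, v, setdiff(boundary, v))
      if (res$independent) {
        boundary <- setdiff(boundary, v)
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  list(target = target, pc = pcT$members, spouses = sort(spouses),
       boundary = boundary)
}

# discover the MB of `target` from data restricted to `vars`
discover_mb <- function(data, table, target, alpha, max_k, backend_kind,
                        model = NULL, vars = NULL) {
  vals <- if (backend_kind == "oracle") NULL else dataset_values(data)
  if (!is.null(vars)) {
    if (!is.null(vals)) vals <- vals[, vars, drop = FALSE]
    table <- table[table$name %in% vars, , drop = FALSE]
    class(table) <- c("tierpc_vartable", "data.frame")
  }
  net <- build_global_network(vals, table, alpha = alpha, max_k = max_k,
                              backend_kind = backend_kind, model = model)
  extract_markov_boundary(net$graph, target)
}

#' Test a target's Markov boundary for multiplicity
#'
#' Distinct Markov boundaries for one target are a faithfulness violation,
#' typically caused by information-equivalent variables (e.g. duplicated or
#' recoded measurements); discovery algorithms assuming a unique boundary
#' can then silently drop true members. This reduced multiplicity test
#' hides, in turn, every subset `R` (up to `max_subset` variables) of the
#' base boundary, re-runs boundary discovery without those columns, and
#' accepts the resulting set `M'` as an additional boundary when the
#' independence-equivalence criterion holds: every base-boundary member not
#' in `M'` is independent of the target given `M'` (at `alpha`, with the
#' configured test). The verdict is `"unique"` iff no accepted alternative
#' exists.
#'
#' @param data dataset (matrix, data frame or `tierpc_dataset`).
#' @param table a [variable_table()].
#' @param target node name.
#' @param alpha significance threshold (default 0.05).
#' @param max_k maximum conditioning-set size for discovery (default 3).
#' @param max_subset largest hidden-subset size (default 2; bounds runtime).
#' @param backend_kind CI backend, as in [build_global_network()].
#' @param model ground-truth model for the oracle backend.
#' @return a `tierpc_multiplicity`: `verdict` (`"unique"` or `"multiple"`),
#'   `boundaries` (list of distinct boundaries, the base first), and
#'   `checks` (per-candidate equivalence-test log).
#' @export
tie_star_multiplicity <- function(data = NULL, table, target, alpha = 0.05,
                                  max_k = 3L, max_subset = 2L,
                                  backend_kind = c("fisher_z", "g2", "oracle"),
                                  model = NULL) {
  backend_kind <- match.arg(backend_kind)
  validate_variable_table(table)
  backend <- ci_backend(backend_kind, data = data, model = model,
                        alpha = alpha)
  base <- local_markov_boundary(backend, target, alpha, max_k,
                                vars = table$name)
  boundaries <- list(base$boundary)
  checks <- list()
  if (length(base$boundary) == 0L) {
    return(structure(list(verdict = "unique", boundaries = boundaries,
                          checks = checks, base = base),
                     class = "tierpc_multiplicity"))
  }
  # mutual blanket criterion: each base member outside the candidate must
  # be screened off by the candidate, and each new candidate member must be
  # screened off by the base — both sets then carry the same information
  # about the target
  equivalence_holds <- function(mb_new) {
    for (v in setdiff(base$boundary, mb_new)) {
      res <- backend$test(target, v, mb_new)
      checks[[length(checks) + 1L]] <<- res
      if (!res$independent) return(FALSE)
    }
    for (v in setdiff(mb_new, base$boundary)) {
      res <- backend$test(target, v, base$boundary)
      checks[[length(checks) + 1L]] <<- res
      if (!res$independent) return(FALSE)
    }
    TRUE
  }
  # iterate to closure: hide subsets drawn from the union of every boundary
  # found so far, so chains of equivalent variables (triplicates and beyond)
  # are all uncovered
  seen <- paste(sort(base$boundary), collapse = ",")
  tried <- character()
  repeat {
    pool <- sort(unique(unlist(boundaries)))
    grew <- FALSE
    for (k in seq_len(min(max_subset, length(pool)))) {
      for (R in utils::combn(pool, k, simplify = FALSE)) {
        rkey <- paste(R, collapse = ",")
        if (rkey %in% tried) next
        tried <- c(tried, rkey)
        vars_kept <- setdiff(table$name, R)
        if (length(vars_kept) < 2L || !target %in% vars_kept) next
        mb_new <- local_markov_boundary(backend, target, alpha, max_k,
                                        vars = vars_kept)$boundary
        if (length(mb_new) == 0L) next
        key <- paste(sort(mb_new), collapse = ",")
        if (key %in% seen) next
        if (equivalence_holds(mb_new)) {
          boundaries[[length(boundaries) + 1L]] <- sort(mb_new)
          seen <- c(seen, key)
          grew <- TRUE
        }
      }
    }
    if (!grew) break
  }
  structure(
    list(verdict = if (length(boundaries) > 1L) "multiple" else "unique",
         boundaries = boundaries, checks = checks, base = base),
    class = "tierpc_multiplicity"
  )
}

#' @export
print.tierpc_multiplicity <- function(x, ...) {
  cat(sprintf("Markov-boundary multiplicity: %s (%d boundary/ies)\n",
              x$verdict, length(x$boundaries)))
  for (i in seq_along(x$boundaries)) {
    cat(sprintf("  [%d] {%s}\n", i, paste(x$boundaries[[i]], collapse = ", ")))
  }
  invisible(x)
}
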