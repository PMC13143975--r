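#' Assemble the global skeleton from symmetric local PC sets
#'
#' Creates an undirected edge for every mutual pair of a symmetry-corrected
#' family of PC sets and merges all recorded separating sets into the
#' graph's sepset map (pairs claimed by several local runs are resolved
#' lexicographically by recording run, deterministically).
#'
#' @param pcsets named list of `tierpc_pcset` after [symmetry_correct()].
#' @param epoque optional named integer vector of node epoques.
#' @return a `tierpc_pdg` with all edges undirected, provenance `"none"`.
#' @export
assemble_skeleton <- function(pcsets, epoque = NULL) {
  vars <- names(pcsets)
  for (x in vars) {
    for (y in pcsets[[x]]$members) {
      if (y %in% vars && !x %in% pcsets[[y]]$members) {
        stop("pcsets are not symmetric (", x, " ~ ", y,
             "); run symmetry_correct() first", call. = FALSE)
      }
    }
  }
  g <- pdg(vars, epoque)
  for (x in vars) {
    for (y in pcsets[[x]]$members) {
      if (x < y && !pdg_adjacent(g, x, y)) {
        g <- pdg_add_edge(g, x, y, "undirected", "none")
      }
    }
  }
  # merge sepsets in lexicographic run order; first recording wins, so the
  # result does not depend on list traversal quirks
  for (x in sort(vars)) {
    for (key in names(pcsets[[x]]$sepsets)) {
      ab <- strsplit(key, "||", fixed = TRUE)[[1L]]
      if (pdg_adjacent(g, ab[1L], ab[2L])) next  # AND-rule kept the edge
      if (is.null(g$sepsets[[key]])) {
        g$sepsets[[key]] <- pcsets[[x]]$sepsets[[key]]
      }
    }
  }
  g
}

#' Orient cross-epoque edges forward in time
#'
#' Every edge joining variables of distinct epoques is oriented from the
#' earlier epoque to the later one with provenance `"temporal"`; edges within
#' an epoque are untouched. Time order is treated as known fact, so these
#' orientations take precedence over all data-driven rules.
#'
#' @param g a `tierpc_pdg`.
#' @param table optional [variable_table()] supplying epoques if the graph
#'   does not carry them yet.
#' @return the oriented graph.
#' @export
orient_temporal <- function(g, table = NULL) {
  if (!is.null(table)) {
    validate_variable_table(table)
    g$epoque <- epoque_map(table)[g$nodes]
    names(g$epoque) <- g$nodes
  }
  if (is.null(g$epoque)) stop("graph has no epoque information", call. = FALSE)
  ep <- g$epoque
  for (i in seq_len(nrow(g$edges))) {
    u <- g$edges$u[i]; v <- g$edges$v[i]
    if (ep[[u]] == ep[[v]]) next
    if (ep[[u]] < ep[[v]]) {
      g$edges$orientation[i] <- "u>v"
    } else {
      g$edges$orientation[i] <- "v>u"
    }
    g$edges$provenance[i] <- "temporal"
  }
  g
}

#' Orient colliders from separating sets
#'
#' For every unshielded triple `a — c — b` (with `a`, `b` non-adjacent), if
#' `c` is absent from the recorded sepset of `(a, b)` the triple is a
#' collider and both edges are oriented into `c` with provenance
#' `"collider"` — unless either orientation contradicts an existing
#' (temporal or earlier-collider) orientation or would create a directed
#' cycle, in which case the triple is skipped and the conflict logged.
#' Triples are visited in lexicographic order, so conflicts resolve
#' first-come deterministically.
#'
#' @param g a `tierpc_pdg` with a populated sepset map.
#' @return the graph, with a data frame of skipped conflicts in attribute
#'   `"conflicts"`.
#' @export
orient_colliders <- function(g) {
  conflicts <- list()
  log_conflict <- function(rule, edge, reason) {
    conflicts[[length(conflicts) + 1L]] <<- data.frame(
      rule = rule, edge = edge, resolution = reason,
      stringsAsFactors = FALSE)
  }
  # unshielded triples in lexicographic (a, b, c) order with a < b
  triples <- list()
  for (c_ in sort(g$nodes)) {
    nb <- pdg_neighbors(g, c_)
    if (length(nb) < 2L) next
    prs <- utils::combn(sort(nb), 2L, simplify = FALSE)
    for (p in prs) {
      if (!pdg_adjacent(g, p[1L], p[2L])) {
        triples[[length(triples) + 1L]] <- c(p[1L], p[2L], c_)
      }
    }
  }
  if (length(triples) > 0L) {
    ord <- order(vapply(triples, function(t) paste(t, collapse = "\r"), ""))
    triples <- triples[ord]
  }
  for (t in triples) {
    a <- t[1L]; b <- t[2L]; c_ <- t[3L]
    key <- pair_key(a, b)
    if (is.null(g$sepsets[[key]])) {
      stop("no sepset recorded for non-adjacent pair ", a, ", ", b,
           call. = FALSE)
    }
    if (c_ %in% g$sepsets[[key]]) next  # chain/fork, leave as is
    edge_label <- paste0(a, "->", c_, ", ", b, "->", c_)
    ok <- TRUE
    extra <- NULL
    for (x in c(a, b)) {
      dir <- pdg_edge_direction(g, x, c_)
      if (dir$directed && dir$from == c_) {  # oriented away from collider
        log_conflict("collider", edge_label,
                     paste0("skip: existing orientation ", c_, "->", x))
        ok <- FALSE
        break
      }
      if (!dir$directed) extra <- rbind(extra, cbind(from = x, to = c_))
    }
    if (!ok) next
    # cycle check with both new arrows hypothetically in place
    if (!is.null(extra)) {
      cyc <- FALSE
      for (i in seq_len(nrow(extra))) {
        others <- extra[-i, , drop = FALSE]
        if (pdg_creates_cycle(g, extra[i, "from"], extra[i, "to"],
                              extra = others)) cyc <- TRUE
      }
      if (cyc) {
        log_conflict("collider", edge_label, "skip: would create cycle")
        next
      }
      for (i in seq_len(nrow(extra))) {
        g <- pdg_set_orientation(g, extra[i, "from"], extra[i, "to"],
                                 "collider")
      }
    }
  }
  attr(g, "conflicts") <- if (length(conflicts) > 0L) {
    do.call(rbind, conflicts)
  } else {
    data.frame(rule = character(), edge = character(),
               resolution = character(), stringsAsFactors = FALSE)
  }
  g
}

# does orienting x -> y create a new unshielded collider at y?
creates_new_collider <- function(g, x, y) {
  for (p in pdg_parents(g, y)) {
    if (p != x && !pdg_adjacent(g, p, x)) return(TRUE)
  }
  FALSE
}

#' Propagate orientations with Meek's rules
#'
#' Applies Meek rules R1-R4 to a fixed point, orienting only previously
#' undirected edges (provenance `"meek"`). Every candidate orientation is
#' additionally guarded: it is skipped if it would create a directed cycle
#' or a new unshielded collider. Edges and rule premises are scanned in
#' lexicographic order, so the outcome is deterministic.
#'
#' Rules (orient `u — v` into `u -> v`):
#' R1: some `w -> u` with `w`, `v` non-adjacent.
#' R2: a directed path `u -> w -> v`.
#' R3: `u — w`, `u — z`, `w -> v`, `z -> v` with `w`, `z` non-adjacent.
#' R4: `u` adjacent to `w`, `w -> z`, `z -> v`, with `w`, `v` non-adjacent.
#'
#' @param g a `tierpc_pdg` after [orient_colliders()].
#' @return the graph with propagated orientations.
#' @export
orient_meek <- function(g) {
  meek_fires <- function(u, v) {
    # R1
    for (w in pdg_parents(g, u)) {
      if (!pdg_adjacent(g, w, v)) return("R1")
    }
    # R2
    ch_u <- pdg_children(g, u)
    if (length(intersect(ch_u, pdg_parents(g, v))) > 0L) return("R2")
    # R3
    und_u <- pdg_undirected_neighbors(g, u)
    pav <- pdg_parents(g, v)
    wz <- intersect(und_u, pav)
    if (length(wz) >= 2L) {
      prs <- utils::combn(sort(wz), 2L, simplify = FALSE)
      for (p in prs) {
        if (!pdg_adjacent(g, p[1L], p[2L])) return("R3")
      }
    }
    # R4
    for (z in pav) {
      for (w in pdg_parents(g, z)) {
        if (w != u && w != v && pdg_adjacent(g, u, w) &&
            !pdg_adjacent(g, w, v)) return("R4")
      }
    }
    NULL
  }
  repeat {
    changed <- FALSE
    e <- g$edges
    und <- which(e$orientation == "none")
    if (length(und) == 0L) break
    und <- und[order(e$u[und], e$v[und])]
    for (i in und) {
      u <- g$edges$u[i]; v <- g$edges$v[i]
      if (g$edges$orientation[i] != "none") next
      for (dir in list(c(u, v), c(v, u))) {
        rule <- meek_fires(dir[1L], dir[2L])
        if (!is.null(rule) &&
            !pdg_creates_cycle(g, dir[1L], dir[2L]) &&
            !creates_new_collider(g, dir[1L], dir[2L])) {
          g <- pdg_set_orientation(g, dir[1L], dir[2L], "meek")
          changed <- TRUE
          break
        }
      }
    }
    if (!changed) break
  }
  g
}

#' Summarize edge-orientation provenance
#'
#' @param g an oriented `tierpc_pdg`.
#' @return a `tierpc_orientation_report`: provenance counts (summing to the
#'   edge count), percentages, and the conflict log from the collider phase.
#' @export
orientation_report <- function(g) {
  prov <- g$edges$provenance
  prov[g$edges$orientation == "none"] <- "none"
  counts <- c(temporal = sum(prov == "temporal"),
              collider = sum(prov == "collider"),
              meek = sum(prov == "meek"),
              unoriented = sum(prov == "none"))
  conflicts <- attr(g, "conflicts")
  if (is.null(conflicts)) {
    conflicts <- data.frame(rule = character(), edge = character(),
                            resolution = character(), stringsAsFactors = FALSE)
  }
  structure(
    list(counts = counts, n_edges = nrow(g$edges),
         pct = if (nrow(g$edges) > 0L) 100 * counts / nrow(g$edges) else
           counts * NA_real_,
         conflicts = conflicts),
    class = "tierpc_orientation_report"
  )
}

#' @export
print.tierpc_orientation_report <- function(x, ...) {
  cat(sprintf("Orientation report: %d edges\n", x$n_edges))
  for (k in names(x$counts)) {
    cat(sprintf("  %-10s %5d (%.1f%%)\n", k, x$counts[[k]], x$pct[[k]]))
  }
  if (nrow(x$conflicts) > 0L) {
    cat(sprintf("  %d orientation conflict(s) logged\n", nrow(x$conflicts)))
  }
  invisible(x)
}

#' Build the global causal network from data
#'
#' The full discovery pipeline: local PC discovery for every variable
#' ([gll_pc()]), AND-rule symmetry correction, skeleton assembly, then
#' orientation by temporal tiers, sepset colliders and Meek propagation (in
#' that precedence order — time order is treated as known fact and is never
#' overwritten by a data-driven rule).
#'
#' @param data a `tierpc_dataset`, matrix or data frame (ignored for the
#'   oracle backend).
#' @param table a [variable_table()] giving each variable's epoque.
#' @param alpha significance threshold (default 0.05).
#' @param max_k maximum conditioning-set size (default 3).
#' @param backend_kind `"fisher_z"`, `"g2"` or `"oracle"`.
#' @param model ground-truth `tierpc_model`, required for the oracle backend.
#' @param symmetry_rule `"AND"` (default) or `"OR"`.
#' @return a `tierpc_global_network`: list with `graph` (a `tierpc_pdg`),
#'   `report` (an orientation report), `pcsets`, and the run parameters.
#' @examples
#' cfg <- sim_config(n_vars = 8, n_rows = 400, edge_density = 0.25, seed = 7,
#'                   missing_rate = 0, vtype_probs = c(cardinal = 1, ordinal = 0, binary = 0))
#' m <- sample_model(cfg)
#' net <- build_global_network(model = m, backend_kind = "oracle",
#'                             table = model_variable_table(m))
#' net$report
#' @export
build_global_network <- function(data = NULL, table = NULL, alpha = 0.05,
                                 max_k = 3L,
                                 backend_kind = c("fisher_z", "g2", "oracle"),
                                 model = NULL,
                                 symmetry_rule = c("AND", "OR")) {
  backend_kind <- match.arg(backend_kind)
  symmetry_rule <- match.arg(symmetry_rule)
  backend <- ci_backend(backend_kind, data = data, model = model,
                        alpha = alpha)
  if (length(backend$vars) < 2L) {
    stop("need at least 2 variables", call. = FALSE)
  }
  if (is.null(table)) {
    if (!is.null(model)) table <- model_variable_table(model)
    else stop("a variable table is required", call. = FALSE)
  }
  validate_variable_table(table)
  absent <- setdiff(table$name, backend$vars)
  if (length(absent) > 0L) {
    stop("variable table names not present in data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (backend_kind != "oracle" && !setequal(table$name, backend$vars)) {
    stop("variable table does not match data columns", call. = FALSE)
  }
  # discovery runs over the table's variables; with the oracle backend this
  # may be a strict subset of the model's nodes (hidden-variable reruns)
  vars_used <- table$name
  pcsets <- lapply(stats::setNames(vars_used, vars_used),
                   function(v) gll_pc(backend, v, alpha, max_k,
                                      vars = vars_used))
  pcsets <- symmetry_correct(pcsets, symmetry_rule)
  g <- assemble_skeleton(pcsets, epoque_map(table))
  g <- orient_temporal(g)
  g <- orient_colliders(g)
  g <- orient_meek(g)
  validate_pdg(g)
  structure(
    list(graph = g, report = orientation_report(g), pcsets = pcsets,
         alpha = alpha, max_k = max_k, backend_kind = backend_kind,
         symmetry_rule = symmetry_rule),
    class = "tierpc_global_network"
  )
}

#' @export
print.tierpc_global_network <- function(x, ...) {
  cat(sprintf("Global causal network (%s backend, alpha=%g, max_k=%d)\n",
              x$backend_kind, x$alpha, x$max_k))
  print(x$graph)
  print(x$report)
  invisible(x)
}

#' Compare a discovered skeleton against a ground-truth model
#'
#' @param g a `tierpc_pdg` (or `tierpc_global_network`).
#' @param model the generating `tierpc_model`.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1` for
#'   adjacencies (orientation-agnostic). Duplicate columns are excluded.
#' @export
skeleton_metrics <- function(g, model) {
  if (inherits(g, "tierpc_global_network")) g <- g$graph
  true_e <- model_edges(model)
  true_keys <- unique(mapply(pair_key, true_e$from, true_e$to))
  est <- g$edges
  base <- model$nodes
  keep <- est$u %in% base & est$v %in% base
  est_keys <- unique(mapply(pair_key, est$u[keep], est$v[keep]))
  if (length(est_keys) == 0L) est_keys <- character()
  tp <- length(intersect(est_keys, true_keys))
  fp <- length(setdiff(est_keys, true_keys))
  fn <- length(setdiff(true_keys, est_keys))
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  list(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
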