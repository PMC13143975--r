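# Independent oracles used to cross-check the package's algorithms. These
# deliberately use different algorithms (moralization, exhaustive
# enumeration, igraph search) than the implementation they validate.

# Build a tierpc_model by hand from a parent list (weights optional).
manual_model <- function(parents, epoque = NULL, weights = NULL,
                         vtype = NULL) {
  nodes <- names(parents)
  if (is.null(epoque)) epoque <- stats::setNames(rep(1L, length(nodes)), nodes)
  if (is.null(vtype)) vtype <- stats::setNames(rep("cardinal", length(nodes)), nodes)
  if (is.null(weights)) {
    weights <- lapply(parents, function(p) stats::setNames(rep(0.8, length(p)), p))
  }
  # topological order via igraph
  el <- do.call(rbind, lapply(nodes, function(v) {
    if (length(parents[[v]]) == 0L) NULL else cbind(parents[[v]], v)
  }))
  topo <- if (is.null(el)) nodes else {
    ig <- igraph::graph_from_edgelist(el, directed = TRUE)
    ig <- ig + igraph::vertices(setdiff(nodes, igraph::V(ig)$name))
    igraph::V(ig)$name[igraph::topo_sort(ig)]
  }
  cfg <- sim_config(n_vars = length(nodes), n_rows = 100, seed = 1)
  structure(
    list(nodes = nodes, epoque = epoque[nodes], vtype = vtype[nodes],
         parents = parents, weights = weights, noise_sd = 1,
         topo_order = topo, duplicates = character(), cfg = cfg),
    class = "tierpc_model"
  )
}

# Moralization-based d-separation check: ancestral subgraph of {x,y} u S,
# moralize, remove S, test undirected connectivity.
msep_moral <- function(model, x, y, S = character()) {
  keep <- unique(c(x, y, S))
  repeat {
    grown <- unique(c(keep, unlist(model$parents[keep], use.names = FALSE)))
    if (length(grown) == length(keep)) break
    keep <- grown
  }
  el <- NULL
  for (v in keep) {
    pa <- intersect(model$parents[[v]], keep)
    if (length(pa) > 0L) el <- rbind(el, cbind(pa, v))
    if (length(pa) > 1L) {  # marry parents
      prs <- utils::combn(pa, 2L)
      el <- rbind(el, t(prs))
    }
  }
  if (is.null(el)) return(TRUE)
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  ig <- ig + igraph::vertices(setdiff(keep, igraph::V(ig)$name))
  ig <- igraph::delete_vertices(ig, intersect(S, igraph::V(ig)$name))
  if (!x %in% igraph::V(ig)$name || !y %in% igraph::V(ig)$name) return(TRUE)
  !is.finite(igraph::distances(ig, x, y)[1L, 1L])
}

# true parents-and-children set of a node
true_pc <- function(model, v) {
  ch <- names(model$parents)[vapply(model$parents, function(p) v %in% p, TRUE)]
  sort(unique(c(model$parents[[v]], ch)))
}

# true Markov boundary from the DAG: parents u children u spouses
true_mb <- function(model, v) {
  ch <- names(model$parents)[vapply(model$parents, function(p) v %in% p, TRUE)]
  sp <- setdiff(unique(unlist(model$parents[ch], use.names = FALSE)), v)
  sort(unique(c(model$parents[[v]], ch, sp)))
}

# Exhaustive-extension consensus: enumerate all orientations of the
# skeleton, keep those that are acyclic, epoque-consistent and whose
# unshielded colliders exactly match the sepsets; an edge is compelled iff
# it has the same direction in every surviving extension.
consensus_orientations <- function(g) {
  e <- g$edges
  m <- nrow(e)
  stopifnot(m <= 14)
  adj <- function(a, b) pdg_adjacent(g, a, b)
  # unshielded triples (a, c, b): a-c, c-b edges, a,b non-adjacent
  triples <- list()
  for (c_ in g$nodes) {
    nb <- pdg_neighbors(g, c_)
    if (length(nb) < 2L) next
    for (p in utils::combn(sort(nb), 2L, simplify = FALSE)) {
      if (!adj(p[1L], p[2L])) triples[[length(triples) + 1L]] <- c(p[1L], p[2L], c_)
    }
  }
  dirs_per_ext <- list()
  for (mask in 0:(2^m - 1)) {
    bits <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    from <- ifelse(bits, e$v, e$u)
    to <- ifelse(bits, e$u, e$v)
    # epoque consistency
    if (!is.null(g$epoque) && any(g$epoque[from] > g$epoque[to])) next
    ig <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
    if (!igraph::is_dag(ig)) next
    # collider pattern must match sepsets on unshielded triples
    ok <- TRUE
    for (t in triples) {
      a <- t[1L]; b <- t[2L]; c_ <- t[3L]
      into_c <- sum(from == a & to == c_) + sum(from == b & to == c_)
      is_collider <- into_c == 2L
      want_collider <- !(c_ %in% g$sepsets[[tierpc:::pair_key(a, b)]])
      if (is_collider != want_collider) { ok <- FALSE; break }
    }
    if (!ok) next
    dirs_per_ext[[length(dirs_per_ext) + 1L]] <- paste(from, to, sep = ">")
  }
  if (length(dirs_per_ext) == 0L) return(NULL)  # no consistent extension
  # per edge: direction fixed across all extensions?
  out <- data.frame(u = e$u, v = e$v, compelled = NA, from = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    d1 <- paste(e$u[i], e$v[i], sep = ">")
    has_uv <- vapply(dirs_per_ext, function(d) d1 %in% d, TRUE)
    out$compelled[i] <- all(has_uv) || all(!has_uv)
    out$from[i] <- if (all(has_uv)) e$u[i] else if (all(!has_uv)) e$v[i] else NA_character_
  }
  out
}

# igraph-based exhaustive directed-path oracle
igraph_paths_to_target <- function(g, target, max_len) {
  de <- tierpc:::pdg_directed_edges(g)
  if (nrow(de) == 0L) return(list())
  ig <- igraph::graph_from_edgelist(de, directed = TRUE)
  ig <- ig + igraph::vertices(setdiff(g$nodes, igraph::V(ig)$name))
  out <- list()
  for (src in setdiff(g$nodes, target)) {
    sp <- igraph::all_simple_paths(ig, from = src, to = target,
                                   mode = "out", cutoff = max_len)
    for (p in sp) out[[length(out) + 1L]] <- igraph::V(ig)$name[p]
  }
  out
}

# a small random tiered model for property tests
random_test_model <- function(seed, n_vars = 10, density = 0.25,
                              epoques = 3, max_in = 3) {
  cfg <- sim_config(n_vars = n_vars, n_rows = 100, epoque_count = epoques,
                    edge_density = density, missing_rate = 0, seed = seed,
                    max_in_degree = max_in,
                    vtype_probs = c(cardinal = 1, ordinal = 0, binary = 0))
  suppressWarnings(sample_model(cfg))
}
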