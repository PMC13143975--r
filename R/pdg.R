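#' Create an empty partially directed graph
#'
#' The central container of the pipeline: an undirected skeleton whose edges
#' are progressively oriented. Each edge stores at most one row per unordered
#' node pair `{u, v}` (with `u < v` lexicographically), an orientation
#' (`"u>v"`, `"v>u"` or `"none"`), and a provenance tag recording which rule
#' oriented it: `"temporal"` (cross-epoque tier), `"collider"` (sepset-based
#' Y-structure), `"meek"` (propagation) or `"none"` (unoriented). Separating
#' sets found during discovery are kept in a map keyed by unordered pair.
#'
#' @param nodes character vector of node names.
#' @param epoque optional named integer vector giving each node's time epoque.
#' @return a `tierpc_pdg` object.
#' @export
pdg <- function(nodes, epoque = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  if (!is.null(epoque)) {
    miss <- setdiff(nodes, names(epoque))
    if (length(miss) > 0L) {
      stop("epoque missing for node(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    epoque <- as.integer(epoque[nodes])
    names(epoque) <- nodes
  }
  structure(
    list(
      nodes = nodes,
      epoque = epoque,
      edges = data.frame(u = character(), v = character(),
                         orientation = character(), provenance = character(),
                         stringsAsFactors = FALSE),
      sepsets = list()
    ),
    class = "tierpc_pdg"
  )
}

pair_key <- function(a, b) {
  if (a <= b) paste(a, b, sep = "||") else paste(b, a, sep = "||")
}

#' Add an edge to a partially directed graph
#'
#' @param g a `tierpc_pdg`.
#' @param from,to endpoint names. For `orientation = "directed"` the edge
#'   points `from -> to`; otherwise order is irrelevant.
#' @param orientation `"undirected"` (default) or `"directed"`.
#' @param provenance provenance tag, one of `"none"`, `"temporal"`,
#'   `"collider"`, `"meek"`.
#' @return the updated graph.
#' @export
pdg_add_edge <- function(g, from, to, orientation = c("undirected", "directed"),
                         provenance = "none") {
  orientation <- match.arg(orientation)
  if (from == to) stop("self-loop on '", from, "' not allowed", call. = FALSE)
  if (!from %in% g$nodes || !to %in% g$nodes) {
    stop("unknown node in edge ", from, " - ", to, call. = FALSE)
  }
  u <- min(from, to); v <- max(from, to)
  if (edge_row(g, u, v) > 0L) {
    stop("edge ", u, " - ", v, " already present", call. = FALSE)
  }
  orient <- if (orientation == "undirected") "none"
            else if (from == u) "u>v" else "v>u"
  g$edges <- rbind(g$edges, data.frame(
    u = u, v = v, orientation = orient, provenance = provenance,
    stringsAsFactors = FALSE))
  g
}

# row index of edge {a,b}, 0 if absent
edge_row <- function(g, a, b) {
  u <- min(a, b); v <- max(a, b)
  idx <- which(g$edges$u == u & g$edges$v == v)
  if (length(idx) == 0L) 0L else idx[1L]
}

#' Test adjacency in a partially directed graph
#' @param g a `tierpc_pdg`.
#' @param a,b node names.
#' @return logical.
#' @export
pdg_adjacent <- function(g, a, b) edge_row(g, a, b) > 0L

#' All neighbours of a node, regardless of orientation
#' @param g a `tierpc_pdg`.
#' @param v node name.
#' @return character vector.
#' @export
pdg_neighbors <- function(g, v) {
  e <- g$edges
  sort(c(e$v[e$u == v], e$u[e$v == v]))
}

#' Parents of a node (tails of directed edges into it)
#' @param g a `tierpc_pdg`.
#' @param v node name.
#' @return character vector.
#' @export
pdg_parents <- function(g, v) {
  e <- g$edges
  sort(c(e$u[e$v == v & e$orientation == "u>v"],
         e$v[e$u == v & e$orientation == "v>u"]))
}

#' Children of a node (heads of directed edges out of it)
#' @param g a `tierpc_pdg`.
#' @param v node name.
#' @return character vector.
#' @export
pdg_children <- function(g, v) {
  e <- g$edges
  sort(c(e$v[e$u == v & e$orientation == "u>v"],
         e$u[e$v == v & e$orientation == "v>u"]))
}

#' Undirected neighbours of a node
#' @param g a `tierpc_pdg`.
#' @param v node name.
#' @return character vector.
#' @export
pdg_undirected_neighbors <- function(g, v) {
  e <- g$edges
  sort(c(e$v[e$u == v & e$orientation == "none"],
         e$u[e$v == v & e$orientation == "none"]))
}

# orient existing edge from -> to; caller is responsible for legality checks
pdg_set_orientation <- function(g, from, to, provenance) {
  i <- edge_row(g, from, to)
  if (i == 0L) stop("no edge ", from, " - ", to, call. = FALSE)
  g$edges$orientation[i] <- if (from == g$edges$u[i]) "u>v" else "v>u"
  g$edges$provenance[i] <- provenance
  g
}

#' Direction of an edge
#' @param g a `tierpc_pdg`.
#' @param a,b endpoint names.
#' @return `NULL` if the pair is non-adjacent; otherwise a list with
#'   `directed` (logical) and, when directed, `from` and `to`.
#' @export
pdg_edge_direction <- function(g, a, b) {
  i <- edge_row(g, a, b)
  if (i == 0L) return(NULL)
  o <- g$edges$orientation[i]
  if (o == "none") return(list(from = NA_character_, to = NA_character_,
                               directed = FALSE))
  if (o == "u>v") list(from = g$edges$u[i], to = g$edges$v[i], directed = TRUE)
  else list(from = g$edges$v[i], to = g$edges$u[i], directed = TRUE)
}

# directed edge list as two-column matrix (from, to)
pdg_directed_edges <- function(g) {
  e <- g$edges
  dir <- e$orientation != "none"
  if (!any(dir)) {
    return(matrix(character(), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  from <- ifelse(e$orientation[dir] == "u>v", e$u[dir], e$v[dir])
  to <- ifelse(e$orientation[dir] == "u>v", e$v[dir], e$u[dir])
  cbind(from = from, to = to)
}

# would orienting from->to create a directed cycle? i.e. is `from` reachable
# from `to` along existing directed edges
pdg_creates_cycle <- function(g, from, to, extra = NULL) {
  de <- pdg_directed_edges(g)
  if (!is.null(extra)) de <- rbind(de, extra)
  if (nrow(de) == 0L) return(FALSE)
  frontier <- to
  seen <- character()
  while (length(frontier) > 0L) {
    nxt <- unique(de[de[, "from"] %in% frontier, "to"])
    nxt <- setdiff(nxt, seen)
    if (from %in% nxt) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- nxt
  }
  FALSE
}

#' Check the structural invariants of a partially directed graph
#'
#' Verifies: no self loops, one edge per unordered pair, acyclicity of the
#' directed subgraph, epoque consistency (no directed edge from a later
#' epoque into an earlier one) and that any pair holding a recorded sepset is
#' non-adjacent.
#'
#' @param g a `tierpc_pdg`.
#' @return `g`, invisibly, if valid; otherwise stops.
#' @export
validate_pdg <- function(g) {
  stopifnot(inherits(g, "tierpc_pdg"))
  e <- g$edges
  if (any(e$u == e$v)) stop("self-loop detected", call. = FALSE)
  if (anyDuplicated(paste(e$u, e$v))) {
    stop("duplicate edge for an unordered pair", call. = FALSE)
  }
  de <- pdg_directed_edges(g)
  if (nrow(de) > 0L) {
    ig <- igraph::graph_from_edgelist(de, directed = TRUE)
    if (!igraph::is_dag(ig)) {
      stop("directed subgraph contains a cycle", call. = FALSE)
    }
    if (!is.null(g$epoque)) {
      bad <- g$epoque[de[, "from"]] > g$epoque[de[, "to"]]
      if (any(bad)) {
        stop("directed edge from later epoque into earlier epoque: ",
             paste(de[bad, "from"], "->", de[bad, "to"], collapse = "; "),
             call. = FALSE)
      }
    }
  }
  for (k in names(g$sepsets)) {
    ab <- strsplit(k, "||", fixed = TRUE)[[1L]]
    if (pdg_adjacent(g, ab[1L], ab[2L])) {
      stop("pair ", ab[1L], ",", ab[2L],
           " has a sepset but is still adjacent", call. = FALSE)
    }
  }
  invisible(g)
}

#' Number of edges
#' @param g a `tierpc_pdg`.
#' @return integer edge count.
#' @export
pdg_n_edges <- function(g) nrow(g$edges)

#' Edge table of a partially directed graph
#'
#' @param g a `tierpc_pdg`.
#' @return data frame with columns `from`, `to`, `directed`, `provenance`;
#'   undirected edges carry the canonical (sorted) endpoint order.
#' @export
pdg_edge_table <- function(g) {
  e <- g$edges
  from <- ifelse(e$orientation == "v>u", e$v, e$u)
  to <- ifelse(e$orientation == "v>u", e$u, e$v)
  data.frame(from = from, to = to, directed = e$orientation != "none",
             provenance = e$provenance, stringsAsFactors = FALSE)
}

#' @export
print.tierpc_pdg <- function(x, ...) {
  n_dir <- sum(x$edges$orientation != "none")
  cat(sprintf("Partially directed graph: %d nodes, %d edges (%d directed, %d undirected)\n",
              length(x$nodes), nrow(x$edges), n_dir, nrow(x$edges) - n_dir))
  tabp <- table(x$edges$provenance)
  if (length(tabp) > 0L) {
    cat("provenance:", paste(sprintf("%s=%d", names(tabp), tabp), collapse = ", "),
        "\n")
  }
  invisible(x)
}
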