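#' Write a network to disk
#'
#' Three Cytoscape-compatible formats:
#' \describe{
#'   \item{`edge_list_tsv`}{a TSV edge list with columns `from`, `to`,
#'     `orientation` (`directed`/`undirected`), `provenance` and `stability`
#'     (percent, empty when unknown). Nodes, epoques and sepsets are
#'     serialized in `#`-prefixed header lines so the format round trips
#'     exactly through [read_network()], including isolated nodes.}
#'   \item{`sif`}{simple interaction format; directed edges use the
#'     interaction label `causes`, undirected edges `assoc`.}
#'   \item{`graphml`}{GraphML with the epoque stored as a node attribute and
#'     provenance/stability as edge attributes.}
#' }
#'
#' The graph's acyclicity and epoque-consistency invariants are re-validated
#' before anything is written.
#'
#' @param g a `tierpc_pdg` or `tierpc_global_network`.
#' @param path output file path.
#' @param format one of `"edge_list_tsv"`, `"sif"`, `"graphml"`.
#' @param stability optional `tierpc_stability` or named numeric vector
#'   (names `"u||v"`, values percent); edges without an entry get an empty
#'   stability field.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path,
                          format = c("edge_list_tsv", "sif", "graphml"),
                          stability = NULL) {
  if (inherits(g, "tierpc_global_network")) g <- g$graph
  stopifnot(inherits(g, "tierpc_pdg"))
  format <- match.arg(format)
  validate_pdg(g)
  stab <- NULL
  if (inherits(stability, "tierpc_stability")) {
    e <- stability$edges
    stab <- stats::setNames(e$percent, paste(e$u, e$v, sep = "||"))
  } else if (!is.null(stability)) {
    stab <- stability
  }
  et <- pdg_edge_table(g)
  et$stability <- if (is.null(stab)) rep(NA_real_, nrow(et)) else {
    keys <- mapply(pair_key, et$from, et$to)
    unname(stab[keys])
  }
  switch(format,
    edge_list_tsv = write_network_tsv(g, et, path),
    sif = write_network_sif(g, et, path),
    graphml = write_network_graphml(g, et, path))
  invisible(path)
}

write_network_tsv <- function(g, et, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (v in g$nodes) {
    ep <- if (is.null(g$epoque)) "" else g$epoque[[v]]
    writeLines(sprintf("# node\t%s\t%s", v, ep), con)
  }
  for (k in names(g$sepsets)) {
    ab <- strsplit(k, "||", fixed = TRUE)[[1L]]
    writeLines(sprintf("# sepset\t%s\t%s\t%s", ab[1L], ab[2L],
                       paste(g$sepsets[[k]], collapse = ",")), con)
  }
  writeLines("from\tto\torientation\tprovenance\tstability", con)
  if (nrow(et) > 0L) {
    lines <- sprintf("%s\t%s\t%s\t%s\t%s", et$from, et$to,
                     ifelse(et$directed, "directed", "undirected"),
                     et$provenance,
                     ifelse(is.na(et$stability), "",
                            format(et$stability, trim = TRUE)))
    writeLines(lines, con)
  }
}

write_network_sif <- function(g, et, path) {
  lines <- character()
  if (nrow(et) > 0L) {
    lines <- sprintf("%s\t%s\t%s", et$from,
                     ifelse(et$directed, "causes", "assoc"), et$to)
  }
  touched <- unique(c(et$from, et$to))
  lines <- c(lines, setdiff(g$nodes, touched))  # isolated nodes, bare names
  writeLines(lines, path)
}

write_network_graphml <- function(g, et, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  key_ep <- xml2::xml_add_child(doc, "key", id = "epoque", `for` = "node",
                                attr.name = "epoque", attr.type = "int")
  xml2::xml_add_child(doc, "key", id = "provenance", `for` = "edge",
                      attr.name = "provenance", attr.type = "string")
  xml2::xml_add_child(doc, "key", id = "stability", `for` = "edge",
                      attr.name = "stability", attr.type = "double")
  gx <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  for (v in g$nodes) {
    nd <- xml2::xml_add_child(gx, "node", id = v)
    if (!is.null(g$epoque)) {
      d <- xml2::xml_add_child(nd, "data", key = "epoque")
      xml2::xml_text(d) <- as.character(g$epoque[[v]])
    }
  }
  for (i in seq_len(nrow(et))) {
    ed <- xml2::xml_add_child(gx, "edge", source = et$from[i],
                              target = et$to[i],
                              directed = tolower(as.character(et$directed[i])))
    d <- xml2::xml_add_child(ed, "data", key = "provenance")
    xml2::xml_text(d) <- et$provenance[i]
    if (!is.na(et$stability[i])) {
      d2 <- xml2::xml_add_child(ed, "data", key = "stability")
      xml2::xml_text(d2) <- format(et$stability[i], trim = TRUE)
    }
  }
  invisible(key_ep)
  xml2::write_xml(doc, path)
}

#' Read a network from a TSV edge list
#'
#' Inverse of [write_network()] with `format = "edge_list_tsv"`: restores
#' nodes (including isolated ones), epoques, edges with orientation and
#' provenance, and the sepset map. Per-edge stability percentages, when
#' present, are returned in the `"stability"` attribute.
#'
#' @param path path to a file written by [write_network()].
#' @return a `tierpc_pdg`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  nodes <- character(); epoque <- integer(); sepsets <- list()
  for (ln in lines[hdr]) {
    f <- strsplit(sub("^# ", "", ln), "\t", fixed = TRUE)[[1L]]
    if (f[1L] == "node") {
      nodes <- c(nodes, f[2L])
      epoque <- c(epoque, if (length(f) >= 3L && nzchar(f[3L]))
        as.integer(f[3L]) else NA_integer_)
    } else if (f[1L] == "sepset") {
      ss <- if (length(f) >= 4L && nzchar(f[4L])) {
        strsplit(f[4L], ",", fixed = TRUE)[[1L]]
      } else character()
      sepsets[[pair_key(f[2L], f[3L])]] <- ss
    }
  }
  body <- lines[!hdr]
  if (length(body) == 0L || body[1L] != "from\tto\torientation\tprovenance\tstability") {
    stop("'", path, "' is not a tierpc edge-list file", call. = FALSE)
  }
  names(epoque) <- nodes
  g <- pdg(nodes, if (all(is.na(epoque))) NULL else epoque)
  stability <- numeric()
  for (ln in body[-1L]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    g <- pdg_add_edge(g, f[1L], f[2L],
                      if (f[3L] == "directed") "directed" else "undirected",
                      provenance = f[4L])
    if (length(f) >= 5L && nzchar(f[5L])) {
      stability[pair_key(f[1L], f[2L])] <- as.numeric(f[5L])
    }
  }
  g$sepsets <- sepsets
  validate_pdg(g)
  attr(g, "stability") <- stability
  g
}

#' Read run parameters from a YAML config file
#'
#' One config file carries every run parameter so a whole analysis is
#' reproducible from a single artifact. Recognized fields: `alpha`, `max_k`,
#' `bootstrap`, `seed`, `path_len`, `target`; missing fields take the
#' documented defaults.
#'
#' @param path path to a YAML file.
#' @return a named list of validated parameters.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- list(
    alpha = if (is.null(raw$alpha)) 0.05 else as.numeric(raw$alpha),
    max_k = if (is.null(raw$max_k)) 3L else as.integer(raw$max_k),
    bootstrap = if (is.null(raw$bootstrap)) 100L else as.integer(raw$bootstrap),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    path_len = if (is.null(raw$path_len)) 4L else as.integer(raw$path_len),
    target = raw$target
  )
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (cfg$max_k < 0L) stop("max_k must be >= 0", call. = FALSE)
  if (cfg$bootstrap < 1L) stop("bootstrap must be >= 1", call. = FALSE)
  if (cfg$path_len < 1L) stop("path_len must be >= 1", call. = FALSE)
  cfg
}

#' Write a run log mirroring the effective parameters
#'
#' @param params named list (e.g. from [read_run_config()], possibly with
#'   extra entries describing the run).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(params, path) {
  params$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(params, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
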