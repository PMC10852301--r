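#' Multilayer network container
#'
#' A minimal edge-list representation of a (possibly signed) multilayer
#' network.  Nodes carry a layer label; undirected edges carry a weight and a
#' method tag (`"MI"` for normalized mutual information in \[0, 1\],
#' `"Pearson"` for signed correlations in \[-1, 1\], `"validation"` for
#' unweighted validation edges).  Edges are stored with endpoints in
#' lexicographic order so that each unordered pair appears at most once.
#'
#' @param nodes data.frame with columns `id` (character, unique) and `layer`
#'   (character).
#' @param edges data.frame with columns `from`, `to` (character node ids),
#'   `weight` (numeric) and `method` (character).  May have zero rows.
#' @param hierarchy optional character vector giving the ordered layer chain
#'   (used by the dynamic network).
#' @return an object of class `ml_network`.
#' @export
ml_network <- function(nodes, edges = empty_edges(), hierarchy = NULL) {
  stopifnot(is.data.frame(nodes), all(c("id", "layer") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$layer <- as.character(nodes$layer)
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node ids")
  }
  edges <- normalize_edges(edges)
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(unknown)) {
      stop("edge endpoints not in node table: ", paste(unknown, collapse = ", "))
    }
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    if (anyDuplicated(edge_key(edges$from, edges$to))) {
      stop("duplicate edges")
    }
  }
  structure(list(nodes = nodes, edges = edges, hierarchy = hierarchy),
            class = "ml_network")
}

#' @export
print.ml_network <- function(x, ...) {
  cat("ml_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  tab <- table(x$nodes$layer)
  cat("  layers:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(x$hierarchy)) {
    cat("  hierarchy:", paste(x$hierarchy, collapse = " > "), "\n")
  }
  invisible(x)
}

empty_edges <- function() {
  data.frame(from = character(), to = character(),
             weight = numeric(), method = character(),
             stringsAsFactors = FALSE)
}

# canonical key for an unordered node pair
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

normalize_edges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) return(empty_edges())
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (is.null(edges$method)) edges$method <- NA_character_
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  swap <- from > to
  edges$from <- ifelse(swap, to, from)
  edges$to <- ifelse(swap, from, to)
  rownames(edges) <- NULL
  edges[, c("from", "to", "weight", "method")]
}

#' Look up the layer of each node id
#' @param network an `ml_network`.
#' @param ids character vector of node ids.
#' @return character vector of layer labels.
#' @export
node_layer <- function(network, ids) {
  network$nodes$layer[match(ids, network$nodes$id)]
}

#' Convert to an igraph object
#'
#' Layer becomes a vertex attribute, weight and method edge attributes.
#'
#' @param network an `ml_network`.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    d = network$edges,
    directed = FALSE,
    vertices = network$nodes
  )
  g
}

#' Write a network as GraphML
#' @param network an `ml_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write / read a network as 4-column edge-list TSV
#'
#' Columns are `from`, `to`, `weight`, `method`.  The node table is written to
#' a sidecar `<path>.nodes.tsv` so that isolated nodes and layer labels
#' round-trip.
#'
#' @param network an `ml_network`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @param hierarchy optional ordered layer chain to attach on read.
#' @export
read_network_tsv <- function(path, hierarchy = NULL) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(from = "character", to = "character"))
  nodes <- utils::read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE,
                             colClasses = c(id = "character", layer = "character"))
  ml_network(nodes, edges, hierarchy = hierarchy)
}
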