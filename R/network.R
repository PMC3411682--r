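#' @importFrom stats setNames
NULL

NET_TYPES <- c("ppi", "genetic", "coexpression", "ecological_bipartite",
               "social", "generic")

# C-locale (byte-order) sort: tie-breaks must not depend on the session locale.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

#' Construct a simple undirected network
#'
#' The central data structure of the package: a binary undirected graph
#' G = (V, E) with string node labels, no self-loops and no duplicate edges.
#' A node may represent a gene, protein, species or any entity of interest;
#' `net_type` is metadata only and changes no algorithm.
#'
#' @param edges A two-column character matrix (or a data.frame coercible to
#'   one), one edge per row. Row order and within-pair order are irrelevant:
#'   edges are stored canonically (pair sorted in C-locale order, rows sorted).
#' @param nodes Optional character vector of node labels. Must include every
#'   edge endpoint; labels beyond the endpoints are kept as isolated
#'   (degree-0) nodes, which can arise after a perturbation.
#' @param net_type One of `"ppi"`, `"genetic"`, `"coexpression"`,
#'   `"ecological_bipartite"`, `"social"`, `"generic"`.
#' @return An object of class `network_graph` with elements `nodes`
#'   (sorted character vector), `edges` (canonical two-column character
#'   matrix) and `net_type`.
#' @examples
#' net <- network_graph(rbind(c("A", "B"), c("B", "C")))
#' network_size(net)
#' @export
network_graph <- function(edges, nodes = NULL, net_type = "generic") {
  net_type <- match.arg(net_type, NET_TYPES)
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    stop("`edges` must be a two-column matrix of node labels")
  }
  storage.mode(edges) <- "character"
  if (any(is.na(edges)) || any(edges == "")) {
    stop("edge endpoints must be non-empty, non-missing labels")
  }
  if (any(grepl("[[:space:]]", edges))) {
    stop("node labels must not contain whitespace")
  }
  if (any(edges[, 1] == edges[, 2])) {
    stop("self-loops are not allowed in a network_graph")
  }
  endpoint_labels <- sort_c(unique(c(edges)))
  if (is.null(nodes)) {
    nodes <- endpoint_labels
  } else {
    nodes <- sort_c(unique(as.character(nodes)))
    if (!all(endpoint_labels %in% nodes)) {
      stop("`nodes` must contain every edge endpoint")
    }
  }
  edges <- canonical_edges(edges, nodes)
  structure(list(nodes = nodes, edges = edges, net_type = net_type),
            class = "network_graph")
}

# Canonicalize: within-pair order and row order by node rank (C locale),
# duplicates collapsed.
canonical_edges <- function(edges, nodes) {
  if (nrow(edges) == 0L) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to"))))
  }
  i <- match(edges[, 1], nodes)
  j <- match(edges[, 2], nodes)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  keep <- !duplicated(lo * (length(nodes) + 1) + hi)
  lo <- lo[keep]
  hi <- hi[keep]
  ord <- order(lo, hi)
  cbind(from = nodes[lo[ord]], to = nodes[hi[ord]])
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %d nodes, %d edges (type: %s)\n",
              length(x$nodes), nrow(x$edges), x$net_type))
  if (length(x$nodes)) {
    shown <- utils::head(x$nodes, 8)
    cat("  nodes:", paste(shown, collapse = ", "),
        if (length(x$nodes) > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' Number of nodes in a network
#' @param net A `network_graph`.
#' @return Integer node count.
#' @export
network_size <- function(net) {
  stopifnot(inherits(net, "network_graph"))
  length(net$nodes)
}

#' Number of edges in a network
#' @param net A `network_graph`.
#' @return Integer edge count.
#' @export
edge_count <- function(net) {
  stopifnot(inherits(net, "network_graph"))
  nrow(net$edges)
}

#' Node degrees
#'
#' Degree k(i) = |N(i)|, the number of vertices adjacent to node i.
#'
#' @param net A `network_graph`.
#' @return Named integer vector over all nodes (isolated nodes get 0).
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "network_graph"))
  d <- tabulate(match(c(net$edges), net$nodes), nbins = length(net$nodes))
  setNames(as.integer(d), net$nodes)
}

#' Isolated (degree-0) nodes
#' @param net A `network_graph`.
#' @return Character vector of labels with no incident edge.
#' @export
isolated_nodes <- function(net) {
  d <- node_degrees(net)
  names(d)[d == 0L]
}

#' Test whether a pair of labels is an edge of the network
#' @param net A `network_graph`.
#' @param a,b Node labels.
#' @return Logical.
#' @export
has_edge <- function(net, a, b) {
  any((net$edges[, 1] == a & net$edges[, 2] == b) |
      (net$edges[, 1] == b & net$edges[, 2] == a))
}

#' Convert a network to an igraph object
#'
#' Isolated nodes are preserved as degree-0 vertices; vertex names carry the
#' node labels, vertex order follows the network's sorted node set.
#'
#' @param net A `network_graph`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "network_graph"))
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges) > 0L) {
    idx <- rbind(match(net$edges[, 1], net$nodes),
                 match(net$edges[, 2], net$nodes))
    g <- igraph::add_edges(g, as.vector(idx))
  }
  g
}

# Internal: subnetwork induced by `keep` labels; isolated survivors retained.
induced_subnetwork <- function(net, keep) {
  keep <- sort_c(unique(keep))
  e <- net$edges
  if (nrow(e)) {
    e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  }
  network_graph(e, nodes = keep, net_type = net$net_type)
}
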