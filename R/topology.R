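#' Connected components
#'
#' Partitions the node set into its connected components. Component ids are
#' `1..n_components`, assigned in decreasing component size with ties broken
#' by the smallest member label, so the numbering (and hence any color
#' mapping) is deterministic.
#'
#' @param net A `network_graph`.
#' @return Named integer vector mapping each node label to its component id.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "network_graph"))
  if (length(net$nodes) == 0L) return(setNames(integer(0), character(0)))
  comp <- igraph::components(as_igraph(net))
  raw <- comp$membership  # named by node label
  sizes <- tabulate(raw, nbins = comp$no)
  # vertex order equals the C-locale-sorted node set, so the smallest member
  # label of each component is its first occurrence
  first_member <- match(seq_len(comp$no), raw)
  rank_order <- order(-sizes, first_member)
  relabel <- integer(comp$no)
  relabel[rank_order] <- seq_len(comp$no)
  setNames(relabel[raw], names(raw))
}

#' Single-source shortest-path distances
#'
#' Breadth-first-search distances from `source` to every node. The distance
#' from a node to itself is 0; nodes with no connecting path are reported as
#' `Inf` (unreachable).
#'
#' @param net A `network_graph`.
#' @param source A node label present in the network.
#' @return Named numeric vector of distances over all nodes.
#' @export
shortest_path_lengths <- function(net, source) {
  stopifnot(inherits(net, "network_graph"))
  if (!source %in% net$nodes) {
    stop(sprintf("unknown source node '%s'", source))
  }
  d <- igraph::distances(as_igraph(net), v = source, algorithm = "unweighted")
  setNames(as.numeric(d[1, ]), colnames(d))
}

# Internal: all-pairs distance matrix (BFS), rows/cols in node order.
all_distances <- function(net) {
  if (length(net$nodes) == 0L) {
    return(matrix(numeric(0), 0, 0))
  }
  igraph::distances(as_igraph(net), algorithm = "unweighted")
}

#' Global topology summary
#'
#' Computes the network-level indicators: size S (node count), edge count
#' \eqn{|E|}, density \eqn{2|E|/(S(S-1))} (0 for S <= 1), average degree
#' \eqn{K = 2|E|/S}, average path length (mean shortest-path distance over
#' ordered pairs of distinct nodes that are connected; `NA` when no such pair
#' exists), diameter (largest finite distance), component count and sizes.
#'
#' @param net A `network_graph`.
#' @param metrics Character vector selecting which fields to compute; the
#'   distance-based fields (`avg_path_length`, `diameter`) and the component
#'   fields dominate the cost on large networks. Defaults to all.
#' @return A list of class `network_summary`.
#' @export
summarize_network <- function(net,
                              metrics = c("density", "avg_degree",
                                          "avg_path_length", "diameter",
                                          "components")) {
  stopifnot(inherits(net, "network_graph"))
  metrics <- match.arg(metrics, several.ok = TRUE)
  s <- length(net$nodes)
  m <- nrow(net$edges)
  out <- list(size = s, edge_count = m,
              density = NA_real_, avg_degree = NA_real_,
              avg_path_length = NA_real_, diameter = NA_real_,
              n_components = NA_integer_, component_sizes = NULL)
  if ("density" %in% metrics) {
    out$density <- if (s >= 2) 2 * m / (s * (s - 1)) else 0
  }
  if ("avg_degree" %in% metrics) {
    out$avg_degree <- if (s >= 1) 2 * m / s else 0
  }
  if (any(c("avg_path_length", "diameter") %in% metrics) && s >= 1) {
    d <- all_distances(net)
    off <- d[row(d) != col(d)]
    finite <- off[is.finite(off)]
    if ("avg_path_length" %in% metrics) {
      out$avg_path_length <- if (length(finite)) mean(finite) else NA_real_
    }
    if ("diameter" %in% metrics) {
      out$diameter <- if (length(finite)) max(finite) else NA_real_
    }
  }
  if ("components" %in% metrics && s >= 1) {
    cc <- connected_components(net)
    sizes <- as.integer(table(cc))
    out$n_components <- length(sizes)
    out$component_sizes <- sort(sizes, decreasing = TRUE)
  } else if (s == 0L) {
    out$n_components <- 0L
    out$component_sizes <- integer(0)
    out$density <- 0
    out$avg_degree <- 0
  }
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary>\n")
  cat(sprintf("  size: %d   edges: %d   density: %s   avg degree: %s\n",
              x$size, x$edge_count, format(x$density, digits = 4),
              format(x$avg_degree, digits = 4)))
  cat(sprintf("  avg path length: %s   diameter: %s   components: %s\n",
              format(x$avg_path_length, digits = 4),
              format(x$diameter, digits = 4),
              format(x$n_components)))
  invisible(x)
}

#' Betweenness centrality
#'
#' For each node v, the sum over unordered pairs \{i, j\} with i != v != j of
#' the fraction of i-j geodesics (shortest paths) that pass through v. Pairs
#' with no connecting path contribute 0. Unnormalized; each unordered pair is
#' counted once.
#'
#' @param net A `network_graph`.
#' @return Named numeric vector over all nodes.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "network_graph"))
  if (length(net$nodes) == 0L) return(setNames(numeric(0), character(0)))
  b <- igraph::betweenness(as_igraph(net), directed = FALSE, weights = NULL)
  setNames(as.numeric(b), names(b))
}

#' Closeness centrality with the disconnected-network substitution rule
#'
#' For each node v, \eqn{(|V|-1) / \sum_{i \ne v} d'(v, i)} where
#' \eqn{d'(v,i)} is the shortest-path distance when one exists and the total
#' number of vertices \eqn{|V|} otherwise. The substitution keeps the measure
#' defined on fragmented networks; an isolated node gets exactly
#' \eqn{1/|V|}.
#'
#' @param net A `network_graph` with at least 2 nodes.
#' @return Named numeric vector over all nodes, values in (0, 1].
#' @export
closeness_centrality <- function(net) {
  stopifnot(inherits(net, "network_graph"))
  nv <- length(net$nodes)
  if (nv < 2L) stop("closeness undefined: network has fewer than 2 nodes")
  d <- all_distances(net)
  d[!is.finite(d)] <- nv
  sums <- rowSums(d)  # diagonal contributes 0
  setNames((nv - 1) / sums, net$nodes)
}

#' Eigenvector centrality by shifted power iteration
#'
#' Entries of the principal eigenvector of the 0/1 adjacency matrix A,
#' rescaled so the maximum entry is 1. A node is central when its neighbors
#' are central. Computed by power iteration on A + I starting from the
#' uniform positive vector; the identity shift leaves the eigenvectors
#' unchanged while making the dominant eigenvalue strictly separated in
#' modulus, so the iteration also converges on bipartite graphs, whose
#' adjacency spectrum is symmetric about 0. On disconnected networks the
#' iteration localizes on the component with the largest spectral radius and
#' other components come out (near) 0; a warning flags this case.
#'
#' @param net A `network_graph` with at least one edge.
#' @param tol Convergence tolerance on the max-norm difference of successive
#'   max-normalized iterates.
#' @param max_iter Maximum number of iterations.
#' @return Named numeric vector over all nodes, maximum entry 1. The
#'   attribute `"n_iter"` records the iterations used. On non-convergence an
#'   error of class `eigenvector_no_convergence` is signaled; its `iterate`
#'   field carries the last iterate so a caller may restart.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(net, "network_graph"))
  if (nrow(net$edges) == 0L) {
    stop("eigenvector centrality requires at least one edge")
  }
  nv <- length(net$nodes)
  a <- matrix(0, nv, nv, dimnames = list(net$nodes, net$nodes))
  i <- match(net$edges[, 1], net$nodes)
  j <- match(net$edges[, 2], net$nodes)
  a[cbind(i, j)] <- 1
  a[cbind(j, i)] <- 1

  cc <- connected_components(net)
  if (max(cc) > 1L) {
    warning("network is disconnected: eigenvector centrality localizes on ",
            "the component with the largest spectral radius")
  }

  x <- rep(1 / nv, nv)
  for (iter in seq_len(max_iter)) {
    y <- as.vector(a %*% x) + x  # (A + I) x
    y <- y / max(y)
    if (max(abs(y - x)) < tol) {
      return(structure(setNames(y, net$nodes), n_iter = iter))
    }
    x <- y
  }
  cond <- structure(
    class = c("eigenvector_no_convergence", "error", "condition"),
    list(message = sprintf(
           "eigenvector centrality did not converge in %d iterations", max_iter),
         call = sys.call(-1), iterate = setNames(x, net$nodes))
  )
  stop(cond)
}

#' Per-node centrality table and sorted listings
#'
#' Combines degree, betweenness, closeness and eigenvector centrality with
#' the component id of each node. Each sorted listing ranks nodes by
#' descending value, ties broken lexicographically by label.
#'
#' @param net A `network_graph` with at least 2 nodes and at least one edge.
#' @param tol,max_iter Passed to [eigenvector_centrality()].
#' @return A data.frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`, `component_id`, one row per node (rows in
#'   label order). The attribute `"sorted"` is a named list of four
#'   data.frames (`degree`, `betweenness`, `closeness`, `eigenvector`), each
#'   with columns `node` and `value` in ranking order.
#' @export
node_metrics <- function(net, tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(net, "network_graph"))
  deg <- node_degrees(net)
  btw <- betweenness_centrality(net)
  clo <- closeness_centrality(net)
  eig <- eigenvector_centrality(net, tol = tol, max_iter = max_iter)
  comp <- connected_components(net)
  df <- data.frame(node = net$nodes,
                   degree = as.integer(deg[net$nodes]),
                   betweenness = as.numeric(btw[net$nodes]),
                   closeness = as.numeric(clo[net$nodes]),
                   eigenvector = as.numeric(eig[net$nodes]),
                   component_id = as.integer(comp[net$nodes]),
                   stringsAsFactors = FALSE, row.names = NULL)
  sorted <- lapply(c(degree = "degree", betweenness = "betweenness",
                     closeness = "closeness", eigenvector = "eigenvector"),
                   function(col) {
                     ord <- order(-df[[col]], match(df$node, net$nodes))
                     data.frame(node = df$node[ord], value = df[[col]][ord],
                                stringsAsFactors = FALSE, row.names = NULL)
                   })
  attr(df, "sorted") <- sorted
  df
}
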