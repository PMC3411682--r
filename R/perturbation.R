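#' Remove nodes and account for secondary extinctions
#'
#' Applies a single or clustered node perturbation: all `targets` (the
#' primary extinctions) are removed simultaneously together with their
#' incident edges. Any surviving node whose degree thereby falls to 0 has
#' lost its entire support link to the remaining subnetwork; it is recorded
#' as a secondary extinction (co-extinction) and removed from the functional
#' remainder as well. No further cascading rounds are needed: removing an
#' already-isolated node cannot isolate another.
#'
#' @param net A `network_graph` without isolated nodes (every node
#'   functional, i.e. holding at least one support link).
#' @param targets Character vector of node labels to remove; non-empty,
#'   duplicate-free, all present in `net`.
#' @return A list of class `perturbation_result` with elements `primaries`
#'   (the targets, in the order given), `secondaries` (sorted labels),
#'   `remaining` (the functional subnetwork, a `network_graph`), `before` and
#'   `after` (`network_summary` objects) and `delta` (after minus before for
#'   the numeric summary fields).
#' @examples
#' star <- make_star(3)
#' res <- remove_nodes(star, "hub")
#' res$secondaries  # all three leaves co-extinct
#' @export
remove_nodes <- function(net, targets) {
  stopifnot(inherits(net, "network_graph"))
  check_functional(net)
  targets <- as.character(targets)
  if (length(targets) == 0L) stop("no target nodes given")
  if (anyDuplicated(targets)) stop("duplicate target nodes")
  missing <- setdiff(targets, net$nodes)
  if (length(missing)) {
    stop(sprintf("unknown target node(s): %s", paste(missing, collapse = ", ")))
  }
  survivors <- setdiff(net$nodes, targets)
  e <- net$edges
  keep <- e[, 1] %in% survivors & e[, 2] %in% survivors
  e_after <- e[keep, , drop = FALSE]
  deg_after <- tabulate(match(c(e_after), survivors), nbins = length(survivors))
  secondaries <- sort_c(survivors[deg_after == 0L])
  remaining <- network_graph(e_after, nodes = setdiff(survivors, secondaries),
                             net_type = net$net_type)
  finish_perturbation(net, remaining, primaries = targets,
                      secondaries = secondaries)
}

#' Remove edges and account for secondary extinctions
#'
#' Applies a single or clustered edge perturbation: the targeted interactions
#' are destabilized simultaneously. A node left without any support link
#' becomes a secondary extinction and leaves the functional subnetwork, even
#' though it was never named as a target itself.
#'
#' @param net A `network_graph` without isolated nodes.
#' @param targets The edges to remove: a two-column character matrix, a list
#'   of length-2 character vectors, or a character vector of
#'   `"A B"`-style pairs. Every pair must be an existing edge.
#' @return A `perturbation_result` (see [remove_nodes()]); `primaries` is the
#'   canonical two-column matrix of removed edges.
#' @export
remove_edges <- function(net, targets) {
  stopifnot(inherits(net, "network_graph"))
  check_functional(net)
  tm <- as_edge_matrix(targets)
  if (nrow(tm) == 0L) stop("no target edges given")
  # canonicalize pair order against the node ranking
  i <- match(tm[, 1], net$nodes)
  j <- match(tm[, 2], net$nodes)
  if (any(is.na(i)) || any(is.na(j))) {
    bad <- which(is.na(i) | is.na(j))[1]
    stop(sprintf("edge (%s, %s) names an unknown node", tm[bad, 1], tm[bad, 2]))
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(net$nodes[lo], net$nodes[hi])
  edge_key <- paste(net$edges[, 1], net$edges[, 2])
  hit <- match(key, edge_key)
  if (anyNA(hit)) {
    bad <- which(is.na(hit))[1]
    stop(sprintf("edge (%s, %s) does not exist in the network",
                 tm[bad, 1], tm[bad, 2]))
  }
  if (anyDuplicated(hit)) stop("duplicate target edges")
  e_after <- net$edges[-hit, , drop = FALSE]
  deg_after <- tabulate(match(c(e_after), net$nodes), nbins = length(net$nodes))
  secondaries <- sort_c(net$nodes[deg_after == 0L])
  remaining <- network_graph(e_after, nodes = setdiff(net$nodes, secondaries),
                             net_type = net$net_type)
  finish_perturbation(net, remaining,
                      primaries = cbind(from = net$nodes[lo], to = net$nodes[hi]),
                      secondaries = secondaries)
}

check_functional <- function(net) {
  iso <- isolated_nodes(net)
  if (length(iso)) {
    stop("network contains isolated (non-functional) nodes: ",
         paste(utils::head(iso, 5), collapse = ", "))
  }
  invisible(net)
}

as_edge_matrix <- function(targets) {
  if (is.matrix(targets)) {
    stopifnot(ncol(targets) == 2)
    m <- targets
  } else if (is.list(targets)) {
    stopifnot(all(lengths(targets) == 2))
    m <- do.call(rbind, targets)
  } else {
    parts <- strsplit(trimws(as.character(targets)), "[[:space:]]+")
    stopifnot(all(lengths(parts) == 2))
    m <- do.call(rbind, parts)
  }
  storage.mode(m) <- "character"
  m
}

finish_perturbation <- function(net, remaining, primaries, secondaries) {
  before <- summarize_network(net)
  after <- summarize_network(remaining)
  num_fields <- c("size", "edge_count", "density", "avg_degree",
                  "avg_path_length", "diameter", "n_components")
  delta <- setNames(
    lapply(num_fields, function(f) {
      as.numeric(after[[f]]) - as.numeric(before[[f]])
    }), num_fields)
  structure(list(primaries = primaries, secondaries = secondaries,
                 remaining = remaining, before = before, after = after,
                 delta = delta),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  n_prim <- if (is.matrix(x$primaries)) nrow(x$primaries) else length(x$primaries)
  what <- if (is.matrix(x$primaries)) "edge(s)" else "node(s)"
  cat(sprintf("<perturbation_result> %d primary %s removed, %d secondary extinction(s)\n",
              n_prim, what, length(x$secondaries)))
  cat(sprintf("  remaining functional subnetwork: %d nodes, %d edges (%s component(s))\n",
              x$after$size, x$after$edge_count, format(x$after$n_components)))
  if (length(x$secondaries)) {
    cat("  secondaries:", paste(utils::head(x$secondaries, 10), collapse = ", "),
        if (length(x$secondaries) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Fragmentation report for a perturbation
#'
#' Compares the connected-component structure before and after a
#' perturbation. The perturbation is flagged `"fragmented"` when the
#' component count increased, and `"collapsed"` when no functional node
#' remains.
#'
#' @param before,after `network_graph` objects; `after` must be a subnetwork
#'   of `before` (nodes and edges subsets).
#' @return A list with `n_components_before`, `n_components_after`,
#'   `components_after` (named id vector, see [connected_components()]),
#'   `new_components` (list of node sets of `after` components that were not
#'   components of `before`), and flags `fragmented` and `collapsed`.
#' @export
fragmentation_report <- function(before, after) {
  stopifnot(inherits(before, "network_graph"), inherits(after, "network_graph"))
  if (!all(after$nodes %in% before$nodes)) {
    stop("`after` contains nodes absent from `before`")
  }
  if (nrow(after$edges) &&
      !all(paste(after$edges[, 1], after$edges[, 2]) %in%
           paste(before$edges[, 1], before$edges[, 2]))) {
    stop("`after` contains edges absent from `before`")
  }
  cb <- connected_components(before)
  ca <- connected_components(after)
  nb <- if (length(cb)) max(cb) else 0L
  na_ <- if (length(ca)) max(ca) else 0L
  before_sets <- if (nb) split(names(cb), cb) else list()
  after_sets <- if (na_) split(names(ca), ca) else list()
  sig <- function(s) paste(sort_c(s), collapse = "\r")
  new_comp <- after_sets[!vapply(after_sets, sig, "") %in%
                           vapply(before_sets, sig, "")]
  list(n_components_before = nb,
       n_components_after = na_,
       components_after = ca,
       new_components = unname(new_comp),
       fragmented = na_ > nb,
       collapsed = length(after$nodes) == 0L)
}
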