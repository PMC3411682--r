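#' Parse a whitespace-delimited edge list
#'
#' Reads the plain-text interaction format: one edge per line, the first two
#' whitespace-separated tokens naming the two endpoints. The input is read as
#' undirected and unweighted: self-loop lines are dropped, duplicate lines
#' (including reversed duplicates such as `"A B"` after `"B A"`) collapse to a
#' single edge, and columns beyond the first two are ignored with a warning so
#' that weighted lists degrade gracefully to binary. Lines starting with `#`
#' and blank lines are skipped.
#'
#' @param text A length-one string (possibly multi-line) or a character vector
#'   of lines.
#' @param net_type Network type tag, metadata only (see [network_graph()]).
#' @return A `network_graph`. The attribute `"parse_report"` holds a list with
#'   counts `input_lines`, `retained_edges`, `dropped_loops`,
#'   `collapsed_duplicates` and `blank_or_comment`, satisfying
#'   `input_lines = retained_edges + dropped_loops + collapsed_duplicates +
#'   blank_or_comment`.
#' @seealso [read_edge_list()], [write_edge_list()]
#' @examples
#' net <- parse_edge_list("A B\nB C\nA A\nB A\n")
#' parse_report(net)
#' @export
parse_edge_list <- function(text, net_type = "generic") {
  if (length(text) == 1L && grepl("\n", text)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    lines <- as.character(text)
  }
  n_input <- length(lines)
  trimmed <- trimws(lines)
  skip <- trimmed == "" | startsWith(trimmed, "#")
  data_idx <- which(!skip)

  from <- character(0)
  to <- character(0)
  extra_cols <- FALSE
  for (i in data_idx) {
    tok <- strsplit(trimmed[i], "[[:space:]]+")[[1]]
    if (length(tok) < 2L) {
      stop(sprintf("parse error at line %d: expected at least 2 tokens, got %d",
                   i, length(tok)))
    }
    if (length(tok) > 2L) extra_cols <- TRUE
    from <- c(from, tok[1])
    to <- c(to, tok[2])
  }
  if (extra_cols) {
    warning("extra columns beyond the first two were ignored ",
            "(input is read as unweighted)")
  }

  loops <- from == to
  n_loops <- sum(loops)
  from <- from[!loops]
  to <- to[!loops]

  # duplicates counted on canonical unordered pairs
  key <- ifelse(from <= to, paste(from, to), paste(to, from))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  from <- from[!dup]
  to <- to[!dup]

  if (length(from) == 0L) {
    stop("empty network: no edges remain after loop/duplicate filtering")
  }
  net <- network_graph(cbind(from, to), net_type = net_type)
  attr(net, "parse_report") <- list(
    input_lines = n_input,
    retained_edges = length(from),
    dropped_loops = n_loops,
    collapsed_duplicates = n_dup,
    blank_or_comment = sum(skip)
  )
  net
}

#' Retrieve the parse report of a parsed network
#' @param net A `network_graph` returned by [parse_edge_list()] or
#'   [read_edge_list()].
#' @return The parse-report list, or `NULL` if the network was not parsed
#'   from text.
#' @export
parse_report <- function(net) attr(net, "parse_report")

#' Read an edge list from a file
#' @param path Path to a UTF-8 text file in the two-column edge-list format.
#' @param net_type Network type tag (metadata only).
#' @return A `network_graph`; see [parse_edge_list()].
#' @export
read_edge_list <- function(path, net_type = "generic") {
  parse_edge_list(readLines(path, warn = FALSE), net_type = net_type)
}

#' Serialize a network as a two-column edge list
#'
#' One line per edge, the two labels separated by a single space, rows in
#' deterministic (C-locale lexicographic) order. Isolated nodes cannot be
#' represented in an edge list; they are omitted here and should be reported
#' via [isolated_nodes()]. Consequently
#' `parse_edge_list(write_edge_list(net))` reproduces `net` up to isolated
#' nodes.
#'
#' @param net A `network_graph` with at least one edge.
#' @param path Optional file path; when given, the text is also written there.
#' @return The edge-list text as a single string (invisibly when `path` is
#'   given).
#' @export
write_edge_list <- function(net, path = NULL) {
  stopifnot(inherits(net, "network_graph"))
  txt <- paste0(paste(net$edges[, 1], net$edges[, 2]), collapse = "\n")
  if (nrow(net$edges)) txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' Export a network to GraphML
#'
#' Writes GraphML 1.0 with the connected-component id stored as a node
#' attribute `component`, so downstream viewers can reproduce the
#' component-based coloring.
#'
#' @param net A `network_graph`.
#' @param path Output file path.
#' @param component_ids Optional named integer vector (node label ->
#'   component id) covering all nodes; defaults to
#'   [connected_components()] of `net`.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path, component_ids = NULL) {
  stopifnot(inherits(net, "network_graph"))
  if (is.null(component_ids)) {
    component_ids <- connected_components(net)
  }
  if (!all(net$nodes %in% names(component_ids))) {
    stop("`component_ids` must cover every node of the network")
  }
  g <- as_igraph(net)
  g <- igraph::set_vertex_attr(g, "component",
                               value = as.integer(component_ids[net$nodes]))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
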