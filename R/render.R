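#' Deterministic component color map
#'
#' Assigns one fill color per connected component; nodes in the same
#' component always share the color, and the component numbering (largest
#' first, ties by smallest member label) makes the mapping reproducible.
#'
#' @param net A `network_graph`.
#' @return Named character vector (node label -> hex color).
#' @export
component_colors <- function(net) {
  cc <- connected_components(net)
  k <- if (length(cc)) max(cc) else 0L
  pal <- grDevices::hcl.colors(max(k, 1L), palette = "Dark 3")
  setNames(pal[cc], names(cc))
}

#' Render a network image with component-based coloring
#'
#' Draws the network with a Fruchterman–Reingold force-directed layout; node
#' fill color is determined solely by the connected component (identical
#' component, identical color), giving an immediate view of whether the
#' network is connected or fragmented. Layout coordinates are stochastic and
#' the image is illustrative: it carries no guarantee of bit-reproducibility,
#' unlike the CSV outputs.
#'
#' @param net A non-empty `network_graph`.
#' @param out_path Output image path; `.svg` (vector, needs cairo) or `.png`.
#' @param labels Draw node labels?
#' @param width,height Device size in inches.
#' @return `out_path`, invisibly.
#' @export
render_network <- function(net, out_path, labels = FALSE,
                           width = 7, height = 7) {
  stopifnot(inherits(net, "network_graph"), length(net$nodes) > 0L)
  g <- as_igraph(net)
  cols <- component_colors(net)
  lay <- igraph::layout_with_fr(g)
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "svg") {
    grDevices::svg(out_path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(out_path, width = width * 100, height = height * 100)
  } else {
    stop("unsupported image format: use .svg or .png")
  }
  on.exit(grDevices::dev.off())
  igraph::plot.igraph(
    g, layout = lay,
    vertex.color = cols[net$nodes],
    vertex.size = if (length(net$nodes) > 60) 4 else 12,
    vertex.label = if (labels) net$nodes else NA,
    vertex.label.color = "black",
    vertex.frame.color = "grey30",
    edge.color = "grey60")
  invisible(out_path)
}
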