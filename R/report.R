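# CSV reporters with fixed, documented column orders. All scientific content
# of a run lives in these files; images are illustrative only.

#' Write a network summary as CSV
#'
#' Column order: `size, edge_count, density, avg_degree, avg_path_length,
#' diameter, n_components, component_sizes` (sizes joined by `;`).
#'
#' @param summary A `network_summary` (or a `perturbation_result`, in which
#'   case before/after/delta rows are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  row_of <- function(s, label) {
    data.frame(which = label, size = s$size, edge_count = s$edge_count,
               density = s$density, avg_degree = s$avg_degree,
               avg_path_length = s$avg_path_length, diameter = s$diameter,
               n_components = s$n_components,
               component_sizes = paste(s$component_sizes, collapse = ";"),
               stringsAsFactors = FALSE)
  }
  if (inherits(summary, "perturbation_result")) {
    d <- summary$delta
    delta_row <- data.frame(which = "delta", size = d$size,
                            edge_count = d$edge_count, density = d$density,
                            avg_degree = d$avg_degree,
                            avg_path_length = d$avg_path_length,
                            diameter = d$diameter,
                            n_components = d$n_components,
                            component_sizes = "", stringsAsFactors = FALSE)
    df <- rbind(row_of(summary$before, "before"),
                row_of(summary$after, "after"), delta_row)
  } else {
    stopifnot(inherits(summary, "network_summary"))
    df <- row_of(summary, "network")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-node metrics as CSV
#'
#' Column order: `node, degree, betweenness, closeness, eigenvector,
#' component_id`.
#'
#' @param metrics Output of [node_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  cols <- c("node", "degree", "betweenness", "closeness", "eigenvector",
            "component_id")
  utils::write.csv(metrics[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a co-extinction curve as CSV
#'
#' Column order: `step, primary, n_secondaries, cumulative_secondaries,
#' remaining_size, pct_removed`, then any recorded summary metrics in the
#' order `density, avg_degree, avg_path_length, n_components`. For random
#' cascades the realized removal permutation is recorded in `#`-prefixed
#' header lines for auditability.
#'
#' @param curve A `coextinction_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "coextinction_curve"))
  rec <- curve$records
  base_cols <- c(step = "step", primary = "primary",
                 n_secondaries = "n_secondaries",
                 cumulative_secondaries = "cumulative_secondaries",
                 remaining_size = "remaining_size",
                 pct_removed = "pct_primaries_removed")
  metric_cols <- intersect(c("density", "avg_degree", "avg_path_length",
                             "n_components"), names(rec))
  df <- rec[, c(unname(base_cols), metric_cols)]
  names(df) <- c(names(base_cols), metric_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# order=%s ranking=%s replicate=%d original_size=%d collapse_step=%s",
                     curve$spec$order, curve$spec$ranking, curve$replicate,
                     curve$original_size,
                     ifelse(is.na(curve$collapse_step), "none",
                            curve$collapse_step)), con)
  if (!is.null(curve$permutation)) {
    writeLines(paste0("# permutation=", paste(curve$permutation, collapse = ";")),
               con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a curve comparison table as CSV
#'
#' Column order: `curve, replicate, step, pct_removed, value`; envelope rows
#' of replicate sets are appended with curve name suffixed `:mean`, `:min`,
#' `:max` and `replicate = 0`.
#'
#' @param comparison Output of [compare_curves()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  df <- data.frame(curve = comparison$curve, replicate = comparison$replicate,
                   step = comparison$step,
                   pct_removed = comparison$pct_primaries_removed,
                   value = comparison$value, stringsAsFactors = FALSE)
  env <- attr(comparison, "envelope")
  for (nm in names(env)) {
    e <- env[[nm]]
    for (stat in c("mean", "min", "max")) {
      df <- rbind(df, data.frame(curve = paste0(nm, ":", stat), replicate = 0L,
                                 step = e$step,
                                 pct_removed = e$pct_primaries_removed,
                                 value = e[[stat]], stringsAsFactors = FALSE))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Machine-readable record of a run: command, input, options, seed and
#' software versions, written as JSON.
#'
#' @param path Output path.
#' @param command Subcommand name.
#' @param options Named list of options as invoked.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, options) {
  manifest <- list(
    command = command,
    options = options,
    package = "netcascade",
    package_version = as.character(utils::packageVersion("netcascade")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    igraph_version = as.character(utils::packageVersion("igraph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
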