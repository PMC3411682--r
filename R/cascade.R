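#' Specify a sequential perturbation cascade
#'
#' @param order Removal order: `"descending"` (generalists / most-connected
#'   first), `"ascending"` (specialists first) or `"random"`.
#' @param ranking `"static"` ranks nodes once on the input network and then
#'   removes them in that fixed order; `"dynamic"` re-ranks the remaining
#'   network after every removal. For `order = "random"`, static shuffles the
#'   full node list once while dynamic draws each victim uniformly from the
#'   currently remaining nodes.
#' @param seed Integer seed, required when `order = "random"`. Replicate `r`
#'   uses `seed + (r - 1)`.
#' @param replicates Number of random replicates (>= 1; only meaningful for
#'   `order = "random"`).
#' @param recorded_metrics Which per-step summary fields of the remaining
#'   functional subnetwork to record, a subset of `"density"`,
#'   `"avg_degree"`, `"avg_path_length"`, `"n_components"`. Size, per-step and
#'   cumulative secondary counts are always recorded. Distance-based metrics
#'   dominate the cost on large networks.
#' @param max_steps Optional cap on the number of primary removals; a
#'   truncated run can end without collapse.
#' @return A list of class `cascade_spec`.
#' @export
cascade_spec <- function(order = c("descending", "ascending", "random"),
                         ranking = c("static", "dynamic"),
                         seed = NULL, replicates = 1L,
                         recorded_metrics = c("density", "avg_degree",
                                              "avg_path_length",
                                              "n_components"),
                         max_steps = Inf) {
  order <- match.arg(order)
  ranking <- match.arg(ranking)
  if (length(recorded_metrics)) {
    recorded_metrics <- match.arg(recorded_metrics, several.ok = TRUE)
  }
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L, max_steps >= 1)
  if (order == "random" && is.null(seed)) {
    stop("`seed` is required for random cascades")
  }
  if (order != "random" && replicates > 1L) {
    stop("replicates > 1 only apply to random cascades")
  }
  structure(list(order = order, ranking = ranking, seed = seed,
                 replicates = replicates, recorded_metrics = recorded_metrics,
                 max_steps = max_steps),
            class = "cascade_spec")
}

#' Degree ranking of nodes for a targeted cascade
#'
#' Static ranking: the full permutation of nodes sorted by their degree in
#' `net` (descending or ascending), ties broken lexicographically by label.
#' Dynamic ranking: a policy function that, given the current remaining
#' network, returns the extreme-degree node under the same tie-break.
#'
#' @param net A `network_graph`.
#' @param order `"descending"` or `"ascending"`.
#' @param ranking `"static"` or `"dynamic"`.
#' @return A character vector (static) or a `function(net) -> label`
#'   (dynamic).
#' @export
degree_ranking <- function(net, order = c("descending", "ascending"),
                           ranking = c("static", "dynamic")) {
  order <- match.arg(order)
  ranking <- match.arg(ranking)
  pick <- function(current) {
    deg <- node_degrees(current)
    # names(deg) follow the C-locale node order, so which.max/min break ties
    # toward the smallest label
    if (order == "descending") names(deg)[which.max(deg)]
    else names(deg)[which.min(deg)]
  }
  if (ranking == "dynamic") return(pick)
  stopifnot(length(net$nodes) > 0L)
  deg <- node_degrees(net)
  sgn <- if (order == "descending") -1 else 1
  net$nodes[order(sgn * deg, seq_along(deg))]
}

#' Run a sequential perturbation cascade
#'
#' Removes one primary node per step (via the [remove_nodes()] semantics:
#' secondary extinctions leave the functional subnetwork together with the
#' primary), records the remaining topology after every step, and stops at
#' complete collapse, at `max_steps`, or when the ranking is exhausted.
#' Ranked nodes that already vanished as secondary extinctions are skipped
#' and never consume a step; the percentage axis counts realized primary
#' removals over the original node count.
#'
#' @param net A non-empty `network_graph` without isolated nodes.
#' @param spec A [cascade_spec()].
#' @return A `coextinction_curve` (see [curve_records()]), or a list of class
#'   `coextinction_curves` when `spec$replicates > 1`. Random curves carry
#'   the realized removal permutation in their `permutation` field for
#'   auditability.
#' @examples
#' run_cascade(make_star(5), cascade_spec("descending"))
#' @export
run_cascade <- function(net, spec) {
  stopifnot(inherits(net, "network_graph"), inherits(spec, "cascade_spec"))
  check_functional(net)
  if (length(net$nodes) == 0L) stop("cannot cascade an empty network")
  if (spec$order == "random" && spec$replicates > 1L) {
    curves <- lapply(seq_len(spec$replicates), function(r) {
      rspec <- spec
      rspec$seed <- spec$seed + (r - 1L)
      rspec$replicates <- 1L
      run_cascade_single(net, rspec, replicate = r)
    })
    return(structure(curves, class = "coextinction_curves"))
  }
  run_cascade_single(net, spec, replicate = 1L)
}

run_cascade_single <- function(net, spec, replicate = 1L) {
  original <- net$nodes
  n0 <- length(original)
  nodes <- original
  edges <- net$edges

  static_order <- NULL
  dynamic_pick <- NULL
  permutation <- NULL
  if (spec$order == "random") {
    if (spec$ranking == "static") {
      permutation <- with_seed(spec$seed, sample(original))
      static_order <- permutation
    } else {
      rng <- new.env()
      with_seed_env_init(rng, spec$seed)
      dynamic_pick <- function(current_nodes) {
        with_rng_env(rng, current_nodes[sample.int(length(current_nodes), 1L)])
      }
    }
  } else if (spec$ranking == "static") {
    static_order <- degree_ranking(net, spec$order, "static")
  } else {
    policy <- degree_ranking(net, spec$order, "dynamic")
  }

  records <- list()
  step <- 0L
  cum_sec <- 0L
  collapse_step <- NA_integer_
  queue_pos <- 0L

  while (length(nodes) > 0L && step < spec$max_steps) {
    if (!is.null(static_order)) {
      repeat {
        queue_pos <- queue_pos + 1L
        if (queue_pos > length(static_order)) break
        if (static_order[queue_pos] %in% nodes) break
      }
      if (queue_pos > length(static_order)) break
      target <- static_order[queue_pos]
    } else if (!is.null(dynamic_pick)) {
      target <- dynamic_pick(nodes)
    } else {
      current <- network_graph(edges, nodes = nodes, net_type = net$net_type)
      target <- policy(current)
    }

    step <- step + 1L
    survivors <- nodes[nodes != target]
    if (nrow(edges)) {
      keep <- edges[, 1] != target & edges[, 2] != target
      edges <- edges[keep, , drop = FALSE]
    }
    deg <- tabulate(match(c(edges), survivors), nbins = length(survivors))
    sec <- sort_c(survivors[deg == 0L])
    nodes <- survivors[deg > 0L]
    cum_sec <- cum_sec + length(sec)

    rec <- list(step = step, primary = target,
                n_secondaries = length(sec),
                secondaries = paste(sec, collapse = ";"),
                cumulative_secondaries = cum_sec,
                remaining_size = length(nodes),
                pct_primaries_removed = 100 * step / n0)
    if (length(spec$recorded_metrics)) {
      remaining <- network_graph(edges, nodes = nodes, net_type = net$net_type)
      sm <- summarize_network(remaining, metrics = sub("^n_components$",
                                                       "components",
                                                       spec$recorded_metrics))
      for (f in spec$recorded_metrics) rec[[f]] <- as.numeric(sm[[f]])
    }
    records[[step]] <- rec

    if (length(nodes) == 0L) {
      collapse_step <- step
      break
    }
  }

  df <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  structure(list(spec = spec, replicate = replicate,
                 original_size = n0,
                 records = df,
                 collapse_step = collapse_step,
                 permutation = permutation),
            class = "coextinction_curve")
}

# RNG stream confined to an environment so dynamic random picks are
# reproducible without touching the caller's RNG state
with_seed_env_init <- function(env, seed) {
  env$state <- with_seed(seed, get(".Random.seed", envir = globalenv()))
  invisible(env)
}

with_rng_env <- function(env, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", env$state, envir = globalenv())
  on.exit({
    env$state <- get(".Random.seed", envir = globalenv())
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  code
}

#' @export
print.coextinction_curve <- function(x, ...) {
  cat(sprintf("<coextinction_curve> %s/%s cascade on %d nodes: %d step(s), ",
              x$spec$order, x$spec$ranking, x$original_size,
              nrow(x$records)))
  if (is.na(x$collapse_step)) cat("no collapse\n")
  else cat(sprintf("complete collapse at step %d\n", x$collapse_step))
  invisible(x)
}

#' @export
print.coextinction_curves <- function(x, ...) {
  cat(sprintf("<coextinction_curves> %d random replicate(s)\n", length(x)))
  for (cv in x) print(cv)
  invisible(x)
}

#' Per-step records of a co-extinction curve
#' @param curve A `coextinction_curve`.
#' @return The records data.frame: one row per primary removal with columns
#'   `step`, `primary`, `n_secondaries`, `secondaries`,
#'   `cumulative_secondaries`, `remaining_size`, `pct_primaries_removed` and
#'   the recorded summary metrics.
#' @export
curve_records <- function(curve) {
  stopifnot(inherits(curve, "coextinction_curve"))
  curve$records
}

#' Leave-one-out perturbation scan
#'
#' Takes every node out of the network in turn (and puts it back): each row
#' reports the topology of the functional subnetwork after removing that one
#' node, together with the secondary extinctions the removal triggers.
#' Removals never accumulate; every row starts from the intact network, so
#' rows are comparable across nodes and across networks.
#'
#' @param net A non-empty `network_graph` without isolated nodes.
#' @return A data.frame with one row per node (label order): `node`,
#'   `n_secondaries`, `size`, `edge_count`, `density`, `avg_degree`,
#'   `avg_path_length`, `n_components`.
#' @export
leave_one_out_scan <- function(net) {
  stopifnot(inherits(net, "network_graph"))
  check_functional(net)
  rows <- lapply(net$nodes, function(v) {
    res <- remove_nodes(net, v)
    a <- res$after
    data.frame(node = v, n_secondaries = length(res$secondaries),
               size = a$size, edge_count = a$edge_count,
               density = a$density, avg_degree = a$avg_degree,
               avg_path_length = a$avg_path_length,
               n_components = a$n_components,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Align co-extinction curves for comparison
#'
#' Builds a long-format table of one recorded metric across several curves
#' from the same original network, keyed by the percentage of primary
#' removals, so opposing extinction sequences (e.g. generalists-first vs
#' specialists-first) can be compared directly. Replicate sets
#' (`coextinction_curves`) additionally contribute a per-step mean and
#' min/max envelope.
#'
#' @param curves Named list whose elements are `coextinction_curve` or
#'   `coextinction_curves` objects, all derived from networks of the same
#'   original size.
#' @param metric Column of the curve records to compare (e.g.
#'   `"remaining_size"`, `"n_secondaries"`, `"cumulative_secondaries"`, or
#'   any recorded summary metric).
#' @return A data.frame with columns `curve`, `replicate`, `step`,
#'   `pct_primaries_removed`, `value`. The attribute `"envelope"` holds, for
#'   each replicate set, a data.frame `step`, `pct_primaries_removed`,
#'   `mean`, `min`, `max`.
#' @export
compare_curves <- function(curves, metric = "remaining_size") {
  stopifnot(is.list(curves), length(curves) >= 1)
  if (is.null(names(curves)) || any(names(curves) == "")) {
    names(curves) <- paste0("curve", seq_along(curves))
  }
  flat <- list()
  sizes <- integer(0)
  envelopes <- list()
  for (nm in names(curves)) {
    cv <- curves[[nm]]
    if (inherits(cv, "coextinction_curve")) cv <- list(cv)
    else if (!inherits(cv, "coextinction_curves") && !is.list(cv)) {
      stop("each element must be a coextinction_curve or a replicate set")
    }
    reps <- lapply(seq_along(cv), function(r) {
      rec <- curve_records(cv[[r]])
      if (!metric %in% names(rec)) {
        stop(sprintf("metric '%s' was not recorded for curve '%s'", metric, nm))
      }
      data.frame(curve = nm, replicate = r, step = rec$step,
                 pct_primaries_removed = rec$pct_primaries_removed,
                 value = rec[[metric]], stringsAsFactors = FALSE)
    })
    sizes <- c(sizes, vapply(cv, function(x) x$original_size, integer(1)))
    flat[[nm]] <- do.call(rbind, reps)
    if (length(cv) > 1L) {
      tab <- do.call(rbind, reps)
      agg <- lapply(split(tab, tab$step), function(d) {
        data.frame(step = d$step[1],
                   pct_primaries_removed = d$pct_primaries_removed[1],
                   mean = mean(d$value), min = min(d$value),
                   max = max(d$value))
      })
      env_df <- do.call(rbind, agg)
      rownames(env_df) <- NULL
      envelopes[[nm]] <- env_df[order(env_df$step), , drop = FALSE]
    }
  }
  if (length(unique(sizes)) > 1L) {
    stop("curves derive from networks of different original sizes")
  }
  out <- do.call(rbind, flat)
  rownames(out) <- NULL
  attr(out, "envelope") <- envelopes
  out
}
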