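pad_labels <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(2L, nchar(as.character(n))), seq_len(n))
}

# run code under a temporarily-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Star network K1,n
#'
#' One hub (`"hub"`) connected to `n` leaves (`"leaf01"`, ...). The canonical
#' fragile topology: removing the hub isolates every leaf at once.
#'
#' @param n Number of leaves (>= 1).
#' @param net_type Metadata tag.
#' @return A `network_graph` with `n + 1` nodes and `n` edges.
#' @export
make_star <- function(n, net_type = "generic") {
  stopifnot(n >= 1)
  leaves <- pad_labels("leaf", n)
  network_graph(cbind("hub", leaves), net_type = net_type)
}

#' Path network on n nodes
#' @param n Number of nodes (>= 2); nodes `"v01" - ...` connected in a line.
#' @param net_type Metadata tag.
#' @return A `network_graph` with `n - 1` edges.
#' @export
make_path <- function(n, net_type = "generic") {
  stopifnot(n >= 2)
  v <- pad_labels("v", n)
  network_graph(cbind(v[-n], v[-1]), net_type = net_type)
}

#' Complete network K_n
#' @param n Number of nodes (>= 2).
#' @param net_type Metadata tag.
#' @return A `network_graph` with `n(n-1)/2` edges.
#' @export
make_complete <- function(n, net_type = "generic") {
  stopifnot(n >= 2)
  v <- pad_labels("v", n)
  idx <- utils::combn(n, 2)
  network_graph(cbind(v[idx[1, ]], v[idx[2, ]]), net_type = net_type)
}

#' Erdős–Rényi random network G(n, p)
#'
#' Each of the `n(n-1)/2` node pairs receives an edge independently with
#' probability `p`. Nodes that end up isolated are dropped so the result is
#' representable as an edge list. Deterministic for a given seed.
#'
#' @param n Number of candidate nodes.
#' @param p Edge probability in (0, 1].
#' @param seed Integer RNG seed.
#' @param net_type Metadata tag.
#' @return A `network_graph`.
#' @export
make_erdos_renyi <- function(n, p, seed, net_type = "generic") {
  stopifnot(n >= 2, p > 0, p <= 1)
  v <- pad_labels("v", n)
  idx <- utils::combn(n, 2)
  keep <- with_seed(seed, stats::runif(ncol(idx)) < p)
  if (!any(keep)) {
    stop("empty network: no edges drawn; increase `p` or change the seed")
  }
  network_graph(cbind(v[idx[1, keep]], v[idx[2, keep]]), net_type = net_type)
}

#' Barabási–Albert preferential-attachment network
#'
#' Starts from an (m+1)-clique and attaches each subsequent node to `m`
#' distinct existing nodes chosen with probability proportional to their
#' current degree. Produces the right-skewed (scale-free-like) degree
#' distribution under which hub-first attacks are maximally damaging. The
#' total edge count is exactly `choose(m + 1, 2) + m * (n - m - 1)`.
#'
#' @param n Total number of nodes (> m + 1).
#' @param m Edges added per arriving node (>= 1).
#' @param seed Integer RNG seed.
#' @param net_type Metadata tag.
#' @return A `network_graph` with `n` nodes.
#' @export
make_barabasi_albert <- function(n, m, seed, net_type = "generic") {
  stopifnot(m >= 1, n > m + 1)
  v <- pad_labels("v", n)
  n0 <- m + 1L
  idx <- utils::combn(n0, 2)
  from <- idx[1, ]
  to <- idx[2, ]
  deg <- integer(n)
  deg[seq_len(n0)] <- m
  with_seed(seed, {
    for (new in (n0 + 1L):n) {
      existing <- seq_len(new - 1L)
      targets <- sample(existing, m, prob = deg[existing])
      from <- c(from, rep.int(new, m))
      to <- c(to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[new] <- m
    }
  })
  network_graph(cbind(v[from], v[to]), net_type = net_type)
}

#' Bipartite interaction web
#'
#' A two-class web (e.g. plants x pollinators): edges run only between the
#' `n_rows` row nodes (`"r01"`, ...) and `n_cols` column nodes (`"c01"`, ...).
#' Each cell of the interaction matrix is filled independently with
#' probability `connectance`; every row and column is then guaranteed at
#' least one interaction so no species starts extinct.
#'
#' @param n_rows,n_cols Class sizes (>= 1).
#' @param connectance Fill probability in (0, 1].
#' @param seed Integer RNG seed.
#' @param net_type Metadata tag, defaults to `"ecological_bipartite"`.
#' @return A `network_graph`.
#' @export
make_bipartite_web <- function(n_rows, n_cols, connectance, seed,
                               net_type = "ecological_bipartite") {
  stopifnot(n_rows >= 1, n_cols >= 1, connectance > 0, connectance <= 1)
  rows <- pad_labels("r", n_rows)
  cols <- pad_labels("c", n_cols)
  with_seed(seed, {
    mat <- matrix(stats::runif(n_rows * n_cols) < connectance, n_rows, n_cols)
    for (i in which(rowSums(mat) == 0)) mat[i, sample.int(n_cols, 1)] <- TRUE
    for (j in which(colSums(mat) == 0)) mat[sample.int(n_rows, 1), j] <- TRUE
  })
  hit <- which(mat, arr.ind = TRUE)
  network_graph(cbind(rows[hit[, 1]], cols[hit[, 2]]), net_type = net_type)
}

#' Two clique modules joined by a low-degree connector
#'
#' Two disjoint k-cliques (`"a.."` and `"b.."`) joined only through a
#' `"bridge"` node with one edge into each clique. The bridge has degree 2 —
#' far below every clique member — yet removing it always fragments the
#' network in two: the classic sparsely-connected-connector scenario in which
#' degree alone understates a node's structural importance.
#'
#' @param k Clique size (>= 2).
#' @param net_type Metadata tag.
#' @return A `network_graph` with `2k + 1` nodes.
#' @export
make_two_modules_bridge <- function(k, net_type = "generic") {
  stopifnot(k >= 2)
  a <- pad_labels("a", k)
  b <- pad_labels("b", k)
  idx <- utils::combn(k, 2)
  edges <- rbind(cbind(a[idx[1, ]], a[idx[2, ]]),
                 cbind(b[idx[1, ]], b[idx[2, ]]),
                 c("bridge", a[1]),
                 c("bridge", b[1]))
  network_graph(edges, net_type = net_type)
}

#' Generate a fixture network from a declarative spec
#'
#' Dispatch surface over the deterministic generators; the same spec always
#' yields the identical network.
#'
#' @param kind One of `"star"`, `"path"`, `"complete"`, `"erdos_renyi"`,
#'   `"barabasi_albert"`, `"bipartite_web"`, `"two_modules_bridge"`.
#' @param params Named list of kind-specific parameters (`n`, `m`, `p`,
#'   `n_rows`, `n_cols`, `connectance`, `k`).
#' @param seed Integer seed, required for the random kinds.
#' @param net_type Metadata tag.
#' @return A `network_graph`.
#' @export
generate_fixture <- function(kind, params = list(), seed = NULL,
                             net_type = "generic") {
  kind <- match.arg(kind, c("star", "path", "complete", "erdos_renyi",
                            "barabasi_albert", "bipartite_web",
                            "two_modules_bridge"))
  needs_seed <- kind %in% c("erdos_renyi", "barabasi_albert", "bipartite_web")
  if (needs_seed && is.null(seed)) stop(sprintf("kind '%s' requires a seed", kind))
  switch(kind,
    star = make_star(params$n, net_type = net_type),
    path = make_path(params$n, net_type = net_type),
    complete = make_complete(params$n, net_type = net_type),
    erdos_renyi = make_erdos_renyi(params$n, params$p, seed, net_type = net_type),
    barabasi_albert = make_barabasi_albert(params$n, params$m, seed,
                                           net_type = net_type),
    bipartite_web = make_bipartite_web(params$n_rows, params$n_cols,
                                       params$connectance, seed,
                                       net_type = net_type),
    two_modules_bridge = make_two_modules_bridge(params$k, net_type = net_type)
  )
}
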