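# Independent brute-force oracles for distances, shortest-path counts,
# centralities and components. Deliberately different algorithms from the
# package: Floyd-Warshall + minimal-walk counting via adjacency powers,
# DFS path enumeration, and union-find.

oracle_adjacency <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges[, 1], net$nodes)
    j <- match(net$edges[, 2], net$nodes)
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  a
}

# All-pairs distances by Floyd-Warshall
oracle_distances <- function(net) {
  a <- oracle_adjacency(net)
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# Number of shortest i-j paths = number of minimal-length walks,
# read off the adjacency-power matrices A^1 .. A^(n-1).
oracle_path_counts <- function(net) {
  a <- oracle_adjacency(net)
  n <- nrow(a)
  d <- oracle_distances(net)
  pows <- vector("list", max(1, n - 1))
  pows[[1]] <- a
  if (n > 2) for (k in 2:(n - 1)) pows[[k]] <- pows[[k - 1]] %*% a
  sigma <- matrix(0, n, n, dimnames = dimnames(a))
  diag(sigma) <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(d[i, j])) {
      sigma[i, j] <- pows[[d[i, j]]][i, j]
    }
  }
  sigma
}

# Unnormalized betweenness, each unordered pair counted once, endpoints
# excluded; sigma(i,v,j) = sigma(i,v) * sigma(v,j) when v lies on a geodesic.
oracle_betweenness <- function(net) {
  d <- oracle_distances(net)
  sigma <- oracle_path_counts(net)
  n <- nrow(d)
  b <- setNames(numeric(n), net$nodes)
  if (n < 3) return(b)
  for (v in seq_len(n)) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (i == v || j == v || !is.finite(d[i, j])) next
        if (d[i, v] + d[v, j] == d[i, j]) {
          b[v] <- b[v] + sigma[i, v] * sigma[v, j] / sigma[i, j]
        }
      }
    }
  }
  b
}

# Closeness with the |V| substitution for unreachable pairs
oracle_closeness <- function(net) {
  d <- oracle_distances(net)
  n <- nrow(d)
  d[!is.finite(d)] <- n
  setNames((n - 1) / rowSums(d), net$nodes)
}

# Components by union-find
oracle_components <- function(net) {
  n <- length(net$nodes)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (nrow(net$edges)) {
    for (r in seq_len(nrow(net$edges))) {
      i <- find(match(net$edges[r, 1], net$nodes))
      j <- find(match(net$edges[r, 2], net$nodes))
      if (i != j) parent[j] <- i
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  setNames(match(roots, unique(roots)), net$nodes)
}

# Same-partition comparison (ids may differ, the grouping must not)
same_partition <- function(p1, p2) {
  stopifnot(identical(sort(names(p1)), sort(names(p2))))
  p2 <- p2[names(p1)]
  all(outer(p1, p1, "==") == outer(p2, p2, "=="))
}

# Exhaustive DFS enumeration of simple paths (second, slower oracle used on
# very small graphs only)
enumerate_betweenness <- function(net) {
  a <- oracle_adjacency(net)
  n <- nrow(a)
  all_paths <- function(i, j) {
    paths <- list()
    walk <- function(cur, visited) {
      if (cur == j) {
        paths[[length(paths) + 1L]] <<- visited
        return()
      }
      for (nb in which(a[cur, ] > 0)) {
        if (!nb %in% visited) walk(nb, c(visited, nb))
      }
    }
    walk(i, i)
    paths
  }
  b <- setNames(numeric(n), net$nodes)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- all_paths(i, j)
    if (!length(paths)) next
    lens <- lengths(paths)
    geo <- paths[lens == min(lens)]
    interior <- lapply(geo, function(p) p[-c(1, length(p))])
    for (v in seq_len(n)) {
      thru <- sum(vapply(interior, function(p) v %in% p, logical(1)))
      b[v] <- b[v] + thru / length(geo)
    }
  }
  b
}

# Random simple graph with at least one edge, as a network_graph
random_net <- function(n, p, seed) {
  labels <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  set.seed(seed)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
  network_graph(cbind(labels[pairs[1, keep]], labels[pairs[2, keep]]),
                nodes = labels)
}

# Convert an igraph graph (e.g. from graph_from_atlas) to a network_graph,
# keeping isolated vertices
net_from_igraph <- function(g) {
  n <- igraph::vcount(g)
  labels <- sprintf("n%02d", seq_len(n))
  e <- igraph::as_edgelist(g, names = FALSE)
  network_graph(cbind(labels[e[, 1]], labels[e[, 2]]), nodes = labels)
}

# Independent step-by-step cascade replay: removes the given node each step
# from a plain adjacency list, drops newly isolated survivors, and records
# sizes. Used to cross-check run_cascade traces.
replay_cascade <- function(net, pick_next) {
  nodes <- net$nodes
  edges <- net$edges
  trace <- list()
  step <- 0L
  cum <- 0L
  repeat {
    if (!length(nodes)) break
    target <- pick_next(nodes, edges)
    if (is.null(target)) break
    step <- step + 1L
    nodes <- setdiff(nodes, target)
    if (nrow(edges)) {
      edges <- edges[edges[, 1] != target & edges[, 2] != target, , drop = FALSE]
    }
    linked <- unique(c(edges))
    sec <- setdiff(nodes, linked)
    nodes <- intersect(nodes, linked)
    cum <- cum + length(sec)
    trace[[step]] <- list(step = step, primary = target,
                          n_secondaries = length(sec),
                          cumulative_secondaries = cum,
                          remaining_size = length(nodes))
  }
  trace
}
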