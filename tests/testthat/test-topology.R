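triangle <- parse_edge_list("A B\nB C\nC A\n")

test_that("connected components match a union-find oracle and order by size", {
  cc <- connected_components(triangle)
  expect_equal(unname(cc), rep(1L, 3))

  two <- parse_edge_list("A B\nC D\n")
  cc2 <- connected_components(two)
  expect_equal(max(cc2), 2L)
  expect_equal(cc2[["A"]], cc2[["B"]])
  expect_equal(cc2[["C"]], cc2[["D"]])
  # equal sizes: tie broken by smallest member, so {A,B} gets id 1
  expect_equal(cc2[["A"]], 1L)

  # sizes decide ids before labels do
  mixed <- parse_edge_list("X Y\nA B\nB C\n")
  cc3 <- connected_components(mixed)
  expect_equal(cc3[["A"]], 1L)  # the size-3 component outranks {X,Y}
  expect_equal(cc3[["X"]], 2L)

  for (seed in 1:10) {
    er <- random_net(40, 0.05, seed)
    expect_true(same_partition(connected_components(er),
                               oracle_components(er)))
  }
})

test_that("shortest-path distances: BFS equals Floyd-Warshall, Inf marks unreachable", {
  pth <- parse_edge_list("A B\nB C\n")
  expect_equal(shortest_path_lengths(pth, "A"), c(A = 0, B = 1, C = 2))
  expect_error(shortest_path_lengths(pth, "Z"), "unknown source")

  disj <- network_graph(rbind(c("A", "B")), nodes = c("A", "B", "C"))
  d <- shortest_path_lengths(disj, "A")
  expect_true(is.infinite(d[["C"]]))

  for (seed in 1:5) {
    net <- random_net(30, 0.08, seed)
    fw <- oracle_distances(net)
    for (src in net$nodes[c(1, 15, 30)]) {
      expect_equal(shortest_path_lengths(net, src), fw[src, ])
    }
  }
})

test_that("summary indicators satisfy the defining identities", {
  s <- summarize_network(triangle)
  expect_equal(s$size, 3L)
  expect_equal(s$density, 1.0)
  expect_equal(s$avg_degree, 2.0)
  expect_equal(s$avg_path_length, 1.0)
  expect_equal(s$n_components, 1L)

  star <- make_star(4)  # K1,4: 20 ordered pairs, 8 at d=1, 12 at d=2
  ss <- summarize_network(star)
  expect_equal(ss$density, 0.4)
  expect_equal(ss$avg_degree, 1.6)
  expect_equal(ss$avg_path_length, 1.6)

  for (seed in 1:5) {
    net <- random_net(25, 0.15, seed)
    sm <- summarize_network(net)
    n <- sm$size
    expect_equal(sm$density, 2 * sm$edge_count / (n * (n - 1)))
    expect_equal(sm$avg_degree, 2 * sm$edge_count / n)
    expect_equal(sm$density, sm$avg_degree / (n - 1))
    expect_equal(sum(sm$component_sizes), n)
    expect_equal(sm$n_components == 1L,
                 igraph::is_connected(as_igraph(net)))
  }
})

test_that("average path length averages over connected ordered pairs only", {
  # {A-B} plus {C-D}: connected pairs all at distance 1
  two <- parse_edge_list("A B\nC D\n")
  expect_equal(summarize_network(two)$avg_path_length, 1.0)
  # no |V| substitution leaks into the path-length average
  pth <- parse_edge_list("A B\nB C\nX Y\n")
  expect_equal(summarize_network(pth)$avg_path_length, (4 * 1 + 2 * 2 + 2) / 8)
})

test_that("betweenness matches both oracles on canonical and random graphs", {
  pth <- parse_edge_list("A B\nB C\n")
  expect_equal(betweenness_centrality(pth), c(A = 0, B = 1, C = 0))

  for (n in c(3, 5, 8)) {
    star <- make_star(n)
    b <- betweenness_centrality(star)
    expect_equal(b[["hub"]], n * (n - 1) / 2)
    expect_true(all(b[names(b) != "hub"] == 0))
  }

  k4 <- make_complete(4)
  expect_true(all(betweenness_centrality(k4) == 0))

  for (seed in 1:10) {
    net <- random_net(8, 0.35, seed)
    expect_equal(betweenness_centrality(net), oracle_betweenness(net),
                 tolerance = 1e-12)
    expect_equal(betweenness_centrality(net), enumerate_betweenness(net),
                 tolerance = 1e-12)
  }
})

test_that("closeness applies the |V| substitution for unreachable pairs", {
  star <- make_star(3)
  expect_equal(closeness_centrality(star)[["hub"]], 1.0)

  # {A-B} plus isolate C, |V| = 3: sum for A is 1 + 3
  net <- network_graph(rbind(c("A", "B")), nodes = c("A", "B", "C"))
  clo <- closeness_centrality(net)
  expect_equal(clo[["A"]], 2 / (1 + 3))
  expect_equal(clo[["C"]], 1 / 3)  # isolated node: 1/|V|

  pth <- parse_edge_list("A B\nB C\n")
  clo2 <- closeness_centrality(pth)
  expect_equal(clo2[["B"]], 1.0)
  expect_equal(clo2[["A"]], 2 / 3)

  expect_error(closeness_centrality(network_graph(NULL, nodes = "A")),
               "fewer than 2")

  for (seed in 1:10) {
    net <- random_net(8, 0.25, seed)
    expect_equal(closeness_centrality(net), oracle_closeness(net))
  }
})

test_that("eigenvector centrality matches closed forms and the eigen oracle", {
  k3 <- make_complete(3)
  expect_equal(unname(eigenvector_centrality(k3)), rep(1, 3),
               tolerance = 1e-8, ignore_attr = TRUE)

  star <- make_star(3)
  e <- eigenvector_centrality(star)
  expect_equal(e[["hub"]], 1.0)
  expect_equal(unname(e[c("leaf01", "leaf02", "leaf03")]), rep(1 / sqrt(3), 3),
               tolerance = 1e-8)

  pth <- parse_edge_list("A B\nB C\n")
  ep <- eigenvector_centrality(pth)
  expect_equal(ep[["B"]], 1.0)
  expect_equal(ep[["A"]], 1 / sqrt(2), tolerance = 1e-8)

  # Rayleigh-quotient residual: A x ~ lambda x
  for (seed in 1:5) {
    net <- random_net(12, 0.3, seed)
    if (max(connected_components(net)) > 1) next
    x <- as.numeric(eigenvector_centrality(net, tol = 1e-12))
    a <- oracle_adjacency(net)
    lambda <- as.numeric(t(x) %*% a %*% x / sum(x^2))
    expect_lt(max(abs(a %*% x - lambda * x)), 1e-6 * lambda)
    # cross-check against R's dense eigendecomposition
    ev <- eigen(a, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / max(abs(ev))
    expect_equal(x, ev, tolerance = 1e-6, ignore_attr = TRUE)
  }

  expect_error(eigenvector_centrality(network_graph(NULL, nodes = c("A", "B"))),
               "at least one edge")
  expect_warning(eigenvector_centrality(parse_edge_list("A B\nC D\n")),
                 "disconnected")
  err <- tryCatch(eigenvector_centrality(make_star(5), max_iter = 2L),
                  error = identity)
  expect_s3_class(err, "eigenvector_no_convergence")
  expect_length(err$iterate, 6L)
})

test_that("node_metrics combines measures with deterministic rankings", {
  pth <- parse_edge_list("A B\nB C\n")
  m <- node_metrics(pth)
  expect_equal(names(m), c("node", "degree", "betweenness", "closeness",
                           "eigenvector", "component_id"))
  srt <- attr(m, "sorted")
  expect_equal(srt$degree$node, c("B", "A", "C"))

  star <- make_star(5)
  ms <- node_metrics(star)
  srt <- attr(ms, "sorted")
  for (measure in names(srt)) {
    expect_equal(srt[[measure]]$node[1], "hub")
    expect_false(is.unsorted(rev(srt[[measure]]$value)))
  }

  k4 <- make_complete(4)
  srt4 <- attr(node_metrics(k4), "sorted")
  for (measure in names(srt4)) {
    expect_equal(srt4[[measure]]$node, sort(k4$nodes))
  }
})

test_that("metrics are label-permutation equivariant", {
  net <- random_net(12, 0.25, seed = 42)
  perm_labels <- setNames(sprintf("z%02d", sample(12)), net$nodes)
  set.seed(42)  # the permutation itself fixed by the seed above
  relabeled <- network_graph(cbind(perm_labels[net$edges[, 1]],
                                   perm_labels[net$edges[, 2]]),
                             nodes = unname(perm_labels))
  for (fn in list(node_degrees, betweenness_centrality, closeness_centrality)) {
    orig <- fn(net)
    new <- fn(relabeled)
    expect_equal(unname(new[perm_labels[names(orig)]]), unname(orig),
                 tolerance = 1e-12)
  }
  expect_true(same_partition(
    setNames(connected_components(relabeled)[perm_labels[net$nodes]],
             net$nodes),
    connected_components(net)))
})
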