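test_that("degree matches direct incidence counts", {
  star <- named_graph(igraph::make_star(5, mode = "undirected"))
  d <- node_degree(star)
  expect_equal(unname(d[1]), 4)
  expect_true(all(d[-1] == 1))

  tri <- named_graph(igraph::make_ring(3))
  expect_true(all(node_degree(tri) == 2))

  g <- rand_gnp(20, 0.2, seed = 11)
  el <- igraph::as_edgelist(g)
  incidence <- table(factor(c(el[, 1], el[, 2]), levels = igraph::V(g)$name))
  expect_equal(as.integer(node_degree(g)), as.integer(incidence))
})

test_that("local clustering equals exhaustive neighbour-pair counting", {
  tri <- named_graph(igraph::make_ring(3))
  expect_true(all(node_clustering(tri) == 1))
  star <- named_graph(igraph::make_star(5, mode = "undirected"))
  expect_true(all(node_clustering(star) == 0))  # degree-1 leaves default to 0
  for (seed in 1:4) {
    g <- rand_gnp(12, 0.35, seed = seed)
    expect_equal(node_clustering(g), oracle_clustering(g), tolerance = 1e-12)
  }
})

test_that("betweenness equals exhaustive shortest-path enumeration", {
  path3 <- protein_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  b <- node_betweenness(path3)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))

  star <- named_graph(igraph::make_star(5, mode = "undirected"))
  expect_equal(unname(node_betweenness(star)[1]), choose(4, 2))

  for (seed in 1:12) {
    g <- rand_gnp(8, 0.35, seed = 100 + seed)
    expect_equal(node_betweenness(g), oracle_betweenness(g), tolerance = 1e-10)
  }
})

test_that("betweenness normalization is min-max with a degenerate-constant rule", {
  expect_equal(unname(normalize_betweenness(c(a = 0, b = 2, c = 4))),
               c(0, 0.5, 1))
  expect_equal(unname(normalize_betweenness(c(a = 3, b = 3))), c(0, 0))
  p4 <- named_graph(igraph::make_ring(4, circular = FALSE))
  expect_equal(unname(normalize_betweenness(node_betweenness(p4))),
               c(0, 1, 1, 0))
  expect_error(normalize_betweenness(numeric(0)), "empty")
})

test_that("eigenvector centrality matches closed forms and dense eigen-decomposition", {
  k4 <- named_graph(igraph::make_full_graph(4))
  res <- eigenvector_centrality(k4)
  expect_equal(unname(res$vector), rep(0.5, 4), tolerance = 1e-8)
  expect_equal(res$lambda, 3, tolerance = 1e-8)

  star <- named_graph(igraph::make_star(5, mode = "undirected"))
  res <- eigenvector_centrality(star)
  expect_equal(res$lambda, 2, tolerance = 1e-8)  # sqrt(k) for K_{1,4}
  expect_equal(unname(res$vector[1] / res$vector[2]), 2, tolerance = 1e-6)

  for (seed in 1:5) {
    g <- rand_gnp(15, 0.25, seed = 200 + seed, connected = TRUE)
    got <- eigenvector_centrality(g)
    want <- oracle_leading_eigen(g)
    expect_equal(unname(got$vector), unname(want$vector), tolerance = 1e-6)
    expect_equal(got$lambda, want$lambda, tolerance = 1e-6)
    expect_true(all(got$vector >= -1e-12))
    expect_equal(sum(got$vector^2), 1, tolerance = 1e-10)
    # residual contract ||Ax - lambda x||_inf < 10 * tolerance
    A <- adj_matrix(g)
    expect_lt(max(abs(A %*% got$vector - got$lambda * got$vector)), 10 * 1e-8)
  }
})

test_that("eigenvector centrality is invariant under node relabeling", {
  g <- rand_gnp(12, 0.3, seed = 31, connected = TRUE)
  perm <- withr::with_seed(1, sample(igraph::vcount(g)))
  g2 <- igraph::permute(g, perm)
  x1 <- eigenvector_centrality(g)$vector
  x2 <- eigenvector_centrality(g2)$vector
  expect_equal(x1[sort(names(x1))], x2[sort(names(x2))], tolerance = 1e-8)
})

test_that("power iteration reports non-convergence with the budget", {
  g <- rand_gnp(10, 0.3, seed = 5, connected = TRUE)
  expect_error(eigenvector_centrality(g, tolerance = 1e-14, max_iterations = 2),
               "2 iterations")
})

test_that("single-source distances are BFS hop counts", {
  path3 <- protein_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  expect_equal(shortest_path_lengths(path3, "A"),
               c(A = 0L, B = 1L, C = 2L))
  disc <- protein_network(data.frame(a = "A", b = "B"), nodes = "D")
  expect_false("D" %in% names(shortest_path_lengths(disc, "A")))
  expect_error(shortest_path_lengths(path3, "Z"), "Unknown source")

  grid <- named_graph(igraph::make_lattice(c(3, 3)))
  d <- shortest_path_lengths(grid, "n01")  # corner: Manhattan distances
  coords <- expand.grid(x = 0:2, y = 0:2)
  expect_equal(unname(d[sprintf("n%02d", 1:9)]), coords$x + coords$y)
})

test_that("eccentricity matches all-pairs BFS and diameter conventions", {
  p5 <- named_graph(igraph::make_ring(5, circular = FALSE))
  prof <- eccentricity_profile(p5)
  expect_equal(unname(prof$eccentricity), c(4, 3, 2, 3, 4))
  expect_equal(prof$diameter, 4)
  expect_true(all(eccentricity_profile(named_graph(igraph::make_full_graph(5)))$eccentricity == 1))
  expect_error(eccentricity_profile(protein_network(
    data.frame(a = c("A", "C"), b = c("B", "D")))), "connected")

  for (seed in 1:4) {
    g <- rand_gnp(12, 0.3, seed = 300 + seed, connected = TRUE)
    expect_equal(as.integer(eccentricity_profile(g)$eccentricity),
                 as.integer(oracle_eccentricity(g)))
  }
})

test_that("adjacent nodes differ by at most one in eccentricity", {
  for (seed in 1:4) {
    g <- rand_gnp(14, 0.25, seed = 400 + seed, connected = TRUE)
    ecc <- eccentricity_profile(g)$eccentricity
    el <- igraph::as_edgelist(g)
    expect_true(all(abs(ecc[el[, 1]] - ecc[el[, 2]]) <= 1))
  }
})

test_that("average distance applies the diameter substitution for unreachable pairs", {
  path3 <- protein_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  l <- average_distance_map(path3)
  expect_equal(unname(l[c("A", "B")]), c(1.5, 1))

  k4 <- named_graph(igraph::make_full_graph(4))
  expect_true(all(average_distance_map(k4) == 1))

  # two components {A-B}, {C}; supplied network diameter 4 substitutes
  disc <- protein_network(data.frame(a = "A", b = "B"), nodes = "C")
  l <- average_distance_map(disc, diameter = 4)
  expect_equal(unname(l["A"]), (1 + 4) / 2)
  expect_equal(unname(l["C"]), 4)

  # on connected graphs the substitution is inactive: plain mean distance
  for (seed in 1:4) {
    g <- rand_gnp(12, 0.3, seed = 500 + seed, connected = TRUE)
    expect_equal(average_distance_map(g), oracle_avg_distance(g),
                 tolerance = 1e-12)
  }
})

test_that("coreness equals the iterative-pruning definition", {
  k4p <- protein_network(data.frame(
    a = c("A", "A", "A", "B", "B", "C", "D"),
    b = c("B", "C", "D", "C", "D", "D", "E")))
  k <- node_coreness(k4p)
  expect_true(all(k[c("A", "B", "C", "D")] == 3))
  expect_equal(unname(k["E"]), 1L)

  tree <- named_graph(igraph::make_tree(10, children = 2, mode = "undirected"))
  expect_true(all(node_coreness(tree) == 1))

  for (seed in 1:3) {
    g <- rand_gnp(30, 0.12, seed = 600 + seed)
    expect_equal(as.integer(node_coreness(g)), as.integer(oracle_coreness(g)))
  }
})

test_that("coreness is bounded by degree and monotone under node removal", {
  for (seed in 1:3) {
    g <- rand_gnp(25, 0.15, seed = 700 + seed)
    k <- node_coreness(g)
    expect_true(all(k <= node_degree(g)))
    victim <- igraph::V(g)$name[1]
    k2 <- node_coreness(remove_nodes(g, victim))
    common <- names(k2)
    expect_true(all(k2[common] <= k[common]))
  }
})

test_that("k-core extraction keeps exactly the high-coreness nodes", {
  g <- rand_gnp(25, 0.2, seed = 801)
  k <- node_coreness(g)
  core3 <- k_core(g, 3)
  expect_setequal(igraph::V(core3)$name, names(k)[k >= 3])
  if (igraph::vcount(core3) > 0) {
    expect_true(all(igraph::degree(core3) >= 3))
  }
})

test_that("the topology profile assembles every index consistently", {
  fx <- tiny_fixture()
  part <- detect_communities(fx$network, seed = 1, min_report_size = 3)
  prof <- topology_profile(fx$network, labels = fx$labels, partition = part)
  expect_equal(nrow(prof), igraph::vcount(fx$network))
  expect_named(prof, c("protein", "class", "degree", "betweenness", "nb",
                       "eigenvector", "clustering", "eccentricity",
                       "avg_distance", "coreness", "community"))
  expect_equal(setNames(prof$betweenness, prof$protein)[sort(prof$protein)],
               oracle_betweenness(fx$network)[sort(prof$protein)],
               tolerance = 1e-10)
  expect_true(all(prof$nb >= 0 & prof$nb <= 1))
  expect_true(all(prof$coreness <= prof$degree))
  expect_true(all(prof$eccentricity <= attr(prof, "diameter")))
  expect_error(topology_profile(protein_network(
    data.frame(a = c("A", "C"), b = c("B", "D")))), "connected")
})
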