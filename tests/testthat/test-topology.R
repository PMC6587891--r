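complete_graph <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0; A
}

path_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

test_that("binarization keeps edges at or above the threshold", {
  set.seed(1)
  C <- pearson_network(matrix(rnorm(8 * 30), 8, 30))
  expect_equal(sum(binarize(C, 0)), 8 * 7)
  expect_equal(sum(binarize(C, max(abs(C)) + 0.01)), 0)
  A <- binarize(C, 0.2)
  cnt <- 0
  for (i in 1:8) for (j in 1:8) if (i != j && abs(C[i, j]) >= 0.2) cnt <- cnt + 1
  expect_equal(sum(A), cnt)
})

test_that("closed forms hold on the complete graph and the 4-path", {
  top <- suppressWarnings(compute_topology(complete_graph(5)))
  expect_equal(top$density, 1)
  expect_equal(top$clustering_coefficient, 1)
  expect_equal(top$characteristic_path_length, 1)
  expect_equal(top$global_efficiency, 1)
  expect_equal(top$local_efficiency, 1)
  expect_equal(top$average_degree, 4)
  expect_equal(top$closeness_centrality, 1)
  expect_equal(top$node_betweenness_centrality, 0)
  expect_equal(top$edge_betweenness_centrality, 1)
  expect_equal(top$radiality, 1)
  expect_true(is.nan(top$assortativity))  # regular graph

  p4 <- suppressWarnings(compute_topology(path_graph(4), t = 0.5))
  expect_equal(p4$characteristic_path_length, 10 / 6)
})

test_that("metrics agree with an independent graph-library oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    A <- random_connected_graph(n, runif(1, 0.35, 0.7))
    got <- suppressWarnings(compute_topology(A * 1, t = 0.5))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    dmat <- igraph::distances(g)
    expect_equal(got$average_degree, mean(igraph::degree(g)), tolerance = 1e-9)
    expect_equal(got$density, igraph::edge_density(g), tolerance = 1e-9)
    expect_equal(got$clustering_coefficient,
                 mean(igraph::transitivity(g, type = "local",
                                           isolates = "zero")),
                 tolerance = 1e-9)
    expect_equal(got$characteristic_path_length, igraph::mean_distance(g),
                 tolerance = 1e-9)
    expect_equal(got$global_efficiency, igraph::global_efficiency(g),
                 tolerance = 1e-9)
    expect_equal(got$local_efficiency,
                 igraph::average_local_efficiency(g), tolerance = 1e-9)
    expect_equal(got$closeness_centrality,
                 mean(igraph::closeness(g, normalized = TRUE)),
                 tolerance = 1e-9)
    expect_equal(got$node_betweenness_centrality,
                 mean(igraph::betweenness(g)), tolerance = 1e-9)
    expect_equal(got$edge_betweenness_centrality,
                 mean(igraph::edge_betweenness(g)), tolerance = 1e-9)
    expect_equal(got$assortativity, igraph::assortativity_degree(g),
                 tolerance = 1e-9)
    diam <- max(dmat)
    expect_equal(got$radiality,
                 mean(diam + 1 - rowSums(dmat) / (n - 1)), tolerance = 1e-9)
  }
})

test_that("disconnected graphs fall back to the largest component with a warning", {
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1   # component of 3
  A[4, 5] <- A[5, 4] <- 1                          # component of 2
  expect_warning(top <- compute_topology(A, t = 0.5), "largest component")
  expect_equal(top$characteristic_path_length, (1 + 1 + 2) * 2 / 6)
})

test_that("structural consistency is a reproducible fraction in [0, 1]", {
  set.seed(5)
  A <- random_connected_graph(20, 0.3) * 1
  s1 <- structural_consistency(A, p_h = 0.1, repeats = 20, seed = 9)
  s2 <- structural_consistency(A, p_h = 0.1, repeats = 20, seed = 9)
  expect_identical(s1, s2)
  expect_gte(s1, 0); expect_lte(s1, 1)
  # a clique is highly predictable: removed clique edges rank on top
  K <- complete_graph(12)
  expect_gt(structural_consistency(K, 0.1, 10, 1), 0.8)
})

test_that("the discrete power-law MLE recovers the exponent of sampled degrees", {
  set.seed(11)
  dmin <- 5
  support <- dmin:100000
  d <- sample(support, 1e4, replace = TRUE, prob = support^(-2.5))
  expect_lt(abs(powerlaw_alpha(d) - 2.5), 0.15)
  expect_true(is.nan(powerlaw_alpha(c(0, 0, 1))))
})

test_that("group topology tables compare groups per metric", {
  set.seed(13)
  mknet <- function(p) {
    A <- matrix(runif(100) < p, 10, 10)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    (A | t(A)) * 1
  }
  nets <- c(lapply(1:8, function(i) mknet(0.8)),
            lapply(1:8, function(i) mknet(0.3)))
  labels <- rep(c("control", "patient"), each = 8)
  tab <- group_topology_table(nets, labels, t = 0.5)
  expect_equal(nrow(tab), 14)
  dens <- tab[tab$metric == "density", ]
  expect_lt(dens$p_value, 0.01)
  expect_gt(dens$control_mean, dens$patient_mean)

  # identical groups: no metric should look significant
  same <- lapply(1:8, function(i) mknet(0.6))
  tab0 <- group_topology_table(c(same, same),
                               rep(c("control", "patient"), each = 8), 0.5)
  p <- tab0$p_value[is.finite(tab0$p_value)]
  expect_true(all(p > 0.99))
})
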