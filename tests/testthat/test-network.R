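test_that("pairwise squared Euclidean distances match hand and brute-force values", {
  X <- rbind(c(0, 0), c(3, 4), c(0, 1))
  D <- pairwise_sq_euclidean(X)
  expect_equal(D[1, 2], 25)
  expect_equal(D[2, 1], 25)
  expect_equal(diag(D), rep(0, 3))

  X2 <- rbind(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0))
  expect_equal(pairwise_sq_euclidean(X2)[1, 2], 0)

  set.seed(42)
  X3 <- matrix(rnorm(4 * 6), 4, 6)
  D3 <- pairwise_sq_euclidean(X3)
  O <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) O[i, j] <- sum((X3[i, ] - X3[j, ])^2)
  expect_lt(max(abs(D3 - O)), 1e-10)
  expect_true(all(D3 >= 0))
})

test_that("k-nearest neighbours respect distance order and tie-break by index", {
  set.seed(7)
  D <- pairwise_sq_euclidean(matrix(rnorm(8 * 10), 8, 10))
  # k = n-1 includes everyone else
  N <- knn_neighbors(D, 7)
  for (i in 1:8) expect_setequal(N$neighbors[[i]], setdiff(1:8, i))

  # ties go to the smaller index
  Dt <- matrix(10, 6, 6); diag(Dt) <- 0
  Dt[1, 2] <- Dt[2, 1] <- 3
  Dt[1, 5] <- Dt[5, 1] <- 3
  expect_identical(knn_neighbors(Dt, 1)$neighbors[[1]], 2L)

  # full-sort oracle
  N3 <- knn_neighbors(D, 3)
  for (i in 1:8) {
    cand <- setdiff(1:8, i)
    ord <- cand[order(D[i, cand], cand)]
    expect_identical(N3$neighbors[[i]], ord[1:3])
  }
  expect_error(knn_neighbors(D, 0), "k must be")
  expect_error(knn_neighbors(D, 8), "k must be")
})

test_that("triplet relative sums equal explicit triplet enumeration", {
  set.seed(11)
  X <- matrix(rnorm(6 * 12), 6, 12)
  D <- pairwise_sq_euclidean(X)
  N <- knn_neighbors(D, 3)
  for (i in 1:6) {
    dp <- triplet_relative_sums(D, N, i)
    for (v in 1:6) {
      s <- 0
      for (u in N$neighbors[[i]]) s <- s + (D[i, v] - D[i, u])
      expect_equal(dp[[v]], s, tolerance = 1e-12)
    }
  }
  # all neighbours equidistant from the centre -> zero for every neighbour
  Deq <- matrix(5, 4, 4); diag(Deq) <- 0
  Neq <- knn_neighbors(Deq, 3)
  dp <- triplet_relative_sums(Deq, Neq, 1)
  expect_equal(unname(dp[Neq$neighbors[[1]]]), rep(0, 3))
  # k = 1: difference of the two distances
  N1 <- knn_neighbors(D, 1)
  u <- N1$neighbors[[2]]
  dp1 <- triplet_relative_sums(D, N1, 2)
  expect_equal(dp1[4], D[2, 4] - D[2, u], tolerance = 1e-12)
})

test_that("triplet distance field is antisymmetric on the neighbour set", {
  set.seed(3)
  X <- matrix(rnorm(7 * 15), 7, 15)
  D <- pairwise_sq_euclidean(X)
  N <- knn_neighbors(D, 4)
  for (i in 1:7) {
    S <- triplet_distance_field(D, N, i)
    Ni <- N$neighbors[[i]]
    Ssub <- S[, Ni]               # rows already indexed by Ni
    expect_lt(max(abs(Ssub + t(Ssub))), 1e-12)
    expect_equal(unname(diag(Ssub)), rep(0, length(Ni)))
  }
})

test_that("second-order network matches the literal construction oracle", {
  set.seed(5)
  X <- matrix(rnorm(5 * 8), 5, 8)
  C <- second_order_network(X, 2)
  expect_lt(max(abs(unclass(C) - oracle_second_order(X, 2))), 1e-10)
  expect_true(all(C >= 0 & C <= 1))
  expect_identical(unclass(C), t(unclass(C)))
})

test_that("identical signals give the degenerate zero second-order network", {
  X <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4)
  expect_warning(C <- second_order_network(X, 2), "degenerate")
  expect_equal(max(abs(C)), 0)
})

test_that("Pearson network has textbook values and rejects constant regions", {
  set.seed(9)
  x <- rnorm(30)
  X <- rbind(x, 2 * x + 3, -x, rnorm(30))
  C <- pearson_network(X)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_equal(diag(unclass(C)), rep(0, 4), ignore_attr = TRUE)

  X5 <- matrix(rnorm(6 * 20), 6, 20)
  C5 <- pearson_network(X5)
  O <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) if (i != j)
    O[i, j] <- cov(X5[i, ], X5[j, ]) / sqrt(var(X5[i, ]) * var(X5[j, ]))
  expect_lt(max(abs(unclass(C5) - O)), 1e-10)

  Xc <- rbind(rnorm(10), rep(2, 10), rnorm(10))
  rownames(Xc) <- c("A", "B", "C")
  expect_error(pearson_network(Xc), "B")
})

test_that("hybrid fusion is the exact convex combination with endpoint identities", {
  set.seed(13)
  X <- matrix(rnorm(8 * 25), 8, 25)
  C1 <- pearson_network(X)
  C2 <- second_order_network(X, 3)
  expect_equal(unclass(hybrid_network(C1, C2, 1)), unclass(C1),
               ignore_attr = TRUE)
  expect_equal(unclass(hybrid_network(C1, C2, 0)), unclass(C2),
               ignore_attr = TRUE)
  H <- hybrid_network(C1, C2, 0.4)
  expect_lt(max(abs(unclass(H) - (0.4 * unclass(C1) + 0.6 * unclass(C2)))), 1e-12)
  # convexity: each entry between the two parents
  lo <- pmin(unclass(C1), unclass(C2)); hi <- pmax(unclass(C1), unclass(C2))
  expect_true(all(H >= lo - 1e-12 & H <= hi + 1e-12))
  expect_true(all(H >= -0.4 - 1e-12 & H <= 1 + 1e-12))

  X2 <- matrix(rnorm(5 * 25), 5, 25)
  expect_error(hybrid_network(pearson_network(X2), C2, 0.5), "dimensions")
  expect_error(hybrid_network(C2, C2, 0.5), "first_order")
})

test_that("thresholding zeroes small magnitudes and nothing else", {
  set.seed(17)
  X <- matrix(rnorm(6 * 30), 6, 30)
  C <- pearson_network(X)
  expect_equal(unclass(threshold_network(C, 0)), unclass(C),
               ignore_attr = TRUE)
  Tbig <- threshold_network(C, max(abs(C)) + 0.1)
  expect_equal(max(abs(Tbig)), 0)
  Tt <- threshold_network(C, 0.1)
  expect_equal(sum(Tt != 0), sum(abs(unclass(C)) >= 0.1))
  expect_identical(unclass(Tt), t(unclass(Tt)))
  expect_error(threshold_network(C, -0.1), "non-negative")
})

test_that("network construction is permutation-equivariant and scale-invariant", {
  set.seed(19)
  X <- matrix(rnorm(7 * 20), 7, 20)
  perm <- sample(7)
  for (build in list(function(x) pearson_network(x),
                     function(x) second_order_network(x, 3))) {
    C <- unclass(build(X))
    Cp <- unclass(build(X[perm, ]))
    expect_lt(max(abs(Cp - C[perm, perm])), 1e-10)
    Cs <- unclass(build(3.7 * X))
    expect_lt(max(abs(Cs - C)), 1e-10)
  }
})
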