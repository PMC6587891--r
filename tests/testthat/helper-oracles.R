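# Independent oracle implementations used to validate the package. These are
# deliberately written as literal loops / generic solvers, sharing no code
# with the implementation under test.

# Literal triplet-enumeration construction of the second-order network:
# squared distances by double loop, k-NN by full sort, relative distances by
# explicit triplet sums, joint min-max normalisation, symmetrisation.
oracle_second_order <- function(X, k) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- sum((X[i, ] - X[j, ])^2)
  Ni <- vector("list", n)
  for (i in 1:n) {
    cand <- setdiff(1:n, i)
    ord <- cand[order(D[i, cand], cand)]
    Ni[[i]] <- ord[1:k]
  }
  M <- matrix(0, n, n)
  comp <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in Ni[[i]]) {
    s <- 0
    for (u in Ni[[i]]) s <- s + (D[i, j] - D[i, u])
    M[i, j] <- -s
    comp[i, j] <- TRUE
  }
  vals <- M[comp]
  if (max(vals) - min(vals) <= 0) {
    M[] <- 0
  } else {
    M[comp] <- (M[comp] - min(vals)) / (max(vals) - min(vals))
  }
  C <- (M + t(M)) / 2
  diag(C) <- 0
  C
}

# Projected-gradient solver for the non-negative elastic net objective.
oracle_nonneg_enet_pg <- function(F, y, l1, l2, iters = 2e5, tol = 1e-12) {
  FtF <- crossprod(F)
  Fty <- drop(crossprod(F, y))
  L <- max(eigen(FtF, symmetric = TRUE, only.values = TRUE)$values) + l2
  b <- rep(0, ncol(F))
  for (it in seq_len(iters)) {
    g <- FtF %*% b - Fty + l1 + l2 * b
    nb <- pmax(0, b - g / L)
    if (max(abs(nb - b)) < tol) { b <- nb; break }
    b <- nb
  }
  drop(b)
}

enet_objective <- function(F, y, b, l1, l2) {
  0.5 * sum((y - F %*% b)^2) + l1 * sum(b) + 0.5 * l2 * sum(b^2)
}

# All-pairs Mann-Whitney AUC with half credit for ties.
oracle_auc_pairs <- function(scores, labels) {
  sp <- scores[labels == "patient"]
  sc <- scores[labels == "control"]
  mean(outer(sp, sc, ">") + 0.5 * outer(sp, sc, "=="))
}

# Dense generalized-eigenproblem solution of the kernel Fisher discriminant.
oracle_kda_direction <- function(features, labels, gamma, epsilon) {
  y <- ifelse(as.character(labels) == "patient", 1, -1)
  n <- nrow(features)
  D <- as.matrix(dist(features))^2
  K <- exp(-gamma * D)
  i1 <- which(y > 0); i2 <- which(y < 0)
  m1 <- rowMeans(K[, i1, drop = FALSE]); m2 <- rowMeans(K[, i2, drop = FALSE])
  M <- (m1 - m2) %*% t(m1 - m2)
  N <- matrix(0, n, n)
  for (idx in list(i1, i2)) {
    Kc <- K[, idx, drop = FALSE]
    H <- diag(length(idx)) - 1 / length(idx)
    N <- N + Kc %*% H %*% t(Kc)
  }
  e <- eigen(solve(N + epsilon * diag(n)) %*% M)
  Re(e$vectors[, which.max(Re(e$values))])
}

cosine_sim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Random connected Erdos-Renyi adjacency matrix.
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    A <- matrix(runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::is_connected(g)) return(A)
  }
}

# Small cohort spec used by several tests (cheap to generate).
tiny_cohort_spec <- function(seed = 1, perturbation = list(c(1, 6, 0.3))) {
  cohort_spec(n_patients = 10, n_controls = 10, n_regions = 10,
              n_timepoints = 100, n_blocks = 2, within = 0.3, between = 0.05,
              perturbation = perturbation, noise_sd = 0.3, seed = seed)
}
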