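#' Connectivity matrix objects
#'
#' A connectivity matrix is an n x n symmetric, zero-diagonal numeric matrix
#' with a `kind` (`"first_order"`, `"second_order"` or `"hybrid"`) and the
#' construction parameters that produced it. Second-order entries lie in
#' \[0, 1\]; first-order (Pearson) off-diagonal entries lie in \[-1, 1\]; a
#' hybrid with weight `mu` therefore lies in \[-mu, 1\].
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param kind one of `"first_order"`, `"second_order"`, `"hybrid"`.
#' @param params named list of construction parameters (`k`, `mu`,
#'   `threshold`, as applicable).
#' @param region_labels optional character vector of region names.
#' @return An object of class `fbn_network` (a numeric matrix with
#'   attributes).
#' @export
fbn_network <- function(values, kind, params = list(), region_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  n <- nrow(values)
  if (ncol(values) != n) stop("connectivity matrix must be square")
  if (max(abs(values - t(values))) > 1e-8)
    stop("connectivity matrix must be symmetric")
  kind <- match.arg(kind, c("first_order", "second_order", "hybrid"))
  if (is.null(region_labels)) region_labels <- default_region_labels(n)
  if (length(region_labels) != n)
    stop("region_labels length must equal the number of regions")
  dimnames(values) <- list(region_labels, region_labels)
  structure(values,
            kind = kind, params = params, region_labels = region_labels,
            class = c("fbn_network", "matrix", "array"))
}

default_region_labels <- function(n) paste0("R", seq_len(n))

#' @export
print.fbn_network <- function(x, ...) {
  p <- attr(x, "params")
  ptxt <- if (length(p)) paste(names(p), unlist(p), sep = "=", collapse = ", ")
          else "none"
  cat(sprintf("<fbn_network> kind=%s  %d regions  params: %s\n",
              attr(x, "kind"), nrow(x), ptxt))
  cat(sprintf("  edge weights in [%.4f, %.4f]\n",
              min(x[upper.tri(x)]), max(x[upper.tri(x)])))
  invisible(x)
}

network_kind <- function(C) attr(C, "kind")
network_params <- function(C) attr(C, "params")

validate_timeseries <- function(X) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("time series must be a numeric matrix (regions x time points)")
  if (nrow(X) < 3) stop("at least 3 regions are required (n >= 3)")
  if (ncol(X) < 2) stop("at least 2 time points are required (m >= 2)")
  if (any(!is.finite(X))) stop("time series contains non-finite values")
  invisible(X)
}

#' Pairwise squared Euclidean distances between region time series
#'
#' `D[i, j] = sum_t (X[i, t] - X[j, t])^2`. These distances operate on the
#' fMRI signals, not on anatomical positions.
#'
#' @param X numeric matrix, regions x time points.
#' @return symmetric, non-negative matrix with an exactly zero diagonal.
#' @export
pairwise_sq_euclidean <- function(X) {
  validate_timeseries(X)
  G <- tcrossprod(X)
  g <- diag(G)
  D <- outer(g, g, "+") - 2 * G
  D <- (D + t(D)) / 2          # kill asymmetric rounding noise
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' k nearest neighbours of each region
#'
#' Neighbours are ranked by distance with ties broken by the smaller region
#' index; each neighbour list excludes the region itself and is sorted by
#' (distance, index).
#'
#' @param D squared-distance matrix from [pairwise_sq_euclidean()].
#' @param k neighbourhood size, `1 <= k <= n - 1`.
#' @return list with `neighbors` (list of integer vectors) and `k`.
#' @export
knn_neighbors <- function(D, k) {
  n <- nrow(D)
  if (k < 1 || k > n - 1) stop(sprintf("k must be in [1, %d], got %s", n - 1, k))
  neighbors <- vector("list", n)
  idx <- seq_len(n)
  for (i in idx) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, idx)       # stable: ties resolved by smaller index
    neighbors[[i]] <- ord[seq_len(k)]
  }
  list(neighbors = neighbors, k = k)
}

#' Triplet relative-distance field for one centre region
#'
#' For centre region `i`, the antisymmetric field over neighbours `u` and
#' regions `v` is `S[u, v] = D[i, v] - D[i, u]`: the distance of `v` from the
#' centre relative to `u`.
#'
#' @param D squared-distance matrix.
#' @param N neighbour sets from [knn_neighbors()].
#' @param i centre region index.
#' @return matrix of dimension `k x n`, rows indexed by the neighbours of `i`
#'   (in neighbour order), columns by all regions.
#' @export
triplet_distance_field <- function(D, N, i) {
  Ni <- N$neighbors[[i]]
  S <- outer(rep(1, length(Ni)), D[i, ]) - matrix(D[i, Ni], length(Ni), ncol(D))
  rownames(S) <- as.character(Ni)
  S
}

#' Aggregated relative distance of every region from a centre
#'
#' Sums the triplet field over the centre's neighbours:
#' `dist'(x_i, x_v) = sum_{u in N_i} (D[i, v] - D[i, u])
#'                  = k * D[i, v] - sum_{u in N_i} D[i, u]`.
#'
#' @inheritParams triplet_distance_field
#' @return numeric vector over all regions `v`.
#' @export
triplet_relative_sums <- function(D, N, i) {
  Ni <- N$neighbors[[i]]
  N$k * D[i, ] - sum(D[i, Ni])
}

#' Triplet-based second-order connectivity network
#'
#' Edge weights are derived from the ordinal structure of each region's
#' k-nearest-neighbourhood: for each centre `i` and neighbour `j`, the
#' negative aggregated relative distance `-dist'(x_i, x_j)` is computed, all
#' computed entries of the subject are min-max rescaled to \[0, 1\] jointly
#' (non-neighbour entries stay 0), and the matrix is symmetrised as
#' `(C + t(C)) / 2`. Regions with larger relative distance from a centre thus
#' receive weaker connectivity.
#'
#' If every computed entry is identical (e.g. all region signals are equal)
#' there is no ordinal information; all entries are set to 0 with a warning.
#'
#' @param X numeric matrix, regions x time points.
#' @param k neighbourhood size.
#' @param region_labels optional region names.
#' @return an `fbn_network` of kind `"second_order"` with entries in \[0, 1\].
#' @export
second_order_network <- function(X, k, region_labels = NULL) {
  validate_timeseries(X)
  n <- nrow(X)
  D <- pairwise_sq_euclidean(X)
  N <- knn_neighbors(D, k)
  M <- matrix(0, n, n)
  computed <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    dp <- triplet_relative_sums(D, N, i)
    Ni <- N$neighbors[[i]]
    M[i, Ni] <- -dp[Ni]
    computed[i, Ni] <- TRUE
  }
  vals <- M[computed]
  rng <- range(vals)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("degenerate normalization: all computed triplet values are equal; ",
            "second-order network set to 0")
    M[] <- 0
  } else {
    M[computed] <- (vals - rng[1]) / (rng[2] - rng[1])
  }
  C <- (M + t(M)) / 2
  diag(C) <- 0
  fbn_network(C, "second_order", params = list(k = k),
              region_labels = region_labels %||% rownames(X))
}

#' First-order (Pearson) connectivity network
#'
#' Classical pairwise Pearson correlation between region time series,
#' `Cov(x_i, x_j) / sqrt(Var(x_i) Var(x_j))`, with the diagonal forced to 0
#' (self-connections are never used downstream).
#'
#' @inheritParams second_order_network
#' @return an `fbn_network` of kind `"first_order"` with off-diagonal entries
#'   in \[-1, 1\].
#' @export
pearson_network <- function(X, region_labels = NULL) {
  validate_timeseries(X)
  v <- apply(X, 1, var)
  if (any(v == 0)) {
    labs <- (region_labels %||% rownames(X)) %||% default_region_labels(nrow(X))
    stop("constant time series (zero variance) in region(s): ",
         paste(labs[v == 0], collapse = ", "))
  }
  C <- cor(t(X))
  C <- (C + t(C)) / 2
  diag(C) <- 0
  fbn_network(C, "first_order", params = list(),
              region_labels = region_labels %||% rownames(X))
}

#' Hybrid network: convex fusion of first- and second-order networks
#'
#' `C = mu * C1 + (1 - mu) * C2`. The first-order network contributes raw
#' pairwise connectivity strength (robust to noise); the second-order network
#' contributes neighbourhood ordinal structure (sensitive to subtle change).
#'
#' @param C1 an `fbn_network` of kind `"first_order"`.
#' @param C2 an `fbn_network` of kind `"second_order"`.
#' @param mu mixing weight in \[0, 1\]; `mu = 1` returns `C1`, `mu = 0`
#'   returns `C2`.
#' @return an `fbn_network` of kind `"hybrid"`.
#' @export
hybrid_network <- function(C1, C2, mu) {
  if (!inherits(C1, "fbn_network") || network_kind(C1) != "first_order")
    stop("C1 must be a first_order fbn_network")
  if (!inherits(C2, "fbn_network") || network_kind(C2) != "second_order")
    stop("C2 must be a second_order fbn_network")
  if (!identical(dim(C1), dim(C2)))
    stop("C1 and C2 have different dimensions")
  if (!identical(attr(C1, "region_labels"), attr(C2, "region_labels")))
    stop("C1 and C2 have different region labels")
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  C <- mu * unclass(C1) + (1 - mu) * unclass(C2)
  fbn_network(C, "hybrid",
              params = list(mu = mu, k = network_params(C2)$k),
              region_labels = attr(C1, "region_labels"))
}

#' Sparsify a network by absolute thresholding
#'
#' Entries with `|C[i, j]| < t` are set to 0; others are kept unchanged.
#' Absolute value is used because first-order entries can be negative.
#'
#' @param C an `fbn_network`.
#' @param t non-negative threshold (the classification experiments scan
#'   `{0, 0.05, ..., 0.4}`).
#' @return an `fbn_network` of the same kind with `threshold` recorded.
#' @export
threshold_network <- function(C, t) {
  if (t < 0) stop("threshold must be non-negative")
  v <- unclass(C)
  v[abs(v) < t] <- 0
  p <- network_params(C)
  p$threshold <- t
  fbn_network(v, network_kind(C), params = p,
              region_labels = attr(C, "region_labels"))
}

#' Build a connectivity network from one subject's time series
#'
#' Convenience wrapper dispatching on `method`; hybrid networks are
#' thresholded after fusion.
#'
#' @param X numeric matrix, regions x time points.
#' @param method `"pearson"`, `"triplet"` or `"hybrid"`.
#' @param k neighbourhood size (triplet / hybrid).
#' @param mu fusion weight (hybrid).
#' @param threshold absolute threshold applied after construction (and after
#'   fusion for hybrid networks); 0 keeps all edges.
#' @param region_labels optional region names.
#' @return an `fbn_network`.
#' @export
build_network <- function(X, method = c("hybrid", "pearson", "triplet"),
                          k = 15, mu = 0.5, threshold = 0,
                          region_labels = NULL) {
  method <- match.arg(method)
  C <- switch(method,
    pearson = pearson_network(X, region_labels),
    triplet = second_order_network(X, k, region_labels),
    hybrid  = hybrid_network(pearson_network(X, region_labels),
                             second_order_network(X, k, region_labels), mu))
  if (threshold > 0) C <- threshold_network(C, threshold) else C
}

`%||%` <- function(a, b) if (is.null(a)) b else a
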