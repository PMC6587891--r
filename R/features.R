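#' Edge index of the upper triangle in row-major (i < j) order
#'
#' Edge order is (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n).
#'
#' @param n number of regions.
#' @return integer matrix with columns `i`, `j` and `n(n-1)/2` rows.
#' @export
edge_index <- function(n) {
  ei <- t(utils::combn(n, 2))
  colnames(ei) <- c("i", "j")
  ei
}

#' Vectorize a symmetric network into its upper-triangle edge weights
#'
#' @param C symmetric zero-diagonal matrix (or `fbn_network`).
#' @return numeric vector of length `n(n-1)/2` in [edge_index()] order.
#' @export
vectorize_network <- function(C) {
  v <- unclass(C)
  if (max(abs(v - t(v))) > 1e-8) stop("network must be symmetric")
  v[edge_index(nrow(v))]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' Inverse of [vectorize_network()].
#'
#' @param v edge-weight vector of length `n(n-1)/2`.
#' @param n number of regions.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
devectorize_network <- function(v, n) {
  ei <- edge_index(n)
  if (length(v) != nrow(ei))
    stop(sprintf("edge vector has length %d, expected %d", length(v), nrow(ei)))
  C <- matrix(0, n, n)
  C[ei] <- v
  C[ei[, 2:1]] <- v
  C
}

#' Non-negative elastic net by cyclic coordinate descent
#'
#' Solves `min_{beta >= 0} 0.5 ||y - F beta||^2 + lambda1 sum(beta) +
#' 0.5 lambda2 ||beta||^2` with non-negative soft-threshold coordinate
#' updates, stopping when the largest coefficient change in a sweep falls
#' below `tol` or after `max_sweeps` sweeps (with a warning). Class labels
#' are coded as the +/-1 regression target. Edges with positive coefficients
#' are the selected discriminative connectivities.
#'
#' @param features numeric matrix, subjects x edges.
#' @param labels vector coercible to +/-1 (a factor with levels
#'   control/patient is coded -1/+1).
#' @param lambda1 L1 penalty (>= 0).
#' @param lambda2 L2 penalty (>= 0).
#' @param tol convergence tolerance on the max coefficient change.
#' @param max_sweeps sweep cap.
#' @return object of class `nn_enet`: `beta`, `selected_edges`, penalties and
#'   convergence information.
#' @export
fit_nonneg_elastic_net <- function(features, labels, lambda1, lambda2,
                                   tol = 1e-8, max_sweeps = 1e4) {
  y <- code_labels(labels)
  stopifnot(nrow(features) == length(y), lambda1 >= 0, lambda2 >= 0)
  if (sum(y > 0) < 2 || sum(y < 0) < 2)
    stop("at least 2 subjects per class are required")
  FtF <- crossprod(features)
  Fty <- drop(crossprod(features, y))
  fit <- nonneg_enet_cd(FtF, Fty, lambda1, lambda2, tol, as.integer(max_sweeps))
  if (!fit$converged)
    warning(sprintf("coordinate descent did not converge in %d sweeps (final max change %.3g)",
                    as.integer(max_sweeps), fit$max_change))
  beta <- drop(fit$beta)
  structure(list(beta = beta, selected_edges = which(beta > 0),
                 lambda1 = lambda1, lambda2 = lambda2,
                 sweeps = fit$sweeps, converged = fit$converged),
            class = "nn_enet")
}

#' @export
print.nn_enet <- function(x, ...) {
  cat(sprintf("<nn_enet> %d/%d edges selected (lambda1=%.3g, lambda2=%.3g, %d sweeps%s)\n",
              length(x$selected_edges), length(x$beta), x$lambda1, x$lambda2,
              x$sweeps, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
coef.nn_enet <- function(object, ...) object$beta

code_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    l <- as.character(labels)
    if (!all(l %in% c("patient", "control")))
      stop("labels must be patient/control or +/-1")
    ifelse(l == "patient", 1, -1)
  } else {
    if (!all(labels %in% c(-1, 1))) stop("numeric labels must be +/-1")
    as.numeric(labels)
  }
}

#' KKT residuals of a non-negative elastic-net solution
#'
#' For the objective of [fit_nonneg_elastic_net()], optimality requires the
#' gradient `-F'(y - F beta) + lambda1 + lambda2 beta` to be 0 on active
#' coordinates and >= 0 on inactive ones.
#'
#' @param model an `nn_enet`.
#' @param features,labels the training data.
#' @return numeric vector of gradients per edge.
#' @export
enet_kkt_gradient <- function(model, features, labels) {
  y <- code_labels(labels)
  r <- y - drop(features %*% model$beta)
  -drop(crossprod(features, r)) + model$lambda1 + model$lambda2 * model$beta
}

#' Gaussian-kernel discriminant analysis (two classes)
#'
#' Kernelised Fisher discriminant: with kernel `K(a,b) = exp(-gamma
#' ||a-b||^2)`, maximises the ratio of between- to within-class scatter in
#' feature space, `(alpha' M alpha) / (alpha' (N + eps I) alpha)`. For two
#' classes the leading direction has the closed form `alpha = (N + eps I)^{-1}
#' (m1 - m2)` with `m_c` the class mean kernel columns. The returned direction
#' is oriented so patients project higher than controls on the training set.
#'
#' @param features numeric matrix, subjects x features.
#' @param labels class labels (patient/control or +/-1; patient is positive).
#' @param gamma kernel bandwidth; default `1 / median(pairwise squared
#'   distance)` of the training features (median heuristic).
#' @param epsilon within-class scatter regulariser; default
#'   `1e-3 * trace(N) / n_train`.
#' @return object of class `kda_model`.
#' @export
fit_kda <- function(features, labels, gamma = NULL, epsilon = NULL) {
  y <- code_labels(labels)
  if (sum(y > 0) < 1 || sum(y < 0) < 1) stop("two classes are required")
  n <- nrow(features)
  D <- sq_dist(features, features)
  if (is.null(gamma)) {
    med <- stats::median(D[upper.tri(D)])
    if (!is.finite(med) || med <= 0) med <- 1
    gamma <- 1 / med
  }
  if (gamma <= 0) stop("gamma must be positive")
  K <- exp(-gamma * D)
  i1 <- which(y > 0); i2 <- which(y < 0)
  m1 <- rowMeans(K[, i1, drop = FALSE])
  m2 <- rowMeans(K[, i2, drop = FALSE])
  Nmat <- matrix(0, n, n)
  for (idx in list(i1, i2)) {
    Kc <- K[, idx, drop = FALSE]
    Hc <- diag(length(idx)) - matrix(1 / length(idx), length(idx), length(idx))
    Nmat <- Nmat + Kc %*% Hc %*% t(Kc)
  }
  if (is.null(epsilon)) epsilon <- 1e-3 * sum(diag(Nmat)) / n
  if (epsilon <= 0) epsilon <- 1e-8
  alpha <- tryCatch(solve(Nmat + epsilon * diag(n), m1 - m2),
                    error = function(e)
                      stop("within-class scatter system is singular; ",
                           "increase epsilon", call. = FALSE))
  model <- structure(list(alpha = alpha, X_train = features, gamma = gamma,
                          epsilon = epsilon, Nmat = Nmat, m1 = m1, m2 = m2),
                     class = "kda_model")
  proj <- kda_transform(model, features)
  if (mean(proj[i1]) < mean(proj[i2])) model$alpha <- -model$alpha
  model
}

#' @export
print.kda_model <- function(x, ...) {
  cat(sprintf("<kda_model> %d training samples, gamma=%.4g, epsilon=%.4g\n",
              nrow(x$X_train), x$gamma, x$epsilon))
  invisible(x)
}

#' Project samples onto the KDA discriminant direction
#'
#' @param model a `kda_model`.
#' @param features numeric matrix, samples x features (same feature space as
#'   training).
#' @return numeric vector of scalar projections.
#' @export
kda_transform <- function(model, features) {
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  Kn <- exp(-model$gamma * sq_dist(features, model$X_train))
  drop(Kn %*% model$alpha)
}

#' @export
predict.kda_model <- function(object, newdata, ...) kda_transform(object, newdata)

sq_dist <- function(A, B) {
  a <- rowSums(A^2); b <- rowSums(B^2)
  D <- outer(a, b, "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Serialize a fitted selection + projection model to JSON-like text
#'
#' Writes coefficients, hyperparameters and selected edge indices as plain
#' JSON (hand-rolled writer; values at full precision).
#'
#' @param model an `nn_enet`.
#' @param path output file.
#' @export
write_enet_json <- function(model, path) {
  num <- function(v) paste(sprintf("%.17g", v), collapse = ", ")
  txt <- sprintf(
    '{\n  "lambda1": %.17g,\n  "lambda2": %.17g,\n  "selected_edges": [%s],\n  "beta": [%s]\n}',
    model$lambda1, model$lambda2,
    paste(model$selected_edges, collapse = ", "), num(model$beta))
  writeLines(txt, path)
  invisible(path)
}
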