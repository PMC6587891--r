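#' Binarize a connectivity matrix
#'
#' An (undirected, self-loop-free) edge is present iff `|C[i, j]| >= t`.
#'
#' @param C connectivity matrix (any kind).
#' @param t non-negative threshold; `t = 0` gives the complete graph.
#' @return logical adjacency matrix.
#' @export
binarize <- function(C, t = 0) {
  if (t < 0) stop("threshold must be non-negative")
  A <- abs(unclass(C)) >= t
  diag(A) <- FALSE
  A & t(A)   # symmetric input stays symmetric; guards asymmetric input
}

# BFS shortest-path lengths from every node (unweighted graph).
shortest_paths_bfs <- function(A) {
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ]))
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[!is.finite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

largest_component <- function(A) {
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  cid <- 0
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ]))
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    frontier <- s
    comp[s] <- cid
    while (length(frontier)) {
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[is.na(comp[nxt])]
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  sizes <- tabulate(comp)
  which(comp == which.max(sizes))
}

# Brandes betweenness (unweighted, undirected). Returns node and edge
# betweenness with each unordered pair of endpoints counted once.
brandes_betweenness <- function(A) {
  n <- nrow(A)
  nbrs <- lapply(seq_len(n), function(i) which(A[i, ]))
  cb <- rep(0, n)
  eb <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma <- rep(0, n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    stack <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      stack <- c(stack, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- rep(0, n)
    for (w in rev(stack)) {
      for (v in preds[[w]]) {
        c_ <- sigma[v] / sigma[w] * (1 + delta[w])
        eb[v, w] <- eb[v, w] + c_
        eb[w, v] <- eb[w, v] + c_
        delta[v] <- delta[v] + c_
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  list(node = cb / 2, edge = eb / 2)  # each unordered pair counted once
}

global_efficiency_adj <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- shortest_paths_bfs(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Structural consistency (link predictability) of a graph
#'
#' Perturbation-based index: a random fraction `p_h` of edges is removed, the
#' remaining adjacency is eigen-decomposed, the eigenvalues are first-order
#' corrected by the removed part (`dlambda_k = v_k' dA v_k`), and the
#' perturbed matrix reconstructed from the corrected spectrum ranks the
#' unobserved node pairs. The index is the fraction of removed edges among
#' the top-ranked `|removed|` pairs, averaged over `repeats` random removals.
#'
#' @param A logical/0-1 adjacency matrix.
#' @param p_h fraction of edges removed per repeat (default 0.1).
#' @param repeats number of random removals averaged (default 20).
#' @param seed RNG seed for the removals.
#' @return scalar in \[0, 1\].
#' @export
structural_consistency <- function(A, p_h = 0.1, repeats = 20, seed = 1) {
  A <- A * 1
  ei <- which(upper.tri(A) & A == 1)
  n_remove <- max(1, round(p_h * length(ei)))
  if (length(ei) <= n_remove) return(NaN)
  set.seed(seed)
  sigma <- numeric(repeats)
  n <- nrow(A)
  for (r in seq_len(repeats)) {
    removed <- sample(ei, n_remove)
    AR <- A
    AR[removed] <- 0
    AR <- pmin(AR, t(AR))
    dA <- A - AR
    e <- eigen(AR, symmetric = TRUE)
    dlam <- colSums(e$vectors * (dA %*% e$vectors))
    At <- e$vectors %*% ((e$values + dlam) * t(e$vectors))
    cand <- which(upper.tri(AR) & AR == 0)  # unobserved pairs
    ord <- cand[order(At[cand], decreasing = TRUE)]
    top <- ord[seq_len(n_remove)]
    sigma[r] <- mean(top %in% removed)
  }
  mean(sigma)
}

#' Discrete power-law exponent by maximum likelihood
#'
#' Continuous-approximation MLE `alpha = 1 + N / sum(log(d / (d_min - 0.5)))`
#' with `d_min` the smallest positive degree observed.
#'
#' @param degrees integer vector of node degrees; zero-degree nodes are
#'   excluded from the fit.
#' @return estimated exponent (NaN if fewer than 2 positive degrees or no
#'   spread).
#' @export
powerlaw_alpha <- function(degrees) {
  d <- degrees[degrees > 0]
  if (length(d) < 2) return(NaN)
  dmin <- min(d)
  s <- sum(log(d / (dmin - 0.5)))
  if (s <= 0) return(NaN)
  1 + length(d) / s
}

topology_metric_names <- c(
  "connectivity_strength", "average_degree", "density",
  "clustering_coefficient", "characteristic_path_length",
  "global_efficiency", "local_efficiency", "closeness_centrality",
  "edge_betweenness_centrality", "node_betweenness_centrality",
  "radiality", "assortativity", "structural_consistency",
  "powerlaw_exponent")

#' Graph-level topological summary of a connectivity network
#'
#' Connectivity strength is the mean over nodes of the summed absolute edge
#' weights of the weighted network; all remaining metrics are computed on the
#' binarized graph (edge iff `|C| >= t`): average degree, density, mean local
#' clustering (degree < 2 contributes 0), characteristic path length (mean
#' shortest path over pairs), global efficiency (mean inverse shortest path),
#' local efficiency (mean over nodes of the average inverse distance between
#' the node's neighbours after the node itself is removed), closeness (mean over nodes of `(n-1)/sum of distances`), mean
#' edge and node betweenness (Brandes, pairs counted once), radiality (mean
#' of `diameter + 1 - mean distance to others`), degree assortativity
#' (Pearson correlation of degrees over edge endpoints), structural
#' consistency (see [structural_consistency()]) and the power-law degree
#' exponent (see [powerlaw_alpha()]).
#'
#' Path-based metrics on a disconnected graph are computed on the largest
#' connected component with a warning; assortativity on a regular graph
#' (all degrees equal) is `NaN` with a warning.
#'
#' @param C an `fbn_network` (or plain symmetric matrix).
#' @param t binarization threshold.
#' @param sc_p_h,sc_repeats,sc_seed structural-consistency parameters.
#' @return one-row data.frame with the fourteen metrics.
#' @export
compute_topology <- function(C, t = 0, sc_p_h = 0.1, sc_repeats = 20,
                             sc_seed = 1) {
  W <- unclass(C)
  n <- nrow(W)
  A <- binarize(W, t)
  deg <- rowSums(A)
  strength <- mean(rowSums(abs(W)))
  avg_degree <- mean(deg)
  n_edges <- sum(A) / 2
  density <- 2 * n_edges / (n * (n - 1))

  # local clustering: fraction of connected neighbour pairs
  clust <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    if (length(nb) < 2) return(0)
    sum(A[nb, nb]) / (length(nb) * (length(nb) - 1))
  }, 0)
  clustering <- mean(clust)

  comp <- largest_component(A)
  disconnected <- length(comp) < n
  if (disconnected)
    warning("graph is disconnected; path-based metrics use the largest component (",
            length(comp), "/", n, " nodes)")
  Ac <- A[comp, comp, drop = FALSE]
  nc <- length(comp)
  if (nc >= 2) {
    Dc <- shortest_paths_bfs(Ac)
    offd <- Dc[row(Dc) != col(Dc)]
    cpl <- mean(offd)
    closeness <- mean((nc - 1) / rowSums(Dc))
    diam <- max(offd)
    radiality <- mean(diam + 1 - rowSums(Dc) / (nc - 1))
  } else {
    cpl <- NaN; closeness <- NaN; radiality <- NaN
  }
  geff <- global_efficiency_adj(A)
  # local efficiency of node i: remove i, average inverse distance between
  # its neighbours through the remaining graph
  leff <- mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    Ai <- A[-i, -i, drop = FALSE]
    pos <- match(nb, seq_len(n)[-i])
    Di <- shortest_paths_bfs(Ai)[pos, pos, drop = FALSE]
    inv <- 1 / Di
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, 0))
  bw <- brandes_betweenness(Ac)
  node_bw <- mean(bw$node)
  edge_bw <- if (sum(Ac) > 0) sum(bw$edge[upper.tri(bw$edge)][Ac[upper.tri(Ac)]]) /
                              (sum(Ac) / 2) else NaN

  # degree assortativity: Pearson over directed edge endpoint degrees
  ends <- which(A, arr.ind = TRUE)
  if (nrow(ends) > 0 && sd(deg[ends[, 1]]) > 0) {
    assort <- cor(deg[ends[, 1]], deg[ends[, 2]])
  } else {
    warning("assortativity undefined: all endpoint degrees equal")
    assort <- NaN
  }
  sc <- structural_consistency(A, sc_p_h, sc_repeats, sc_seed)
  alpha <- powerlaw_alpha(deg)
  out <- data.frame(connectivity_strength = strength,
                    average_degree = avg_degree, density = density,
                    clustering_coefficient = clustering,
                    characteristic_path_length = cpl,
                    global_efficiency = geff, local_efficiency = leff,
                    closeness_centrality = closeness,
                    edge_betweenness_centrality = edge_bw,
                    node_betweenness_centrality = node_bw,
                    radiality = radiality, assortativity = assort,
                    structural_consistency = sc, powerlaw_exponent = alpha)
  out
}

#' Group comparison of topological metrics
#'
#' Computes the fourteen metrics for every subject network and compares the
#' two groups per metric with a Welch two-sample t-test.
#'
#' @param networks list of `fbn_network` objects (one per subject).
#' @param labels labels aligned with `networks` (`patient`/`control`).
#' @param t binarization threshold passed to [compute_topology()].
#' @param ... further arguments for [compute_topology()].
#' @return data.frame with per-group mean and sd and the Welch p-value per
#'   metric; subjects with an undefined metric are excluded pairwise and
#'   counted in `n_excluded`.
#' @export
group_topology_table <- function(networks, labels, t = 0, ...) {
  stopifnot(length(networks) == length(labels))
  l <- as.character(labels)
  if (!all(c("patient", "control") %in% l)) stop("both groups are required")
  rows <- suppressWarnings(
    do.call(rbind, lapply(networks, compute_topology, t = t, ...)))
  out <- lapply(topology_metric_names, function(mn) {
    v <- rows[[mn]]
    ok <- is.finite(v)
    vp <- v[ok & l == "patient"]; vc <- v[ok & l == "control"]
    p <- if (length(vp) > 1 && length(vc) > 1 && (sd(vp) > 0 || sd(vc) > 0))
      t.test(vp, vc)$p.value else NaN
    data.frame(metric = mn, control_mean = mean(vc), control_sd = sd(vc),
               patient_mean = mean(vp), patient_sd = sd(vp), p_value = p,
               n_excluded = sum(!ok))
  })
  do.call(rbind, out)
}
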