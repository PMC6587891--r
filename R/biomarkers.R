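#' Significant alteration of connectivity (SAC) edge ranking
#'
#' The raw alteration score of an edge is the absolute difference between the
#' patient-group and control-group mean edge weights (`stat = "meandiff"`) or
#' the absolute Welch t statistic (`stat = "t"`, for sensitivity analysis).
#' Raw scores are min-max normalised over edges to \[0, 1\] — so the
#' top-ranked edge scores exactly 1 whenever any between-group difference
#' exists — and sorted descending with ties broken lexicographically by
#' region pair.
#'
#' @param patient_networks,control_networks lists of `fbn_network` objects
#'   (or symmetric matrices), at least 2 per group.
#' @param stat `"meandiff"` (default) or `"t"`.
#' @return data.frame of class `sac_table`: `region_A`, `region_B`, `i`, `j`,
#'   `weight_score`, one row per unordered pair, sorted descending.
#' @export
sac_scores <- function(patient_networks, control_networks,
                       stat = c("meandiff", "t")) {
  stat <- match.arg(stat)
  if (length(patient_networks) < 2 || length(control_networks) < 2)
    stop("at least 2 subjects per group are required")
  Vp <- t(vapply(patient_networks, vectorize_network,
                 numeric(length(vectorize_network(patient_networks[[1]])))))
  Vc <- t(vapply(control_networks, vectorize_network, numeric(ncol(Vp))))
  if (ncol(Vp) != ncol(Vc)) stop("groups have different network sizes")
  raw <- if (stat == "meandiff") {
    abs(colMeans(Vp) - colMeans(Vc))
  } else {
    vp <- apply(Vp, 2, var) / nrow(Vp)
    vc <- apply(Vc, 2, var) / nrow(Vc)
    se <- sqrt(vp + vc)
    d <- abs(colMeans(Vp) - colMeans(Vc))
    ifelse(se > 0, d / se, 0)
  }
  rng <- range(raw)
  if (diff(rng) <= 0) {
    warning("all edge alteration scores are equal; SAC scores set to 0")
    score <- rep(0, length(raw))
  } else {
    score <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  n <- nrow(as.matrix(unclass(patient_networks[[1]])))
  ei <- edge_index(n)
  labels <- attr(patient_networks[[1]], "region_labels") %||%
    default_region_labels(n)
  out <- data.frame(region_A = labels[ei[, 1]], region_B = labels[ei[, 2]],
                    i = ei[, 1], j = ei[, 2], weight_score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight_score, out$i, out$j), ]
  rownames(out) <- NULL
  class(out) <- c("sac_table", "data.frame")
  out
}

#' @export
print.sac_table <- function(x, n = 10, ...) {
  cat(sprintf("<sac_table> %d edges; top %d:\n", nrow(x), min(n, nrow(x))))
  print.data.frame(head(as.data.frame(x)[c("region_A", "region_B",
                                           "weight_score")], n))
  invisible(x)
}

#' Region weights accumulated from top SAC edges
#'
#' For each region, sums the weight scores of the top-`top_n` SAC rows in
#' which the region participates, then min-max normalises the sums to
#' \[0, 1\] and sorts descending.
#'
#' @param sac a [sac_scores()] table.
#' @param top_n number of top SAC rows to accumulate (default 30).
#' @return data.frame with `region` and `weight_score`, sorted descending.
#' @export
region_weights <- function(sac, top_n = 30) {
  if (top_n > nrow(sac)) stop("top_n exceeds the number of SAC rows")
  top <- sac[seq_len(top_n), ]
  regions <- unique(c(top$region_A, top$region_B))
  raw <- vapply(regions, function(r)
    sum(top$weight_score[top$region_A == r | top$region_B == r]), 0)
  rng <- range(raw)
  score <- if (diff(rng) <= 0) rep(if (rng[1] > 0) 1 else 0, length(raw))
           else (raw - rng[1]) / (rng[2] - rng[1])
  out <- data.frame(region = regions, weight_score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight_score, out$region), ]
  rownames(out) <- NULL
  out
}

#' Extract group-mean subnetworks over a region subset
#'
#' @param patient_networks,control_networks lists of subject networks.
#' @param regions character vector of region names (or integer indices),
#'   e.g. the top-15 regions from [region_weights()].
#' @return list with `patient`, `control` (group-mean submatrices),
#'   `difference` (patient minus control), and `mean_strength` (mean edge
#'   weight per group over the subnetwork's pairs).
#' @export
subnet_extract <- function(patient_networks, control_networks, regions) {
  labels <- attr(patient_networks[[1]], "region_labels") %||%
    default_region_labels(nrow(unclass(patient_networks[[1]])))
  if (is.character(regions)) {
    idx <- match(regions, labels)
    if (anyNA(idx))
      stop("unknown region name(s): ",
           paste(regions[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(regions)
    if (any(idx < 1 | idx > length(labels))) stop("region index out of range")
  }
  group_mean <- function(nets) {
    M <- Reduce(`+`, lapply(nets, function(C) unclass(C)[idx, idx])) /
      length(nets)
    dimnames(M) <- list(labels[idx], labels[idx])
    M
  }
  P <- group_mean(patient_networks)
  C <- group_mean(control_networks)
  up <- upper.tri(P)
  list(patient = P, control = C, difference = P - C,
       mean_strength = c(patient = mean(P[up]), control = mean(C[up])))
}
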