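#' Nearest-neighbour classification on 1-D discriminant scores
#'
#' Each test sample receives the label of the training sample with the
#' smallest absolute score difference; ties go to the training sample with
#' the smaller index.
#'
#' @param train_scores numeric vector of training projections.
#' @param train_labels labels aligned with `train_scores`.
#' @param test_scores numeric vector of test projections.
#' @return vector of predicted labels (same type as `train_labels`).
#' @export
nn_classify <- function(train_scores, train_labels, test_scores) {
  if (length(train_scores) == 0) stop("empty training set")
  stopifnot(length(train_scores) == length(train_labels))
  idx <- vapply(test_scores,
                function(s) which.min(abs(train_scores - s)), 0L)
  train_labels[idx]
}

#' Confusion counts with patient as the positive class
#'
#' @param predicted,truth label vectors (values `patient`/`control`).
#' @return list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  p <- as.character(predicted); t <- as.character(truth)
  list(TP = sum(p == "patient" & t == "patient"),
       TN = sum(p == "control" & t == "control"),
       FP = sum(p == "patient" & t == "control"),
       FN = sum(p == "control" & t == "patient"))
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' `AUC = (sum of patient ranks - Npat(Npat+1)/2) / (Npat * Nnor)` with
#' ascending average ranks, which equals the fraction of
#' patient/control pairs ordered correctly with half credit for ties.
#'
#' @param scores numeric vector (higher = more patient-like).
#' @param labels labels (`patient`/`control`).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  l <- as.character(labels)
  n_pat <- sum(l == "patient"); n_nor <- sum(l == "control")
  if (n_pat == 0 || n_nor == 0) stop("both classes are required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[l == "patient"]) - n_pat * (n_pat + 1) / 2) / (n_pat * n_nor)
}

metric_names <- c("ACC", "SEN", "SPE", "PPV", "NPV", "F1", "BAC", "AUC")

#' Classification metrics from confusion counts and scores
#'
#' Computes ACC, SEN, SPE, PPV, NPV, F1, BAC from the confusion counts and
#' AUC from the scores by the rank formula. A ratio with zero denominator is
#' reported as `NaN` with a warning, never silently 0.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN` (patient = positive).
#' @param scores optional numeric scores for AUC.
#' @param labels labels aligned with `scores`.
#' @return named numeric vector of the eight metrics (AUC is `NA` when no
#'   scores are given).
#' @export
compute_metrics <- function(counts, scores = NULL, labels = NULL) {
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NaN)
    }
    num / den
  }
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  ACC <- safe(TP + TN, total, "ACC")
  SEN <- safe(TP, TP + FN, "SEN")
  SPE <- safe(TN, TN + FP, "SPE")
  PPV <- safe(TP, TP + FP, "PPV")
  NPV <- safe(TN, FN + TN, "NPV")
  F1 <- if (is.finite(SEN) && is.finite(PPV)) {
    if (SEN + PPV == 0) { warning("F1 undefined: SEN + PPV = 0"); NaN }
    else 2 * SEN * PPV / (SEN + PPV)
  } else NaN
  BAC <- (SEN + SPE) / 2
  AUC <- if (!is.null(scores)) auc_rank(scores, labels) else NA_real_
  c(ACC = ACC, SEN = SEN, SPE = SPE, PPV = PPV, NPV = NPV, F1 = F1,
    BAC = BAC, AUC = AUC)
}

#' DeLong paired comparison of two correlated AUCs
#'
#' Placement-value estimate of the variance of `AUC_A - AUC_B` for two score
#' vectors on the same subjects, with a two-sided normal p-value. If the
#' variance estimate is zero, the p-value is 1 when the AUCs are equal and an
#' error otherwise.
#'
#' @param scores_A,scores_B paired score vectors on identical subjects.
#' @param labels labels (`patient`/`control`).
#' @return list with `auc_A`, `auc_B`, `var_diff`, `z`, `p`.
#' @export
delong_compare <- function(scores_A, scores_B, labels) {
  l <- as.character(labels)
  stopifnot(length(scores_A) == length(l), length(scores_B) == length(l))
  ip <- which(l == "patient"); ic <- which(l == "control")
  if (length(ip) == 0 || length(ic) == 0) stop("both classes are required")
  placements <- function(s) {
    sp <- s[ip]; sc <- s[ic]
    v10 <- vapply(sp, function(x) mean((x > sc) + 0.5 * (x == sc)), 0)
    v01 <- vapply(sc, function(x) mean((sp > x) + 0.5 * (sp == x)), 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  A <- placements(scores_A); B <- placements(scores_B)
  cov0 <- function(x, y) if (length(x) > 1) sum((x - mean(x)) * (y - mean(y))) / (length(x) - 1) else 0
  s10 <- cov0(A$v10, A$v10) + cov0(B$v10, B$v10) - 2 * cov0(A$v10, B$v10)
  s01 <- cov0(A$v01, A$v01) + cov0(B$v01, B$v01) - 2 * cov0(A$v01, B$v01)
  var_diff <- s10 / length(ip) + s01 / length(ic)
  d <- A$auc - B$auc
  if (var_diff <= 0) {
    if (d == 0) return(list(auc_A = A$auc, auc_B = B$auc, var_diff = 0,
                            z = 0, p = 1))
    stop("zero variance estimate with unequal AUCs; DeLong z undefined")
  }
  z <- d / sqrt(var_diff)
  list(auc_A = A$auc, auc_B = B$auc, var_diff = var_diff, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Cross-validation plan
#'
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats number of shuffled repeats (default 20).
#' @param stratified keep the class ratio within one subject per fold.
#' @param seed master seed; the whole repeated run is reproducible from it.
#' @return object of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10, n_repeats = 20, stratified = TRUE, seed = 1) {
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_plan")
}

make_folds <- function(labels, n_folds, stratified = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (cl in unique(as.character(labels))) {
      idx <- which(as.character(labels) == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
  }
  fold
}

#' Fit the selection + projection + nearest-neighbour classifier
#'
#' The fitted-model core of the pipeline: selects discriminative edges with
#' the non-negative elastic net, projects the selected features with
#' Gaussian-kernel discriminant analysis and classifies by the nearest
#' training subject on the 1-D projection. If the elastic net selects no
#' edge, all edges are used for the projection.
#'
#' @param features numeric matrix, subjects x edges.
#' @param labels training labels (`patient`/`control`).
#' @param lambda1,lambda2 elastic-net penalties.
#' @param gamma,epsilon KDA hyperparameters (see [fit_kda()]).
#' @return object of class `hfbn_model` with `predict` and `print` methods.
#' @export
hfbn_fit <- function(features, labels, lambda1 = 0.01, lambda2 = 0.01,
                     gamma = NULL, epsilon = NULL) {
  enet <- fit_nonneg_elastic_net(features, labels, lambda1, lambda2)
  sel <- enet$selected_edges
  if (length(sel) == 0) sel <- seq_len(ncol(features))
  kda <- fit_kda(features[, sel, drop = FALSE], labels, gamma, epsilon)
  train_scores <- kda_transform(kda, features[, sel, drop = FALSE])
  mu_s <- mean(train_scores); sd_s <- sd(train_scores)
  if (!is.finite(sd_s) || sd_s == 0) sd_s <- 1
  structure(list(enet = enet, kda = kda, selected = sel,
                 train_scores = (train_scores - mu_s) / sd_s,
                 score_center = mu_s, score_scale = sd_s,
                 train_labels = labels),
            class = "hfbn_model")
}

#' @export
print.hfbn_model <- function(x, ...) {
  cat(sprintf("<hfbn_model> %d training subjects, %d selected edges\n",
              length(x$train_labels), length(x$enet$selected_edges)))
  invisible(x)
}

#' Predict group labels and discriminant scores for new subjects
#'
#' @param object an `hfbn_model`.
#' @param newdata numeric matrix, subjects x edges (full edge space; the
#'   model applies its own edge selection).
#' @param ... unused.
#' @return list with `labels` (predicted) and `scores` (standardised KDA
#'   projections, higher = more patient-like).
#' @export
predict.hfbn_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  s <- kda_transform(object$kda, newdata[, object$selected, drop = FALSE])
  s <- (s - object$score_center) / object$score_scale
  list(labels = nn_classify(object$train_scores, object$train_labels, s),
       scores = s)
}

#' Per-subject edge-feature matrix for a cohort
#'
#' Builds each subject's network with [build_network()] and vectorises it.
#'
#' @param cohort an `fbn_cohort`.
#' @param method,k,mu,threshold network construction parameters.
#' @return numeric matrix, subjects x `n(n-1)/2` edges.
#' @export
build_feature_matrix <- function(cohort, method = "hybrid", k = 15, mu = 0.5,
                                 threshold = 0) {
  t(vapply(cohort$subjects,
           function(X) vectorize_network(
             build_network(X, method, k = k, mu = mu, threshold = threshold)),
           numeric(nrow(cohort$subjects[[1]]) *
                   (nrow(cohort$subjects[[1]]) - 1) / 2)))
}

# Cache of per-subject Pearson / second-order edge vectors; the hybrid at any
# mu is their convex combination, so a (k) cache makes mu/threshold sweeps
# cheap.
feature_components <- function(cohort, k, method = "hybrid") {
  n <- nrow(cohort$subjects[[1]])
  n_edge <- n * (n - 1) / 2
  V1 <- if (method != "triplet")
    t(vapply(cohort$subjects,
             function(X) vectorize_network(pearson_network(X)),
             numeric(n_edge)))
  V2 <- if (method != "pearson")
    t(vapply(cohort$subjects,
             function(X) vectorize_network(second_order_network(X, k)),
             numeric(n_edge)))
  list(V1 = V1, V2 = V2)
}

combine_features <- function(comp, method, mu, threshold) {
  FM <- switch(method,
               pearson = comp$V1,
               triplet = comp$V2,
               hybrid = mu * comp$V1 + (1 - mu) * comp$V2)
  if (threshold > 0) FM[abs(FM) < threshold] <- 0
  FM
}

default_lambda_grid <- 10^seq(-3, 0)

tune_lambda_inner <- function(FM, labels, lambda_grid, n_inner = 5) {
  best <- lambda_grid[[1]]; best_acc <- -Inf
  fold <- make_folds(labels, min(n_inner, min(table(labels))))
  for (lam in lambda_grid) {
    correct <- 0; total <- 0
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2) next
      fit <- try(suppressWarnings(
        hfbn_fit(FM[tr, , drop = FALSE], labels[tr], lam, lam)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      pr <- predict(fit, FM[!tr, , drop = FALSE])
      correct <- correct + sum(pr$labels == labels[!tr])
      total <- total + sum(!tr)
    }
    acc <- if (total > 0) correct / total else -Inf
    if (acc > best_acc) { best_acc <- acc; best <- lam }
  }
  best
}

#' Repeated stratified cross-validated evaluation of the pipeline
#'
#' For every repeat the cohort is reshuffled into stratified folds; within
#' each fold all fitting (optional inner-CV penalty tuning, elastic-net edge
#' selection, KDA projection, nearest-neighbour rule) happens on the training
#' partition only. Out-of-fold predictions and standardised scores are pooled
#' per repeat into one confusion table and one AUC; the report carries the
#' per-repeat metric values plus their mean and standard deviation.
#'
#' @param cohort an `fbn_cohort`.
#' @param params list of pipeline parameters: `method`, `k`, `mu`,
#'   `threshold`, `lambda1`, `lambda2`, `tune_lambda` (inner 5-fold CV over
#'   `lambda_grid` with the two penalties tied), `gamma`, `epsilon`.
#' @param plan a [cv_plan()].
#' @return object of class `fbn_metrics`.
#' @export
run_repeated_cv <- function(cohort, params = list(), plan = cv_plan()) {
  p <- utils::modifyList(list(method = "hybrid", k = 15, mu = 0.5,
                              threshold = 0, lambda1 = 0.01, lambda2 = 0.01,
                              tune_lambda = TRUE,
                              lambda_grid = default_lambda_grid,
                              gamma = NULL, epsilon = NULL), params)
  labels <- cohort$labels
  if (min(table(labels)) < plan$n_folds)
    warning("fewer subjects per class than folds; stratification is approximate")
  comp <- feature_components(cohort, p$k, p$method)
  FM <- combine_features(comp, p$method, p$mu, p$threshold)
  per_repeat <- matrix(NA_real_, plan$n_repeats, length(metric_names),
                       dimnames = list(NULL, metric_names))
  for (r in seq_len(plan$n_repeats)) {
    set.seed((plan$seed + 7919L * r) %% .Machine$integer.max)
    fold <- make_folds(labels, plan$n_folds, plan$stratified)
    pred <- rep(NA_character_, length(labels))
    score <- rep(NA_real_, length(labels))
    for (f in seq_len(plan$n_folds)) {
      tr <- fold != f
      if (!any(!tr)) next
      lam1 <- p$lambda1; lam2 <- p$lambda2
      if (isTRUE(p$tune_lambda)) {
        lam1 <- lam2 <- tune_lambda_inner(FM[tr, , drop = FALSE], labels[tr],
                                          p$lambda_grid)
      }
      fit <- suppressWarnings(hfbn_fit(FM[tr, , drop = FALSE], labels[tr],
                                       lam1, lam2, p$gamma, p$epsilon))
      pr <- predict(fit, FM[!tr, , drop = FALSE])
      pred[!tr] <- as.character(pr$labels)
      score[!tr] <- pr$scores
    }
    ok <- !is.na(pred)
    counts <- confusion_counts(pred[ok], labels[ok])
    if (length(unique(as.character(labels[ok]))) < 2) {
      warning("repeat ", r, " evaluated a single class; metrics skipped")
      next
    }
    per_repeat[r, ] <- suppressWarnings(
      compute_metrics(counts, score[ok], labels[ok]))
  }
  structure(list(per_repeat = as.data.frame(per_repeat),
                 mean = colMeans(per_repeat, na.rm = TRUE),
                 sd = apply(per_repeat, 2, sd, na.rm = TRUE),
                 params = p[c("method", "k", "mu", "threshold", "tune_lambda")],
                 plan = plan),
            class = "fbn_metrics")
}

#' @export
print.fbn_metrics <- function(x, ...) {
  cat(sprintf("<fbn_metrics> %s (k=%s, mu=%s, t=%s); %d-fold CV x %d repeats\n",
              x$params$method, x$params$k, x$params$mu, x$params$threshold,
              x$plan$n_folds, x$plan$n_repeats))
  out <- sprintf("%.2f +/- %.2f", 100 * x$mean, 100 * x$sd)
  names(out) <- names(x$mean)
  print(noquote(out))
  invisible(x)
}

#' @export
summary.fbn_metrics <- function(object, ...) {
  data.frame(metric = names(object$mean),
             mean_pct = 100 * unname(object$mean),
             sd_pct = 100 * unname(object$sd))
}

#' Hyperparameter grid for the greedy search
#'
#' @param k_values neighbourhood sizes (default `{5, 10, ..., 45}`).
#' @param mu_values fusion weights (default `{0, 0.1, ..., 1}`).
#' @param threshold_values absolute thresholds (default `{0, 0.05, ..., 0.4}`).
#' @return object of class `search_grid`.
#' @export
search_grid <- function(k_values = seq(5, 45, 5), mu_values = seq(0, 1, 0.1),
                        threshold_values = seq(0, 0.4, 0.05)) {
  stopifnot(length(k_values) > 0, length(mu_values) > 0,
            length(threshold_values) > 0,
            all(mu_values >= 0 & mu_values <= 1), all(threshold_values >= 0))
  structure(list(k_values = k_values, mu_values = mu_values,
                 threshold_values = threshold_values), class = "search_grid")
}

score_candidate <- function(comp, labels, method, mu, threshold, n_folds,
                            seed, lambda = 0.01) {
  FM <- combine_features(comp, method, mu, threshold)
  set.seed(seed)
  fold <- make_folds(labels, n_folds)
  correct <- 0; total <- 0
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (length(unique(as.character(labels[tr]))) < 2 || !any(!tr)) next
    fit <- suppressWarnings(hfbn_fit(FM[tr, , drop = FALSE], labels[tr],
                                     lambda, lambda))
    pr <- predict(fit, FM[!tr, , drop = FALSE])
    correct <- correct + sum(pr$labels == labels[!tr])
    total <- total + sum(!tr)
  }
  if (total > 0) correct / total else -Inf
}

#' Greedy coordinate-wise hyperparameter search
#'
#' Optimises the neighbourhood size `k` first (with `mu` at 0.5 and
#' threshold 0), then `mu` at the best `k`, then the threshold at the best
#' `(k, mu)`. Each candidate is scored by stratified k-fold CV accuracy in
#' which every fitting step uses training folds only; ties go to the smaller
#' parameter value. The returned report re-evaluates the selected triple
#' under the full repeated-CV plan.
#'
#' @param cohort an `fbn_cohort`.
#' @param grid a [search_grid()].
#' @param plan a [cv_plan()]; its fold count and seed also drive the
#'   candidate scoring.
#' @param lambda fixed elastic-net penalty used while scoring candidates.
#' @return list with `k`, `mu`, `threshold`, `score` (selection CV accuracy)
#'   and `metrics` (an `fbn_metrics` for the selected triple).
#' @export
greedy_grid_search <- function(cohort, grid = search_grid(), plan = cv_plan(),
                               lambda = 0.01) {
  labels <- cohort$labels
  n <- nrow(cohort$subjects[[1]])
  k_values <- grid$k_values[grid$k_values <= n - 1]
  if (length(k_values) == 0) stop("no legal k in grid for n = ", n)
  comps <- list()
  get_comp <- function(k) {
    key <- as.character(k)
    if (is.null(comps[[key]])) comps[[key]] <<- feature_components(cohort, k)
    comps[[key]]
  }
  pick <- function(values, score_fn) {
    scores <- vapply(values, score_fn, 0)
    best <- which(scores == max(scores))[[1]]   # ties -> smaller value
    list(value = values[[best]], score = scores[[best]])
  }
  bk <- pick(k_values, function(k)
    score_candidate(get_comp(k), labels, "hybrid", 0.5, 0, plan$n_folds,
                    plan$seed, lambda))
  comp <- get_comp(bk$value)
  bm <- pick(grid$mu_values, function(mu)
    score_candidate(comp, labels, "hybrid", mu, 0, plan$n_folds, plan$seed,
                    lambda))
  bt <- pick(grid$threshold_values, function(t)
    score_candidate(comp, labels, "hybrid", bm$value, t, plan$n_folds,
                    plan$seed, lambda))
  metrics <- run_repeated_cv(cohort,
                             list(method = "hybrid", k = bk$value,
                                  mu = bm$value, threshold = bt$value),
                             plan)
  list(k = bk$value, mu = bm$value, threshold = bt$value, score = bt$score,
       metrics = metrics)
}
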