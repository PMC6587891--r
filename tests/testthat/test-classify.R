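test_that("1-D nearest-neighbour classification matches brute force with index tie-break", {
  expect_equal(nn_classify(c(1, 2, 3), c("a", "b", "c"), 2), "b")
  expect_equal(nn_classify(5, "patient", c(-10, 0, 100)),
               rep("patient", 3))
  # equidistant neighbours: smaller training index wins
  expect_equal(nn_classify(c(0, 2), c("lo", "hi"), 1), "lo")

  set.seed(1)
  tr <- rnorm(15); te <- rnorm(7)
  lab <- sample(c("patient", "control"), 15, replace = TRUE)
  got <- nn_classify(tr, lab, te)
  for (i in seq_along(te)) {
    d <- abs(tr - te[i])
    expect_equal(got[i], lab[which(d == min(d))[1]])
  }
  expect_error(nn_classify(numeric(0), character(0), 1), "empty")
})

test_that("metrics follow their defining formulas, including undefined ratios", {
  m <- compute_metrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(unname(m["ACC"]), 0.85)
  expect_equal(unname(m["SEN"]), 0.9)
  expect_equal(unname(m["SPE"]), 0.8)
  expect_equal(unname(m["BAC"]), 0.85)
  expect_equal(unname(m["PPV"]), 9 / 11)
  expect_equal(unname(m["NPV"]), 8 / 9)
  expect_equal(unname(m["F1"]), 2 * 0.9 * (9 / 11) / (0.9 + 9 / 11))

  expect_warning(m0 <- compute_metrics(list(TP = 0, FN = 0, TN = 5, FP = 5)),
                 "SEN undefined")
  expect_true(is.nan(m0[["SEN"]]))
})

test_that("rank AUC equals the all-pairs Mann-Whitney oracle, ties included", {
  lab <- rep(c("patient", "control"), c(4, 4))
  expect_equal(auc_rank(c(5, 6, 7, 8, 1, 2, 3, 4), lab), 1)
  expect_equal(auc_rank(c(1, 2, 3, 4, 5, 6, 7, 8), lab), 0)
  set.seed(2)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    l <- sample(c("patient", "control"), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc_rank(s, l), oracle_auc_pairs(s, l), tolerance = 1e-12)
  }
})

test_that("DeLong comparison handles self-comparison, agrees with pROC and bootstrap variance", {
  set.seed(3)
  n <- 20
  lab <- rep(c("patient", "control"), each = n)
  sA <- c(rnorm(n, 1), rnorm(n, 0))
  sB <- 0.6 * sA + 0.4 * c(rnorm(n, 0.5), rnorm(n, 0))

  expect_equal(delong_compare(sA, sA, lab)$p, 1)

  res <- delong_compare(sA, sB, lab)
  pr <- pROC::roc.test(pROC::roc(lab, sA, levels = c("control", "patient"),
                                 direction = "<", quiet = TRUE),
                       pROC::roc(lab, sB, levels = c("control", "patient"),
                                 direction = "<", quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(res$p, pr$p.value, tolerance = 1e-9)

  # stratified bootstrap variance of the AUC difference
  B <- 1e4
  set.seed(4)
  d <- replicate(B, {
    ip <- sample(n, replace = TRUE); ic <- n + sample(n, replace = TRUE)
    a1 <- oracle_auc_pairs(c(sA[ip], sA[ic]), lab)
    a2 <- oracle_auc_pairs(c(sB[ip], sB[ic]), lab)
    a1 - a2
  })
  expect_lt(abs(res$var_diff - var(d)) / var(d), 0.15)
})

test_that("cross-validation folds partition subjects with balanced classes and are reproducible", {
  spec <- tiny_cohort_spec(seed = 8)
  co <- generate_cohort(spec)
  plan <- cv_plan(n_folds = 5, n_repeats = 2, seed = 10)
  set.seed(plan$seed)
  fold <- hybridFBN:::make_folds(co$labels, 5)
  expect_equal(sort(unique(fold)), 1:5)
  expect_length(fold, 20)
  tab <- table(fold, co$labels)
  expect_lte(max(tab) - min(tab), 1)

  params <- list(method = "pearson", tune_lambda = FALSE)
  m1 <- run_repeated_cv(co, params, plan)
  m2 <- run_repeated_cv(co, params, plan)
  expect_identical(m1$per_repeat, m2$per_repeat)
  expect_equal(unname(m1$mean["BAC"]),
               unname((m1$mean["SEN"] + m1$mean["SPE"]) / 2))
})

test_that("greedy search returns singleton grids unchanged and is deterministic", {
  spec <- tiny_cohort_spec(seed = 12)
  co <- generate_cohort(spec)
  g1 <- search_grid(k_values = 3, mu_values = 0.4, threshold_values = 0.05)
  plan <- cv_plan(n_folds = 5, n_repeats = 1, seed = 2)
  res <- greedy_grid_search(co, g1, plan)
  expect_equal(res$k, 3)
  expect_equal(res$mu, 0.4)
  expect_equal(res$threshold, 0.05)

  g2 <- search_grid(k_values = c(2, 4), mu_values = c(0.2, 0.8),
                    threshold_values = c(0, 0.1))
  r1 <- greedy_grid_search(co, g2, plan)
  r2 <- greedy_grid_search(co, g2, plan)
  expect_equal(r1[c("k", "mu", "threshold", "score")],
               r2[c("k", "mu", "threshold", "score")])
})

test_that("the fitted pipeline model predicts its own training data well on separable input", {
  set.seed(13)
  n <- 16
  F <- rbind(matrix(rnorm(n * 6, 1), n, 6), matrix(rnorm(n * 6, -1), n, 6))
  F <- abs(F)  # non-negative features suit the non-negative selector
  F[1:n, 1] <- F[1:n, 1] + 2
  lab <- factor(rep(c("patient", "control"), each = n),
                levels = c("control", "patient"))
  fit <- hfbn_fit(F, lab, 0.01, 0.01)
  pr <- predict(fit, F)
  expect_gt(mean(pr$labels == lab), 0.9)
  expect_gt(mean(pr$scores[1:n]), mean(pr$scores[(n + 1):(2 * n)]))
})
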