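test_that("stratified split: proportions, disjointness, reproducibility", {
  tab <- toy_labeled_table(200)  # 400 rows balanced
  sp <- split_train_test(tab, 0.25, seed = 1)
  expect_equal(nrow(sp$train), 300)
  expect_equal(nrow(sp$test), 100)
  expect_equal(sum(sp$test$CLASS == 1), 50)
  expect_equal(nrow(rbind(sp$train, sp$test)), nrow(tab))

  # odd counts: class proportions preserved within one row
  tab2 <- toy_labeled_table(30)[c(1:31, 35:60), ]
  sp2 <- split_train_test(tab2, 0.25, seed = 2)
  for (cl in 0:1) {
    n_cl <- sum(tab2$CLASS == cl)
    expect_lte(abs(sum(sp2$test$CLASS == cl) - 0.25 * n_cl), 1)
  }
  sp3 <- split_train_test(tab, 0.25, seed = 1)
  expect_identical(sp3$test, sp$test)
})

test_that("metric formulas match hand arithmetic and edge cases", {
  m <- metrics_from_counts(40, 45, 5, 10)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["precision"]), 40 / 45)
  expect_equal(unname(m["recall"]), 0.8)
  expect_equal(unname(m["mcc"]),
               (40 * 45 - 5 * 10) / sqrt(45 * 50 * 50 * 55))

  perfect <- metrics_from_counts(50, 50, 0, 0)
  expect_equal(unname(perfect), rep(1, 4))

  # all predicted positive on a balanced test: accuracy .5, mcc 0
  expect_warning(all_pos <- metrics_from_counts(50, 0, 50, 0), "undefined")
  expect_equal(unname(all_pos["accuracy"]), 0.5)
  expect_equal(unname(all_pos["mcc"]), 0)
})

test_that("grid search matches brute-force re-evaluation on fixed folds", {
  tab <- toy_labeled_table(40, shift = 1.2, seed = 3)
  grids <- default_grids()
  grids$random_forest <- expand.grid(n_estimators = c(10, 40),
                                     max_features = c("sqrt", "log2"),
                                     criterion = "gini",
                                     stringsAsFactors = FALSE)
  fit <- tune_and_fit("random_forest", tab, cv_folds = 5, grids = grids,
                      seed = 5)
  cvt <- fit$cv_table
  # winner is the first grid row attaining the maximal CV accuracy
  expect_equal(which(cvt$cv_accuracy == max(cvt$cv_accuracy))[1],
               which(cvt$n_estimators == fit$best_params$n_estimators &
                     cvt$max_features == fit$best_params$max_features))
  # brute-force recomputation of one grid point on the same folds
  g <- 2L
  fold <- divorph:::make_folds(tab$CLASS, 5, seed = 5)
  hits <- 0L
  for (k in 1:5) {
    f <- divorph:::fit_one("random_forest", tab[fold != k, ],
                           as.list(cvt[g, 1:3]), 5, seed = 5 + k)
    hits <- hits + sum(divorph:::predict_class(
      f, divorph:::feature_matrix(tab[fold == k, ])) ==
        tab$CLASS[fold == k])
  }
  expect_equal(hits / nrow(tab), cvt$cv_accuracy[g])

  # grid of size one returns that configuration
  grids$random_forest <- grids$random_forest[2, , drop = FALSE]
  fit1 <- tune_and_fit("random_forest", tab, grids = grids, seed = 5)
  expect_equal(fit1$best_params$n_estimators, 40)
})

test_that("all four models learn a linearly separable table", {
  tab <- toy_labeled_table(60, shift = 6, seed = 4)  # wide separation
  grids <- default_grids()
  grids$random_forest <- grids$random_forest[grids$random_forest$n_estimators == 50, ][1:2, ]
  grids$gradient_boosting <- grids$gradient_boosting[1:2, ]
  grids$bayes <- data.frame(var_smoothing = 1:3)
  sp <- split_train_test(tab, 0.25, seed = 4)
  for (m in MODEL_NAMES) {
    fit <- tune_and_fit(m, sp$train, grids = grids, seed = 4)
    rep <- evaluate(fit, sp$test)
    expect_gte(rep$metrics[["accuracy"]], 0.95)
    if (m == "logreg") expect_gte(fit$cv_accuracy, 0.99)
  }
})

test_that("permutation importance finds the planted feature", {
  set.seed(6)
  n <- 160
  tab <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                    flat = rep(1, n))
  tab$CLASS <- as.integer(tab$signal > 0)
  grids <- default_grids()
  grids$random_forest <- grids$random_forest[1, , drop = FALSE]
  fit <- tune_and_fit("random_forest", tab, grids = grids, seed = 6)
  imp <- importance(fit, tab, "permutation", seed = 7)
  expect_equal(imp$feature[1], "signal")
  expect_equal(imp$importance[imp$feature == "flat"], 0)
  imp2 <- importance(fit, tab, "permutation", seed = 7)
  expect_identical(imp, imp2)

  lfit <- tune_and_fit("logreg", tab, seed = 6)
  co <- importance(lfit, method = "coefficient")
  expect_equal(co$feature[1], "signal")
})

test_that("ensemble vote matches the 2-of-3 threshold on all 8 patterns", {
  votes <- expand.grid(logreg = 0:1, random_forest = 0:1,
                       gradient_boosting = 0:1)
  out <- ensemble_call(votes)
  expect_equal(out$divergent,
               rowSums(votes) >= 2)
  expect_error(ensemble_call(votes[, 1:2]), "missing model vote")
})
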