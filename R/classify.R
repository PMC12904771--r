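# The four classifiers (Gaussian naive Bayes, logistic regression via
# glmnet's built-in cross-validation, random forest and gradient boosting on
# the package's CART engine), grid-search tuning by 5-fold CV accuracy,
# evaluation metrics, feature importances and the 2-of-3 ensemble call.
# Positive class (CLASS = 1) is always simulated/divergent.

#' The four classifier names
#' @export
MODEL_NAMES <- c("bayes", "logreg", "random_forest", "gradient_boosting")

feature_matrix <- function(table) {
  as.matrix(table[setdiff(names(table), c("query_id", "CLASS"))])
}

#' Stratified train/test split
#'
#' @param table A labeled feature table with a binary `CLASS` column.
#' @param test_fraction Fraction held out (default 0.25).
#' @param seed Optional seed.
#' @return List with `train` and `test` tables (disjoint, union = input,
#'   class proportions preserved within one row).
#' @export
split_train_test <- function(table, test_fraction = 0.25, seed = NULL) {
  stopifnot("CLASS" %in% names(table), test_fraction > 0, test_fraction < 1)
  counts <- table(table$CLASS)
  if (length(counts) < 2L || any(counts < 2L))
    stop("both classes need >= 2 rows for a stratified split")
  if (!is.null(seed)) set.seed(seed)
  test_idx <- unlist(lapply(split(seq_len(nrow(table)), table$CLASS),
                            function(ix) sample(ix, round(length(ix) * test_fraction))))
  list(train = table[-test_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE])
}

# stratified fold assignment 1..k
make_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- which(y == cls)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

#' Default hyperparameter grids
#'
#' The full replication grids (random forest: estimators 1..951 in steps
#' of 50, max features sqrt/log2, criterion gini/entropy/log-loss; gradient
#' boosting adds learning rate 0.1..1 and log-loss/exponential loss; naive
#' Bayes: var smoothing 1..20) are large.
#' The default is a reduced desk-scale grid (estimators 50/200/500);
#' `paper_grid = TRUE` restores the full sweep. For binary splits the
#' log-loss criterion coincides with entropy and is treated as its alias.
#'
#' @param paper_grid Use the full replication grids.
#' @param log_smoothing Use a log-scale naive-Bayes smoothing grid instead
#'   of the unusually large literal 1..20 grid.
#' @return Named list of per-model grids (data frames).
#' @export
default_grids <- function(paper_grid = FALSE, log_smoothing = FALSE) {
  est <- if (paper_grid) seq(1, 1000, by = 50) else c(50, 200, 500)
  lr <- if (paper_grid) seq(0.1, 1, by = 0.1) else c(0.1, 0.5, 1)
  crit <- if (paper_grid) c("gini", "entropy", "log_loss") else c("gini", "entropy")
  gb_mf <- if (paper_grid) c("sqrt", "log2") else "sqrt"
  vs <- if (log_smoothing) 10^seq(-9, 0) else 1:20
  list(
    bayes = expand.grid(var_smoothing = vs),
    logreg = NULL,  # glmnet's built-in regularization-path CV
    random_forest = expand.grid(n_estimators = est,
                                max_features = c("sqrt", "log2"),
                                criterion = crit,
                                stringsAsFactors = FALSE),
    gradient_boosting = expand.grid(n_estimators = est,
                                    learning_rate = lr,
                                    loss = c("log_loss", "exponential"),
                                    max_features = gb_mf,
                                    stringsAsFactors = FALSE))
}

## ---- Gaussian naive Bayes ------------------------------------------------

fit_bayes <- function(X, y, var_smoothing = 1) {
  stats_by <- function(cls) {
    Xi <- X[y == cls, , drop = FALSE]
    list(mean = colMeans(Xi),
         var = apply(Xi, 2, stats::var),
         prior = nrow(Xi) / nrow(X))
  }
  mod <- list(classes = c(0L, 1L),
              stats = list(stats_by(0L), stats_by(1L)),
              var_smoothing = var_smoothing)
  eps <- var_smoothing * max(vapply(mod$stats, function(s) max(s$var), numeric(1)),
                             .Machine$double.eps)
  for (k in 1:2) mod$stats[[k]]$var <- mod$stats[[k]]$var + eps
  structure(mod, class = "divorph_bayes")
}

predict_bayes <- function(fit, X) {
  ll <- vapply(1:2, function(k) {
    s <- fit$stats[[k]]
    rowSums(dnorm(X, rep(s$mean, each = nrow(X)),
                  rep(sqrt(s$var), each = nrow(X)), log = TRUE)) + log(s$prior)
  }, numeric(nrow(X)))
  as.integer(ll[, 2L] > ll[, 1L])
}

## ---- logistic regression (glmnet built-in CV) ----------------------------

fit_logreg <- function(X, y, cv_folds = 5, seed = NULL) {
  foldid <- make_folds(y, cv_folds, seed)
  fit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                           foldid = foldid, type.measure = "class")
  structure(list(fit = fit), class = "divorph_logreg")
}

predict_logreg_glmnet <- function(fit, X) {
  as.integer(predict(fit$fit, X, s = "lambda.min", type = "class"))
}

## ---- random forest -------------------------------------------------------

mtry_of <- function(max_features, p) {
  switch(max_features,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         stop("unknown max_features: ", max_features))
}

fit_rf <- function(X, y, n_estimators = 200, max_features = "sqrt",
                   criterion = "gini", max_depth = 25L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  crit <- if (criterion %in% c("entropy", "log_loss")) 1L else 0L
  n <- nrow(X); p <- ncol(X)
  w <- rep(1, n)
  trees <- lapply(seq_len(n_estimators), function(b) {
    idx <- sample.int(n, n, replace = TRUE) - 1L
    .cpp_grow_tree(X, as.numeric(y), w, idx, FALSE, crit,
                   mtry_of(max_features, p), max_depth, 2L,
                   sample.int(.Machine$integer.max, 1L))
  })
  structure(list(trees = trees, p = p), class = "divorph_rf")
}

rf_prob <- function(fit, X) {
  probs <- vapply(fit$trees, function(tr) {
    leaf <- .cpp_tree_apply(tr, X) + 1L
    tr$value[leaf]
  }, numeric(nrow(X)))
  rowMeans(probs)
}

predict_rf <- function(fit, X) as.integer(rf_prob(fit, X) >= 0.5)

## ---- gradient boosting ---------------------------------------------------

# Friedman gradient boosting with depth-3 regression trees on the negative
# gradient; leaf values are one Newton step. loss = "log_loss" (binomial
# deviance) or "exponential" (AdaBoost).

fit_gb <- function(X, y, n_estimators = 200, learning_rate = 0.1,
                   loss = "log_loss", max_features = "sqrt",
                   max_depth = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  w <- rep(1, n)
  ybar <- mean(y)
  ybar <- min(max(ybar, 1e-6), 1 - 1e-6)
  f0 <- if (loss == "log_loss") log(ybar / (1 - ybar))
        else 0.5 * log(ybar / (1 - ybar))
  Fx <- rep(f0, n)
  ypm <- 2 * y - 1
  trees <- vector("list", n_estimators)
  gammas <- vector("list", n_estimators)
  idx <- seq_len(n) - 1L
  for (m in seq_len(n_estimators)) {
    if (loss == "log_loss") {
      pr <- 1 / (1 + exp(-Fx))
      r <- y - pr
      den_fun <- function(leaf_rows) {
        d <- sum(pr[leaf_rows] * (1 - pr[leaf_rows]))
        if (d < 1e-10) 1e-10 else d
      }
      num <- r
    } else {
      ew <- exp(-ypm * Fx)
      r <- ypm * ew
      den_fun <- function(leaf_rows) {
        d <- sum(ew[leaf_rows])
        if (d < 1e-10) 1e-10 else d
      }
      num <- r
    }
    tr <- .cpp_grow_tree(X, r, w, idx, TRUE, 0L, mtry_of(max_features, p),
                         max_depth, 2L, sample.int(.Machine$integer.max, 1L))
    leaf <- .cpp_tree_apply(tr, X) + 1L
    gam <- vapply(split(seq_len(n), leaf), function(rows)
      sum(num[rows]) / den_fun(rows), numeric(1))
    gam_full <- numeric(length(tr$value))
    gam_full[as.integer(names(gam))] <- gam
    Fx <- Fx + learning_rate * gam_full[leaf]
    trees[[m]] <- tr
    gammas[[m]] <- gam_full
  }
  structure(list(trees = trees, gammas = gammas, f0 = f0,
                 learning_rate = learning_rate, loss = loss),
            class = "divorph_gb")
}

gb_score <- function(fit, X) {
  Fx <- rep(fit$f0, nrow(X))
  for (m in seq_along(fit$trees)) {
    leaf <- .cpp_tree_apply(fit$trees[[m]], X) + 1L
    Fx <- Fx + fit$learning_rate * fit$gammas[[m]][leaf]
  }
  Fx
}

predict_gb <- function(fit, X) as.integer(gb_score(fit, X) > 0)

## ---- common surface ------------------------------------------------------

predict_class <- function(fit, X) {
  if (inherits(fit, "divorph_bayes")) predict_bayes(fit, X)
  else if (inherits(fit, "divorph_logreg")) predict_logreg_glmnet(fit, X)
  else if (inherits(fit, "divorph_rf")) predict_rf(fit, X)
  else if (inherits(fit, "divorph_gb")) predict_gb(fit, X)
  else stop("not a divorph model fit")
}

#' Predict 0/1 labels from a tuned model
#'
#' @param model A `divorph_model` from [tune_and_fit].
#' @param table A feature table (same scaling as the training table).
#' @return Integer vector of 0/1 predictions (1 = divergent).
#' @export
predict_labels <- function(model, table) {
  predict_class(model$fit, feature_matrix(table))
}

fit_one <- function(name, train, config, cv_folds, seed) {
  X <- feature_matrix(train); y <- train$CLASS
  switch(name,
    bayes = fit_bayes(X, y, var_smoothing = config$var_smoothing),
    logreg = fit_logreg(X, y, cv_folds = cv_folds, seed = seed),
    random_forest = fit_rf(X, y, n_estimators = config$n_estimators,
                           max_features = config$max_features,
                           criterion = config$criterion, seed = seed),
    gradient_boosting = fit_gb(X, y, n_estimators = config$n_estimators,
                               learning_rate = config$learning_rate,
                               loss = config$loss,
                               max_features = config$max_features,
                               seed = seed),
    stop("unknown model: ", name))
}

#' Grid-search tuning by cross-validated accuracy
#'
#' Exhaustive search over the model's grid, scored by mean accuracy over
#' stratified k-fold cross-validation on fixed folds; ties go to the first
#' configuration in grid order. The winning configuration is refit on the
#' full training table. Logistic regression has no external grid: glmnet's
#' built-in cross-validation selects the regularization strength.
#'
#' @param model_name One of `"bayes"`, `"logreg"`, `"random_forest"`,
#'   `"gradient_boosting"`.
#' @param train Scaled labeled training table.
#' @param cv_folds Number of CV folds (default 5).
#' @param grids Grids as from [default_grids].
#' @param seed Seed controlling folds and stochastic fits.
#' @return A list of class `divorph_model`: `name`, `fit`, `best_params`,
#'   `cv_accuracy`, `cv_table`.
#' @export
tune_and_fit <- function(model_name, train, cv_folds = 5,
                         grids = default_grids(), seed = 1L) {
  model_name <- match.arg(model_name, MODEL_NAMES)
  grid <- grids[[model_name]]
  y <- train$CLASS
  if (min(table(y)) < cv_folds)
    stop("too few rows per class for ", cv_folds, "-fold CV")
  if (is.null(grid)) {  # logreg
    fit <- fit_one("logreg", train, NULL, cv_folds, seed)
    lmin <- fit$fit$lambda.min
    cvacc <- 1 - fit$fit$cvm[fit$fit$lambda == lmin]
    return(structure(list(name = model_name, fit = fit,
                          best_params = list(lambda = lmin),
                          cv_accuracy = cvacc, cv_table = NULL),
                     class = "divorph_model"))
  }
  fold <- make_folds(y, cv_folds, seed)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    config <- as.list(grid[g, , drop = FALSE])
    hits <- 0L
    for (k in seq_len(cv_folds)) {
      tr <- train[fold != k, , drop = FALSE]
      te <- train[fold == k, , drop = FALSE]
      f <- fit_one(model_name, tr, config, cv_folds, seed + k)
      hits <- hits + sum(predict_class(f, feature_matrix(te)) == te$CLASS)
    }
    acc[g] <- hits / nrow(train)
  }
  best <- which.max(acc)  # ties -> first in grid order
  config <- as.list(grid[best, , drop = FALSE])
  fit <- fit_one(model_name, train, config, cv_folds, seed)
  structure(list(name = model_name, fit = fit, best_params = config,
                 cv_accuracy = acc[best],
                 cv_table = cbind(grid, cv_accuracy = acc)),
            class = "divorph_model")
}

#' Binary classification metrics from a confusion matrix
#'
#' Accuracy, precision, recall and Matthews correlation coefficient.
#' Undefined denominators yield 0 with a warning.
#'
#' @param tp,tn,fp,fn Confusion counts (positive class = divergent).
#' @return Named numeric vector.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  safe <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (0 denominator); reporting 0"); 0 }
    else num / den
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(accuracy = safe(tp + tn, tp + tn + fp + fn, "accuracy"),
    precision = safe(tp, tp + fp, "precision"),
    recall = safe(tp, tp + fn, "recall"),
    mcc = if (mcc_den == 0) { warning("MCC undefined; reporting 0"); 0 }
          else (tp * tn - fp * fn) / mcc_den)
}

#' Evaluate a tuned model on a test table
#'
#' @param model A `divorph_model`.
#' @param test Scaled labeled test table.
#' @return A list of class `model_report`: name, best hyperparameters,
#'   metrics and the confusion counts.
#' @export
evaluate <- function(model, test) {
  stopifnot(nrow(test) > 0)
  pred <- predict_labels(model, test)
  truth <- test$CLASS
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  structure(list(name = model$name, best_params = model$best_params,
                 metrics = metrics_from_counts(tp, tn, fp, fn),
                 confusion = c(tp = tp, tn = tn, fp = fp, fn = fn)),
            class = "model_report")
}

#' Feature importance
#'
#' Permutation importance (mean accuracy drop over `n_repeats` shuffles of
#' one feature column at a time, on the test table) or, for logistic
#' regression, signed coefficients ranked by absolute value.
#'
#' @param model A `divorph_model`.
#' @param test Scaled labeled table (permutation method).
#' @param method "permutation" or "coefficient".
#' @param n_repeats Shuffles per feature (default 10).
#' @param seed Seed for the shuffles.
#' @param top Keep the top-n features (default 10).
#' @return A `data.frame` with feature, importance and method, ranked.
#' @export
importance <- function(model, test = NULL,
                       method = c("permutation", "coefficient"),
                       n_repeats = 10, seed = 1L, top = 10L) {
  method <- match.arg(method)
  if (method == "coefficient") {
    if (!inherits(model$fit, "divorph_logreg"))
      stop("coefficient importance requires the logistic regression model")
    cf <- as.matrix(stats::coef(model$fit$fit, s = "lambda.min"))
    cf <- cf[rownames(cf) != "(Intercept)", 1L]
    out <- data.frame(feature = names(cf), importance = unname(cf),
                      method = "coefficient", stringsAsFactors = FALSE)
    out <- out[order(-abs(out$importance)), , drop = FALSE]
  } else {
    stopifnot(!is.null(test))
    set.seed(seed)
    X <- feature_matrix(test); truth <- test$CLASS
    base_acc <- mean(predict_class(model$fit, X) == truth)
    drops <- vapply(colnames(X), function(f) {
      mean(vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, f] <- sample(Xp[, f])
        base_acc - mean(predict_class(model$fit, Xp) == truth)
      }, numeric(1)))
    }, numeric(1))
    out <- data.frame(feature = names(drops), importance = unname(drops),
                      method = "permutation", stringsAsFactors = FALSE)
    out <- out[order(-out$importance), , drop = FALSE]
  }
  rownames(out) <- NULL
  utils::head(out, top)
}

#' Majority-vote ensemble divergence call
#'
#' Combines the binary votes of logistic regression, random forest and
#' gradient boosting (naive Bayes is excluded for its consistently poorer
#' performance): a query is called divergent when at least two of the three
#' models vote divergent.
#'
#' @param votes A `data.frame` with columns `logreg`, `random_forest`,
#'   `gradient_boosting` (0/1), and optionally `query_id`.
#' @return The input with a `divergent` logical column appended.
#' @export
ensemble_call <- function(votes) {
  need <- c("logreg", "random_forest", "gradient_boosting")
  missing <- setdiff(need, names(votes))
  if (length(missing)) stop("missing model vote(s): ",
                            paste(missing, collapse = ", "))
  votes$divergent <- rowSums(votes[need]) >= 2
  votes
}

#' Train, evaluate and ensemble on one labeled dataset
#'
#' Convenience wrapper running the full supervised stage: stratified 75/25
#' split, z-scaling fitted on the training split (leak-free; set
#' `scale_on_all = TRUE` to replicate whole-table scaling), grid-search
#' tuning of the requested models, per-model test metrics, and the 2-of-3
#' ensemble accuracy on the test split.
#'
#' @param dataset Labeled unscaled feature table with `CLASS`.
#' @param models Model names to train (default all four).
#' @param cv_folds,grids,seed Passed to [tune_and_fit].
#' @param test_fraction Held-out fraction (default 0.25).
#' @param scale_on_all Fit the scaler on the combined table.
#' @return A list of class `classification_run`: `models`, `reports` (each
#'   with test metrics and top-10 feature importances: permutation for
#'   bayes/forest/boosting, signed coefficients for logreg),
#'   `ensemble_accuracy`, `votes`, `scaler`, `split`.
#' @export
run_classification <- function(dataset, models = MODEL_NAMES, cv_folds = 5,
                               grids = default_grids(), seed = 1L,
                               test_fraction = 0.25, scale_on_all = FALSE) {
  split <- split_train_test(dataset, test_fraction, seed = seed)
  scaler <- fit_scaler(if (scale_on_all) dataset else split$train)
  train <- suppressWarnings(apply_scaler(split$train, scaler))
  test <- suppressWarnings(apply_scaler(split$test, scaler))
  fits <- lapply(models, function(m)
    tune_and_fit(m, train, cv_folds = cv_folds, grids = grids, seed = seed))
  names(fits) <- models
  reports <- lapply(fits, function(f) {
    rep <- evaluate(f, test)
    rep$importances <- if (f$name == "logreg")
      importance(f, method = "coefficient")
    else importance(f, test, method = "permutation", seed = seed)
    rep
  })
  ens_acc <- NA_real_
  votes <- NULL
  voters <- c("logreg", "random_forest", "gradient_boosting")
  if (all(voters %in% models)) {
    votes <- as.data.frame(lapply(fits[voters], predict_labels, table = test))
    votes <- ensemble_call(votes)
    ens_acc <- mean(as.integer(votes$divergent) == test$CLASS)
  }
  structure(list(models = fits, reports = reports,
                 ensemble_accuracy = ens_acc, votes = votes,
                 scaler = scaler, split = list(train = train, test = test)),
            class = "classification_run")
}
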