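# Tree-ensemble regressors: gradient boosting ("XGB"), AdaBoost.R2 ("AB")
# and random forest ("RF") over in-package CART regression trees, plus the
# 5-fold cross-validated hyperparameter search.

DEFAULT_N_GRID     <- c(50L, 100L, 200L, 400L)
DEFAULT_DEPTH_GRID <- c(2L, 3L, 4L, 6L)

#' Fit a single regression tree
#'
#' Exact greedy CART with the weighted squared-error criterion, depth
#' limited. Mostly an internal building block for [train_ensemble()].
#'
#' @param X Numeric matrix (samples x features).
#' @param y Numeric response.
#' @param w Optional sample weights (default uniform).
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf Minimum samples per leaf (default 1).
#' @param feature_subset Optional integer vector of 1-based candidate
#'   feature columns (default all).
#' @return A `cp_tree` (node arrays).
#' @export
fit_tree <- function(X, y, w = NULL, max_depth = 4L, min_leaf = 1L,
                     feature_subset = NULL) {
  X <- as.matrix(X)
  w <- w %||% rep(1, nrow(X))
  stopifnot(length(y) == nrow(X), length(w) == nrow(X))
  fs <- (feature_subset %||% seq_len(ncol(X))) - 1L
  tr <- .tree_fit_cpp(X, as.numeric(y), as.numeric(w), as.integer(max_depth),
                      as.integer(min_leaf), as.integer(fs))
  class(tr) <- "cp_tree"
  tr
}

#' @noRd
predict_tree <- function(tree, X) .tree_predict_cpp(tree, as.matrix(X))

#' Train a tree ensemble
#'
#' Three aggregation strategies over depth-limited CART trees:
#' * `"XGB"`: least-squares gradient boosting with shrinkage
#'   (`learning_rate`, default 0.1); each tree fits the current residuals.
#' * `"AB"`: AdaBoost.R2 with linear loss; trees are fit with adaptive
#'   sample weights and combined by the weighted median.
#' * `"RF"`: bagging with bootstrap resampling and per-tree random feature
#'   subsets (`mtry = max(1, floor(p/3))`); trees are averaged.
#'
#' @param X Numeric matrix or data.frame (samples x features).
#' @param y Numeric response.
#' @param algorithm `"XGB"`, `"AB"` or `"RF"`.
#' @param n_estimators Number of trees.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed (bootstrap / feature subsampling).
#' @param learning_rate Shrinkage for `"XGB"` (default 0.1).
#' @param min_leaf Minimum samples per leaf (default 2).
#' @return A `tree_ensemble` object.
#' @export
train_ensemble <- function(X, y, algorithm = c("XGB", "AB", "RF"),
                           n_estimators = 100L, max_depth = 3L, seed = 1L,
                           learning_rate = 0.1, min_leaf = 2L) {
  algorithm <- match.arg(algorithm)
  Xm <- as.matrix(X)
  storage.mode(Xm) <- "double"
  y <- as.numeric(y)
  if (stats::var(y) == 0)
    cp_stop("train_ensemble(): degenerate target (zero variance)")
  n <- nrow(Xm); p <- ncol(Xm)
  set.seed(as.integer(seed))
  trees <- vector("list", n_estimators)
  betas <- NULL
  base <- 0

  if (algorithm == "XGB") {
    base <- mean(y)
    resid <- y - base
    for (m in seq_len(n_estimators)) {
      tr <- fit_tree(Xm, resid, max_depth = max_depth, min_leaf = min_leaf)
      resid <- resid - learning_rate * predict_tree(tr, Xm)
      trees[[m]] <- tr
    }
  } else if (algorithm == "AB") {
    w <- rep(1 / n, n)
    betas <- numeric(0)
    kept <- list()
    for (m in seq_len(n_estimators)) {
      tr <- fit_tree(Xm, y, w = w, max_depth = max_depth, min_leaf = min_leaf)
      pred <- predict_tree(tr, Xm)
      aerr <- abs(y - pred)
      emax <- max(aerr)
      if (emax <= 0) { kept[[length(kept) + 1L]] <- tr; betas <- c(betas, 1e-10); break }
      err <- aerr / emax
      ebar <- sum(w * err)
      if (ebar >= 0.5) {
        if (length(kept) == 0) { kept[[1L]] <- tr; betas <- 0.5 / (1 - 0.5) }
        break
      }
      beta <- max(ebar / (1 - ebar), 1e-10)
      kept[[length(kept) + 1L]] <- tr
      betas <- c(betas, beta)
      w <- w * beta^(1 - err)
      w <- w / sum(w)
    }
    trees <- kept
  } else { # RF
    mtry <- max(1L, floor(p / 3))
    for (m in seq_len(n_estimators)) {
      boot <- sample.int(n, n, replace = TRUE)
      fs <- sort(sample.int(p, mtry))
      tr <- fit_tree(Xm[boot, , drop = FALSE], y[boot], max_depth = max_depth,
                     min_leaf = min_leaf, feature_subset = fs)
      trees[[m]] <- tr
    }
  }

  structure(list(algorithm = algorithm, trees = trees, base = base,
                 learning_rate = learning_rate, betas = betas,
                 n_estimators = length(trees), max_depth = max_depth,
                 feature_names = colnames(Xm), seed = seed,
                 format_version = 1L),
            class = "tree_ensemble")
}

#' Predict from a tree ensemble
#'
#' @param object A `tree_ensemble`.
#' @param newdata Matrix or data.frame with the training feature columns.
#' @param n_trees Use only the first `n_trees` trees (prefix evaluation;
#'   default all). Supports the shared-fit grid search over `n_estimators`.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.tree_ensemble <- function(object, newdata, n_trees = NULL, ...) {
  Xm <- ensemble_matrix(object, newdata)
  k <- min(n_trees %||% object$n_estimators, object$n_estimators)
  if (k < 1) cp_stop("predict.tree_ensemble(): need at least one tree")
  preds <- vapply(object$trees[seq_len(k)],
                  function(tr) predict_tree(tr, Xm), numeric(nrow(Xm)))
  preds <- matrix(preds, nrow = nrow(Xm))
  switch(object$algorithm,
    XGB = object$base + object$learning_rate * rowSums(preds),
    RF  = rowMeans(preds),
    AB  = weighted_median_rows(preds, log(1 / object$betas[seq_len(k)])))
}

# Row-wise weighted median of predictions (AdaBoost.R2 combination rule).
#' @noRd
weighted_median_rows <- function(preds, wts) {
  wts <- pmax(wts, 0)
  if (sum(wts) <= 0) wts <- rep(1, length(wts))
  apply(preds, 1, function(v) {
    o <- order(v)
    cw <- cumsum(wts[o])
    v[o][which(cw >= 0.5 * sum(wts))[1]]
  })
}

#' @noRd
ensemble_matrix <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing_cols) > 0)
      cp_stop("feature-name mismatch with training: missing %s",
              paste(missing_cols, collapse = ", "))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    if (!identical(colnames(newdata), object$feature_names)) {
      if (!all(object$feature_names %in% colnames(newdata)))
        cp_stop("feature-name mismatch with training")
      newdata <- newdata[, object$feature_names, drop = FALSE]
    }
  }
  Xm <- as.matrix(newdata)
  storage.mode(Xm) <- "double"
  Xm
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("tree_ensemble %s: %d trees, max_depth %d\n",
              x$algorithm, x$n_estimators, x$max_depth))
  invisible(x)
}

#' Stratified train/validation split
#'
#' @param strata Factor-like vector (e.g. treatment labels).
#' @param ratio Train:validation ratio (default 5, i.e. 5:1).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
stratified_split <- function(strata, ratio = 5, seed = 1L) {
  set.seed(as.integer(seed))
  idx_val <- integer(0)
  for (g in unique(strata)) {
    ig <- which(strata == g)
    n_val <- max(1L, round(length(ig) / (ratio + 1)))
    if (length(ig) <= 1) next
    idx_val <- c(idx_val, sample(ig, n_val))
  }
  list(train = setdiff(seq_along(strata), idx_val), validation = sort(idx_val))
}

#' Tune and train an ensemble with 5-fold cross-validation
#'
#' Splits the data 5:1 into training and validation (stratified by
#' `strata` when given), grid-searches `n_estimators` and `max_depth` by
#' mean 5-fold CV R-squared on the training part (one shared fit per depth
#' and fold, evaluated at every `n_estimators` prefix), and refits the best
#' configuration on the full training part. Ties prefer the smaller model.
#'
#' @param features Matrix or data.frame of predictors.
#' @param target_values Numeric response (>= 30 samples).
#' @param algorithm `"XGB"`, `"AB"` or `"RF"`.
#' @param seed Integer seed (split, folds, tree randomness).
#' @param strata Optional stratification labels for the 5:1 split.
#' @param n_grid,depth_grid Hyperparameter grids (defaults
#'   `c(50, 100, 200, 400)` and `c(2, 3, 4, 6)`).
#' @param cv_folds Number of CV folds (default 5).
#' @param target_name Label stored in the bundle (for reporting).
#' @return A `model_bundle`: the fitted `model`, tuned `n_estimators` and
#'   `max_depth`, the CV table, and the train/validation indices.
#' @export
tune_and_train <- function(features, target_values,
                           algorithm = c("XGB", "AB", "RF"), seed = 1L,
                           strata = NULL, n_grid = DEFAULT_N_GRID,
                           depth_grid = DEFAULT_DEPTH_GRID, cv_folds = 5L,
                           target_name = "target") {
  algorithm <- match.arg(algorithm)
  Xm <- as.matrix(features)
  storage.mode(Xm) <- "double"
  y <- as.numeric(target_values)
  if (nrow(Xm) < 30) cp_stop("tune_and_train(): need >= 30 samples")
  if (any(!is.finite(Xm))) cp_stop("tune_and_train(): non-finite features")
  if (stats::var(y) == 0) cp_stop("tune_and_train(): degenerate target (zero variance)")

  split <- if (is.null(strata)) {
    stratified_split(rep("all", nrow(Xm)), 5, seed)
  } else stratified_split(strata, 5, seed)
  tr_idx <- split$train
  Xt <- Xm[tr_idx, , drop = FALSE]; yt <- y[tr_idx]

  set.seed(child_seed(seed, 17))
  folds <- sample(rep_len(seq_len(cv_folds), length(yt)))
  cv <- expand.grid(n_estimators = n_grid, max_depth = depth_grid)
  cv$mean_r2 <- NA_real_
  for (d in depth_grid) {
    r2s <- matrix(NA_real_, cv_folds, length(n_grid))
    for (f in seq_len(cv_folds)) {
      hold <- folds == f
      if (stats::var(yt[!hold]) == 0) next
      mdl <- train_ensemble(Xt[!hold, , drop = FALSE], yt[!hold], algorithm,
                            n_estimators = max(n_grid), max_depth = d,
                            seed = child_seed(seed, 100 * d + f))
      for (gi in seq_along(n_grid)) {
        pr <- predict(mdl, Xt[hold, , drop = FALSE], n_trees = n_grid[gi])
        r2s[f, gi] <- evaluate_regression(yt[hold], pr)$r2
      }
    }
    for (gi in seq_along(n_grid))
      cv$mean_r2[cv$max_depth == d & cv$n_estimators == n_grid[gi]] <-
        mean(r2s[, gi], na.rm = TRUE)
  }
  # best by mean CV R^2; ties prefer fewer trees, then shallower depth
  ord <- order(-cv$mean_r2, cv$n_estimators, cv$max_depth)
  best <- cv[ord[1], ]
  model <- train_ensemble(Xt, yt, algorithm, n_estimators = best$n_estimators,
                          max_depth = best$max_depth,
                          seed = child_seed(seed, 7))
  structure(list(algorithm = algorithm, model = model,
                 n_estimators = best$n_estimators, max_depth = best$max_depth,
                 cv = cv, train = tr_idx, validation = split$validation,
                 feature_names = colnames(Xm), target_name = target_name,
                 seed = seed, format_version = 1L),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle %s -> %s: n_estimators %d, max_depth %d (CV R2 %.3f)\n",
              x$algorithm, x$target_name, x$n_estimators, x$max_depth,
              max(x$cv$mean_r2, na.rm = TRUE)))
  invisible(x)
}

#' @rdname predict.tree_ensemble
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}
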