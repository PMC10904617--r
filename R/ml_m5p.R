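#' Fit an m5p model-tree random forest
#'
#' An ensemble of model trees: decision trees whose leaves hold ordinary
#' least-squares linear models instead of constants. Each tree draws a
#' bootstrap sample of the rows and a random subset of the features, then
#' grows greedily on the split that maximises the standard-deviation
#' reduction of the target between parent and children (the
#' variance-minimisation criterion of the M5' family). Leaf models are fit
#' on the tree's feature subset; a node whose linear fit is already exact
#' becomes a leaf, so a noiseless linear target yields single-leaf trees.
#' No smoothing or pruning beyond the minimum-leaf and variance stopping
#' rules is applied.
#'
#' @param data Data frame with numeric feature columns and the target.
#' @param target Name of the target column (default `"y"`).
#' @param n_trees Number of trees (default 10).
#' @param min_leaf Minimum rows per leaf (default 4).
#' @param feature_fraction Fraction of features drawn per tree (default 1).
#' @param sample_fraction Bootstrap sample size as a fraction of `n`
#'   (default 1; sampling is with replacement).
#' @param seed Seed making the ensemble bit-reproducible.
#' @return An `m5p_forest` object.
#' @examples
#' d <- generate_regression_data("linear", n = 100, noise_sd = 0, seed = 1)
#' fit <- m5p_fit(d, seed = 1)
#' max(abs(m5p_predict(fit, d) - d$y)) < 1e-6
#' @export
m5p_fit <- function(data, target = "y", n_trees = 10, min_leaf = 4,
                    feature_fraction = 1, sample_fraction = 1, seed = NULL) {
  data <- as.data.frame(data)
  if (!target %in% names(data)) {
    abort(paste0("target column '", target, "' not found"))
  }
  features <- setdiff(names(data), target)
  if (length(features) == 0) abort("no feature columns")
  n <- nrow(data)
  if (n < 2 * min_leaf) abort("need at least 2*min_leaf rows")
  X <- as.matrix(data[features])
  y <- data[[target]]
  if (anyNA(X) || anyNA(y)) abort("missing values are not supported")

  trees <- withr::with_seed(seed %||% 1L, {
    lapply(seq_len(n_trees), function(i) {
      n_feat <- max(1L, ceiling(feature_fraction * length(features)))
      feat <- sort(sample(length(features), n_feat))
      rows <- sample(n, size = max(2L * min_leaf, round(sample_fraction * n)),
                     replace = TRUE)
      list(features = features[feat],
           root = grow_m5p_node(X[rows, feat, drop = FALSE], y[rows],
                                min_leaf, sd_root = sd(y[rows])))
    })
  })
  structure(list(trees = trees, features = features, target = target,
                 params = list(n_trees = n_trees, min_leaf = min_leaf,
                               feature_fraction = feature_fraction,
                               sample_fraction = sample_fraction),
                 seed = seed),
            class = "m5p_forest")
}

# OLS leaf model with intercept; rank-deficient coefficients are zeroed so
# prediction stays finite on the training domain
fit_leaf <- function(X, y) {
  coefs <- lm.fit(cbind(`(Intercept)` = 1, X), y)$coefficients
  coefs[is.na(coefs)] <- 0
  coefs
}

leaf_rmse <- function(X, y, coefs) {
  pred <- drop(cbind(1, X) %*% coefs)
  sqrt(mean((y - pred)^2))
}

# standard-deviation reduction over all (feature, threshold) candidates via
# cumulative sums; returns NULL when no admissible split improves on the node
best_sdr_split <- function(X, y, min_leaf) {
  n <- length(y)
  sd_node <- sd_pop(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    ys <- y[ord]
    xs <- X[ord, j]
    cs <- cumsum(ys)
    cs2 <- cumsum(ys^2)
    idx <- seq_len(n - 1)
    nl <- idx
    nr <- n - idx
    okcut <- xs[idx] < xs[idx + 1] & nl >= min_leaf & nr >= min_leaf
    if (!any(okcut)) next
    ml <- cs[idx] / nl
    vl <- pmax(cs2[idx] / nl - ml^2, 0)
    mr <- (cs[n] - cs[idx]) / nr
    vr <- pmax((cs2[n] - cs2[idx]) / nr - mr^2, 0)
    sdr <- sd_node - (nl * sqrt(vl) + nr * sqrt(vr)) / n
    sdr[!okcut] <- -Inf
    i <- which.max(sdr)
    if (is.null(best) || sdr[i] > best$sdr) {
      best <- list(feature = j, value = (xs[i] + xs[i + 1]) / 2, sdr = sdr[i])
    }
  }
  best
}

sd_pop <- function(y) sqrt(max(mean(y^2) - mean(y)^2, 0))

grow_m5p_node <- function(X, y, min_leaf, sd_root) {
  coefs <- fit_leaf(X, y)
  n <- length(y)
  # stop: too small, nearly constant target, or the linear model is exact
  if (n < 2 * min_leaf ||
      sd_pop(y) < 0.05 * sd_root ||
      leaf_rmse(X, y, coefs) <= 1e-10 * (sd_root + 1e-12)) {
    return(list(leaf = TRUE, coefs = coefs, n = n))
  }
  split <- best_sdr_split(X, y, min_leaf)
  if (is.null(split) || split$sdr <= 1e-12 * (sd_root + 1e-12)) {
    return(list(leaf = TRUE, coefs = coefs, n = n))
  }
  left <- X[, split$feature] <= split$value
  list(leaf = FALSE, feature = split$feature, value = split$value, n = n,
       left = grow_m5p_node(X[left, , drop = FALSE], y[left],
                            min_leaf, sd_root),
       right = grow_m5p_node(X[!left, , drop = FALSE], y[!left],
                             min_leaf, sd_root))
}

predict_m5p_node <- function(node, X) {
  n <- nrow(X)
  if (node$leaf) return(drop(cbind(1, X) %*% node$coefs))
  out <- numeric(n)
  left <- X[, node$feature] <= node$value
  if (any(left)) {
    out[left] <- predict_m5p_node(node$left, X[left, , drop = FALSE])
  }
  if (any(!left)) {
    out[!left] <- predict_m5p_node(node$right, X[!left, , drop = FALSE])
  }
  out
}

#' Predict from an m5p forest
#'
#' The ensemble prediction is the unweighted mean over the trees.
#'
#' @param ensemble An `m5p_forest`.
#' @param newdata Data frame containing the training feature columns.
#' @return Numeric predictions.
#' @export
m5p_predict <- function(ensemble, newdata) {
  stopifnot(inherits(ensemble, "m5p_forest"))
  newdata <- as.data.frame(newdata)
  missing <- setdiff(ensemble$features, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("newdata is missing feature(s): ",
                 paste(missing, collapse = ", ")))
  }
  preds <- vapply(ensemble$trees, function(tree) {
    X <- as.matrix(newdata[tree$features])
    predict_m5p_node(tree$root, X)
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1) return(mean(preds))
  rowMeans(preds)
}

#' @export
predict.m5p_forest <- function(object, newdata, ...) {
  m5p_predict(object, newdata)
}

count_leaves <- function(node) {
  if (node$leaf) return(1L)
  count_leaves(node$left) + count_leaves(node$right)
}

#' @export
print.m5p_forest <- function(x, ...) {
  leaves <- vapply(x$trees, function(t) count_leaves(t$root), integer(1))
  cat(sprintf(
    "<m5p_forest> %d trees on %d features, %.1f leaves/tree (min_leaf %d)\n",
    length(x$trees), length(x$features), mean(leaves), x$params$min_leaf))
  invisible(x)
}

#' @export
tidy.m5p_forest <- function(x, ...) {
  tibble::tibble(
    tree = seq_along(x$trees),
    n_leaves = vapply(x$trees, function(t) count_leaves(t$root), integer(1)),
    features = vapply(x$trees, function(t) paste(t$features, collapse = ","),
                      character(1))
  )
}

#' k-fold model selection by validation error
#'
#' Shuffles the rows with a seed, partitions them into `k` folds whose sizes
#' differ by at most one, fits a model on each training complement and
#' scores it on the held-out fold by mean absolute error (with R-squared
#' reported alongside). Returns the model of the best fold - the smallest
#' validation MAE - together with the full per-fold metric table.
#'
#' @param data Data frame of features and target.
#' @param target Target column name.
#' @param k Number of folds (default 10; must not exceed `nrow(data)`).
#' @param fit_fn Function `data -> model`; defaults to [m5p_fit()] with the
#'   same seed.
#' @param predict_fn Function `(model, data) -> predictions`; defaults to
#'   [m5p_predict()].
#' @param seed Seed for the shuffle (and the default `fit_fn`).
#' @return List: `model`, `best_fold`, `metrics` (tibble of fold, n_val,
#'   mae, r_squared), `folds` (the index partition).
#' @export
kfold_best_model <- function(data, target = "y", k = 10, fit_fn = NULL,
                             predict_fn = NULL, seed = NULL) {
  data <- as.data.frame(data)
  n <- nrow(data)
  if (k > n) abort("k must not exceed the number of rows")
  if (k < 2) abort("k must be at least 2")
  fit_fn <- fit_fn %||% function(d) m5p_fit(d, target = target, seed = seed)
  predict_fn <- predict_fn %||% function(m, d) m5p_predict(m, d)

  perm <- withr::with_seed(seed %||% 1L, sample(n))
  fold_id <- rep(seq_len(k), length.out = n)
  folds <- split(perm, fold_id)

  fits <- vector("list", k)
  metrics <- purrr::map(seq_len(k), function(i) {
    val <- folds[[i]]
    model <- fit_fn(data[-val, , drop = FALSE])
    fits[[i]] <<- model
    pred <- predict_fn(model, data[val, , drop = FALSE])
    truth <- data[[target]][val]
    sst <- sum((truth - mean(truth))^2)
    tibble::tibble(
      fold = i, n_val = length(val),
      mae = mean(abs(pred - truth)),
      r_squared = if (sst > 0) 1 - sum((pred - truth)^2) / sst else NA_real_)
  })
  metrics <- dplyr::bind_rows(metrics)
  best <- which.min(metrics$mae)
  list(model = fits[[best]], best_fold = best, metrics = metrics,
       folds = folds)
}
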