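test_that("graph construction validates endpoints, loops and feature shapes", {
  x <- matrix(1:6, 3, 2)
  expect_error(molecular_graph(x, rbind(c(1, 4))), "out of range")
  expect_error(molecular_graph(x, rbind(c(2, 2))), "self-loops")
  expect_error(molecular_graph(x, rbind(c(1, 2)), edge_features = matrix(0, 2, 1)),
               "one row per edge")
  g <- molecular_graph(x, rbind(c(1, 2), c(2, 3)))
  expect_s3_class(g, "molecular_graph")
})

test_that("forward pass with T = 0 reduces to the readout of raw features", {
  g <- molecular_graph(matrix(c(2, -1, 0.5), 1, 3), matrix(integer(0), 0, 2))
  model <- mpnn_model(node_dim = 3, n_steps = 0,
                      readout_fn = function(H, w) colSums(H))
  expect_equal(mpnn_forward(g, model), c(2, -1, 0.5))
})

test_that("a two-node path with identity message and additive update is computable by hand", {
  h1 <- c(1, 2)
  h2 <- c(10, 20)
  g <- molecular_graph(rbind(h1, h2), rbind(c(1, 2)))
  model <- mpnn_model(
    node_dim = 2, n_steps = 1,
    message_fn = function(h_v, h_w, e, w) h_w,       # identity message
    update_fn = function(h, m, w) h + m,             # additive update
    readout_fn = function(H, w) colSums(H))          # sum readout
  # after one round both nodes hold h1 + h2; the readout doubles it
  expect_equal(mpnn_forward(g, model), 2 * (h1 + h2))
})

test_that("the default forward pass is invariant to vertex relabelling", {
  withr::with_seed(42, {
    g <- random_graph()
    model <- mpnn_model(node_dim = 3, edge_dim = 2, n_steps = 2, seed = 5)
    y0 <- mpnn_forward(g, model)
    for (i in 1:100) {
      yp <- mpnn_forward(permute_graph(g, sample(8)), model)
      expect_equal(yp, y0, tolerance = 1e-10)
    }
  })
})

test_that("dimension mismatches are rejected", {
  g <- molecular_graph(matrix(0, 2, 3), rbind(c(1, 2)))
  expect_error(mpnn_forward(g, mpnn_model(node_dim = 4)), "node dimension")
  expect_error(mpnn_forward(g, mpnn_model(node_dim = 3, edge_dim = 2)),
               "edge dimension")
})

test_that("m5p recovers a noiseless linear target with single-leaf trees", {
  d <- generate_regression_data("linear", n = 120, noise_sd = 0, seed = 1)
  fit <- m5p_fit(d, seed = 1)
  expect_true(all(tidy(fit)$n_leaves == 1))
  expect_lt(mean(abs(m5p_predict(fit, d) - d$y)), 1e-6)
})

test_that("m5p predicts a constant target exactly", {
  d <- tibble::tibble(x1 = runif(60), x2 = runif(60), y = 5)
  fit <- m5p_fit(d, seed = 2)
  expect_equal(m5p_predict(fit, d), rep(5, 60), tolerance = 1e-12)
})

test_that("m5p beats the constant-mean baseline on piecewise-linear data", {
  train <- generate_regression_data("piecewise", n = 500, noise_sd = 0.05,
                                    seed = 42)
  test <- generate_regression_data("piecewise", n = 300, noise_sd = 0.05,
                                   seed = 43)
  fit <- m5p_fit(train, n_trees = 20, seed = 42)
  mae_model <- mean(abs(m5p_predict(fit, test) - test$y))
  mae_baseline <- mean(abs(mean(train$y) - test$y))
  expect_lt(mae_model, 0.25 * mae_baseline)
})

test_that("ensemble prediction is the unweighted tree mean", {
  d <- generate_regression_data("piecewise", n = 80, noise_sd = 0.2, seed = 3)
  one <- m5p_fit(d, n_trees = 1, seed = 9)
  expect_equal(m5p_predict(one, d),
               pcabsim:::predict_m5p_node(one$trees[[1]]$root,
                                          as.matrix(d[one$trees[[1]]$features])))
  # duplicating every tree leaves the mean unchanged
  dup <- one
  dup$trees <- c(one$trees, one$trees)
  expect_equal(m5p_predict(dup, d), m5p_predict(one, d))
})

test_that("m5p is bit-reproducible from its seed", {
  d <- generate_regression_data("piecewise", n = 200, noise_sd = 0.1, seed = 4)
  f1 <- m5p_fit(d, n_trees = 8, feature_fraction = 0.7,
                sample_fraction = 0.8, seed = 123)
  f2 <- m5p_fit(d, n_trees = 8, feature_fraction = 0.7,
                sample_fraction = 0.8, seed = 123)
  expect_identical(f1, f2)
  expect_identical(m5p_predict(f1, d), m5p_predict(f2, d))
})

test_that("k-fold selection partitions the data and returns the MAE argmin", {
  d <- generate_regression_data("linear", n = 83, noise_sd = 0.3, seed = 6)
  res <- kfold_best_model(d, k = 10, seed = 11)
  idx <- sort(unname(unlist(res$folds)))
  expect_identical(idx, 1:83)
  sizes <- lengths(res$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(nrow(res$metrics), 10)
  expect_equal(res$best_fold, which.min(res$metrics$mae))
  expect_lte(min(res$metrics$mae), mean(res$metrics$mae))
  # deterministic from the seed
  res2 <- kfold_best_model(d, k = 10, seed = 11)
  expect_identical(res$folds, res2$folds)
  expect_equal(res$metrics, res2$metrics)
  expect_error(kfold_best_model(d, k = 100, seed = 1), "must not exceed")
})

test_that("derived ADME formulas invert the published parameter table", {
  expect_equal(fup_from_ppbr(0.86582), 0.13418)
  expect_equal(fup_from_ppbr(0), 1)
  expect_equal(fup_from_ppbr(0.5), 0.5)
  expect_error(fup_from_ppbr(1), "0, 1")

  expect_equal(clapp_from_vss_halflife(1, 0.693), 1)
  expect_equal(clapp_from_vss_halflife(100, 6.93), 10)
  expect_equal(clapp_from_vss_halflife(2 * 7, 3),
               2 * clapp_from_vss_halflife(7, 3))
  expect_error(clapp_from_vss_halflife(0, 1), "positive")

  expect_equal(gika_from_papp(1.25, 1.25), 2)
  # Papp back-computed from the published gi_ka: 1.51647 * 1.25 / 2
  expect_equal(gika_from_papp(0.94779375), 1.51647)
  expect_equal(gika_from_papp(0.9, 2.5), gika_from_papp(0.9, 1.25) / 2)
  expect_error(gika_from_papp(-0.1), "positive")
})
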