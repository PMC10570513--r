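test_that("feature specs define the documented input sets", {
  expect_length(feature_spec("c7")$columns, 8)
  expect_length(feature_spec("kinematics")$columns, 7)
  expect_true(all(feature_spec("kinematics")$columns %in%
                    feature_spec("c7")$columns))
  ds <- toy_cycle_dataset()
  ft <- build_feature_table(ds, feature_spec("c7"))
  expect_equal(nrow(ft$X), nrow(ds))
  expect_equal(colnames(ft$X), feature_spec("c7")$columns)
  expect_error(build_feature_table(ds[, -5], feature_spec("c7")), "missing")
})

test_that("min-max scaler maps training data to [0,1] and never clips", {
  X <- cbind(a = c(0, 5, 10), b = c(-2, 0, 6))
  sc <- fit_scaler(X)
  expect_equal(apply_scaler(sc, X)[, "a"], c(0, 0.5, 1))
  out <- apply_scaler(sc, cbind(a = 20, b = 7))
  expect_gt(out[1, "a"], 1)  # preserved, not clipped
  rt <- apply_scaler(sc, apply_scaler(sc, X), inverse = TRUE)
  expect_equal(rt, X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(fit_scaler(cbind(a = c(1, 1, 1), b = 1:3)), "a")
  # leakage guard: adding test rows changes the fitted scaler
  sc2 <- fit_scaler(rbind(X, c(100, 100)))
  expect_false(isTRUE(all.equal(sc$max, sc2$max)))
})

test_that("data splitting isolates held-out subjects and honours 80/20", {
  ds <- toy_cycle_dataset(n_subjects = 6)
  sp <- split_data(ds, inter_subjects = c(5, 6), seed = 3)
  expect_setequal(unique(ds$subject[sp$test]), c(5, 6))
  expect_false(any(ds$subject[sp$train] %in% c(5, 6)))
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(intersect(sp$train, sp$test), 0)
  n_intra <- sum(!ds$subject %in% c(5, 6))
  expect_lte(abs(length(sp$train) - 0.8 * n_intra), 1)
  expect_error(split_data(toy_cycle_dataset(n_subjects = 2), 2), "3 subjects")
})

test_that("random forest training is reproducible and can memorize", {
  ds <- toy_cycle_dataset()
  ft <- build_feature_table(ds, feature_spec("c7"))
  sc <- fit_scaler(ft$X); Xs <- apply_scaler(sc, ft$X)
  m1 <- train_grf_rf(Xs, ft$y, rf_config(n_trees = 30, seed = 7))
  m2 <- train_grf_rf(Xs, ft$y, rf_config(n_trees = 30, seed = 7))
  expect_identical(predict(m1, Xs), predict(m2, Xs))
  expect_equal(m1$mtry, 3)  # floor(log2(8))
  # a deep forest on unique inputs reproduces its training labels
  n <- 300
  set.seed(2)
  Xu <- cbind(x1 = runif(n), x2 = runif(n))
  yu <- sin(6 * Xu[, 1]) + Xu[, 2]
  deep <- train_grf_rf(Xu, yu, rf_config(n_trees = 50, seed = 1),
                       replace = FALSE, sample.fraction = 1, mtry = 2)
  expect_lt(sqrt(mean((predict(deep, Xu) - yu)^2)), 1e-10)
})

test_that("a single depth-1 tree fits a step function with split in (0,1)", {
  X <- cbind(x = rep(c(0, 1), each = 10))
  y <- rep(c(0, 1), each = 10)
  stump <- train_grf_rf(X, y, rf_config(n_trees = 1, max_depth = 1, seed = 1),
                        replace = FALSE, sample.fraction = 1, mtry = 1)
  grid <- cbind(x = seq(-0.5, 1.5, by = 0.1))
  p <- predict(stump, grid)
  expect_equal(p[grid[, 1] <= 0], rep(0, sum(grid[, 1] <= 0)))
  expect_equal(p[grid[, 1] >= 1], rep(1, sum(grid[, 1] >= 1)))
  expect_true(all(diff(p) >= 0))
})

test_that("predictions preserve rows and reject mismatched columns", {
  ds <- toy_cycle_dataset()
  ft <- build_feature_table(ds, feature_spec("kinematics"))
  Xs <- apply_scaler(fit_scaler(ft$X), ft$X)
  m <- train_grf_rf(Xs, ft$y, rf_config(n_trees = 20, seed = 1))
  expect_length(predict(m, Xs[1:37, ]), 37)
  const <- Xs[rep(1, 5), ]
  expect_equal(diff(range(predict(m, const))), 0)
  bad <- Xs; colnames(bad)[1] <- "wrong"
  expect_error(predict(m, bad), "columns")
})

test_that("permutation importance matches a brute-force reimplementation", {
  ds <- toy_cycle_dataset()
  ft <- build_feature_table(ds, feature_spec("c7"))
  Xs <- apply_scaler(fit_scaler(ft$X), ft$X)
  m <- train_grf_rf(Xs, ft$y, rf_config(n_trees = 25, seed = 5))
  imp <- permutation_importance(m, Xs, ft$y, repeats = 3, seed = 42)
  # oracle: same shuffles, same arithmetic, written independently
  base <- sqrt(mean((predict(m, Xs) - ft$y)^2))
  set.seed(42)
  oracle <- numeric(ncol(Xs))
  for (j in seq_len(ncol(Xs))) {
    acc <- 0
    for (r in 1:3) {
      Xp <- Xs
      Xp[, j] <- Xs[sample.int(nrow(Xs)), j]
      acc <- acc + sqrt(mean((predict(m, Xp) - ft$y)^2)) - base
    }
    oracle[j] <- acc / 3
  }
  expect_equal(unname(imp), oracle, tolerance = 1e-12)
  expect_error(permutation_importance(m, Xs, ft$y, repeats = 0), "repeats")
})

test_that("a feature the model ignores has exactly zero importance", {
  X <- cbind(x = rep(c(0, 1), each = 20), junk = runif(40))
  y <- rep(c(0, 1), each = 20)
  stump <- train_grf_rf(X, y, rf_config(n_trees = 1, max_depth = 1, seed = 2),
                        replace = FALSE, sample.fraction = 1, mtry = 1,
                        split.select.weights = c(1, 0))
  imp <- permutation_importance(stump, X, y, repeats = 4, seed = 1)
  expect_equal(unname(imp["junk"]), 0)
  expect_gt(imp["x"], 0.3)
})

test_that("a shuffled perfect predictor loses about sd(y)*sqrt(2)", {
  # identity "model" on one feature equal to the label
  set.seed(14)
  y <- rnorm(4000)
  X <- cbind(y = y)
  ident <- structure(list(kind = "identity"), class = "identity_model")
  assign("predict.identity_model",
         function(object, newdata, ...) newdata[, 1], envir = globalenv())
  withr::defer(rm("predict.identity_model", envir = globalenv()))
  imp <- permutation_importance(ident, X, y, repeats = 5, seed = 2)
  expect_equal(unname(imp), sd(y) * sqrt(2), tolerance = 0.05)
})

test_that("feedforward training is reproducible and fits its training set", {
  ds <- toy_cycle_dataset(n_subjects = 3, strides = 3)
  ft <- build_feature_table(ds, feature_spec("c7"))
  Xs <- apply_scaler(fit_scaler(ft$X), ft$X)
  cfg <- fnn_config(epochs = 40, seed = 9)
  f1 <- train_grf_fnn(Xs, ft$y, cfg)
  f2 <- train_grf_fnn(Xs, ft$y, cfg)
  expect_equal(predict(f1, Xs), predict(f2, Xs), tolerance = 1e-6)
  rmse_tr <- sqrt(mean((predict(f1, Xs) - ft$y)^2))
  expect_lt(rmse_tr, 0.15)
  # max-norm constraint holds on every hidden layer
  for (l in seq_len(length(f1$fit$W) - 1)) {
    expect_lte(max(sqrt(colSums(f1$fit$W[[l]]^2))), 4 + 1e-8)
  }
  expect_error(train_grf_fnn(Xs * NA, ft$y, cfg), "NaN")
})

test_that("early stopping restores the best validation weights", {
  ds <- toy_cycle_dataset(n_subjects = 4)
  ft <- build_feature_table(ds, feature_spec("kinematics"))
  Xs <- apply_scaler(fit_scaler(ft$X), ft$X)
  idx <- seq_len(nrow(Xs)) %% 5 != 0
  fit <- train_grf_fnn(Xs[idx, ], ft$y[idx],
                       fnn_config(epochs = 60, patience = 8, seed = 4),
                       X_val = Xs[!idx, ], y_val = ft$y[!idx])
  vr <- sqrt(mean((predict(fit, Xs[!idx, ]) - ft$y[!idx])^2))
  expect_equal(vr, min(fit$val_history), tolerance = 1e-10)
})

test_that("training error does not exceed validation error on average", {
  # overfitting direction: over replicated noisy datasets the forest fits
  # its own training rows at least as well as held-out rows
  diffs <- numeric(10)
  for (r in 1:10) {
    ds <- toy_cycle_dataset(n_subjects = 3, strides = 2, seed = 100 + r)
    ft <- build_feature_table(ds, feature_spec("c7"))
    Xs <- apply_scaler(fit_scaler(ft$X), ft$X)
    set.seed(r)
    idx <- sample(c(TRUE, FALSE), nrow(Xs), replace = TRUE, prob = c(0.8, 0.2))
    m <- train_grf_rf(Xs[idx, ], ft$y[idx], rf_config(n_trees = 40, seed = r))
    tr <- sqrt(mean((predict(m, Xs[idx, ]) - ft$y[idx])^2))
    va <- sqrt(mean((predict(m, Xs[!idx, ]) - ft$y[!idx])^2))
    diffs[r] <- tr - va
  }
  expect_lte(mean(diffs), 0)
})
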