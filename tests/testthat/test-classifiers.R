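toy_xy <- function(n = 60, d = 4, sep = 3, seed = 1) {
  withr::with_seed(seed, {
    y <- factor(rep(c("healthy", "diseased"), each = n / 2),
                levels = c("healthy", "diseased"))
    X <- matrix(rnorm(n * d), n, d)
    X[y == "diseased", 1] <- X[y == "diseased", 1] + sep
    colnames(X) <- paste0("Q1_R.f", seq_len(d))
    list(X = X, y = y)
  })
}

test_that("all six methods train and predict through one interface", {
  txy <- toy_xy()
  for (m in c("RF", "GB", "NB", "SVM", "LR", "MLP")) {
    cfg <- classifier_config(m, trees = 30, depth = 3, neurons = 8,
                             layers = 1, seed = 4)
    fit <- train_classifier(cfg, txy$X, txy$y)
    pred <- predict(fit, txy$X)
    expect_s3_class(pred, "factor")
    expect_equal(levels(pred), c("healthy", "diseased"))
    mets <- classification_metrics(confusion_counts(txy$y, pred))
    # linearly separable toy data: every method fits the training set
    expect_gt(mets$F1, 0.95)
  }
})

test_that("training is deterministic given the seed", {
  txy <- toy_xy(sep = 1)
  for (m in c("RF", "GB", "MLP")) {
    cfg <- classifier_config(m, trees = 30, depth = 3, neurons = 8,
                             layers = 1, seed = 11)
    p1 <- predict(train_classifier(cfg, txy$X, txy$y), txy$X)
    p2 <- predict(train_classifier(cfg, txy$X, txy$y), txy$X)
    expect_identical(p1, p2)
  }
})

test_that("permuted labels give chance-level held-out F1", {
  set.seed(99)
  f1 <- replicate(20, {
    n <- 80
    X <- matrix(rnorm(n * 6), n, 6)
    y <- factor(sample(rep(c("healthy", "diseased"), n / 2)),
                levels = c("healthy", "diseased"))
    tr <- seq_len(n / 2)
    cfg <- classifier_config("GB", trees = 20, depth = 3, seed = 1)
    fit <- train_classifier(cfg, X[tr, ], y[tr])
    classification_metrics(
      confusion_counts(y[-tr], predict(fit, X[-tr, ])))$F1
  })
  expect_gt(mean(f1), 0.40)
  expect_lt(mean(f1), 0.60)
})

test_that("grid search maximises mean F1 with a first-point tie-break", {
  pools <- synthetic_twin_pools(24, strength = 2)
  folds <- fivefold_resplits(pools$healthy, pools$diseased, seed = 2,
                             folds = 2)
  grid <- expand.grid(trees = c(10L, 30L), depth = c(2L, 3L))
  gs <- grid_search("GB", folds, grid = grid, measurements = "Q1",
                    seed = 5)
  expect_equal(nrow(gs$table), nrow(grid))     # one row per grid point
  expect_true(all(c("trees", "depth", "mean_F1") %in% names(gs$table)))
  expect_equal(gs$table$mean_F1[which.max(gs$table$mean_F1)],
               max(gs$table$mean_F1))
  expect_s3_class(gs$best, "classifier_config")
  # ties break to the first point in iteration order
  fake <- gs$table; fake$mean_F1 <- 0.9
  expect_equal(which.max(fake$mean_F1), 1L)
  expect_error(grid_search("GB", folds, grid = grid[0, ]), "empty")
})

test_that("paper-scale grids have the quoted cardinalities", {
  expect_equal(nrow(hyperparameter_grid("RF", paper_scale = TRUE)),
               40 * 19)
  expect_equal(nrow(hyperparameter_grid("GB", paper_scale = TRUE)),
               10 * 19)
  expect_equal(nrow(hyperparameter_grid("MLP", paper_scale = TRUE)),
               20 * 6)
})

test_that("MLP early stopping fires by the 75-iteration/1e-3 rule", {
  txy <- toy_xy(n = 40, sep = 0.5, seed = 8)
  val <- toy_xy(n = 20, sep = 0.5, seed = 9)
  # strictly improving validation loss -> runs to the cap
  cfg <- classifier_config("MLP", neurons = 4, layers = 1, seed = 2,
                           max_iter = 30L, min_iter = 100L)
  fit <- train_classifier(cfg, txy$X, txy$y, X_val = val$X, y_val = val$y,
                          early_stopping = TRUE)
  expect_equal(fit$fit$stopped_at, 30L)
  expect_false(fit$fit$early_stopped)
  expect_length(fit$traces$train, 30)
  expect_length(fit$traces$validation, 30)
  # a flat validation trace stops right after the minimum iterations
  cfg2 <- classifier_config("MLP", neurons = 4, layers = 1, seed = 2,
                            max_iter = 200L, min_iter = 75L,
                            learning_rate = 1e-6)
  fit2 <- train_classifier(cfg2, txy$X, txy$y, X_val = val$X,
                           y_val = val$y, early_stopping = TRUE)
  expect_equal(fit2$fit$stopped_at, 76L)
  expect_true(fit2$fit$early_stopped)
  # early stopping without a validation set is an error
  expect_error(train_classifier(cfg2, txy$X, txy$y, early_stopping = TRUE),
               "validation")
})

test_that("early stopping protects against an engineered overfit", {
  # tiny training set, wide network, noisy labels: validation loss rises
  # after an early minimum; the early-stopped model must not be worse on
  # validation loss than the cap-trained one
  withr::with_seed(21, {
    n <- 24
    X <- matrix(rnorm(n * 30), n, 30)
    y <- factor(rep(c("healthy", "diseased"), n / 2),
                levels = c("healthy", "diseased"))
    Xv <- matrix(rnorm(40 * 30), 40, 30)
    yv <- factor(sample(rep(c("healthy", "diseased"), 20)),
                 levels = c("healthy", "diseased"))
  })
  base <- classifier_config("MLP", neurons = 60, layers = 2, seed = 3,
                            max_iter = 150L, learning_rate = 0.3)
  full <- train_classifier(base, X, y, X_val = Xv, y_val = yv)
  es <- train_classifier(base, X, y, X_val = Xv, y_val = yv,
                         early_stopping = TRUE)
  va_full <- full$traces$validation
  va_es <- es$traces$validation
  expect_lte(va_es[length(va_es)], va_full[length(va_full)] + 1e-6)
})

test_that("train_with_early_stopping needs the three-way split", {
  pools <- synthetic_twin_pools(24)
  ds <- assemble_ml_dataset(pools$healthy, pools$diseased, seed = 1)
  cfg <- classifier_config("MLP", neurons = 6, layers = 1, seed = 1,
                           max_iter = 20L, min_iter = 5L)
  expect_error(train_with_early_stopping(cfg, ds, "Q1"), "validation")
  ds3 <- assemble_ml_dataset(pools$healthy, pools$diseased, seed = 1,
                             early_stopping = TRUE)
  out <- train_with_early_stopping(cfg, ds3, "Q1")
  expect_true(is.numeric(out$metrics$F1))
  expect_length(out$model$traces$validation, out$model$fit$stopped_at)
})
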