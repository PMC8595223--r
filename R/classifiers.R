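#' Classifier configuration
#'
#' Six binary classification methods share one interface:
#' \describe{
#'   \item{RF}{random forest (`ranger`); hyper-parameters `trees`, `depth`.}
#'   \item{GB}{gradient-boosted trees (`xgboost`, logistic objective,
#'     learning rate 0.1); hyper-parameters `trees`, `depth`.}
#'   \item{NB}{naive Bayes with per-feature normal likelihoods (`e1071`).}
#'   \item{SVM}{support vector machine with radial basis kernel
#'     (`e1071`); kernel width by the variance-scaled rule
#'     `gamma = 1/(d Var(X))`.}
#'   \item{LR}{L2-regularised linear logistic regression (`glmnet`,
#'     ridge penalty `lambda = 1/n`).}
#'   \item{MLP}{multi-layer perceptron with equal-width hidden layers and
#'     logistic activations, trained by mini-batch gradient descent
#'     (in-package implementation exposing per-iteration log-loss traces);
#'     hyper-parameters `neurons`, `layers`.}
#' }
#'
#' @param method one of `"RF"`, `"GB"`, `"NB"`, `"SVM"`, `"LR"`, `"MLP"`.
#' @param trees,depth tree-ensemble hyper-parameters (RF, GB).
#' @param neurons,layers MLP architecture.
#' @param seed integer seed recorded and used for all method randomness.
#' @param ... further method-specific settings (MLP: `learning_rate`,
#'   `batch_size`, `max_iter`).
#' @return a `classifier_config`.
#' @export
classifier_config <- function(method, trees = 100L, depth = 6L,
                              neurons = 60L, layers = 2L, seed = 1L, ...) {
  method <- match.arg(method, c("RF", "GB", "NB", "SVM", "LR", "MLP"))
  structure(list(method = method, trees = as.integer(trees),
                 depth = as.integer(depth), neurons = as.integer(neurons),
                 layers = as.integer(layers), seed = as.integer(seed),
                 extra = list(...)),
            class = "classifier_config")
}

#' Train a classifier
#'
#' @param config a [classifier_config()].
#' @param X standardised training feature matrix.
#' @param y factor with levels `healthy`, `diseased`.
#' @param X_val,y_val optional validation split (used by the MLP early
#'   stopping criterion; traces are recorded for tree ensembles too when
#'   provided).
#' @param early_stopping enable the MLP early-stopping criterion: stop
#'   once more than 75 iterations have run and the improvement in
#'   validation log loss between two consecutive iterations falls below
#'   1e-3 (iteration cap 200).
#' @return a `trained_classifier`.
#' @export
train_classifier <- function(config, X, y, X_val = NULL, y_val = NULL,
                             early_stopping = FALSE) {
  stopifnot(inherits(config, "classifier_config"))
  y01 <- as.integer(y == "diseased")
  fit <- switch(config$method,
    RF = with_seed(config$seed,
      ranger::ranger(x = as.data.frame(X), y = y,
                     num.trees = config$trees, max.depth = config$depth,
                     num.threads = 1L, seed = config$seed,
                     probability = FALSE)),
    GB = {
      dtr <- xgboost::xgb.DMatrix(X, label = y01)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = config$depth,
                      eta = 0.1, nthread = 1L, seed = config$seed),
        data = dtr, nrounds = config$trees, verbose = 0)
    },
    NB = e1071::naiveBayes(x = as.data.frame(X), y = y),
    SVM = e1071::svm(x = X, y = y, kernel = "radial",
                     gamma = 1 / (ncol(X) * stats::var(as.vector(X))),
                     probability = FALSE, scale = FALSE),
    LR = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = 1 / nrow(X)),
    MLP = mlp_train(X, y01, neurons = config$neurons,
                    layers = config$layers, seed = config$seed,
                    X_val = X_val,
                    y_val = if (!is.null(y_val))
                      as.integer(y_val == "diseased"),
                    early_stopping = early_stopping,
                    extra = config$extra))
  structure(list(fit = fit, config = config,
                 features = colnames(X),
                 traces = if (config$method == "MLP") fit$traces),
            class = "trained_classifier")
}

#' Predict health labels
#'
#' @param object a `trained_classifier`.
#' @param newdata standardised feature matrix.
#' @param ... unused.
#' @return factor with levels `healthy`, `diseased`.
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  cfg <- object$config
  lab <- switch(cfg$method,
    RF = as.character(predict(object$fit, data = as.data.frame(newdata),
                              num.threads = 1L,
                              seed = cfg$seed)$predictions),
    GB = ifelse(predict(object$fit, xgboost::xgb.DMatrix(newdata)) > 0.5,
                "diseased", "healthy"),
    NB = as.character(predict(object$fit, as.data.frame(newdata))),
    SVM = as.character(predict(object$fit, newdata)),
    LR = ifelse(predict(object$fit, newdata, type = "response")[, 1] > 0.5,
                "diseased", "healthy"),
    MLP = ifelse(mlp_forward(object$fit, newdata) > 0.5,
                 "diseased", "healthy"))
  factor(lab, levels = c("healthy", "diseased"))
}

## ---- multi-layer perceptron --------------------------------------------

logistic <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(d, neurons, layers) {
  sizes <- c(d, rep(neurons, layers), 1L)
  W <- lapply(seq_len(length(sizes) - 1L), function(i)
    matrix(rnorm(sizes[i] * sizes[i + 1L], sd = sqrt(1 / sizes[i])),
           sizes[i], sizes[i + 1L]))
  b <- lapply(seq_len(length(sizes) - 1L), function(i)
    numeric(sizes[i + 1L]))
  list(W = W, b = b)
}

mlp_forward_full <- function(net, X) {
  L <- length(net$W)
  act <- vector("list", L + 1L)
  act[[1L]] <- X
  for (i in seq_len(L)) {
    z <- sweep(act[[i]] %*% net$W[[i]], 2, net$b[[i]], "+")
    act[[i + 1L]] <- logistic(z)   # logistic hidden AND sigmoid output
  }
  act
}

mlp_forward <- function(net, X) {
  drop(mlp_forward_full(net, X)[[length(net$W) + 1L]])
}

mlp_logloss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# mini-batch gradient descent with momentum on the cross-entropy loss;
# one "iteration" = one epoch over the training set
mlp_train <- function(X, y01, neurons, layers, seed, X_val = NULL,
                      y_val = NULL, early_stopping = FALSE, extra = list()) {
  lr <- extra$learning_rate %||% 0.05
  batch <- extra$batch_size %||% 32L
  max_iter <- extra$max_iter %||% 200L
  min_iter <- extra$min_iter %||% 75L
  tol <- extra$stop_tol %||% 1e-3
  momentum <- 0.9
  n <- nrow(X)
  if (early_stopping && is.null(X_val))
    stop("early stopping requires a validation partition")
  with_seed(seed, {
    net <- mlp_init(ncol(X), neurons, layers)
    vel_W <- lapply(net$W, function(w) w * 0)
    vel_b <- lapply(net$b, function(b) b * 0)
    tr_loss <- va_loss <- numeric(0)
    best <- NULL
    stopped_at <- max_iter
    for (it in seq_len(max_iter)) {
      idx <- sample.int(n)
      for (s in seq(1L, n, by = batch)) {
        rows <- idx[s:min(s + batch - 1L, n)]
        act <- mlp_forward_full(net, X[rows, , drop = FALSE])
        L <- length(net$W)
        m <- length(rows)
        delta <- (act[[L + 1L]] - y01[rows]) / m   # dLoss/dz at output
        for (i in rev(seq_len(L))) {
          gW <- crossprod(act[[i]], delta)
          gb <- colSums(delta)
          if (i > 1L) {
            a <- act[[i]]
            delta <- (delta %*% t(net$W[[i]])) * a * (1 - a)
          }
          vel_W[[i]] <- momentum * vel_W[[i]] - lr * gW
          vel_b[[i]] <- momentum * vel_b[[i]] - lr * gb
          net$W[[i]] <- net$W[[i]] + vel_W[[i]]
          net$b[[i]] <- net$b[[i]] + vel_b[[i]]
        }
      }
      tr_loss[it] <- mlp_logloss(mlp_forward(net, X), y01)
      if (!is.null(X_val))
        va_loss[it] <- mlp_logloss(mlp_forward(net, X_val), y_val)
      if (early_stopping && it > min_iter) {
        improvement <- va_loss[it - 1L] - va_loss[it]
        if (improvement < tol) { stopped_at <- it; break }
      }
    }
    net$traces <- list(train = tr_loss, validation = va_loss)
    net$stopped_at <- stopped_at
    net$early_stopped <- early_stopping && stopped_at < max_iter
    net
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train an MLP with the early-stopping protocol
#'
#' Requires an `ml_dataset` assembled with a validation partition
#' (50/25/25 split). Training halts once more than 75 iterations have run
#' and the validation log-loss improvement between consecutive iterations
#' drops below 1e-3, or at the 200-iteration cap. Per-iteration train and
#' validation log-loss traces are retained on the returned model.
#'
#' @param config an MLP [classifier_config()].
#' @param dataset an `ml_dataset` with `validation`.
#' @param measurements,laterality feature selection (see
#'   [assemble_features()]).
#' @return list: `model` (`trained_classifier`), `transform`, and the
#'   test-set `metrics`.
#' @export
train_with_early_stopping <- function(config, dataset,
                                      measurements = measurement_names(),
                                      laterality = "bilateral") {
  if (is.null(dataset$validation))
    stop("dataset has no validation partition; assemble with early_stopping = TRUE")
  tr <- assemble_features(dataset$train, measurements, laterality)
  va <- assemble_features(dataset$validation, measurements, laterality)
  te <- assemble_features(dataset$test, measurements, laterality)
  z <- zscore_fit(tr$X)
  model <- train_classifier(config, zscore_apply(z, tr$X), tr$y,
                            X_val = zscore_apply(z, va$X), y_val = va$y,
                            early_stopping = TRUE)
  pred <- predict(model, zscore_apply(z, te$X))
  list(model = model, transform = z,
       metrics = classification_metrics(confusion_counts(te$y, pred)))
}

## ---- grid search -------------------------------------------------------

#' Hyper-parameter grids
#'
#' `paper_scale = TRUE` returns the full published-scale grids: RF trees
#' 10-400 by 10 and depth 20-200 by 10 (760 points); GB depth 2-20 by 1
#' and trees 10-100 by 10 (190 points); MLP neurons 10-200 by 10 and
#' layers 1-6 (120 points). The default desk-scale grids are thinned
#' subsets for interactive use.
#'
#' @param method `"RF"`, `"GB"` or `"MLP"`.
#' @param paper_scale full grids instead of the thinned defaults.
#' @return data.frame of grid points.
#' @export
hyperparameter_grid <- function(method, paper_scale = FALSE) {
  method <- match.arg(method, c("RF", "GB", "MLP"))
  if (paper_scale) {
    switch(method,
      RF = expand.grid(trees = seq(10L, 400L, 10L),
                       depth = seq(20L, 200L, 10L)),
      GB = expand.grid(trees = seq(10L, 100L, 10L),
                       depth = seq(2L, 20L, 1L)),
      MLP = expand.grid(neurons = seq(10L, 200L, 10L),
                        layers = seq(1L, 6L, 1L)))
  } else {
    switch(method,
      RF = expand.grid(trees = c(50L, 100L, 200L), depth = c(20L, 60L)),
      GB = expand.grid(trees = c(50L, 100L), depth = c(3L, 6L, 10L)),
      MLP = expand.grid(neurons = c(30L, 60L), layers = c(1L, 2L)))
  }
}

#' Grid search over hyper-parameters by mean F1
#'
#' Trains one classifier per grid point on each resplit and selects the
#' point with the highest mean test F1. Ties break to the earliest point
#' in grid iteration order.
#'
#' @param method classifier method name.
#' @param datasets list of `ml_dataset` resplits.
#' @param grid data.frame of hyper-parameters (default from
#'   [hyperparameter_grid()]).
#' @param measurements,laterality feature selection.
#' @param seed seed forwarded to each configuration.
#' @return list: `best` (`classifier_config`), `table` (one row per grid
#'   point with mean F1).
#' @export
grid_search <- function(method, datasets, grid = NULL,
                        measurements = measurement_names(),
                        laterality = "bilateral", seed = 1L) {
  if (is.null(grid)) grid <- hyperparameter_grid(method)
  if (!nrow(grid)) stop("empty grid")
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- do.call(classifier_config,
                   c(list(method = method, seed = seed), as.list(grid[g, ])))
    f1 <- vapply(datasets, function(ds) {
      r <- evaluate_on_dataset(cfg, ds, measurements, laterality)
      r$F1
    }, numeric(1))
    mean(f1)
  }, numeric(1))
  grid$mean_F1 <- scores
  best_row <- which.max(scores)   # which.max takes the first maximum
  best <- do.call(classifier_config,
                  c(list(method = method, seed = seed),
                    as.list(grid[best_row, setdiff(names(grid), "mean_F1")])))
  list(best = best, table = grid)
}

# fit on a dataset's train split, evaluate on its test split
evaluate_on_dataset <- function(config, dataset,
                                measurements = measurement_names(),
                                laterality = "bilateral") {
  tr <- assemble_features(dataset$train, measurements, laterality)
  te <- assemble_features(dataset$test, measurements, laterality)
  z <- zscore_fit(tr$X)
  model <- train_classifier(config, zscore_apply(z, tr$X), tr$y)
  pred <- predict(model, zscore_apply(z, te$X))
  classification_metrics(confusion_counts(te$y, pred))
}
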