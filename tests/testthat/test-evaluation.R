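test_that("metric identities hold", {
  m <- classification_metrics(list(TP = 90, FP = 10, FN = 10, TN = 90))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$F1, 0.9)
  expect_equal(m$recall, m$sensitivity)
  expect_false(m$degenerate)

  # degenerate convention: no true positives -> F1 = 0, flagged
  z <- classification_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_equal(z$F1, 0)
  expect_true(z$degenerate)

  # published-table consistency: on a balanced test set, sensitivity
  # 0.8547 and specificity 0.8502 imply F1 within 0.01 of 0.8521
  n <- 10000
  tp <- round(0.8547 * n); fn <- n - tp
  tn <- round(0.8502 * n); fp <- n - tn
  m2 <- classification_metrics(list(TP = tp, FP = fp, FN = fn, TN = tn))
  expect_lt(abs(m2$F1 - 0.8521), 0.01)

  # randomised identity check: F1 = 2TP/(2TP+FP+FN), accuracy on balanced
  # sets = (sens + spec)/2
  set.seed(2)
  for (i in 1:20) {
    cts <- as.list(stats::setNames(sample(0:50, 4, TRUE),
                                   c("TP", "FP", "FN", "TN")))
    mm <- classification_metrics(cts)
    with(cts, {
      if (2 * TP + FP + FN > 0)
        expect_equal(mm$F1, 2 * TP / (2 * TP + FP + FN))
    })
    expect_true(all(unlist(mm[c("F1", "sensitivity", "specificity",
                                "precision", "recall")]) >= 0))
    expect_true(all(unlist(mm[c("F1", "sensitivity", "specificity",
                                "precision", "recall")]) <= 1))
  }
})

test_that("combination enumeration and record bookkeeping are exact", {
  combos <- measurement_combinations()
  expect_length(combos, 63)
  expect_length(measurement_combinations(c("Q1", "Q2", "P1")), 7)

  pools <- synthetic_twin_pools(20)
  folds <- fivefold_resplits(pools$healthy, pools$diseased, seed = 4,
                             folds = 5)
  rec <- suppressWarnings(
    combination_search(folds, methods = c("NB", "LR"),
                       measurements = c("Q1", "P1", "P2")))
  expect_equal(nrow(rec), 2 * 7 * 5)
  expect_equal(unname(table(rec$method)), c(35L, 35L), ignore_attr = TRUE)
  expect_false(any(is.na(rec$F1)))
  expect_true(all(rec$fold %in% 1:5))
})

test_that("per-count summaries are order statistics of the fold means", {
  pools <- synthetic_twin_pools(20)
  folds <- fivefold_resplits(pools$healthy, pools$diseased, seed = 4,
                             folds = 2)
  rec <- combination_search(folds, methods = "NB",
                            measurements = c("Q1", "P1", "P2"))
  summ <- summarise_by_count(rec)
  expect_equal(nrow(summ), 3)            # k = 1, 2, 3
  expect_true(all(summ$max_F1 >= summ$mean_F1 - 1e-12))
  expect_true(all(summ$mean_F1 >= summ$min_F1 - 1e-12))
  # k = 3 has exactly one combination
  expect_equal(summ$max_F1[summ$n_measurements == 3],
               summ$min_F1[summ$n_measurements == 3])
  # the arg-max is recoverable from the record table by brute force
  avg <- stats::aggregate(F1 ~ combination + n_measurements, rec, mean)
  for (k in 1:3) {
    slice <- avg[avg$n_measurements == k, ]
    expect_equal(summ$best_combination[summ$n_measurements == k],
                 slice$combination[which.max(slice$F1)])
  }
})

test_that("the inclusion partition splits 63 combinations into 32/31", {
  pools <- synthetic_twin_pools(16)
  folds <- fivefold_resplits(pools$healthy, pools$diseased, seed = 4,
                             folds = 1)
  rec <- combination_search(folds, methods = "NB")
  part <- q1_partition(rec)$NB
  expect_equal(nrow(part$include), 32)
  expect_equal(nrow(part$exclude), 31)
  # the two slices partition all combinations
  expect_length(intersect(part$include$combination,
                          part$exclude$combination), 0)
  expect_equal(sum(part$hist_include$counts) +
                 sum(part$hist_exclude$counts), 63)
})

test_that("summed split-improvement importance is normalised", {
  # planted signal: only Q1 carries class information
  pools <- synthetic_twin_pools(40, signal = "Q1", strength = 3)
  ds <- assemble_ml_dataset(pools$healthy, pools$diseased, seed = 6)
  tr <- assemble_features(ds$train, measurement_names())
  z <- zscore_fit(tr$X)
  fit <- train_classifier(classifier_config("GB", trees = 60, depth = 3,
                                            seed = 2),
                          zscore_apply(z, tr$X), tr$y)
  imp <- measurement_importance(fit)
  expect_length(imp, 6)
  expect_equal(sum(imp), 100, tolerance = 0.1)
  expect_true(all(imp >= 0))
  expect_gt(imp[["Q1"]], 90)
  # importance is defined only for the tree-boosting method
  nb <- train_classifier(classifier_config("NB"), zscore_apply(z, tr$X),
                         tr$y)
  expect_error(measurement_importance(nb), "GB")
})

test_that("severity ratio analysis matches combinations and identities", {
  pools <- synthetic_twin_pools(16, signal = c("Q1", "P1"), strength = 2)
  folds <- fivefold_resplits(pools$healthy, pools$diseased, seed = 4,
                             folds = 1)
  rec <- combination_search(folds, methods = "GB",
                            measurements = c("Q1", "P1"))
  ratios <- severity_ratio_analysis(rec, rec)
  expect_equal(nrow(ratios), 3)
  expect_true(all(ratios$ratio == 1))
  # mismatched combinations are an error
  expect_error(severity_ratio_analysis(rec[rec$combination != "Q1", ], rec),
               "matched")
})

test_that("unilateral evaluation reports right/left/bilateral rows", {
  pools <- synthetic_twin_pools(24, signal = "Q1", strength = 2)
  folds <- fivefold_resplits(pools$healthy, pools$diseased, seed = 4,
                             folds = 2)
  tab <- unilateral_evaluation(folds, measurements = c("Q1", "P3"),
                               method = "GB")
  expect_equal(nrow(tab), 6)
  expect_setequal(tab$side, c("right", "left", "bilateral"))
  expect_true(all(tab$F1 >= 0 & tab$F1 <= 1))
  # the synthetic signal is symmetric: right and left track each other
  q1 <- tab[tab$measurement == "Q1", ]
  expect_lt(abs(q1$sensitivity[q1$side == "right"] -
                q1$sensitivity[q1$side == "left"]), 0.1)
})
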