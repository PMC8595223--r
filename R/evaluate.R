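#' Confusion counts for binary screening
#'
#' The positive class is `diseased` (screening convention).
#'
#' @param truth,predicted factors with levels `healthy`, `diseased`.
#' @return list with TP, FP, FN, TN.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  t1 <- truth == "diseased"; p1 <- predicted == "diseased"
  list(TP = sum(t1 & p1), FP = sum(!t1 & p1),
       FN = sum(t1 & !p1), TN = sum(!t1 & !p1))
}

#' Screening metrics from confusion counts
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP), recall = sensitivity,
#' F1 = 2 precision recall / (precision + recall) = 2TP/(2TP+FP+FN).
#' Zero-denominator cases return 0 and set the `degenerate` flag.
#'
#' @param counts list with TP, FP, FN, TN.
#' @return list of metrics (all in [0, 1]) plus `degenerate`.
#' @export
classification_metrics <- function(counts) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  with(counts, {
    sens <- safe(TP, TP + FN)
    spec <- safe(TN, TN + FP)
    prec <- safe(TP, TP + FP)
    f1 <- safe(2 * TP, 2 * TP + FP + FN)
    list(F1 = f1, sensitivity = sens, specificity = spec,
         precision = prec, recall = sens,
         degenerate = (TP + FN == 0) || (TN + FP == 0) || (TP + FP == 0))
  })
}

#' All non-empty measurement combinations
#'
#' @param measurements available measurement names (default all six).
#' @return list of character vectors (63 for six measurements).
#' @export
measurement_combinations <- function(measurements = measurement_names()) {
  n <- length(measurements)
  unlist(lapply(seq_len(n), function(k)
    utils::combn(measurements, k, simplify = FALSE)), recursive = FALSE)
}

combo_label <- function(combo) paste(combo, collapse = "+")

#' Exhaustive measurement-combination search
#'
#' Trains and tests every method on every non-empty combination of the
#' available bilateral measurements over every resplit, and records F1,
#' sensitivity and specificity per (method, combination, fold).
#'
#' @param datasets list of `ml_dataset` resplits (shared pool).
#' @param methods character vector of method names.
#' @param configs optional named list mapping method name to a
#'   [classifier_config()] (otherwise defaults are used).
#' @param measurements measurements to enumerate subsets of.
#' @param laterality `"bilateral"`, `"right"` or `"left"`.
#' @param seed seed forwarded to the classifiers.
#' @return data.frame: one row per method x combination x fold with the
#'   metrics; failures are recorded with `NA` metrics, never dropped.
#' @export
combination_search <- function(datasets, methods = c("RF", "GB"),
                               configs = NULL,
                               measurements = measurement_names(),
                               laterality = "bilateral", seed = 1L) {
  combos <- measurement_combinations(measurements)
  rows <- list()
  for (m in methods) {
    cfg <- if (!is.null(configs) && !is.null(configs[[m]])) configs[[m]]
           else classifier_config(m, seed = seed)
    for (ci in seq_along(combos)) {
      for (fi in seq_along(datasets)) {
        res <- tryCatch(
          evaluate_on_dataset(cfg, datasets[[fi]], combos[[ci]], laterality),
          error = function(e)
            list(F1 = NA_real_, sensitivity = NA_real_,
                 specificity = NA_real_, error = conditionMessage(e)))
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, combination = combo_label(combos[[ci]]),
          n_measurements = length(combos[[ci]]), fold = fi,
          F1 = res$F1, sensitivity = res$sensitivity,
          specificity = res$specificity, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# fold-averaged record table: one row per method x combination
average_records <- function(records) {
  agg <- stats::aggregate(records[c("F1", "sensitivity", "specificity")],
                          by = records[c("method", "combination",
                                         "n_measurements")],
                          FUN = mean)
  agg[order(agg$method, agg$n_measurements, agg$combination), ]
}

#' Per-measurement-count summary of a combination search
#'
#' For each number of input measurements k, the mean, maximum and minimum
#' fold-averaged F1 over all combinations of size k, per method, with the
#' arg-max/arg-min combinations.
#'
#' @param records output of [combination_search()].
#' @return data.frame with one row per method x k.
#' @export
summarise_by_count <- function(records) {
  avg <- average_records(records)
  out <- lapply(split(avg, avg[c("method", "n_measurements")], drop = TRUE),
    function(d) {
      if (!nrow(d)) return(NULL)
      data.frame(method = d$method[1], n_measurements = d$n_measurements[1],
                 mean_F1 = mean(d$F1), max_F1 = max(d$F1),
                 min_F1 = min(d$F1),
                 best_combination = d$combination[which.max(d$F1)],
                 worst_combination = d$combination[which.min(d$F1)],
                 best_sensitivity = d$sensitivity[which.max(d$F1)],
                 best_specificity = d$specificity[which.max(d$F1)],
                 stringsAsFactors = FALSE)
    })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$method, res$n_measurements), ]
}

#' Partition combination-search records by inclusion of one measurement
#'
#' Splits the fold-averaged F1 scores into combinations that include vs
#' exclude the given measurement (32 vs 31 of the 63 six-measurement
#' combinations for the default) and bins them into histograms.
#'
#' @param records output of [combination_search()].
#' @param measurement measurement to partition on (default `"Q1"`).
#' @param breaks histogram bin edges.
#' @return list per method: `include`, `exclude` (data.frames of
#'   fold-averaged records), and the two histograms.
#' @export
q1_partition <- function(records, measurement = "Q1",
                         breaks = seq(0.4, 1, by = 0.05)) {
  avg <- average_records(records)
  has <- vapply(strsplit(avg$combination, "+", fixed = TRUE),
                function(x) measurement %in% x, logical(1))
  lapply(split(seq_len(nrow(avg)), avg$method), function(i) {
    inc <- avg[i[has[i]], ]; exc <- avg[i[!has[i]], ]
    clip <- function(x) pmin(pmax(x, min(breaks)), max(breaks))
    list(include = inc, exclude = exc,
         hist_include = graphics::hist(clip(inc$F1), breaks = breaks, plot = FALSE),
         hist_exclude = graphics::hist(clip(exc$F1), breaks = breaks, plot = FALSE))
  })
}

#' Summed split-improvement importance per measurement
#'
#' For a gradient-boosted model trained on all six bilateral measurements
#' (132 features), sums the per-feature split-improvement (gain)
#' importances over each measurement's 22 coefficients and normalises the
#' six shares to 100%.
#'
#' @param model a `trained_classifier` with method `"GB"`.
#' @param measurements measurement names to group by.
#' @return named numeric vector of percentage shares (sums to 100).
#' @export
measurement_importance <- function(model,
                                   measurements = measurement_names()) {
  if (model$config$method != "GB")
    stop("split-improvement importance requires the GB method")
  imp <- xgboost::xgb.importance(model = model$fit)
  full <- stats::setNames(rep(0, length(model$features)), model$features)
  full[imp$Feature] <- imp$Gain
  grp <- vapply(strsplit(names(full), "_", fixed = TRUE), `[[`, "", 1L)
  shares <- vapply(measurements, function(m) sum(full[grp == m]), numeric(1))
  if (sum(shares) == 0) stop("model exposes no importances")
  100 * shares / sum(shares)
}

#' F1 ratios between low- and high-severity aneurysm runs
#'
#' @param records_low,records_high combination-search records for the
#'   low-severity and reference severity bands (matched combinations).
#' @param method method to compare (default `"GB"`).
#' @return data.frame with per-combination fold-averaged F1 of both runs
#'   and their ratio low/high.
#' @export
severity_ratio_analysis <- function(records_low, records_high,
                                    method = "GB") {
  lo <- average_records(records_low[records_low$method == method, ])
  hi <- average_records(records_high[records_high$method == method, ])
  m <- merge(lo[c("combination", "n_measurements", "F1")],
             hi[c("combination", "F1")], by = "combination",
             suffixes = c("_low", "_high"))
  if (nrow(m) < nrow(lo) || nrow(m) < nrow(hi))
    stop("combinations are not matched between the two runs")
  m$ratio <- m$F1_low / m$F1_high
  m[order(m$n_measurements, m$combination), ]
}

#' Unilateral measurement evaluation
#'
#' Compares right-only, left-only and bilateral versions of given
#' measurements for one disease pool: sensitivity, specificity and F1 per
#' side, averaged over resplits.
#'
#' @param datasets list of `ml_dataset` resplits.
#' @param measurements measurements to evaluate one at a time.
#' @param method method name (default `"GB"`).
#' @param config optional [classifier_config()].
#' @param seed classifier seed.
#' @return data.frame: one row per measurement x side.
#' @export
unilateral_evaluation <- function(datasets, measurements = c("Q1", "P3"),
                                  method = "GB", config = NULL, seed = 1L) {
  cfg <- config %||% classifier_config(method, seed = seed)
  rows <- list()
  for (m in measurements) {
    for (lat in c("right", "left", "bilateral")) {
      mets <- lapply(datasets, function(ds)
        evaluate_on_dataset(cfg, ds, m, lat))
      rows[[length(rows) + 1L]] <- data.frame(
        measurement = m, side = lat,
        F1 = mean(vapply(mets, `[[`, 0, "F1")),
        sensitivity = mean(vapply(mets, `[[`, 0, "sensitivity")),
        specificity = mean(vapply(mets, `[[`, 0, "specificity")),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
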