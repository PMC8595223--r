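#' Fourier-series coefficients of a periodic waveform
#'
#' Projects one cycle of a uniformly sampled periodic signal onto a
#' truncated Fourier series
#' `u(t) = sum_{n=0}^{N} a_n sin(n w t) + b_n cos(n w t)`, `w = 2 pi / T`,
#' by discrete projection (equivalent to least squares on a uniform grid):
#' `b_0` is the sample mean, `a_n = (2/M) sum u_k sin(n w t_k)`,
#' `b_n = (2/M) sum u_k cos(n w t_k)`. The projection is exact for signals
#' band-limited to `N w`. The degenerate `a_0` term (which multiplies
#' `sin(0) = 0`) is dropped, so the representation has `2N + 1`
#' coefficients — 11 for the default truncation order `N = 5`.
#'
#' @param u numeric vector: samples of one period on a uniform grid
#'   (`t_k = k T / M`, `k = 0..M-1`).
#' @param period cardiac period T, s.
#' @param N truncation order (default 5).
#' @return A `fourier_features` object: coefficients ordered
#'   `[b0, a1..aN, b1..bN]`, with the period attached.
#' @export
fourier_coefficients <- function(u, period, N = 5L) {
  M <- length(u)
  if (M < 2 * (2 * N + 1))
    stop("need at least ", 2 * (2 * N + 1), " samples for order ", N)
  tk <- (seq_len(M) - 1) / M            # t_k / T
  a <- vapply(seq_len(N), function(n)
    2 / M * sum(u * sin(2 * pi * n * tk)), numeric(1))
  b <- vapply(seq_len(N), function(n)
    2 / M * sum(u * cos(2 * pi * n * tk)), numeric(1))
  coef <- c(mean(u), a, b)
  names(coef) <- c("b0", paste0("a", seq_len(N)), paste0("b", seq_len(N)))
  structure(list(coef = coef, N = N, period = period),
            class = "fourier_features")
}

#' Evaluate a truncated Fourier series at arbitrary times
#'
#' @param features a `fourier_features` object.
#' @param t times, s (periodic with the stored period).
#' @return reconstructed values.
#' @export
fourier_reconstruct <- function(features, t) {
  w <- 2 * pi / features$period
  N <- features$N
  cf <- features$coef
  out <- rep(cf[["b0"]], length(t))
  for (n in seq_len(N))
    out <- out + cf[[paste0("a", n)]] * sin(n * w * t) +
                 cf[[paste0("b", n)]] * cos(n * w * t)
  out
}

#' The six bilateral measurement names
#' @export
measurement_names <- function() c("Q1", "Q2", "Q3", "P1", "P2", "P3")

#' Featurise one patient's waveform set
#'
#' @param ws a `waveform_set`.
#' @param N truncation order.
#' @return named numeric vector: for each site column (e.g. `Q1_R`) the 11
#'   coefficients, names like `Q1_R.b0`, `Q1_R.a1`, ...
#' @keywords internal
featurise_waveforms <- function(ws, N = 5L) {
  cols <- colnames(ws$samples)
  out <- lapply(cols, function(cn) {
    f <- fourier_coefficients(ws$samples[, cn], ws$period, N)$coef
    names(f) <- paste(cn, names(f), sep = ".")
    f
  })
  unlist(out)
}

#' Assemble a feature matrix for a measurement combination
#'
#' Column order is fixed and documented: measurements in the canonical
#' order Q1, Q2, Q3, P1, P2, P3 (restricted to the combination), within
#' each measurement side R then L (bilateral) or the single requested
#' side, within each side the coefficients `b0, a1..a5, b1..b5`. A
#' bilateral measurement contributes 22 columns, a unilateral one 11.
#'
#' @param patients list of `virtual_patient` objects (with waveforms).
#' @param measurements character subset of
#'   `c("Q1","Q2","Q3","P1","P2","P3")`.
#' @param laterality `"bilateral"`, `"right"` or `"left"`.
#' @param N truncation order.
#' @return list: `X` (matrix, one row per patient), `y` (factor
#'   healthy/diseased), `subject` (ids).
#' @export
assemble_features <- function(patients, measurements,
                              laterality = c("bilateral", "right", "left"),
                              N = 5L) {
  laterality <- match.arg(laterality)
  measurements <- measurement_names()[measurement_names() %in% measurements]
  if (!length(measurements)) stop("empty measurement combination")
  sides <- switch(laterality, bilateral = c("R", "L"),
                  right = "R", left = "L")
  wanted <- as.vector(t(outer(measurements, sides, paste, sep = "_")))
  rows <- lapply(patients, function(p) {
    f <- featurise_waveforms(p$waveforms, N)
    sel <- unlist(lapply(wanted, function(w)
      f[grep(paste0("^", w, "\\."), names(f))]))
    if (length(sel) != length(wanted) * (2 * N + 1))
      stop("patient ", p$id, " is missing a requested site")
    sel
  })
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  list(X = X,
       y = factor(vapply(patients, `[[`, "", "label"),
                  levels = c("healthy", "diseased")),
       subject = vapply(patients, `[[`, NA_integer_, "id"))
}

#' Fit a Z-score standardisation on a training matrix
#'
#' Column means and population (1/M) standard deviations are estimated on
#' the training matrix only; the same transform is then applied to any
#' other matrix (no leakage from validation/test data). Zero-variance
#' columns are dropped with a warning.
#'
#' @param X training feature matrix.
#' @return A `zscore_transform`.
#' @export
zscore_fit <- function(X) {
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))   # population convention
  keep <- sdev > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance column(s) dropped")
  structure(list(mean = mu, sd = sdev, keep = keep),
            class = "zscore_transform")
}

#' Apply a fitted Z-score transform
#'
#' @param transform a `zscore_transform` from [zscore_fit()].
#' @param X matrix with the same columns as the training matrix.
#' @return standardised matrix (zero-variance training columns removed).
#' @export
zscore_apply <- function(transform, X) {
  Z <- sweep(sweep(X, 2, transform$mean), 2,
             ifelse(transform$keep, transform$sd, 1), "/")
  Z[, transform$keep, drop = FALSE]
}
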