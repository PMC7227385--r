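#' Forecast error metrics
#'
#' `mae` is the mean absolute error `(1/n) * sum(|y - yhat|)`, `mse` the mean
#' squared error `(1/n) * sum((y - yhat)^2)`, and `cc` the Pearson
#' correlation `cov(y, yhat) / (sd(y) * sd(yhat))` (the divisor convention
#' cancels between numerator and denominator). `cc` refuses constant inputs
#' rather than silently returning 0 or NaN: a constant prediction is a
#' degenerate forecast, not a poor-but-valid one.
#'
#' @param y,yhat Numeric vectors of equal length (actual, predicted).
#' @return A single number.
#' @examples
#' mae(c(1, 2, 3), c(1, 1, 4))  # 2/3
#' cc(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
mae <- function(y, yhat) {
  check_paired(y, yhat, 1L)
  mean(abs(y - yhat))
}

#' @rdname mae
#' @export
mse <- function(y, yhat) {
  check_paired(y, yhat, 1L)
  mean((y - yhat)^2)
}

#' @rdname mae
#' @export
cc <- function(y, yhat) {
  check_paired(y, yhat, 2L)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("degenerate data: cc is undefined for a constant series", call. = FALSE)
  stats::cov(y, yhat) / (stats::sd(y) * stats::sd(yhat))
}

check_paired <- function(y, yhat, min_n) {
  if (length(y) != length(yhat))
    stop(sprintf("length mismatch: y has %d values, yhat %d",
                 length(y), length(yhat)), call. = FALSE)
  if (length(y) < min_n)
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  invisible(TRUE)
}

#' Per-feature metrics for a stride forecast
#'
#' Computes MAE, MSE and CC per feature for either the first predicted
#' window only (`scope = "first_window"`, the earliest `w_out` samples) or
#' the whole stitched stride (`scope = "full_stride"`). Metrics are reported
#' on whatever scale the inputs carry — pass de-normalised trajectories for
#' original-unit errors. The per-sample absolute-error trace is attached as
#' the `"abs_error"` attribute for error-profile plots.
#'
#' @param predicted,actual Aligned matrices (rows = samples, columns =
#'   features), e.g. from [forecast_stride()].
#' @param scope `"full_stride"` or `"first_window"`.
#' @param w_out Output-window length; required for `scope = "first_window"`.
#' @return A data frame of class `metrics_report` with columns `feature`,
#'   `scope`, `mae`, `mse`, `cc`, `n`.
#' @export
evaluate_forecast <- function(predicted, actual,
                              scope = c("full_stride", "first_window"),
                              w_out = NULL) {
  scope <- match.arg(scope)
  predicted <- as.matrix(predicted); actual <- as.matrix(actual)
  if (!all(dim(predicted) == dim(actual)))
    stop(sprintf("misaligned series: predicted %d x %d vs actual %d x %d",
                 nrow(predicted), ncol(predicted), nrow(actual), ncol(actual)),
         call. = FALSE)
  if (scope == "first_window") {
    if (is.null(w_out)) stop("w_out is required for scope = 'first_window'",
                             call. = FALSE)
    keep <- seq_len(min(w_out, nrow(predicted)))
    predicted <- predicted[keep, , drop = FALSE]
    actual <- actual[keep, , drop = FALSE]
  }
  feats <- colnames(actual)
  if (is.null(feats)) feats <- .features[seq_len(ncol(actual))]
  rep <- data.frame(
    feature = feats, scope = scope,
    mae = vapply(seq_along(feats), function(f) mae(actual[, f], predicted[, f]), 1),
    mse = vapply(seq_along(feats), function(f) mse(actual[, f], predicted[, f]), 1),
    cc = vapply(seq_along(feats), function(f) cc(actual[, f], predicted[, f]), 1),
    n = nrow(actual), stringsAsFactors = FALSE)
  attr(rep, "abs_error") <- abs(actual - predicted)
  class(rep) <- c("metrics_report", "data.frame")
  rep
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("Forecast metrics (%s, n = %d samples/feature):\n",
              x$scope[1], x$n[1]))
  df <- data.frame(feature = x$feature, mae = signif(x$mae, digits),
                   mse = signif(x$mse, digits), cc = signif(x$cc, digits))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report (or several) as CSV / YAML
#'
#' @param reports A `metrics_report` or list of them.
#' @param path Output file; extension `.yaml`/`.yml` selects YAML, anything
#'   else CSV (one row per feature per scope).
#' @export
write_metrics <- function(reports, path) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) as.data.frame(unclass(r))))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lapply(split(df, seq_len(nrow(df))), as.list), path)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

# shared by the sweep and horizon drivers: fit on training windows, forecast
# the held-out stride, return per-scope de-normalised metrics
fit_and_score <- function(train_series, test_series, w_in, w_out, norm,
                          scopes = "full_stride", ...) {
  wcfg <- window_config(w_in, w_out)
  train_norm <- lapply(train_series, zscore_apply, params = norm)
  wd <- make_windows_multi(train_norm, wcfg)
  fit <- gait_forecaster(wd, w_in = w_in, w_out = w_out, ...)
  test_trim <- if (inherits(test_series, "kinematic_series") &&
                   length(test_series$stride_boundaries) >= 2L)
    trim_test_series(test_series, w_in) else test_series
  fc <- forecast_stride(fit, test_trim, norm_params = norm)
  reports <- lapply(scopes, function(s)
    evaluate_forecast(fc$predicted, fc$actual, scope = s, w_out = w_out))
  names(reports) <- scopes
  list(fit = fit, forecast = fc, reports = reports)
}

#' Sweep the input-window size
#'
#' Trains one model per input-window size at a fixed output window and
#' scores each on the held-out stride, mirroring the experiment of varying
#' the input window at five-sample intervals with the prediction window
#' fixed to five samples. One fixed seed is used per size by default
#' (deterministic and cheap); pass several `seeds` to replicate.
#'
#' @param train_series List of training [kinematic_series()] (original
#'   units).
#' @param test_series Held-out [kinematic_series()]: priming cycle followed
#'   by the test stride.
#' @param sizes Input-window sizes in samples (strictly increasing;
#'   default 5, 10, ..., 40).
#' @param w_out Fixed output-window size (default 5).
#' @param seeds Seeds; each size is trained once per seed and metrics are
#'   averaged.
#' @param ... Passed to [forecaster_config()] (units, epochs, ...).
#' @return Data frame of class `sweep_result`: one row per size per feature
#'   with `mae` and `mse` (original units).
#' @export
input_window_sweep <- function(train_series, test_series,
                               sizes = seq(5L, 40L, by = 5L), w_out = 5L,
                               seeds = 1L, ...) {
  sizes <- as.integer(sizes)
  if (!length(sizes)) stop("sizes must be non-empty", call. = FALSE)
  if (length(sizes) > 1L && any(diff(sizes) <= 0L))
    stop("sizes must be strictly increasing", call. = FALSE)
  norm <- zscore_fit(train_series)
  rows <- lapply(sizes, function(sz) {
    per_seed <- lapply(seeds, function(sd_i) {
      res <- tryCatch(
        fit_and_score(train_series, test_series, w_in = sz, w_out = w_out,
                      norm = norm, seed = sd_i, ...),
        error = function(e) stop(sprintf("input window size %d: %s",
                                         sz, conditionMessage(e)), call. = FALSE))
      res$reports$full_stride
    })
    r1 <- per_seed[[1]]
    data.frame(input_window = sz, feature = r1$feature,
               mae = rowMeans(sapply(per_seed, `[[`, "mae")),
               mse = rowMeans(sapply(per_seed, `[[`, "mse")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @export
print.sweep_result <- function(x, digits = 4, ...) {
  cat("Input-window sweep (whole-stride metrics, fixed output window):\n")
  df <- as.data.frame(unclass(x))
  df$mae <- signif(df$mae, digits); df$mse <- signif(df$mse, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare forecast horizons
#'
#' Fixes the input window and trains one model per output horizon, reporting
#' first-window and whole-stride metrics for each — the structure of
#' comparing 5- versus 10-sample prediction windows.
#'
#' @inheritParams input_window_sweep
#' @param w_in Fixed input-window size (default 25).
#' @param horizons Output-window sizes to compare (default 5 and 10).
#' @param seed Training seed.
#' @param ... Passed to [forecaster_config()].
#' @return Data frame of class `horizon_comparison`: one row per horizon per
#'   scope per feature with `mae`, `mse`, `cc`, `n`.
#' @export
horizon_comparison <- function(train_series, test_series, w_in = 25L,
                               horizons = c(5L, 10L), seed = 1L, ...) {
  horizons <- as.integer(horizons)
  if (!length(horizons) || any(horizons < 1L))
    stop("horizons must be positive window sizes", call. = FALSE)
  norm <- zscore_fit(train_series)
  rows <- lapply(horizons, function(h) {
    res <- fit_and_score(train_series, test_series, w_in = w_in, w_out = h,
                         norm = norm, scopes = c("first_window", "full_stride"),
                         seed = seed, ...)
    do.call(rbind, lapply(res$reports, function(r) {
      df <- as.data.frame(unclass(r))
      df$horizon <- h
      df
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("horizon", "scope", "feature", "mae", "mse", "cc", "n")]
  class(out) <- c("horizon_comparison", "data.frame")
  out
}

#' @export
print.horizon_comparison <- function(x, digits = 4, ...) {
  cat("Forecast-horizon comparison (fixed input window):\n")
  df <- as.data.frame(unclass(x))
  for (col in c("mae", "mse", "cc")) df[[col]] <- signif(df[[col]], digits)
  print(df, row.names = FALSE)
  invisible(x)
}
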