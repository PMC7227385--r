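#' Forecaster architecture and training hyperparameters
#'
#' Configuration of the encoder-decoder LSTM: the encoder consumes an input
#' window (`w_in` samples x `n_features`), its final hidden state is repeated
#' `w_out` times (the adapter), a decoder LSTM unrolls over that repeated
#' code, and a per-time-step dense layer maps each decoder state to the four
#' channels. Training minimises mean absolute error with Adam on batches of
#' `batch_windows` windows.
#'
#' @param encoder_units,decoder_units LSTM cells per layer.
#' @param n_features Number of channels (4 for the gait problem).
#' @param w_in,w_out Input/output window lengths in samples; must match the
#'   [window_config()] used to build the data.
#' @param epochs Training epochs (default 50).
#' @param batch_windows Windows per batch (default 100).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param clipnorm Global gradient-norm clip; `Inf` disables. Rectified
#'   cell activations make exploding gradients a real hazard, and norm
#'   clipping is the standard remedy.
#' @param activation Cell input/output activation for both LSTM layers:
#'   `"relu"` (default) or `"tanh"`. Gates are always logistic.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @return An object of class `forecaster_config`.
#' @export
forecaster_config <- function(encoder_units = 100L, decoder_units = 100L,
                              n_features = 4L, w_in = 25L, w_out = 5L,
                              epochs = 50L, batch_windows = 100L,
                              learning_rate = 0.001, beta1 = 0.9,
                              beta2 = 0.999, epsilon = 1e-7, clipnorm = 5,
                              activation = c("relu", "tanh"), seed = 1L) {
  activation <- match.arg(activation)
  cfg <- list(encoder_units = as.integer(encoder_units),
              decoder_units = as.integer(decoder_units),
              n_features = as.integer(n_features),
              w_in = as.integer(w_in), w_out = as.integer(w_out),
              epochs = as.integer(epochs),
              batch_windows = as.integer(batch_windows),
              learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
              epsilon = epsilon, clipnorm = clipnorm,
              activation = activation, seed = as.integer(seed))
  with(cfg, {
    if (encoder_units < 1L || decoder_units < 1L)
      stop("invalid forecaster_config: unit counts must be >= 1", call. = FALSE)
    if (n_features < 1L || w_in < 1L || w_out < 1L)
      stop("invalid forecaster_config: n_features, w_in, w_out must be >= 1",
           call. = FALSE)
    if (epochs < 0L) stop("invalid forecaster_config: epochs must be >= 0",
                          call. = FALSE)
    if (batch_windows < 1L)
      stop("invalid forecaster_config: batch_windows must be >= 1", call. = FALSE)
    if (!is.finite(learning_rate) || learning_rate <= 0)
      stop("invalid forecaster_config: learning_rate must be > 0", call. = FALSE)
  })
  class(cfg) <- "forecaster_config"
  cfg
}

#' @export
print.forecaster_config <- function(x, ...) {
  cat(sprintf(
    "Encoder-decoder LSTM config: %d -> %d units, window %d -> %d x %d features\n",
    x$encoder_units, x$decoder_units, x$w_in, x$w_out, x$n_features))
  cat(sprintf("  %s cell activation; Adam lr %g, %d epochs, %d-window batches, seed %d\n",
              x$activation, x$learning_rate, x$epochs, x$batch_windows, x$seed))
  invisible(x)
}

glorot_uniform <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# per-gate orthogonal recurrent blocks
orthogonal_gates <- function(units, n_gates = 4L) {
  do.call(cbind, lapply(seq_len(n_gates), function(i)
    qr.Q(qr(matrix(rnorm(units * units), units, units)))))
}

init_forecaster_params <- function(cfg) {
  with_seed(cfg$seed, {
    U <- cfg$encoder_units; V <- cfg$decoder_units; F_ <- cfg$n_features
    forget_one <- function(u) {
      b <- numeric(4L * u)
      b[(u + 1L):(2L * u)] <- 1  # forget-gate bias 1: remember by default
      b
    }
    list(enc_Wx = glorot_uniform(F_, 4L * U),
         enc_Wh = orthogonal_gates(U),
         enc_b = forget_one(U),
         dec_Wx = glorot_uniform(U, 4L * V),
         dec_Wh = orthogonal_gates(V),
         dec_b = forget_one(V),
         out_W = glorot_uniform(V, F_),
         out_b = numeric(F_))
  })
}

# (n, T, F) R array -> (n, F, T) cube layout expected by the C++ core
to_cube_layout <- function(a) aperm(a, c(1L, 3L, 2L))
from_cube_layout <- function(a) aperm(a, c(1L, 3L, 2L))

#' Fit the encoder-decoder LSTM gait forecaster
#'
#' Trains the sequence-to-sequence model on a [make_windows()] dataset of
#' normalised kinematics, minimising mean absolute error with Adam. Training
#' is deterministic given the config seed (single-threaded, seeded weight
#' initialisation and batch shuffling). With `epochs = 0` the model is
#' returned at its random initialisation — the untrained baseline used in
#' sweep comparisons.
#'
#' @param windows A `windowed_dataset` of training windows (normalised scale).
#' @param config A [forecaster_config()]; if `NULL`, one is built from the
#'   dataset's window geometry and `...`.
#' @param ... Passed to [forecaster_config()] when `config` is `NULL`.
#' @return An object of class `gait_forecaster`: the fitted weights, the
#'   config, and the per-epoch training-loss history (normalised-scale MAE).
#' @examples
#' cfg <- synth_config(n_subjects = 2, strides_per_subject = 4, seed = 7)
#' d <- generate_dataset(cfg)
#' np <- zscore_fit(d$train)
#' wd <- make_windows(zscore_apply(d$train[[1]], np), w_in = 10, w_out = 5)
#' fit <- gait_forecaster(wd, encoder_units = 8, decoder_units = 8,
#'                        epochs = 2, seed = 1)
#' fit
#' @export
gait_forecaster <- function(windows, config = NULL, ...) {
  stopifnot(inherits(windows, "windowed_dataset"))
  n <- dim(windows$inputs)[1]
  if (n < 1L) stop("no training windows supplied", call. = FALSE)
  if (is.null(config)) {
    dots <- list(...)
    dots$w_in <- dots$w_out <- dots$n_features <- NULL  # geometry is the data's
    config <- do.call(forecaster_config,
                      c(dots, list(w_in = windows$config$w_in,
                                   w_out = windows$config$w_out,
                                   n_features = windows$n_features)))
  }
  stopifnot(inherits(config, "forecaster_config"))
  if (config$w_in != windows$config$w_in || config$w_out != windows$config$w_out ||
      config$n_features != windows$n_features)
    stop(sprintf(
      "config/window geometry mismatch: config %d->%d x %d, data %d->%d x %d",
      config$w_in, config$w_out, config$n_features,
      windows$config$w_in, windows$config$w_out, windows$n_features),
      call. = FALSE)

  params <- init_forecaster_params(config)
  X <- to_cube_layout(windows$inputs)
  Tg <- to_cube_layout(windows$targets)
  res <- cpp_train(params, X, Tg,
                   epochs = config$epochs,
                   batch_windows = config$batch_windows,
                   lr = config$learning_rate, beta1 = config$beta1,
                   beta2 = config$beta2, eps = config$epsilon,
                   clipnorm = config$clipnorm, activation = config$activation,
                   seed = config$seed, shuffle = TRUE)
  structure(list(params = res$params, config = config,
                 history = as.numeric(res$history), n_windows = n),
            class = "gait_forecaster")
}

#' @export
print.gait_forecaster <- function(x, ...) {
  cat("Encoder-decoder LSTM gait forecaster\n")
  cat(sprintf("  window: %d samples in -> %d samples out, %d features\n",
              x$config$w_in, x$config$w_out, x$config$n_features))
  cat(sprintf("  units: encoder %d, decoder %d (%s cell activation), %s parameters\n",
              x$config$encoder_units, x$config$decoder_units,
              x$config$activation, format(n_params(x), big.mark = ",")))
  if (length(x$history))
    cat(sprintf("  trained %d epochs on %d windows; final MAE %.4g (normalised)\n",
                length(x$history), x$n_windows, tail(x$history, 1)))
  else
    cat(sprintf("  untrained (random initialisation), %d windows attached\n",
                x$n_windows))
  invisible(x)
}

#' @export
summary.gait_forecaster <- function(object, ...) {
  h <- object$history
  out <- list(config = object$config, n_params = n_params(object),
              n_windows = object$n_windows, history = h,
              initial_loss = if (length(h)) h[1] else NA_real_,
              final_loss = if (length(h)) tail(h, 1) else NA_real_)
  class(out) <- "summary.gait_forecaster"
  out
}

#' @export
print.summary.gait_forecaster <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %s trainable parameters, %d training windows\n",
              format(x$n_params, big.mark = ","), x$n_windows))
  if (length(x$history))
    cat(sprintf("  training MAE (normalised): %.4g -> %.4g over %d epochs\n",
                x$initial_loss, x$final_loss, length(x$history)))
  invisible(x)
}

#' @export
coef.gait_forecaster <- function(object, ...) object$params

#' Number of trainable parameters
#'
#' Per LSTM layer `4 * (n_in * u + u^2 + u)` (fused input, recurrent and bias
#' blocks for the four gates), plus the dense head `u_dec * F + F`.
#'
#' @param object A `gait_forecaster`.
#' @return Integer parameter count.
#' @export
n_params <- function(object) {
  sum(vapply(object$params, length, 1L))
}

#' @export
plot.gait_forecaster <- function(x, ...) {
  if (!length(x$history)) {
    warning("no training history to plot (untrained model)")
    return(invisible(x))
  }
  plot(seq_along(x$history), x$history, type = "b", pch = 16,
       xlab = "epoch", ylab = "training MAE (normalised)",
       main = "Encoder-decoder LSTM training loss", ...)
  invisible(x)
}

#' Predict output windows for new input windows
#'
#' @param object A fitted `gait_forecaster`.
#' @param newdata A `windowed_dataset` or a 3-D array `n x w_in x F` on the
#'   normalised scale.
#' @param ... Unused.
#' @return Array `n x w_out x F` of predicted windows (normalised scale).
#' @export
predict.gait_forecaster <- function(object, newdata, ...) {
  a <- if (inherits(newdata, "windowed_dataset")) newdata$inputs else newdata
  if (length(dim(a)) != 3L)
    stop("newdata must be a windowed_dataset or an n x w_in x F array",
         call. = FALSE)
  if (dim(a)[2] != object$config$w_in || dim(a)[3] != object$config$n_features)
    stop(sprintf("newdata windows are %d x %d, model expects %d x %d",
                 dim(a)[2], dim(a)[3], object$config$w_in,
                 object$config$n_features), call. = FALSE)
  Y <- cpp_predict(object$params, to_cube_layout(a), object$config$w_out,
                   object$config$activation)
  from_cube_layout(Y)
}

#' @export
residuals.gait_forecaster <- function(object, windows, ...) {
  if (missing(windows))
    stop("supply the windowed_dataset whose residuals are wanted", call. = FALSE)
  predict(object, windows) - windows$targets
}

#' @export
fitted.gait_forecaster <- function(object, windows, ...) {
  if (missing(windows))
    stop("supply the windowed_dataset whose fitted values are wanted",
         call. = FALSE)
  predict(object, windows)
}

#' Forecast a whole stride window-by-window
#'
#' Slides over the measured series exactly as the training transformation
#' does: each input window contains measured samples (not earlier
#' predictions), the model predicts the next `w_out` samples, and consecutive
#' predicted windows are stitched into a contiguous trajectory covering the
#' series from sample `w_in + 1` onward. The first `w_in` samples of `series`
#' are the priming window taken from the preceding gait cycle. Set
#' `recursive = TRUE` to feed predictions back as inputs instead (free-run
#' forecasting; error then compounds across the stride).
#'
#' @param object A fitted `gait_forecaster`.
#' @param series A [kinematic_series()] (original units) holding the priming
#'   samples immediately followed by the stride(s) to forecast, or a numeric
#'   matrix on the same scale.
#' @param norm_params The training-set [zscore_fit()] parameters; predictions
#'   are de-normalised through them. Pass `NULL` if `series` is already
#'   normalised and normalised output is wanted.
#' @param recursive Feed predictions back as model inputs (default `FALSE`).
#' @return List with `predicted` and `actual` matrices (rows = the forecast
#'   samples, columns = features, original units when `norm_params` is
#'   given), aligned sample-for-sample.
#' @export
forecast_stride <- function(object, series, norm_params = NULL,
                            recursive = FALSE) {
  stopifnot(inherits(object, "gait_forecaster"))
  m <- if (inherits(series, "kinematic_series")) series$values else as.matrix(series)
  w_in <- object$config$w_in; w_out <- object$config$w_out
  if (nrow(m) < w_in + w_out)
    stop(sprintf("series too short: %d samples, need priming w_in=%d plus at least w_out=%d",
                 nrow(m), w_in, w_out), call. = FALSE)
  norm <- if (is.null(norm_params)) m else zscore_apply(m, norm_params)
  wd <- make_windows(norm, w_in = w_in, w_out = w_out)

  if (!recursive) {
    pred <- stitch_targets(predict(object, wd))
  } else {
    n_win <- dim(wd$inputs)[1]
    buf <- norm[seq_len(w_in), , drop = FALSE]
    pred <- matrix(0, n_win * w_out, ncol(m))
    for (i in seq_len(n_win)) {
      x <- array(buf, dim = c(1L, w_in, ncol(m)))
      y <- predict(object, x)[1, , , drop = TRUE]
      y <- matrix(y, w_out, ncol(m))
      pred[((i - 1L) * w_out + 1L):(i * w_out), ] <- y
      buf <- rbind(buf, y)[(w_out + 1L):(w_in + w_out), , drop = FALSE]
    }
  }
  actual <- stitch_targets(wd$targets)
  if (!is.null(norm_params)) {
    pred <- zscore_invert(pred, norm_params)
    actual <- zscore_invert(actual, norm_params)
  }
  colnames(pred) <- colnames(actual) <- .features[seq_len(ncol(pred))]
  list(predicted = pred, actual = actual)
}

#' Trim a held-out series to priming samples plus the test stride
#'
#' A held-out series from [generate_dataset()] holds one full preceding
#' stride followed by the test stride(s). Forecasting only needs the last
#' `w_in` samples of the preceding cycle as priming, so this keeps rows from
#' `w_in` samples before the second stride onset through the end of the
#' series. The result feeds [forecast_stride()] directly, making the
#' evaluated samples exactly the test stride.
#'
#' @param series A [kinematic_series()] with at least two stride boundaries.
#' @param w_in Priming length in samples.
#' @return A [kinematic_series()] of `w_in + test-stride` samples.
#' @export
trim_test_series <- function(series, w_in) {
  stopifnot(inherits(series, "kinematic_series"))
  b <- series$stride_boundaries
  if (length(b) < 2L)
    stop("test series needs a preceding stride plus a test stride", call. = FALSE)
  onset <- b[2L]
  if (onset - w_in < 1L)
    stop(sprintf("preceding stride too short for %d priming samples", w_in),
         call. = FALSE)
  keep <- (onset - w_in):nrow(series$values)
  kinematic_series(series$values[keep, , drop = FALSE], series$sample_rate,
                   b[-1L] - (onset - w_in) + 1L, subject_id = series$subject_id)
}

#' Save / load a fitted forecaster
#'
#' The weights go to an RDS file and a YAML sidecar carries the architecture
#' configuration (and optional normalisation parameters) in readable form.
#'
#' @param object A `gait_forecaster`.
#' @param path Path of the RDS checkpoint; the sidecar is `path` with a
#'   `.yaml` extension appended.
#' @param norm_params Optional `norm_params` to store alongside.
#' @export
write_forecaster <- function(object, path, norm_params = NULL) {
  stopifnot(inherits(object, "gait_forecaster"))
  saveRDS(list(model = object, norm_params = norm_params), path)
  side <- unclass(object$config)
  if (!is.null(norm_params))
    side$normalisation <- list(mean = as.list(norm_params$mean),
                               sd = as.list(norm_params$sd))
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_forecaster
#' @export
read_forecaster <- function(path) {
  x <- readRDS(path)
  if (!inherits(x$model, "gait_forecaster"))
    stop("file does not contain a gait_forecaster checkpoint", call. = FALSE)
  x
}
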