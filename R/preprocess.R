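#' Zero-phase low-pass filter a kinematic series
#'
#' Applies a 2nd-order Butterworth low-pass forward and backward per channel
#' (an effective 4th-order zero-phase response, the standard conditioning for
#' biomechanical signals: no phase lag, so gait-event timing is preserved).
#' Output length equals input length and stride boundaries are untouched.
#'
#' @param series A [kinematic_series()] or a numeric matrix/vector.
#' @param cutoff Cut-off frequency in Hz; must satisfy `0 < cutoff <
#'   sample_rate / 2`.
#' @param sample_rate Sampling rate in Hz; taken from `series` when it is a
#'   [kinematic_series()].
#' @return Same type as the input, filtered per channel.
#' @export
lowpass <- function(series, cutoff = 15, sample_rate = NULL) {
  is_ks <- inherits(series, "kinematic_series")
  if (is_ks) sample_rate <- series$sample_rate
  if (is.null(sample_rate))
    stop("sample_rate is required when filtering a bare matrix", call. = FALSE)
  nyq <- sample_rate / 2
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("cutoff must lie in (0, %g) Hz (Nyquist); got %g", nyq, cutoff),
         call. = FALSE)
  bf <- signal::butter(2, cutoff / nyq, type = "low")
  filt1 <- function(x) zero_phase_filter(bf, x)
  if (is_ks) {
    out <- series
    out$values <- apply(series$values, 2, filt1)
    colnames(out$values) <- .features
    out
  } else if (is.matrix(series)) {
    apply(series, 2, filt1)
  } else {
    filt1(as.numeric(series))
  }
}

# Forward-backward filtering with odd-reflection end padding, so start-up
# transients fall on the padding rather than the data (the Matlab/Scipy
# filtfilt convention; a constant signal passes through exactly).
zero_phase_filter <- function(bf, x) {
  n <- length(x)
  ord <- max(length(bf$a), length(bf$b)) - 1L
  npad <- min(n - 2L, 10L * ord)
  if (npad < 1L)
    stop("signal too short to filter", call. = FALSE)
  dc <- sum(bf$b) / sum(bf$a)
  run <- function(z) as.numeric(signal::filter(
    bf, z, init.x = rep(z[1], length(bf$b) - 1L),
    init.y = rep(z[1] * dc, length(bf$a) - 1L)))
  ext <- c(2 * x[1] - x[(npad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - npad)])
  y <- run(ext)
  y <- rev(run(rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Fit z-score normalisation parameters
#'
#' Pools all samples of the supplied training series per feature and records
#' the mean and standard deviation (population convention, divisor n; at gait
#' dataset sizes the n vs n-1 distinction is negligible and the population
#' form makes apply/fit exactly idempotent). Fit normalisation on the
#' training subjects only and reuse the parameters for held-out data.
#'
#' @param x A [kinematic_series()], a list of them, or a numeric matrix with
#'   one column per feature.
#' @return An object of class `norm_params`: list of `mean` and `sd`, one
#'   entry per feature.
#' @export
zscore_fit <- function(x) {
  m <- pool_values(x)
  if (nrow(m) < 2L)
    stop("zscore_fit needs at least 2 pooled samples per feature", call. = FALSE)
  mu <- colMeans(m)
  n <- nrow(m)
  sdev <- sqrt(pmax(colSums((m - rep(mu, each = n))^2) / n, 0))
  bad <- which(sdev <= 0 | !is.finite(sdev))
  if (length(bad))
    stop(sprintf("zero-variance feature(s): %s — cannot z-score",
                 paste(colnames(m)[bad], collapse = ", ")), call. = FALSE)
  structure(list(mean = mu, sd = sdev), class = "norm_params")
}

pool_values <- function(x) {
  if (inherits(x, "kinematic_series")) return(x$values)
  if (is.list(x) && all(vapply(x, inherits, TRUE, "kinematic_series")))
    return(do.call(rbind, lapply(x, `[[`, "values")))
  m <- as.matrix(x)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  m
}

#' @export
print.norm_params <- function(x, ...) {
  cat("z-score normalisation parameters (population SD):\n")
  print(data.frame(feature = names(x$mean), mean = unname(x$mean),
                   sd = unname(x$sd)), row.names = FALSE)
  invisible(x)
}

#' Apply or invert z-score normalisation
#'
#' `zscore_apply` maps each feature to `(x - mean) / sd`; `zscore_invert` is
#' its exact inverse, so `zscore_invert(zscore_apply(x, p), p)` reproduces `x`
#' to floating-point accuracy.
#'
#' @param x A [kinematic_series()] or numeric matrix.
#' @param params A `norm_params` object from [zscore_fit()].
#' @return Same type as `x`, transformed per feature.
#' @export
zscore_apply <- function(x, params) zscore_transform(x, params, invert = FALSE)

#' @rdname zscore_apply
#' @export
zscore_invert <- function(x, params) zscore_transform(x, params, invert = TRUE)

zscore_transform <- function(x, params, invert) {
  stopifnot(inherits(params, "norm_params"))
  is_ks <- inherits(x, "kinematic_series")
  m <- if (is_ks) x$values else as.matrix(x)
  if (ncol(m) != length(params$mean))
    stop(sprintf("feature count mismatch: data has %d columns, params %d",
                 ncol(m), length(params$mean)), call. = FALSE)
  out <- if (invert) sweep(sweep(m, 2, params$sd, "*"), 2, params$mean, "+")
         else        sweep(sweep(m, 2, params$mean, "-"), 2, params$sd, "/")
  if (is_ks) { x$values <- out; colnames(x$values) <- .features; x } else out
}

#' Numerical differentiation of a sampled signal
#'
#' First derivative by central differences (one-sided at the ends); second
#' derivative by the second central difference with end values replicated
#' from the nearest interior point. This is how angular velocity is obtained
#' from segment Euler/Cardan angles and linear acceleration from the double
#' derivative of segment displacement. Output length equals input length.
#'
#' @param x Numeric vector or matrix (columns differentiated independently).
#' @param order 1 or 2.
#' @param dt Sampling interval in seconds.
#' @return Numeric vector/matrix of the same shape.
#' @export
differentiate <- function(x, order = 1L, dt) {
  if (is.matrix(x)) return(apply(x, 2, differentiate, order = order, dt = dt))
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("differentiate needs a signal of length >= 3", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  order <- as.integer(order)
  if (order == 1L) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    d[1] <- (x[2] - x[1]) / dt
    d[n] <- (x[n] - x[n - 1]) / dt
    d
  } else if (order == 2L) {
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
    d[1] <- d[2]
    d[n] <- d[n - 1]
    d
  } else stop("order must be 1 or 2", call. = FALSE)
}

#' Save / load normalisation parameters as YAML
#'
#' One mapping per feature with `mean` and `sd`, so train-time parameters can
#' be reused at inference.
#'
#' @param params A `norm_params` object.
#' @param path File path.
#' @export
write_norm_params <- function(params, path) {
  stopifnot(inherits(params, "norm_params"))
  obj <- lapply(seq_along(params$mean), function(i)
    list(mean = unname(params$mean[i]), sd = unname(params$sd[i])))
  names(obj) <- names(params$mean)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_norm_params
#' @export
read_norm_params <- function(path) {
  obj <- yaml::read_yaml(path)
  mu <- vapply(obj, function(e) as.numeric(e$mean), numeric(1))
  sdev <- vapply(obj, function(e) as.numeric(e$sd), numeric(1))
  structure(list(mean = mu, sd = sdev), class = "norm_params")
}
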