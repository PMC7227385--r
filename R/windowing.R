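#' Sliding-window configuration
#'
#' Pairs an input window of `w_in` samples with an output (prediction) window
#' of `w_out` samples. The slide between consecutive windows is locked to the
#' output size, so successive target windows tile the series without gap or
#' overlap.
#'
#' @param w_in Input window length in samples (>= 1).
#' @param w_out Output window length in samples (>= 1); also the slide.
#' @return An object of class `window_config`.
#' @export
window_config <- function(w_in = 25L, w_out = 5L) {
  w_in <- as.integer(w_in); w_out <- as.integer(w_out)
  if (is.na(w_in) || w_in < 1L) stop("w_in must be >= 1", call. = FALSE)
  if (is.na(w_out) || w_out < 1L) stop("w_out must be >= 1", call. = FALSE)
  structure(list(w_in = w_in, w_out = w_out, slide = w_out),
            class = "window_config")
}

#' Transform a series into aligned input/target windows
#'
#' Converts an `M x F` series into a 3-D supervised dataset: window `i`
#' (1-based) has input rows `o_i .. o_i + w_in - 1` and target rows
#' `o_i + w_in .. o_i + w_in + w_out - 1`, with `o_i = (i - 1) * w_out + 1`.
#' The number of windows is `floor((M - w_in - w_out) / w_out) + 1`; trailing
#' samples that do not fill a complete target window are dropped (never
#' padded). Feature order is preserved.
#'
#' @param series A [kinematic_series()] or numeric matrix (rows = samples).
#' @param config A [window_config()], or `w_in`/`w_out` given directly.
#' @param w_in,w_out Convenience scalars used when `config` is missing.
#' @return An object of class `windowed_dataset`: list with `inputs`
#'   (`n x w_in x F` array), `targets` (`n x w_out x F`), `offsets` (1-based
#'   start row of each input window) and the `window_config`.
#' @examples
#' m <- matrix(rnorm(120), 30, 4)
#' wd <- make_windows(m, w_in = 25, w_out = 5)
#' dim(wd$inputs)   # 1 x 25 x 4
#' @export
make_windows <- function(series, config = NULL, w_in = 25L, w_out = 5L) {
  if (is.null(config)) config <- window_config(w_in, w_out)
  stopifnot(inherits(config, "window_config"))
  m <- if (inherits(series, "kinematic_series")) series$values else as.matrix(series)
  storage.mode(m) <- "double"
  M <- nrow(m); F_ <- ncol(m)
  need <- config$w_in + config$w_out
  if (M < need)
    stop(sprintf("insufficient data: %d samples, need at least w_in + w_out = %d",
                 M, need), call. = FALSE)
  n <- (M - need) %/% config$slide + 1L
  offsets <- (seq_len(n) - 1L) * config$slide + 1L

  # gather by index matrix: rows of all input (resp. target) windows at once
  in_rows <- outer(offsets, 0:(config$w_in - 1L), `+`)      # n x w_in
  tg_rows <- outer(offsets + config$w_in, 0:(config$w_out - 1L), `+`)
  inputs <- array(m[as.vector(in_rows), , drop = FALSE],
                  dim = c(n, config$w_in, F_))
  targets <- array(m[as.vector(tg_rows), , drop = FALSE],
                   dim = c(n, config$w_out, F_))
  structure(list(inputs = inputs, targets = targets, offsets = offsets,
                 config = config, n_features = F_),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("Windowed dataset: %d windows (input %d x %d, target %d x %d, slide %d)\n",
              length(x$offsets), x$config$w_in, x$n_features,
              x$config$w_out, x$n_features, x$config$slide))
  invisible(x)
}

#' Concatenate windowed datasets from several series
#'
#' Windows each series independently (windows never straddle subject
#' boundaries, where the signal is discontinuous) and stacks the results.
#'
#' @param series_list List of [kinematic_series()] or matrices.
#' @param config A [window_config()].
#' @return A `windowed_dataset`; `offsets` restart per source series and a
#'   `series_index` element records each window's source.
#' @export
make_windows_multi <- function(series_list, config) {
  parts <- lapply(series_list, make_windows, config = config)
  inputs <- do.call(abind3, lapply(parts, `[[`, "inputs"))
  targets <- do.call(abind3, lapply(parts, `[[`, "targets"))
  structure(list(inputs = inputs, targets = targets,
                 offsets = unlist(lapply(parts, `[[`, "offsets")),
                 series_index = rep(seq_along(parts),
                                    vapply(parts, function(p) length(p$offsets), 1L)),
                 config = config, n_features = parts[[1]]$n_features),
            class = "windowed_dataset")
}

# bind 3-D arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], 1))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 1L
  for (a in arrs) {
    k <- dim(a)[1]
    out[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  out
}

#' Stitch target windows back into a contiguous series
#'
#' Because the slide equals the output size, the target windows of a
#' [make_windows()] dataset partition the covered range; concatenating them
#' in order reproduces the source rows `w_in + 1 .. w_in + n * w_out`
#' exactly. The same operation turns per-window predictions into a
#' whole-stride trajectory.
#'
#' @param x A `windowed_dataset`, or a 3-D array of per-window predictions
#'   (`n x w_out x F`).
#' @return Numeric matrix, `n * w_out` rows by `F` columns.
#' @export
stitch_targets <- function(x) {
  arr <- if (inherits(x, "windowed_dataset")) x$targets else x
  d <- dim(arr)
  if (length(d) != 3L) stop("expected an n x w_out x F array", call. = FALSE)
  out <- matrix(0, d[1] * d[2], d[3])
  for (i in seq_len(d[1]))
    out[((i - 1L) * d[2] + 1L):(i * d[2]), ] <- arr[i, , ]
  out
}

#' Save / load a windowed dataset (compressed binary archive)
#'
#' @param x A `windowed_dataset`.
#' @param path File path.
#' @export
write_windows <- function(x, path) {
  stopifnot(inherits(x, "windowed_dataset"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "windowed_dataset"))
    stop("file does not contain a windowed_dataset", call. = FALSE)
  x
}
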