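#' @useDynLib gaitcast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd coef predict residuals fitted
#' @importFrom utils read.csv write.csv head tail
NULL

# Canonical feature order used everywhere in the package.
.features <- c("thigh_la", "shank_la", "thigh_av", "shank_av")

#' Configuration for the synthetic gait generator
#'
#' Describes a cohort of synthetic walkers whose segment kinematics are
#' stride-locked quasi-periodic waveforms: each of the four channels (thigh and
#' shank linear acceleration, m/s^2; thigh and shank angular velocity, deg/s)
#' is a low-order harmonic series in stride phase, perturbed per subject
#' (amplitude factors and phase offsets drawn once per subject), jittered per
#' stride in duration, and corrupted by additive Gaussian sensor noise.
#'
#' Defaults mirror a treadmill-walking study design: six subjects, 533 strides
#' each (so a five-subject training set holds 2,665 strides), 100 Hz sampling
#' and a 1.7 s mean stride so one stride spans 170 samples.
#'
#' @param n_subjects Number of subjects (>= 2; the last is held out for
#'   testing).
#' @param strides_per_subject Strides recorded per subject.
#' @param sample_rate Sampling rate in samples/second.
#' @param stride_duration_mean Mean stride duration in seconds.
#' @param stride_duration_sd Between-stride SD of stride duration in seconds.
#' @param n_harmonics Number of harmonics of the stride frequency per channel.
#' @param amplitude_scales Length-4 positive vector of channel amplitude
#'   scales, in channel units (m/s^2 for the LA channels, deg/s for the AV
#'   channels), ordered as `c(thigh_la, shank_la, thigh_av, shank_av)`.
#' @param subject_variation_sd Dimensionless SD of the per-subject
#'   multiplicative amplitude perturbation; also scales the per-subject
#'   harmonic phase offsets (SD `2 * pi * subject_variation_sd` radians).
#' @param noise_sd Additive Gaussian noise SD per channel, in channel units;
#'   a scalar is recycled across the four channels.
#' @param seed Integer root seed. All randomness derives from per-subject
#'   seeds so adding a subject never perturbs earlier subjects' data.
#' @return An object of class `synth_config` (a validated list).
#' @examples
#' cfg <- synth_config(n_subjects = 2, strides_per_subject = 5)
#' s <- generate_subject(cfg, 0)
#' dim(s$values)
#' @export
synth_config <- function(n_subjects = 6,
                         strides_per_subject = 533,
                         sample_rate = 100,
                         stride_duration_mean = 1.7,
                         stride_duration_sd = 0.03,
                         n_harmonics = 4,
                         amplitude_scales = c(2, 3, 150, 300),
                         subject_variation_sd = 0.08,
                         noise_sd = 0.02 * amplitude_scales,
                         seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    strides_per_subject = as.integer(strides_per_subject),
    sample_rate = sample_rate,
    stride_duration_mean = stride_duration_mean,
    stride_duration_sd = stride_duration_sd,
    n_harmonics = as.integer(n_harmonics),
    amplitude_scales = as.numeric(amplitude_scales),
    subject_variation_sd = subject_variation_sd,
    noise_sd = rep_len(as.numeric(noise_sd), 4L),
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid synth_config: field '%s' %s", field, msg), call. = FALSE)
  }
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 2L)
    stop_cfg("n_subjects", "must be >= 2 (training plus one held-out subject)")
  if (is.na(cfg$strides_per_subject) || cfg$strides_per_subject < 1L)
    stop_cfg("strides_per_subject", "must be >= 1")
  if (!is.finite(cfg$sample_rate) || cfg$sample_rate <= 0)
    stop_cfg("sample_rate", "must be > 0")
  if (!is.finite(cfg$stride_duration_mean) || cfg$stride_duration_mean <= 0)
    stop_cfg("stride_duration_mean", "must be > 0")
  if (!is.finite(cfg$stride_duration_sd) || cfg$stride_duration_sd < 0)
    stop_cfg("stride_duration_sd", "must be >= 0")
  if (is.na(cfg$n_harmonics) || cfg$n_harmonics < 1L)
    stop_cfg("n_harmonics", "must be >= 1")
  if (length(cfg$amplitude_scales) != 4L || any(!is.finite(cfg$amplitude_scales)) ||
      any(cfg$amplitude_scales <= 0))
    stop_cfg("amplitude_scales", "must be 4 finite positive values")
  if (!is.finite(cfg$subject_variation_sd) || cfg$subject_variation_sd < 0)
    stop_cfg("subject_variation_sd", "must be >= 0")
  if (any(!is.finite(cfg$noise_sd)) || any(cfg$noise_sd < 0))
    stop_cfg("noise_sd", "must be >= 0")
  if (is.na(cfg$seed)) stop_cfg("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic gait cohort configuration\n")
  cat(sprintf("  subjects: %d (last one held out), strides/subject: %d\n",
              x$n_subjects, x$strides_per_subject))
  cat(sprintf("  sample rate: %g Hz, stride %.3g s (SD %.3g s), %d harmonics\n",
              x$sample_rate, x$stride_duration_mean, x$stride_duration_sd,
              x$n_harmonics))
  cat(sprintf("  amplitude scales: %s\n",
              paste(sprintf("%s=%g", .features, x$amplitude_scales), collapse = ", ")))
  cat(sprintf("  subject variation SD: %g, noise SD: %s, seed: %d\n",
              x$subject_variation_sd,
              paste(signif(x$noise_sd, 3), collapse = "/"), x$seed))
  invisible(x)
}

# Run expr with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a kinematic time series
#'
#' The package's basic container: an n x 4 matrix of the four kinematic
#' channels in fixed column order (`thigh_la`, `shank_la`, `thigh_av`,
#' `shank_av`), the sampling rate, and the sample indices of successive heel
#' strikes of the same foot (stride onsets, 1-based).
#'
#' @param values Numeric matrix, n_samples x 4, all finite.
#' @param sample_rate Samples per second.
#' @param stride_boundaries Strictly increasing 1-based sample indices of
#'   stride onsets; consecutive gaps must be >= 2 samples.
#' @param subject_id Subject label.
#' @return An object of class `kinematic_series`.
#' @export
kinematic_series <- function(values, sample_rate, stride_boundaries = integer(),
                             subject_id = "subject") {
  values <- as.matrix(values)
  if (ncol(values) != 4L)
    stop("kinematic_series requires exactly 4 feature columns", call. = FALSE)
  if (any(!is.finite(values)))
    stop("kinematic_series values must all be finite", call. = FALSE)
  storage.mode(values) <- "double"
  colnames(values) <- .features
  b <- as.integer(stride_boundaries)
  if (length(b)) {
    if (any(b < 1L) || any(b > nrow(values)))
      stop("stride_boundaries must lie within the series", call. = FALSE)
    if (length(b) > 1L && any(diff(b) < 2L))
      stop("stride_boundaries must be strictly increasing with gaps >= 2 samples",
           call. = FALSE)
  }
  structure(list(values = values, sample_rate = sample_rate,
                 stride_boundaries = b, subject_id = as.character(subject_id)),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("Kinematic series '%s': %d samples x 4 channels @ %g Hz, %d strides\n",
              x$subject_id, nrow(x$values), x$sample_rate,
              length(x$stride_boundaries)))
  invisible(x)
}

# Fixed base waveform shape (before per-subject perturbation): harmonic
# amplitudes decay as 1/k and each channel gets distinct fixed phases so the
# four channels are linearly independent waveforms.
base_waveform_params <- function(n_harmonics, amplitude_scales) {
  k <- seq_len(n_harmonics)
  amp <- outer(1 / k, amplitude_scales)          # n_harmonics x 4
  phase <- outer(0.7 * k, c(0, 1.1, 2.3, 3.6))   # fixed, channel-specific
  list(amp = amp, phase = phase)
}

#' Generate one subject's synthetic gait series
#'
#' Each channel is a sum of `n_harmonics` sinusoids at integer multiples of
#' the stride frequency. Per-subject amplitude factors and phase offsets are
#' drawn once per subject; stride durations are jittered per stride; i.i.d.
#' Gaussian noise is added per sample. The output is deterministic given
#' `(cfg$seed, subject_index)`.
#'
#' @param cfg A [synth_config()].
#' @param subject_index 0-based subject index in `[0, n_subjects)`.
#' @return A [kinematic_series()] with one stride boundary per stride onset.
#' @export
generate_subject <- function(cfg, subject_index) {
  validate_synth_config(cfg)
  subject_index <- as.integer(subject_index)
  if (is.na(subject_index) || subject_index < 0L || subject_index >= cfg$n_subjects)
    stop(sprintf("subject_index must be in [0, %d)", cfg$n_subjects), call. = FALSE)

  base <- base_waveform_params(cfg$n_harmonics, cfg$amplitude_scales)
  # per-subject stream, independent of other subjects
  sub_seed <- (cfg$seed + 10007L * (subject_index + 1L)) %% .Machine$integer.max

  with_seed(sub_seed, {
    K <- cfg$n_harmonics
    amp_factor <- matrix(pmax(1 + rnorm(K * 4L, 0, cfg$subject_variation_sd), 0.05),
                         K, 4L)
    phase_off <- matrix(rnorm(K * 4L, 0, 2 * pi * cfg$subject_variation_sd), K, 4L)
    durations <- pmax(cfg$stride_duration_mean +
                        rnorm(cfg$strides_per_subject, 0, cfg$stride_duration_sd),
                      0.2)
    n_per_stride <- pmax(round(durations * cfg$sample_rate), 2L)

    # stride phase in cycles, resets at each stride onset
    phase_cycles <- unlist(lapply(n_per_stride, function(n) (seq_len(n) - 1) / n),
                           use.names = FALSE)
    n_total <- length(phase_cycles)
    boundaries <- cumsum(c(1L, n_per_stride[-length(n_per_stride)]))

    vals <- matrix(0, n_total, 4L)
    for (f in 1:4) {
      x <- numeric(n_total)
      for (k in seq_len(K)) {
        x <- x + base$amp[k, f] * amp_factor[k, f] *
          sin(2 * pi * k * phase_cycles + base$phase[k, f] + phase_off[k, f])
      }
      if (cfg$noise_sd[f] > 0) x <- x + rnorm(n_total, 0, cfg$noise_sd[f])
      vals[, f] <- x
    }
    kinematic_series(vals, cfg$sample_rate, boundaries,
                     subject_id = sprintf("S%02d", subject_index))
  })
}

#' Generate a leave-one-subject-out synthetic dataset
#'
#' Subjects `0 .. n_subjects - 2` form the training set; the last subject
#' contributes the test series, truncated to `test_strides` strides plus one
#' preceding stride whose tail supplies the priming samples. The split is
#' structural (by subject identity), never random.
#'
#' @param cfg A [synth_config()].
#' @param test_strides Number of test strides to keep (default 1).
#' @return A list with elements `train` (list of [kinematic_series()]) and
#'   `test` (one [kinematic_series()] holding `test_strides + 1` strides).
#' @export
generate_dataset <- function(cfg, test_strides = 1L) {
  validate_synth_config(cfg)
  test_strides <- as.integer(test_strides)
  if (is.na(test_strides) || test_strides < 1L)
    stop("test_strides must be >= 1", call. = FALSE)
  if (test_strides + 1L > cfg$strides_per_subject)
    stop("test_strides + 1 exceeds strides_per_subject", call. = FALSE)

  train <- lapply(seq_len(cfg$n_subjects - 1L) - 1L,
                  function(i) generate_subject(cfg, i))
  full <- generate_subject(cfg, cfg$n_subjects - 1L)

  # keep one priming stride plus test_strides strides
  b <- full$stride_boundaries
  n_keep <- test_strides + 1L
  start <- b[1L]
  end <- if (length(b) > n_keep) b[n_keep + 1L] - 1L else nrow(full$values)
  vals <- full$values[start:end, , drop = FALSE]
  new_b <- b[seq_len(n_keep)] - start + 1L
  test <- kinematic_series(vals, full$sample_rate, new_b, subject_id = full$subject_id)

  list(train = train, test = test)
}

#' Write / read a kinematic series as CSV
#'
#' Columns: `time_s`, the four channels, and a 0/1 `stride_start` flag.
#' Round-trips are lossless to better than 1e-12 relative error.
#'
#' @param series A [kinematic_series()].
#' @param path File path.
#' @return `write_kinematic_csv` returns `path` invisibly;
#'   `read_kinematic_csv` returns a [kinematic_series()].
#' @export
write_kinematic_csv <- function(series, path) {
  stopifnot(inherits(series, "kinematic_series"))
  n <- nrow(series$values)
  flag <- integer(n)
  flag[series$stride_boundaries] <- 1L
  df <- data.frame(time_s = (seq_len(n) - 1) / series$sample_rate,
                   series$values, stride_start = flag, check.names = FALSE)
  write.csv(format(df, digits = 17, scientific = NA, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinematic_csv
#' @param subject_id Subject label to attach on read.
#' @export
read_kinematic_csv <- function(path, subject_id = "subject") {
  df <- read.csv(path)
  need <- c("time_s", .features, "stride_start")
  if (!all(need %in% names(df)))
    stop(sprintf("CSV at '%s' lacks required columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  dt <- diff(df$time_s)
  rate <- 1 / stats::median(dt)
  kinematic_series(as.matrix(df[.features]), rate,
                   which(df$stride_start == 1), subject_id = subject_id)
}

#' Serialise a kinematic series to R's compressed binary format
#'
#' @inheritParams write_kinematic_csv
#' @export
write_kinematic_rds <- function(series, path) {
  stopifnot(inherits(series, "kinematic_series"))
  saveRDS(series, path)
  invisible(path)
}

#' @rdname write_kinematic_rds
#' @export
read_kinematic_rds <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "kinematic_series"))
    stop("file does not contain a kinematic_series", call. = FALSE)
  x
}
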