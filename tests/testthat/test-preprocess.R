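test_that("low-pass filter passes DC and the passband, kills the stopband", {
  rate <- 100
  t <- seq(0, 10, by = 1 / rate)
  # DC passes untouched
  expect_equal(lowpass(rep(3, 500), cutoff = 15, sample_rate = rate),
               rep(3, 500), tolerance = 1e-9)
  rms <- function(x) sqrt(mean(x^2))
  hi <- sin(2 * pi * 30 * t)
  lo <- sin(2 * pi * 2 * t)
  expect_lt(rms(lowpass(hi, 15, rate)) / rms(hi), 0.10)
  expect_lt(abs(rms(lowpass(lo, 15, rate)) / rms(lo) - 1), 0.05)
  # attenuation agrees with the analytic forward-backward Butterworth gain
  # (interior samples, away from the filter's edge transients)
  mid <- 300:700
  expect_equal(rms(lowpass(hi, 15, rate)[mid]) / rms(hi[mid]),
               butter2_filtfilt_gain(30, 15, rate), tolerance = 0.02)
  expect_equal(rms(lowpass(lo, 15, rate)[mid]) / rms(lo[mid]),
               butter2_filtfilt_gain(2, 15, rate), tolerance = 0.01)
})

test_that("filtering is linear and preserves series structure", {
  set.seed(1)
  x <- rnorm(400); y <- rnorm(400)
  lx <- lowpass(x, 10, 100); ly <- lowpass(y, 10, 100)
  expect_equal(lowpass(2 * x - 3 * y, 10, 100), 2 * lx - 3 * ly,
               tolerance = 1e-9)

  cfg <- synth_config(n_subjects = 2, strides_per_subject = 4, seed = 2)
  s <- generate_subject(cfg, 0)
  f <- lowpass(s, cutoff = 15)
  expect_identical(f$stride_boundaries, s$stride_boundaries)
  expect_identical(dim(f$values), dim(s$values))
  expect_error(lowpass(s, cutoff = 50), "Nyquist")
})

test_that("z-score fit uses the population divisor and rejects degenerate data", {
  p <- zscore_fit(matrix(c(1, 3, 1, 3), ncol = 2))
  expect_equal(unname(p$mean), c(2, 2))
  expect_equal(unname(p$sd), c(1, 1))  # divisor n, not n-1

  set.seed(3)
  std <- scale(matrix(rnorm(400), 100, 4))
  n <- nrow(std)
  std <- sweep(std, 2, apply(std, 2, function(x) sqrt(mean((x - mean(x))^2))), "/")
  p2 <- zscore_fit(std)
  expect_equal(unname(p2$mean), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(p2$sd), rep(1, 4), tolerance = 1e-9)

  expect_error(zscore_fit(matrix(c(1, 1, 1, 2, 3, 4), ncol = 2)), "zero-variance")
})

test_that("z-score apply/invert are exact inverses with unit statistics", {
  set.seed(4)
  m <- matrix(rnorm(4000, mean = 7, sd = 3), 1000, 4)
  colnames(m) <- c("thigh_la", "shank_la", "thigh_av", "shank_av")
  p <- zscore_fit(m)
  z <- zscore_apply(m, p)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-9)
  n <- nrow(z)
  sds <- apply(z, 2, function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(sds), rep(1, 4), tolerance = 1e-9)
  expect_equal(zscore_invert(z, p), m, tolerance = 1e-9)
  # point cases: x = mean -> 0, x = mean + sd -> 1
  one <- zscore_apply(rbind(p$mean, p$mean + p$sd), p)
  expect_equal(unname(one[1, ]), rep(0, 4))
  expect_equal(unname(one[2, ]), rep(1, 4))
  expect_error(zscore_apply(m[, 1:3], p), "mismatch")
})

test_that("normalisation parameters survive a YAML round-trip", {
  cfg <- synth_config(n_subjects = 2, strides_per_subject = 4, seed = 5)
  p <- zscore_fit(generate_subject(cfg, 0))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_norm_params(p, path)
  q <- read_norm_params(path)
  expect_equal(q$mean, p$mean, tolerance = 1e-12)
  expect_equal(q$sd, p$sd, tolerance = 1e-12)
})

test_that("numerical derivatives match closed forms", {
  dt <- 0.01
  t <- seq(0, 2, by = dt)
  # linear ramp: d/dt (5t) = 5
  d1 <- differentiate(5 * t, order = 1, dt = dt)
  expect_equal(d1[2:(length(t) - 1)], rep(5, length(t) - 2), tolerance = 1e-9)
  # quadratic: d2/dt2 (t^2) = 2
  d2 <- differentiate(t^2, order = 2, dt = dt)
  expect_equal(d2[2:(length(t) - 1)], rep(2, length(t) - 2), tolerance = 1e-6)
  # sinusoid: first derivative within O(dt^2) of the analytic derivative
  f <- 3
  x <- sin(2 * pi * f * t)
  dx <- differentiate(x, order = 1, dt = dt)
  interior <- 2:(length(t) - 1)
  err <- max(abs(dx[interior] - 2 * pi * f * cos(2 * pi * f * t[interior])))
  expect_lt(err, (2 * pi * f)^3 * dt^2 / 6 * 1.01)
  # iterated first derivative agrees with the direct second difference
  # (both stencils are exact on cubics, so any disagreement is roundoff)
  p3 <- t^3 + t^2 - 4 * t
  dd <- differentiate(differentiate(p3, 1, dt), 1, dt)
  d2p <- differentiate(p3, 2, dt)
  expect_equal(dd[3:(length(t) - 2)], d2p[3:(length(t) - 2)], tolerance = 1e-6)
  expect_error(differentiate(c(1, 2), 1, dt), "length")
  expect_error(differentiate(x, 1, 0), "dt")
})
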