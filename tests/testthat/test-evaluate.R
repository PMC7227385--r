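test_that("hand-computed metric values are reproduced exactly", {
  expect_equal(mae(c(1, 2, 3), c(1, 1, 4)), 2 / 3)
  expect_equal(mse(c(1, 2, 3), c(1, 1, 4)), 2 / 3)
  expect_equal(cc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mse(1:5, 1:5), 0)
  # constant error e everywhere: mse = e^2
  expect_equal(mse(rep(0, 7), rep(0.3, 7)), 0.09)
  # perfect linear relations
  y <- rnorm(20)
  expect_equal(cc(y, 2 * y + 3), 1)
  expect_equal(cc(y, -y), -1)
})

test_that("metrics agree with independent loop implementations to 1e-12", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(2:200, 1)
    y <- rnorm(n, sd = runif(1, 0.1, 10))
    yhat <- y + rnorm(n, sd = runif(1, 0.01, 5))
    expect_equal(mae(y, yhat), loop_mae(y, yhat), tolerance = 1e-12)
    expect_equal(mse(y, yhat), loop_mse(y, yhat), tolerance = 1e-12)
    expect_equal(cc(y, yhat), loop_cc(y, yhat), tolerance = 1e-12)
  }
})

test_that("metric invariances hold", {
  set.seed(22)
  y <- rnorm(50); yhat <- rnorm(50)
  # translation invariance of the error metrics
  expect_equal(mae(y + 5, yhat + 5), mae(y, yhat), tolerance = 1e-12)
  expect_equal(mse(y + 5, yhat + 5), mse(y, yhat), tolerance = 1e-12)
  # cc invariance under positive affine rescaling of either argument
  expect_equal(cc(3 * y + 2, yhat), cc(y, yhat), tolerance = 1e-12)
  expect_equal(cc(y, 0.5 * yhat - 7), cc(y, yhat), tolerance = 1e-12)
})

test_that("degenerate and mismatched metric inputs raise errors", {
  expect_error(mae(1:3, 1:4), "mismatch")
  expect_error(mse(1:3, 1:4), "mismatch")
  expect_error(cc(rep(1, 5), 1:5), "degenerate|constant")
  expect_error(cc(1:5, rep(2, 5)), "degenerate|constant")
  expect_error(cc(1, 1), "at least 2")
})

test_that("evaluate_forecast reports all four features per scope", {
  set.seed(23)
  actual <- matrix(rnorm(170 * 4), 170, 4)
  colnames(actual) <- c("thigh_la", "shank_la", "thigh_av", "shank_av")
  noisy <- actual + rnorm(170 * 4, sd = 0.1)

  perfect <- evaluate_forecast(actual, actual, scope = "full_stride")
  expect_equal(perfect$feature, colnames(actual))
  expect_equal(perfect$mae, rep(0, 4))
  expect_equal(perfect$mse, rep(0, 4))
  expect_equal(perfect$cc, rep(1, 4))
  expect_equal(perfect$n, rep(170L, 4))

  first <- evaluate_forecast(noisy, actual, scope = "first_window", w_out = 5)
  expect_equal(first$n, rep(5L, 4))
  expect_equal(first$mae[1], mae(actual[1:5, 1], noisy[1:5, 1]))
  ae <- attr(first, "abs_error")
  expect_equal(dim(ae), c(5L, 4L))
  expect_equal(ae[, 2], abs(actual[1:5, 2] - noisy[1:5, 2]))

  expect_error(evaluate_forecast(noisy[1:10, ], actual), "misaligned")
  expect_error(evaluate_forecast(noisy, actual, scope = "first_window"),
               "w_out")
})

test_that("metric reports serialise to CSV and YAML", {
  set.seed(24)
  actual <- matrix(rnorm(100 * 4), 100, 4)
  pred <- actual + rnorm(400, sd = 0.2)
  reps <- list(evaluate_forecast(pred, actual, "first_window", w_out = 5),
               evaluate_forecast(pred, actual, "full_stride"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metrics(reps, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), 8L)  # 4 features x 2 scopes
  expect_equal(back$mae[5:8], reps[[2]]$mae, tolerance = 1e-12)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_metrics(reps, yml)
  expect_length(yaml::read_yaml(yml), 8L)
})

test_that("sweep and horizon drivers have the specified structure", {
  d <- make_small_cohort(seed = 31, n_subjects = 3, strides = 6)
  # tiny models keep this structural test fast
  sw <- input_window_sweep(d$train, d$test, sizes = c(5, 10), w_out = 5,
                           encoder_units = 6, decoder_units = 6, epochs = 1,
                           batch_windows = 200)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 2L * 4L)
  expect_equal(unique(sw$input_window), c(5L, 10L))
  expect_true(all(sw$mae >= 0) && all(sw$mse >= 0))

  single <- input_window_sweep(d$train, d$test, sizes = 10, w_out = 5,
                               encoder_units = 6, decoder_units = 6,
                               epochs = 1, batch_windows = 200)
  expect_equal(nrow(single), 4L)
  expect_error(input_window_sweep(d$train, d$test, sizes = c(10, 5)),
               "increasing")

  hz <- horizon_comparison(d$train, d$test, w_in = 25, horizons = c(5, 10),
                           encoder_units = 6, decoder_units = 6, epochs = 1,
                           batch_windows = 200, seed = 1)
  expect_s3_class(hz, "horizon_comparison")
  # 2 horizons x 2 scopes x 4 features
  expect_equal(nrow(hz), 16L)
  expect_equal(unique(hz$scope), c("first_window", "full_stride"))
  expect_equal(unique(hz$feature), c("thigh_la", "shank_la", "thigh_av",
                                     "shank_av"))
  expect_equal(hz$n[hz$scope == "first_window" & hz$horizon == 5],
               rep(5L, 4))
})
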