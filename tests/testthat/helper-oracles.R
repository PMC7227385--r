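# Independent brute-force oracles used to verify the package's vectorised /
# compiled implementations. These deliberately use naive loops and separate
# arithmetic paths from the code under test.

# sliding-window transformation by explicit triple loop
brute_force_windows <- function(m, w_in, w_out) {
  M <- nrow(m); F_ <- ncol(m)
  slide <- w_out
  n <- floor((M - w_in - w_out) / slide) + 1
  inputs <- array(NA_real_, c(n, w_in, F_))
  targets <- array(NA_real_, c(n, w_out, F_))
  for (i in seq_len(n)) {
    o <- (i - 1) * slide
    for (t in seq_len(w_in))
      for (f in seq_len(F_)) inputs[i, t, f] <- m[o + t, f]
    for (t in seq_len(w_out))
      for (f in seq_len(F_)) targets[i, t, f] <- m[o + w_in + t, f]
  }
  list(inputs = inputs, targets = targets,
       offsets = (seq_len(n) - 1) * slide + 1)
}

loop_mae <- function(y, yhat) {
  s <- 0
  for (j in seq_along(y)) s <- s + abs(y[j] - yhat[j])
  s / length(y)
}

loop_mse <- function(y, yhat) {
  s <- 0
  for (j in seq_along(y)) s <- s + (y[j] - yhat[j])^2
  s / length(y)
}

loop_cc <- function(y, yhat) {
  n <- length(y)
  my <- sum(y) / n; mp <- sum(yhat) / n
  num <- 0; dy <- 0; dp <- 0
  for (j in seq_len(n)) {
    num <- num + (y[j] - my) * (yhat[j] - mp)
    dy <- dy + (y[j] - my)^2
    dp <- dp + (yhat[j] - mp)^2
  }
  num / sqrt(dy * dp)
}

# textbook standard (peephole-free, bias-free) LSTM, plain loops
standard_lstm_run <- function(w, x) {
  T_ <- nrow(x); H <- ncol(w$w_hi)
  h <- numeric(H); s <- numeric(H)
  outputs <- states <- matrix(0, T_, H)
  sig <- function(z) 1 / (1 + exp(-z))
  for (t in seq_len(T_)) {
    xi <- x[t, ]
    gi <- sig(colSums(xi * w$w_xi) + colSums(h * w$w_hi))
    gf <- sig(colSums(xi * w$w_xf) + colSums(h * w$w_hf))
    gc <- tanh(colSums(xi * w$w_xc) + colSums(h * w$w_hc))
    s <- gf * s + gi * gc
    go <- sig(colSums(xi * w$w_xo) + colSums(h * w$w_ho))
    h <- go * tanh(s)
    outputs[t, ] <- h
    states[t, ] <- s
  }
  list(outputs = outputs, states = states)
}

# analytic magnitude response of a digital (bilinear-transform, prewarped)
# 2nd-order Butterworth applied forward-backward: squared one-pass magnitude
butter2_filtfilt_gain <- function(freq, cutoff, fs = 100) {
  ratio <- tan(pi * freq / fs) / tan(pi * cutoff / fs)
  1 / (1 + ratio^4)
}

# small synthetic cohort shared by slow end-to-end tests
make_small_cohort <- function(seed, n_subjects = 6, strides = 30) {
  cfg <- synth_config(n_subjects = n_subjects, strides_per_subject = strides,
                      seed = seed)
  generate_dataset(cfg)
}
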