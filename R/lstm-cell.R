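#' Parameters of the peephole LSTM reference cell
#'
#' A from-scratch single-layer LSTM memory block with the three
#' peephole-weighted connections from the cell state into the input, forget
#' and output gates. Biases are fixed at zero. This cell is the package's
#' verification oracle for recurrent arithmetic: with the peephole weights
#' zeroed it must reproduce a standard LSTM step exactly.
#'
#' Weight shapes, for `n_input` inputs and `n_hidden` cells:
#' input weights `w_xi`, `w_xf`, `w_xc`, `w_xo` are `n_input x n_hidden`;
#' recurrent weights `w_hi`, `w_hf`, `w_hc`, `w_ho` are `n_hidden x n_hidden`;
#' peephole weights `w_ci`, `w_cf`, `w_co` are length-`n_hidden` vectors
#' (diagonal connections, one per cell).
#'
#' @param n_input Number of inputs.
#' @param n_hidden Number of memory cells.
#' @param init_sd SD of the Gaussian weight initialisation.
#' @param peephole If `FALSE`, peephole weights are set to zero.
#' @param seed Optional seed for reproducible weights.
#' @return An object of class `lstm_cell_params`.
#' @export
lstm_cell_params <- function(n_input, n_hidden, init_sd = 0.5,
                             peephole = TRUE, seed = NULL) {
  draw <- function() {
    mk <- function(r, c) matrix(rnorm(r * c, 0, init_sd), r, c)
    p <- list(
      w_xi = mk(n_input, n_hidden), w_xf = mk(n_input, n_hidden),
      w_xc = mk(n_input, n_hidden), w_xo = mk(n_input, n_hidden),
      w_hi = mk(n_hidden, n_hidden), w_hf = mk(n_hidden, n_hidden),
      w_hc = mk(n_hidden, n_hidden), w_ho = mk(n_hidden, n_hidden),
      w_ci = rnorm(n_hidden, 0, init_sd),
      w_cf = rnorm(n_hidden, 0, init_sd),
      w_co = rnorm(n_hidden, 0, init_sd)
    )
    if (!peephole) p$w_ci <- p$w_cf <- p$w_co <- numeric(n_hidden)
    p
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  p$n_input <- as.integer(n_input)
  p$n_hidden <- as.integer(n_hidden)
  class(p) <- "lstm_cell_params"
  p
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One step of the peephole LSTM reference cell
#'
#' Computes, with `f` the logistic sigmoid and `g = h = tanh` by default:
#' input gate from input, previous output and previous state (peephole);
#' forget gate likewise; cell input from input and previous output only;
#' state update `s_t = b_f * s_{t-1} + b_i * g(a_c)`; output gate peeping at
#' the *current* state `s_t`; and cell output `b_c = b_o * h(s_t)`. Biases
#' are zero throughout.
#'
#' @param params An [lstm_cell_params()] object.
#' @param x_t Input vector at time t (length `n_input`).
#' @param prev_output Cell output vector at t-1 (length `n_hidden`).
#' @param prev_state Cell state vector at t-1 (length `n_hidden`).
#' @param g,h Cell input / output activation functions (default `tanh`).
#' @return List with `output` and `state`, each length `n_hidden`, plus the
#'   gate activations (`input_gate`, `forget_gate`, `output_gate`).
#' @export
lstm_cell_step <- function(params, x_t, prev_output, prev_state,
                           g = tanh, h = tanh) {
  stopifnot(inherits(params, "lstm_cell_params"))
  x_t <- as.numeric(x_t)
  prev_output <- as.numeric(prev_output)
  prev_state <- as.numeric(prev_state)
  if (length(x_t) != params$n_input)
    stop(sprintf("x_t has length %d, expected %d", length(x_t), params$n_input),
         call. = FALSE)
  if (length(prev_output) != params$n_hidden || length(prev_state) != params$n_hidden)
    stop(sprintf("state vectors must have length %d", params$n_hidden),
         call. = FALSE)

  a_i <- drop(x_t %*% params$w_xi + prev_output %*% params$w_hi) +
    params$w_ci * prev_state
  b_i <- sigmoid(a_i)
  a_f <- drop(x_t %*% params$w_xf + prev_output %*% params$w_hf) +
    params$w_cf * prev_state
  b_f <- sigmoid(a_f)
  a_c <- drop(x_t %*% params$w_xc + prev_output %*% params$w_hc)
  s_t <- b_f * prev_state + b_i * g(a_c)
  a_o <- drop(x_t %*% params$w_xo + prev_output %*% params$w_ho) +
    params$w_co * s_t                      # output gate peeps at current state
  b_o <- sigmoid(a_o)
  list(output = b_o * h(s_t), state = s_t,
       input_gate = b_i, forget_gate = b_f, output_gate = b_o)
}

#' Run the reference cell over a sequence
#'
#' @param params An [lstm_cell_params()] object.
#' @param x Numeric matrix, `T x n_input`, one row per time step.
#' @param g,h Activations passed to [lstm_cell_step()].
#' @return List with `outputs` and `states`, each `T x n_hidden`.
#' @export
lstm_cell_run <- function(params, x, g = tanh, h = tanh) {
  x <- as.matrix(x)
  T_ <- nrow(x)
  out <- st <- matrix(0, T_, params$n_hidden)
  o <- s <- numeric(params$n_hidden)
  for (t in seq_len(T_)) {
    step <- lstm_cell_step(params, x[t, ], o, s, g = g, h = h)
    o <- step$output; s <- step$state
    out[t, ] <- o; st[t, ] <- s
  }
  list(outputs = out, states = st)
}
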