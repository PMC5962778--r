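#' Feedback-error teaching signals from perceived hand position
#'
#' The trainer never sees a target output; instead the displacement of each
#' hand's proprioceptively perceived position from the centre of the visual
#' field is converted into motor-command errors on the eight output units
#' (feedback-error learning). With perceived coordinates `(xL, yL)`,
#' `(xR, yR)` (block centres, cm, y up) and block pitch `d`:
#'
#' \deqn{e_0 = (x_0 + d - x_L)/d, \quad e_1 = (y_0 + d - y_L)/d,}
#' \deqn{e_2 = -e_0, \quad e_3 = -e_1,}
#'
#' and likewise `e_4..e_7` for the right hand. The unit order per hand is
#' right, up, left, down (matching the decoder's preferred directions).
#' Because perceived positions are block centres, every error is exactly
#' -1, 0 or +1, and all are 0 iff the hand is perceived in the central
#' block.
#'
#' @param perceived_left,perceived_right cm coordinates from
#'   [perceived_block()].
#' @param geometry an [grid_geometry()] object.
#' @return numeric vector `e` of length 8.
#' @export
motor_errors <- function(perceived_left, perceived_right, geometry) {
  cx <- geometry$x0 + geometry$d
  cy <- geometry$y0 + geometry$d
  centres <- geometry$x0 + (0:2) * geometry$d
  ok <- function(p) all(p %in% centres)
  if (!ok(perceived_left) || !ok(perceived_right))
    stop("perceived positions must be block centres")
  d <- geometry$d
  e01 <- c((cx - perceived_left[[1]]) / d, (cy - perceived_left[[2]]) / d)
  e45 <- c((cx - perceived_right[[1]]) / d, (cy - perceived_right[[2]]) / d)
  c(e01, -e01, e45, -e45)
}

#' Overall network error
#'
#' `J = 1/2 * sum(e_k^2)` over the eight motor-command errors. Since each
#' error is in \{-1, 0, +1\}, J takes values 0, 0.5, ..., 4, and J = 0 iff
#' both hands are perceived in the central block.
#'
#' @param errors vector from [motor_errors()].
#' @return numeric scalar.
#' @export
network_error <- function(errors) 0.5 * sum(errors^2)

## ---- RTRL sensitivity machinery (pure-R reference implementation) -------
##
## Trainable hidden-layer weights are flattened into one vector w of length
## n_wh = n_in*n_hidden + n_hidden^2 + n_hidden with column-major mapping:
##   W_in[i, j]  -> (j-1)*n_in + i
##   W_rec[m, j] -> n_in*n_hidden + (j-1)*n_hidden + m
##   b_hid[j]    -> n_in*n_hidden + n_hidden^2 + j
## The sensitivity matrix P is n_hidden x n_wh with P[j, w] = d hidden_j / d w.
## Masked (ownership x corollary-discharge) weights never receive an
## immediate term, so their sensitivity columns stay identically zero.

#' Fresh sensitivity state
#'
#' @param network an `"hr_network"` object.
#' @return an `"hr_sens"` list: `P` (n_hidden x n_wh sensitivities),
#'   gradient accumulators for hidden-layer weights (`g_wh`), output weights
#'   (`g_out`) and output biases (`g_bout`), and the update counter.
#' @export
init_sensitivities <- function(network) {
  n_wh <- network$n_in * network$n_hidden + network$n_hidden^2 +
    network$n_hidden
  s <- list(P = matrix(0, network$n_hidden, n_wh),
            g_wh = numeric(n_wh),
            g_out = matrix(0, network$n_hidden, network$n_out),
            g_bout = numeric(network$n_out),
            steps = 0L)
  class(s) <- "hr_sens"
  s
}

#' Propagate RTRL sensitivities one step
#'
#' Exact recursion for the one-step-recurrent logistic hidden layer:
#' `P_j(t) = sigma'(net_j) * (sum_m W_rec[m, j] P_m(t-1) + immediate_j)`,
#' where the immediate term is the input `x_i` (for an input weight into j),
#' the previous hidden activation `h_m(t-1)` (for a recurrent weight into j)
#' or 1 (for j's bias). Call after [net_forward()] for the same step.
#'
#' @param network the network after the step's forward pass (holds `hidden`
#'   and `h_prev_old`).
#' @param input the step's input vector.
#' @param sens an `"hr_sens"` object.
#' @return the updated sensitivity state.
#' @export
propagate_sensitivities <- function(network, input, sens) {
  n_in <- network$n_in
  n_hid <- network$n_hidden
  off_rec <- n_in * n_hid
  off_b <- off_rec + n_hid^2
  P <- crossprod(network$W_rec, sens$P)
  cd_first <- network$layout$cd_offset + 1L
  js <- seq_len(n_hid)
  for (i in which(input != 0)) {
    jmax <- if (i >= cd_first) network$n_agency else n_hid
    j <- seq_len(jmax)
    P[cbind(j, (j - 1L) * n_in + i)] <- P[cbind(j, (j - 1L) * n_in + i)] +
      input[i]
  }
  hp <- network$h_prev_old
  for (m in seq_len(n_hid)) {
    P[cbind(js, off_rec + (js - 1L) * n_hid + m)] <-
      P[cbind(js, off_rec + (js - 1L) * n_hid + m)] + hp[m]
  }
  P[cbind(js, off_b + js)] <- P[cbind(js, off_b + js)] + 1
  dh <- network$hidden * (1 - network$hidden)
  sens$P <- P * dh
  sens
}

#' Accumulate the step's gradient and update every `update_period` steps
#'
#' Each step contributes `sum_k e_k * d y_k / d w` (the feedback-error form:
#' gradient ascent on `e . y`, i.e. the delta rule with injected output
#' errors). Output-layer derivatives come directly from the chain rule;
#' hidden-layer derivatives go through the sensitivity matrix. After
#' `update_period` steps (default 10) the summed gradient is applied as
#' `delta_w = eta * g`, the accumulator is cleared and the connectivity mask
#' re-enforced.
#'
#' @param network the network after the step's forward pass.
#' @param sens an `"hr_sens"` object (already propagated for this step).
#' @param errors motor-command errors for this step.
#' @param learning_rate step size eta.
#' @param update_period steps between weight updates.
#' @return list `network`, `sens` (both updated).
#' @export
accumulate_and_update <- function(network, sens, errors,
                                  learning_rate = 0.1, update_period = 10L) {
  y <- network$output
  delta <- errors * y * (1 - y)
  q <- drop(network$W_out %*% delta)
  sens$g_wh <- sens$g_wh + drop(crossprod(sens$P, q))
  sens$g_out <- sens$g_out + outer(network$hidden, delta)
  sens$g_bout <- sens$g_bout + delta
  sens$steps <- sens$steps + 1L
  if (sens$steps %% update_period == 0L) {
    n_in <- network$n_in
    n_hid <- network$n_hidden
    off_rec <- n_in * n_hid
    off_b <- off_rec + n_hid^2
    eta <- learning_rate
    network$W_in <- (network$W_in +
      eta * matrix(sens$g_wh[1:off_rec], n_in, n_hid)) * network$mask_in
    network$W_rec <- network$W_rec +
      eta * matrix(sens$g_wh[(off_rec + 1L):off_b], n_hid, n_hid)
    network$b_hid <- network$b_hid + eta * sens$g_wh[(off_b + 1L):(off_b + n_hid)]
    network$W_out <- network$W_out + eta * sens$g_out
    network$b_out <- network$b_out + eta * sens$g_bout
    if (!all(is.finite(network$W_in)) || !all(is.finite(network$W_rec)))
      stop("non-finite weights after update; training aborted")
    sens$g_wh[] <- 0
    sens$g_out[] <- 0
    sens$g_bout[] <- 0
  }
  list(network = network, sens = sens)
}

#' Accumulated RTRL gradient over a fixed input/error sequence
#'
#' Driver used for gradient verification: runs the network over a given
#' sequence of inputs with injected output errors and returns the summed
#' gradient of `F = sum_t sum_k e_k(t) y_k(t)` with respect to every
#' trainable weight, without applying any update. The independent check is
#' central finite differences of `F` computed by re-running the forward
#' passes alone.
#'
#' @param network an `"hr_network"` object.
#' @param inputs list of input vectors (one per step).
#' @param error_seq list of length-8 error vectors (one per step).
#' @return list `g_wh`, `g_out`, `g_bout` (summed gradients) and `F`
#'   (the objective value).
#' @export
rtrl_sequence_gradient <- function(network, inputs, error_seq) {
  stopifnot(length(inputs) == length(error_seq))
  sens <- init_sensitivities(network)
  Fval <- 0
  for (t in seq_along(inputs)) {
    network <- net_forward(network, inputs[[t]])
    sens <- propagate_sensitivities(network, inputs[[t]], sens)
    y <- network$output
    e <- error_seq[[t]]
    Fval <- Fval + sum(e * y)
    delta <- e * y * (1 - y)
    q <- drop(network$W_out %*% delta)
    sens$g_wh <- sens$g_wh + drop(crossprod(sens$P, q))
    sens$g_out <- sens$g_out + outer(network$hidden, delta)
    sens$g_bout <- sens$g_bout + delta
  }
  list(g_wh = sens$g_wh, g_out = sens$g_out, g_bout = sens$g_bout, F = Fval)
}
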