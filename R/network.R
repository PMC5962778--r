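#' Logistic activation
#'
#' `1 / (1 + exp(-net))`; every hidden and output unit uses it, so all
#' activations lie strictly in (0, 1).
#'
#' @param net numeric net input.
#' @return numeric in (0, 1).
#' @export
logistic <- function(net) 1 / (1 + exp(-net))

#' Initialise the partitioned recurrent network
#'
#' A three-layer network: `n_in` input units project to `n_hidden` logistic
#' hidden units with full recurrent hidden-hidden connectivity, which project
#' to 8 logistic output units (4 per hand). The hidden layer is split in two
#' equal parts: the first ("agency") half receives all inputs; the second
#' ("ownership") half receives visual and proprioceptive input but no
#' corollary discharge -- enforced by a binary mask on the input weights that
#' is re-applied after every weight update.
#'
#' All trainable weights and biases are drawn uniformly on \[-0.1, 0.1\] from
#' R's global RNG; the previous-step hidden state starts at 0.5 (the logistic
#' of zero net input).
#'
#' @param geometry an [grid_geometry()] object (fixes `n_in` via the layout).
#' @param n_hidden number of hidden units (even; default 48 = 24 + 24).
#' @param n_out number of output units (8: right/up/left/down per hand).
#' @param init_range half-width of the uniform initialisation interval.
#' @return an `"hr_network"` list: weight matrices `W_in` (n_in x n_hidden),
#'   `W_rec` (n_hidden x n_hidden, entry \[m, j\] = weight m -> j), `W_out`
#'   (n_hidden x 8), biases `b_hid`, `b_out`, the binary `mask_in`,
#'   activations `h_prev`, `hidden`, `output`, and bookkeeping fields.
#' @export
init_network <- function(geometry, n_hidden = 48L, n_out = 8L,
                         init_range = 0.1) {
  layout <- input_layout(geometry)
  n_in <- layout$total
  n_hidden <- as.integer(n_hidden)
  if (n_hidden %% 2L != 0L) stop("n_hidden must be even (two equal parts)")
  runifm <- function(nr, nc)
    matrix(stats::runif(nr * nc, -init_range, init_range), nr, nc)
  net <- list(
    W_in = runifm(n_in, n_hidden),
    W_rec = runifm(n_hidden, n_hidden),
    W_out = runifm(n_hidden, n_out),
    b_hid = stats::runif(n_hidden, -init_range, init_range),
    b_out = stats::runif(n_out, -init_range, init_range),
    mask_in = network_mask(layout, n_hidden),
    h_prev = rep(0.5, n_hidden),
    hidden = rep(0.5, n_hidden),
    output = rep(0.5, n_out),
    n_in = n_in, n_hidden = n_hidden, n_out = as.integer(n_out),
    n_agency = n_hidden %/% 2L,
    layout = layout
  )
  net$W_in <- net$W_in * net$mask_in
  class(net) <- "hr_network"
  net
}

#' Connectivity mask of the input weights
#'
#' 1 everywhere except the corollary-discharge rows of the ownership
#' (second-half) hidden columns, which are 0.
#'
#' @param layout an [input_layout()] object.
#' @param n_hidden hidden-layer size.
#' @return binary matrix `total x n_hidden`.
#' @export
network_mask <- function(layout, n_hidden) {
  m <- matrix(1, layout$total, n_hidden)
  cd_rows <- (layout$cd_offset + 1L):(layout$cd_offset + layout$n_cd)
  own_cols <- (n_hidden %/% 2L + 1L):n_hidden
  m[cd_rows, own_cols] <- 0
  m
}

#' One forward pass
#'
#' `hidden(t) = logistic(W_in' x + W_rec' hidden(t-1) + b_hid)`;
#' `output(t) = logistic(W_out' hidden(t) + b_out)`. The stored previous
#' hidden state is advanced, so the network carries exactly one step of
#' recurrent history.
#'
#' @param network an `"hr_network"` object.
#' @param input numeric vector of length `network$n_in`.
#' @return the network with `hidden`, `output` and `h_prev` updated.
#' @export
net_forward <- function(network, input) {
  if (length(input) != network$n_in) stop("input dimension mismatch")
  net_h <- drop(crossprod(network$W_in, input)) +
    drop(crossprod(network$W_rec, network$h_prev)) + network$b_hid
  h <- logistic(net_h)
  y <- logistic(drop(crossprod(network$W_out, h)) + network$b_out)
  network$h_prev_old <- network$h_prev
  network$h_prev <- h
  network$hidden <- h
  network$output <- y
  network$net_hidden <- net_h
  network
}

#' @export
print.hr_network <- function(x, ...) {
  cat(sprintf("Recurrent logistic network: %d inputs -> %d hidden (%d agency + %d ownership) -> %d outputs\n",
              x$n_in, x$n_hidden, x$n_agency, x$n_hidden - x$n_agency, x$n_out))
  invisible(x)
}
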