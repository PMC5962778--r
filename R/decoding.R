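#' Decode output activations into a movement command
#'
#' The simplified population-vector rule: each hand has four output units
#' with preferred directions right, up, left, down. Per axis, the decoder
#' takes the difference between the opposing units' activities; if the
#' difference reaches the threshold (default 0.8) the hand moves one square
#' in the winning direction, otherwise it does not move on that axis. The
#' two axes are evaluated independently, so diagonal moves are possible.
#'
#' Output units 1-4 drive the left hand, 5-8 the right; "up" means
#' decreasing row index (screen frame).
#'
#' @param output numeric vector of 8 activations in (0, 1).
#' @param threshold activation difference needed to trigger a move.
#' @return integer vector `c(dxL, dyL, dxR, dyR)`, each in -1..1.
#' @examples
#' y <- rep(0.5, 8); y[2] <- 0.9; y[4] <- 0.1   # left-hand up vs down
#' decode_move(y)                               # dyL = -1 (upward)
#' @export
decode_move <- function(output, threshold = 0.8) {
  stopifnot(length(output) == 8L, threshold > 0, threshold <= 1)
  axis <- function(pos, neg) {
    d <- pos - neg
    if (d >= threshold) 1L else if (d <= -threshold) -1L else 0L
  }
  c(axis(output[1], output[3]),          # x: right vs left
    -axis(output[2], output[4]),         # y: up wins => row decreases
    axis(output[5], output[7]),
    -axis(output[6], output[8]))
}
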