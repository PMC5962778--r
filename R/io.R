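#' Save a network checkpoint
#'
#' Writes all weight matrices, the connectivity mask, the recurrent state
#' and the step counter to a JSON file (doubles serialised at full
#' precision, so a round trip restores them bit-identically). Sensitivities
#' are excluded by default for size; include them for exact-resume runs.
#'
#' @param network an `"hr_network"` object.
#' @param path output file path.
#' @param step training step at which the snapshot was taken.
#' @param sens optional `"hr_sens"` state to embed (exact resume).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(network, path, step = NA_integer_, sens = NULL) {
  obj <- list(
    format = "handregard-checkpoint-1",
    step = step,
    n_in = network$n_in, n_hidden = network$n_hidden, n_out = network$n_out,
    W_in = network$W_in, W_rec = network$W_rec, W_out = network$W_out,
    b_hid = network$b_hid, b_out = network$b_out,
    mask_in = network$mask_in, h_prev = network$h_prev)
  if (!is.null(sens))
    obj$sens <- list(P = sens$P, g_wh = sens$g_wh, g_out = sens$g_out,
                     g_bout = sens$g_bout, steps = sens$steps)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path a file written by [save_checkpoint()].
#' @return list with `network` (an `"hr_network"`), `step` and `sens`
#'   (`NULL` unless the checkpoint embedded sensitivities).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "handregard-checkpoint-1"))
    stop("not a handregard checkpoint (or unsupported version): ", path)
  net <- list(W_in = obj$W_in, W_rec = obj$W_rec, W_out = obj$W_out,
              b_hid = obj$b_hid, b_out = obj$b_out,
              mask_in = obj$mask_in, h_prev = obj$h_prev,
              hidden = rep(0.5, obj$n_hidden), output = rep(0.5, obj$n_out),
              n_in = obj$n_in, n_hidden = obj$n_hidden, n_out = obj$n_out,
              n_agency = obj$n_hidden %/% 2L,
              layout = NULL)
  class(net) <- "hr_network"
  sens <- NULL
  if (!is.null(obj$sens)) {
    sens <- list(P = obj$sens$P, g_wh = obj$sens$g_wh,
                 g_out = obj$sens$g_out, g_bout = obj$sens$g_bout,
                 steps = obj$sens$steps)
    class(sens) <- "hr_sens"
  }
  list(network = net, step = obj$step, sens = sens)
}

#' Write a trajectory log as CSV
#'
#' Columns: `t`, `lx`, `ly`, `rx`, `ry`, `in_center`.
#'
#' @param traj n x 4 integer matrix from [run_segment()] (`log_traj`).
#' @param in_center 0/1 vector from the same segment.
#' @param t0 absolute step of the first row.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, in_center, t0, path) {
  df <- data.frame(t = t0 + seq_len(nrow(traj)) - 1L,
                   lx = traj[, 1], ly = traj[, 2],
                   rx = traj[, 3], ry = traj[, 4],
                   in_center = in_center)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
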