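#' Train the hand-regard model
#'
#' Fits the closed-loop sensorimotor model: a recurrent logistic network,
#' embedded in the grid world, learns by modified RTRL with feedback-error
#' teaching signals to bring both simulated hands into the centre of the
#' visual field. Entities are repositioned every 1000 steps, the distractor
#' takes a random step every 50 steps, weights update every 10 steps, and
#' weight checkpoints are saved every `checkpoint_period` steps. Success is
#' observed over an `obs_window`-step window at the start of every
#' `obs_interval` steps (the 3 h-per-week observation ratio of the infant
#' study the schedule emulates) and plotted at interval midpoints.
#'
#' Randomness is split into two named streams derived from `seed`: the
#' network-initialisation stream (`seed`) and the world stream
#' (`seed + 1000003`), so changing the network init does not change the
#' placement sequence.
#'
#' @param config an [hr_config()]; `hr_config("scaled")` by default.
#' @param seed integer seed.
#' @param engine `"cpp"` (default) or `"R"` (reference; only sensible for
#'   very short `total_steps`).
#' @param log_J record the overall error J at every training step
#'   (memory: one double per step).
#' @param verbose print a line per checkpoint.
#' @return an object of class `"hand_regard"`: a list with `config`, `seed`,
#'   `network` (final), `checkpoints` (list of `list(step, weights)`),
#'   `success` (data.frame `step`, `rate`: the training success series),
#'   `J` (optional numeric vector) and `call`.
#' @seealso [test_case_rate()], [run_suite()], [detect_assemblies()],
#'   [detect_u_shapes()].
#' @examples
#' \donttest{
#' fit <- hand_regard(hr_config("scaled", total_steps = 5e4,
#'                              checkpoint_period = 5e4), seed = 1)
#' fit$success
#' }
#' @export
hand_regard <- function(config = hr_config("scaled"), seed = 1L,
                        engine = c("cpp", "R"), log_J = FALSE,
                        verbose = FALSE) {
  engine <- match.arg(engine)
  validate_config(config)
  cl <- match.call()
  set.seed(seed)
  net <- init_network(config$geometry, config$n_hidden,
                      init_range = config$init_range)
  set.seed(world_seed_for(seed))
  state <- init_state(net, config, config$training_case, learn = TRUE)
  n_seg <- as.integer(config$total_steps %/% config$checkpoint_period)
  seg_len <- as.integer(config$checkpoint_period)
  checkpoints <- vector("list", n_seg)
  success <- list()
  J_all <- if (log_J) vector("list", n_seg) else NULL
  for (k in seq_len(n_seg)) {
    t0 <- state$world$t
    seg <- run_segment(state, seg_len, config, learn = TRUE,
                       engine = engine, log_J = log_J)
    state <- seg$state
    success[[k]] <- success_windows(seg$in_center, t0, config)
    if (log_J) J_all[[k]] <- seg$J
    checkpoints[[k]] <- list(step = state$world$t,
                             weights = snapshot_weights(state$network))
    if (verbose)
      message(sprintf("step %g: training success (last window) %.3f",
                      state$world$t,
                      utils::tail(success[[k]]$rate, 1)))
  }
  fit <- list(config = config, seed = as.integer(seed),
              network = state$network,
              checkpoints = checkpoints,
              success = do.call(rbind, success),
              J = if (log_J) unlist(J_all) else NULL,
              call = cl)
  class(fit) <- "hand_regard"
  fit
}

## per-interval success points from one segment's in-centre log
success_windows <- function(in_center, t0, cfg) {
  starts <- seq(t0, t0 + length(in_center) - 1, by = cfg$obs_interval)
  rate <- vapply(starts, function(s) {
    idx <- (s - t0 + 1L):(s - t0 + cfg$obs_window)
    mean(in_center[idx])
  }, numeric(1))
  data.frame(step = starts + cfg$obs_interval / 2, rate = rate)
}

snapshot_weights <- function(net) {
  list(W_in = net$W_in, W_rec = net$W_rec, W_out = net$W_out,
       b_hid = net$b_hid, b_out = net$b_out)
}

#' @export
print.hand_regard <- function(x, ...) {
  cat("Closed-loop hand-regard model (RTRL-trained recurrent network)\n")
  cat(sprintf("  preset '%s', seed %d, %g training steps, %d checkpoints\n",
              x$config$preset, x$seed, x$config$total_steps,
              length(x$checkpoints)))
  cat(sprintf("  training success rate: first window %.3f, last window %.3f (no-movement baseline %.3f)\n",
              x$success$rate[1], utils::tail(x$success$rate, 1),
              baseline_success_rate(x$config$geometry)))
  invisible(x)
}

#' @export
summary.hand_regard <- function(object, ...) {
  asm <- detect_assemblies(object$network$W_rec)
  out <- list(
    preset = object$config$preset,
    seed = object$seed,
    total_steps = object$config$total_steps,
    baseline = baseline_success_rate(object$config$geometry),
    success = object$success,
    final_rate = utils::tail(object$success$rate, 1),
    max_rate = max(object$success$rate),
    n_assemblies = length(asm$assemblies),
    u_shapes = if (nrow(object$success) >= 5) detect_u_shapes(object$success)
               else data.frame(start = numeric(0), trough = numeric(0),
                               end = numeric(0), depth = numeric(0),
                               recovery = numeric(0))
  )
  class(out) <- "summary.hand_regard"
  out
}

#' @export
print.summary.hand_regard <- function(x, ...) {
  cat(sprintf("hand-regard fit (preset '%s', seed %d, %g steps)\n",
              x$preset, x$seed, x$total_steps))
  cat(sprintf("  success rate: final %.3f, max %.3f, untrained baseline %.3f\n",
              x$final_rate, x$max_rate, x$baseline))
  cat(sprintf("  cell assemblies in final recurrent weights: %d\n",
              x$n_assemblies))
  cat(sprintf("  U-shaped dips detected in the training series: %d\n",
              nrow(x$u_shapes)))
  invisible(x)
}

#' @export
coef.hand_regard <- function(object, ...) snapshot_weights(object$network)

#' Plot the training success-rate series
#'
#' Success rate against training step, with the analytic no-movement
#' baseline as a dashed reference line.
#'
#' @param x a [hand_regard()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hand_regard <- function(x, ...) {
  graphics::plot(x$success$step, x$success$rate, type = "o", pch = 16,
                 xlab = "training step", ylab = "success rate",
                 ylim = c(0, max(0.5, max(x$success$rate))), ...)
  graphics::abline(h = baseline_success_rate(x$config$geometry), lty = 2)
  invisible(x)
}

#' Simulate test-phase success rates from a fitted model
#'
#' Runs the frozen network in the test phase `nsim` times with fresh world
#' seeds and returns the success rates -- the model's analogue of
#' simulating from a fitted model.
#'
#' @param object a [hand_regard()] fit.
#' @param nsim number of test runs.
#' @param seed base world seed (runs use `seed`, `seed + 1`, ...).
#' @param case test case id 1-7 (or an [case_config()]).
#' @param checkpoint index into `object$checkpoints`; default the last.
#' @param ... unused.
#' @return numeric vector of `nsim` success rates.
#' @export
simulate.hand_regard <- function(object, nsim = 1, seed = 1L, case = 1L,
                                 checkpoint = NULL, ...) {
  k <- checkpoint %||% length(object$checkpoints)
  w <- object$checkpoints[[k]]$weights
  vapply(seq_len(nsim) - 1L, function(i)
    test_case_rate(w, case, object$config, world_seed = seed + i),
    numeric(1))
}
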