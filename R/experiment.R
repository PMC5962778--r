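#' Initialise a closed-loop simulation state
#'
#' Bundles the network, sensitivity state, world and previous movement
#' command. The world draws from the current RNG state; callers seed it
#' (the package uses a world seed stream separate from the network-init
#' stream, so different cases can be compared on identical worlds).
#'
#' @param network an [init_network()] object.
#' @param cfg an [hr_config()] object.
#' @param case an [case_config()] object.
#' @param learn will this state be trained? (allocates sensitivities)
#' @return an `"hr_state"` list.
#' @export
init_state <- function(network, cfg, case, learn = TRUE) {
  s <- list(network = network,
            sens = if (learn) init_sensitivities(network) else NULL,
            world = init_world(cfg$geometry, case),
            prev_cmd = c(0L, 0L, 0L, 0L),
            case = case)
  class(s) <- "hr_state"
  s
}

#' One closed-loop time step (pure-R reference)
#'
#' Executes in order: scheduled repositioning; the distractor's scheduled
#' random step; input encoding (corollary discharge from the previous
#' command); forward pass; population-vector decoding; when learning,
#' sensitivity propagation, feedback-error conversion and the periodic
#' weight update; hand movement; post-move success recording.
#'
#' This is the readable reference implementation; [run_segment()] with
#' `engine = "cpp"` runs the same step in compiled code and the two agree
#' draw-for-draw under a common seed.
#'
#' @param state an [init_state()] object.
#' @param cfg an [hr_config()] object.
#' @param learn update weights?
#' @return the updated state, with `state$in_center` (logical) and
#'   `state$J` (overall error, when learning) for the step just executed.
#' @export
step_once <- function(state, cfg, learn = TRUE) {
  g <- cfg$geometry
  t <- state$world$t
  if (schedule_due(t, cfg$reposition_period))
    state$world <- reposition(state$world, g, state$case)
  if (schedule_due(t, cfg$other_move_period))
    state$world <- step_other(state$world, g, state$case)
  x <- build_input(state$world, state$prev_cmd, g, state$case)
  state$network <- net_forward(state$network, x)
  cmd <- decode_move(state$network$output, cfg$threshold)
  if (learn) {
    state$sens <- propagate_sensitivities(state$network, x, state$sens)
    e <- motor_errors(perceived_block(state$world$left, g),
                      perceived_block(state$world$right, g), g)
    upd <- accumulate_and_update(state$network, state$sens, e,
                                 cfg$learning_rate, cfg$update_period)
    state$network <- upd$network
    state$sens <- upd$sens
    state$J <- network_error(e)
  }
  state$world <- apply_moves(state$world, cmd, g)
  state$prev_cmd <- cmd
  state$in_center <- in_center(state$world$left, g) ||
    in_center(state$world$right, g)
  state
}

#' Run a segment of the closed loop
#'
#' Advances the simulation `n_steps` steps with either the compiled
#' production engine or the pure-R reference engine, returning the updated
#' state plus per-step logs.
#'
#' @inheritParams step_once
#' @param n_steps number of steps to run.
#' @param engine `"cpp"` (production) or `"R"` (reference; short runs only).
#' @param log_traj,log_hidden,log_J record per-step hand positions, hidden
#'   activations, overall error.
#' @return list with `state` and logs: `in_center` (integer 0/1 per step),
#'   optionally `traj` (n x 4: lx, ly, rx, ry post-move), `hidden`
#'   (n x n_hidden), `J`.
#' @export
run_segment <- function(state, n_steps, cfg, learn = TRUE,
                        engine = c("cpp", "R"),
                        log_traj = FALSE, log_hidden = FALSE, log_J = FALSE) {
  engine <- match.arg(engine)
  n_steps <- as.integer(n_steps)
  if (engine == "R") {
    cen <- integer(n_steps)
    traj <- if (log_traj) matrix(0L, n_steps, 4) else NULL
    hid <- if (log_hidden) matrix(0, n_steps, state$network$n_hidden) else NULL
    Jv <- if (log_J) numeric(n_steps) else NULL
    for (s in seq_len(n_steps)) {
      state <- step_once(state, cfg, learn)
      cen[s] <- as.integer(state$in_center)
      if (log_traj) traj[s, ] <- c(state$world$left, state$world$right)
      if (log_hidden) hid[s, ] <- state$network$hidden
      if (log_J) Jv[s] <- state$J
    }
    return(list(state = state, in_center = cen, traj = traj,
                hidden = hid, J = Jv))
  }
  net <- state$network
  sens <- state$sens
  if (learn && is.null(sens)) sens <- init_sensitivities(net)
  empty <- is.null(sens)
  res <- hr_run_cpp(
    net$W_in, net$W_rec, net$W_out, net$b_hid, net$b_out, net$mask_in,
    net$h_prev,
    if (empty) matrix(0, 0, 0) else sens$P,
    if (empty) numeric(0) else sens$g_wh,
    if (empty) matrix(0, 0, 0) else sens$g_out,
    if (empty) numeric(0) else sens$g_bout,
    if (empty) 0L else sens$steps,
    c(state$world$left, state$world$right), state$world$others,
    state$prev_cmd,
    state$world$t, n_steps,
    cfg$geometry$area_width, cfg$geometry$area_height,
    cfg$geometry$block_size, cfg$geometry$fov_rows,
    state$case$hand_value, state$case$other_value, state$case$cd_enabled,
    state$case$phase == "test",
    learn, cfg$learning_rate, as.integer(cfg$update_period),
    as.integer(cfg$reposition_period), as.integer(cfg$other_move_period),
    cfg$threshold,
    log_traj, log_hidden, log_J)
  net$W_in <- res$W_in; net$W_rec <- res$W_rec; net$W_out <- res$W_out
  net$b_hid <- drop(res$b_hid); net$b_out <- drop(res$b_out)
  net$h_prev <- drop(res$h_prev)
  state$network <- net
  if (learn) {
    sens$P <- res$P
    sens$g_wh <- drop(res$g_wh)
    sens$g_out <- res$g_out
    sens$g_bout <- drop(res$g_bout)
    sens$steps <- res$sens_steps
    state$sens <- sens
  }
  state$world$left <- res$hands[1:2]
  state$world$right <- res$hands[3:4]
  state$world$others <- res$others
  state$world$t <- res$t
  state$prev_cmd <- res$prev_cmd
  list(state = state,
       in_center = res$in_center,
       traj = if (log_traj) res$traj else NULL,
       hidden = if (log_hidden) res$hidden_log else NULL,
       J = if (log_J) res$J else NULL)
}

#' Analytic no-movement baseline success rate
#'
#' With an untrained network the outputs sit near 0.5, no activation
#' difference reaches the decoder threshold, and the hands never move; the
#' success rate is then the probability that at least one of two uniformly
#' placed hands lands in the centre block:
#' `1 - (1 - p)^2` with `p = block_size^2 / (area_width * area_height)`
#' (= 25/225 = 1/9 under the default geometry, giving about 0.210).
#'
#' @param geometry an [grid_geometry()] object.
#' @return numeric scalar.
#' @export
baseline_success_rate <- function(geometry) {
  p <- geometry$block_size^2 / (geometry$area_width * geometry$area_height)
  1 - (1 - p)^2
}

world_seed_for <- function(seed) as.integer(seed + 1000003L)

#' Test-phase success rate for one case
#'
#' Loads a saved weight set, freezes learning, places the distractors inside
#' the field of view and runs the closed loop for `cfg$test_window` steps
#' (100 placements of 1000 steps under the defaults), returning the fraction
#' of steps with at least one hand inside the centre block. The recurrent
#' state restarts at 0.5 and the world RNG is seeded per call, so every case
#' sees the identical placement sequence for a given `world_seed` (paired
#' comparison across cases).
#'
#' @param weights a checkpoint weight list (elements `W_in`, `W_rec`,
#'   `W_out`, `b_hid`, `b_out`) or an `"hr_network"`.
#' @param case a case id 1-7 or an [case_config()] with `phase = "test"`.
#' @param cfg an [hr_config()] object.
#' @param world_seed seed for the placement/distractor stream.
#' @param engine see [run_segment()].
#' @return numeric success rate in \[0, 1\].
#' @export
test_case_rate <- function(weights, case, cfg, world_seed = 1L,
                           engine = "cpp") {
  if (is.numeric(case) && length(case) == 1L) case <- test_cases(case)
  stopifnot(case$phase == "test")
  net <- as_network(weights, cfg)
  set.seed(world_seed)
  state <- init_state(net, cfg, case, learn = FALSE)
  seg <- run_segment(state, cfg$test_window, cfg, learn = FALSE,
                     engine = engine)
  mean(seg$in_center)
}

as_network <- function(weights, cfg) {
  if (inherits(weights, "hr_network")) {
    weights$h_prev <- rep(0.5, weights$n_hidden)
    return(weights)
  }
  layout <- input_layout(cfg$geometry)
  n_hid <- ncol(weights$W_in)
  net <- list(W_in = weights$W_in, W_rec = weights$W_rec,
              W_out = weights$W_out,
              b_hid = weights$b_hid, b_out = weights$b_out,
              mask_in = network_mask(layout, n_hid),
              h_prev = rep(0.5, n_hid),
              hidden = rep(0.5, n_hid), output = rep(0.5, ncol(weights$W_out)),
              n_in = nrow(weights$W_in), n_hidden = n_hid,
              n_out = ncol(weights$W_out), n_agency = n_hid %/% 2L,
              layout = layout)
  class(net) <- "hr_network"
  net
}

#' Success-rate table over seeds, checkpoints and test cases
#'
#' Runs the test phase for every combination of fitted model, saved
#' checkpoint and case, the long-format result the discrimination analysis
#' works from.
#'
#' @param fits a list of [hand_regard()] objects (one per training seed).
#' @param cases integer case ids (default all seven).
#' @param checkpoints `"final"` or `"all"`.
#' @param world_seed world stream seed shared by all cells (paired worlds).
#' @return data.frame with columns `seed`, `step`, `case`, `rate`.
#' @export
run_suite <- function(fits, cases = 1:7, checkpoints = c("final", "all"),
                      world_seed = 1L) {
  checkpoints <- match.arg(checkpoints)
  if (inherits(fits, "hand_regard")) fits <- list(fits)
  rows <- list()
  for (f in fits) {
    cps <- if (checkpoints == "final") f$checkpoints[length(f$checkpoints)]
           else f$checkpoints
    for (cp in cps) for (cs in cases) {
      rate <- test_case_rate(cp$weights, cs, f$config, world_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = f$seed, step = cp$step, case = cs, rate = rate)
    }
  }
  do.call(rbind, rows)
}
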