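test_that("feedback-error equations over all nine perceived blocks", {
  g <- grid_geometry()
  centre <- c(g$x0 + g$d, g$y0 + g$d)
  ## centred hand: all four errors zero
  e <- motor_errors(centre, centre, g)
  expect_equal(e, rep(0, 8))
  ## left hand at (x0, y0): +1, +1, -1, -1
  e2 <- motor_errors(c(g$x0, g$y0), centre, g)
  expect_equal(e2[1:4], c(1, 1, -1, -1))
  expect_equal(e2[5:8], rep(0, 4))
  ## full enumeration: errors in {-1, 0, 1}, zero only at the centre block,
  ## and the antisymmetric pairs always hold
  for (bx in 0:2) for (by in 0:2) {
    p <- c(g$x0 + bx * g$d, g$y0 + by * g$d)
    e <- motor_errors(p, p, g)
    expect_true(all(e %in% c(-1, 0, 1)))
    expect_equal(e[3], -e[1]); expect_equal(e[4], -e[2])
    expect_equal(e[7], -e[5]); expect_equal(e[8], -e[6])
    if (bx == 1 && by == 1) expect_true(all(e == 0))
    else expect_true(any(e != 0))
  }
  expect_error(motor_errors(c(1, 1), centre, g), "block centres")
})

test_that("overall error J is half the sum of squared errors", {
  expect_equal(network_error(rep(0, 8)), 0)
  expect_equal(network_error(c(1, 1, -1, -1, 1, 1, -1, -1)), 4)
  expect_equal(network_error(c(0, 0, 0, 0, 1, 1, -1, -1)), 2)
  expect_equal(network_error(c(1, 0, -1, 0, 0, 0, 0, 0)), 1)
})

test_that("RTRL sensitivities match finite differences on a toy sequence", {
  cfg <- hr_config("scaled")
  set.seed(42)
  net <- init_network(cfg$geometry, 6L)   # 100 inputs, 6 hidden units
  T_steps <- 12
  inputs <- lapply(1:T_steps, function(i) {
    x <- numeric(net$n_in); x[sample(net$n_in, 6)] <- runif(6); x
  })
  errs <- lapply(1:T_steps, function(i) sample(c(-1, 0, 1), 8, replace = TRUE))
  g <- rtrl_sequence_gradient(net, inputs, errs)
  Ffun <- function(n2) {
    s <- 0
    for (t in 1:T_steps) {
      n2 <- net_forward(n2, inputs[[t]])
      s <- s + sum(errs[[t]] * n2$output)
    }
    s
  }
  n_in <- net$n_in; n_hid <- net$n_hidden
  off_rec <- n_in * n_hid; off_b <- off_rec + n_hid^2
  ## masked weight flat indices (excluded from FD; asserted zero below)
  lay <- net$layout
  cd_rows <- (lay$cd_offset + 1):(lay$cd_offset + 10)
  own_cols <- (net$n_agency + 1):n_hid
  masked <- as.vector(outer(cd_rows, (own_cols - 1) * n_in, `+`))
  expect_true(all(g$g_wh[masked] == 0))

  eps <- 1e-5
  set.seed(7)
  idx <- c(sample(setdiff(1:off_rec, masked), 15),
           off_rec + sample(n_hid^2, 10), off_b + sample(n_hid, 3))
  for (w in idx) {
    perturb <- function(d) {
      n2 <- net
      if (w <= off_rec) {
        i <- (w - 1) %% n_in + 1; j <- (w - 1) %/% n_in + 1
        n2$W_in[i, j] <- n2$W_in[i, j] + d
      } else if (w <= off_b) {
        v <- w - off_rec; m <- (v - 1) %% n_hid + 1; j <- (v - 1) %/% n_hid + 1
        n2$W_rec[m, j] <- n2$W_rec[m, j] + d
      } else n2$b_hid[w - off_b] <- n2$b_hid[w - off_b] + d
      n2
    }
    fd <- (Ffun(perturb(eps)) - Ffun(perturb(-eps))) / (2 * eps)
    denom <- max(abs(fd), abs(g$g_wh[w]), 1e-8)
    expect_lt(abs(fd - g$g_wh[w]) / denom, 1e-4)
  }
  ## output-layer weights via direct chain rule
  fd_out <- (Ffun({n2 <- net; n2$W_out[2, 3] <- n2$W_out[2, 3] + eps; n2}) -
             Ffun({n2 <- net; n2$W_out[2, 3] <- n2$W_out[2, 3] - eps; n2})) /
    (2 * eps)
  expect_lt(abs(fd_out - g$g_out[2, 3]) / abs(fd_out), 1e-4)
})

test_that("zero recurrent weights reduce sensitivities to the feedforward gradient", {
  cfg <- hr_config("scaled")
  set.seed(13)
  net <- init_network(cfg$geometry, 4L)
  net$W_rec[] <- 0
  x <- numeric(net$n_in); x[c(2, 30, 85)] <- c(0.5, 1, 1)
  net <- net_forward(net, x)
  sens <- propagate_sensitivities(net, x, init_sensitivities(net))
  ## closed form: dh_j/dW_in[i,j] = h_j(1-h_j) x_i, zero across units
  dh <- net$hidden * (1 - net$hidden)
  for (j in 1:4) for (i in c(2, 30, 85)) {
    col <- (j - 1) * net$n_in + i
    expect_equal(sens$P[j, col], dh[j] * x[i])
    expect_true(all(sens$P[-j, col] == 0))
  }
})

test_that("updates fire every update_period steps; zero error leaves weights", {
  cfg <- hr_config("scaled")
  set.seed(20)
  net <- init_network(cfg$geometry, 6L)
  sens <- init_sensitivities(net)
  x <- numeric(net$n_in); x[c(1, 50)] <- 1
  e <- c(1, 0, -1, 0, 0, 1, 0, -1)
  w0 <- net$W_out
  for (s in 1:9) {
    net <- net_forward(net, x)
    sens <- propagate_sensitivities(net, x, sens)
    upd <- accumulate_and_update(net, sens, e, 0.1, 10L)
    net <- upd$network; sens <- upd$sens
    expect_identical(net$W_out, w0)   # no update before the 10th step
  }
  net <- net_forward(net, x)
  sens <- propagate_sensitivities(net, x, sens)
  upd <- accumulate_and_update(net, sens, e, 0.1, 10L)
  expect_false(identical(upd$network$W_out, w0))  # 10th step applies
  ## masked weights remain exactly zero after the update
  lay <- net$layout
  cd_rows <- (lay$cd_offset + 1):(lay$cd_offset + 10)
  own_cols <- (net$n_agency + 1):net$n_hidden
  expect_true(all(upd$network$W_in[cd_rows, own_cols] == 0))

  ## all-zero errors: a full window of updates changes nothing
  set.seed(21)
  net2 <- init_network(cfg$geometry, 6L)
  sens2 <- init_sensitivities(net2)
  snap <- net2[c("W_in", "W_rec", "W_out", "b_hid", "b_out")]
  for (s in 1:10) {
    net2 <- net_forward(net2, x)
    sens2 <- propagate_sensitivities(net2, x, sens2)
    upd2 <- accumulate_and_update(net2, sens2, rep(0, 8), 0.1, 10L)
    net2 <- upd2$network; sens2 <- upd2$sens
  }
  expect_identical(net2[c("W_in", "W_rec", "W_out", "b_hid", "b_out")], snap)
})
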