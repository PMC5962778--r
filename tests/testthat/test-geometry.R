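test_that("geometry invariants: dimensions, block partition, centre region", {
  g <- grid_geometry()
  expect_equal(g$area_width * g$square_size, 60)   # outstretched-arm span
  expect_equal(g$d, 20)
  expect_equal(g$n_visual, 210)

  ## every square belongs to exactly one block; 3x3 blocks tile the area
  blocks <- outer(0:(g$area_height - 1), 0:(g$area_width - 1),
                  function(y, x) (y %/% g$block_size) * 3 + x %/% g$block_size)
  expect_setequal(unique(as.vector(blocks)), 0:8)
  expect_true(all(table(blocks) == g$block_size^2))

  ## exactly 25 of the 225 squares are in the centre region
  n_cen <- sum(sapply(0:(g$area_width - 1), function(x)
    sum(sapply(0:(g$area_height - 1), function(y) in_center(c(x, y), g)))))
  expect_identical(n_cen, 25L)
  expect_true(in_center(c(7, 7), g))
  expect_false(in_center(c(0, 0), g))
  expect_false(in_center(c(14, 14), g))
})

test_that("perceived position is the block centre, error bounded by 10 cm", {
  g <- grid_geometry()
  ## centre of the central block is (x0 + d, y0 + d)
  expect_equal(unname(perceived_block(c(7, 7), g)), c(g$x0 + g$d, g$y0 + g$d))
  ## a block-centre square perceives itself (fixed point)
  expect_equal(unname(perceived_block(c(2, 12), g)), c(g$x0, g$y0))
  ## exhaustive scan: per-axis error = at most 10 cm minus half a square,
  ## and every perceived coordinate is one of the three block centres
  centres <- g$x0 + (0:2) * g$d
  errs <- c()
  for (x in 0:14) for (y in 0:14) {
    p <- perceived_block(c(x, y), g)
    expect_true(all(p %in% centres))
    true_x <- (x + 0.5) * g$square_size
    true_y_up <- (g$area_height - y - 0.5) * g$square_size
    errs <- c(errs, abs(true_x - p[["x"]]), abs(true_y_up - p[["y"]]))
  }
  expect_equal(max(errs), 10 - g$square_size / 2)
})

test_that("placement respects phase regions and replays under a seed", {
  g <- grid_geometry()
  test_case20 <- case_config(n_others = 20L, phase = "test")
  set.seed(5)
  w <- init_world(g, test_case20)
  expect_identical(w$t, 0L)
  expect_equal(nrow(w$others), 20L)
  ## membership oracle: all others inside the field of view
  expect_true(all(w$others[, 1] >= 0 & w$others[, 1] < g$area_width))
  expect_true(all(w$others[, 2] >= 0 & w$others[, 2] < g$fov_rows))
  ## hands anywhere in the area
  expect_true(all(c(w$left, w$right) >= 0))
  expect_true(all(c(w$left[1], w$right[1]) < g$area_width))
  expect_true(all(c(w$left[2], w$right[2]) < g$area_height))

  ## empty-others case
  set.seed(5)
  w0 <- init_world(g, case_config(n_others = 0L))
  expect_equal(nrow(w0$others), 0L)

  ## too many others rejected
  expect_error(init_world(g, case_config(n_others = 9999L)),
               "available squares")

  ## determinism: identical seeds give identical placement sequences
  seqs <- lapply(1:2, function(i) {
    set.seed(11)
    ws <- init_world(g, case_config())
    replicate(5, {
      ws <<- reposition(ws, g, case_config())
      c(ws$left, ws$right, ws$others)
    })
  })
  expect_identical(seqs[[1]], seqs[[2]])
})

test_that("schedules fire at multiples only, never at t = 0", {
  expect_false(schedule_due(0L, 1000L))
  expect_false(schedule_due(999L, 1000L))
  expect_true(schedule_due(1000L, 1000L))
  expect_true(schedule_due(50L, 50L))
  expect_false(schedule_due(5000L, 0L))  # disabled schedule
})

test_that("distractor steps stay in region; hands clamp at boundaries", {
  g <- grid_geometry()
  case <- case_config()
  ## interior other moves to one of its 4 neighbours
  w <- list(left = c(0L, 0L), right = c(0L, 0L),
            others = matrix(c(7L, 7L), 1), t = 50L)
  class(w) <- "hr_world"
  set.seed(3)
  w2 <- step_other(w, g, case)
  expect_equal(sum(abs(w2$others - c(7L, 7L))), 1)
  ## corner other with outward proposal stays put (rejection)
  moved <- replicate(50, {
    wc <- w; wc$others <- matrix(c(0L, 0L), 1)
    wo <- step_other(wc, g, case)
    wo$others
  })
  expect_true(all(moved >= 0))

  ## hand clamping
  w$left <- c(14L, 7L)
  w3 <- apply_moves(w, c(1L, 0L, 0L, 0L), g)
  expect_equal(unname(w3$left), c(14L, 7L))
  expect_equal(w3$t, w$t + 1L)
  ## identity command leaves positions, advances time
  w4 <- apply_moves(w, c(0L, 0L, 0L, 0L), g)
  expect_equal(w4$left, w$left)
  ## interior move
  w$left <- c(7L, 7L)
  w5 <- apply_moves(w, c(1L, 0L, 0L, 0L), g)
  expect_equal(unname(w5$left), c(8L, 7L))
})

test_that("random-walk fuzz: positions never leave the movable area", {
  g <- grid_geometry(9L, 9L, 4, 3L, 8L)
  case <- case_config(n_others = 3L)
  set.seed(21)
  w <- init_world(g, case)
  for (t in 1:500) {
    w$t <- t
    if (schedule_due(t, 100L)) w <- reposition(w, g, case)
    if (schedule_due(t, 10L)) w <- step_other(w, g, case)
    cmd <- as.integer(sample(-1:1, 4, replace = TRUE))
    w <- apply_moves(w, cmd, g)
    w$t <- t
    pos <- rbind(w$left, w$right, w$others)
    expect_true(all(pos >= 0 & pos[, 1] < g$area_width &
                      pos[, 2] < g$area_height))
  }
})
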