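make_world <- function(left, right, others = matrix(integer(0), 0, 2), t = 0L) {
  w <- list(left = as.integer(left), right = as.integer(right),
            others = others, t = t)
  class(w) <- "hr_world"
  w
}

test_that("input layout totals 238 under the default geometry", {
  lay <- input_layout(grid_geometry())
  expect_identical(lay$total, 238L)
  expect_identical(lay$n_visual, 210L)
  expect_identical(lay$n_proprio, 18L)
  expect_identical(lay$n_cd, 10L)
  ## scaled geometry keeps the same structure
  expect_identical(input_layout(grid_geometry(9L, 9L, 4, 3L, 8L))$total, 100L)
  ## layout table covers the whole vector without gaps
  tab <- layout_table(grid_geometry())
  expect_equal(tab$first, c(1L, 211L, 220L, 229L, 234L))
  expect_equal(max(tab$last), 238L)
})

test_that("visual encoding: values, field-of-view masking, precedence", {
  g <- grid_geometry()
  w <- make_world(c(3, 2), c(10, 13), matrix(c(5L, 5L), 1))
  v <- encode_visual(w, g, case_config())
  expect_equal(v[2 * 15 + 3 + 1], 0.5)    # left hand square
  expect_equal(v[13 * 15 + 10 + 1], 0.5)  # right hand square
  expect_equal(v[5 * 15 + 5 + 1], 0.2)    # distractor square
  expect_equal(sum(v != 0), 3)

  ## entities below the field of view produce nothing
  w2 <- make_world(c(3, 14), c(10, 14), matrix(c(5L, 14L), 1))
  expect_true(all(encode_visual(w2, g, case_config()) == 0))

  ## case 4 codes the distractor like a hand (0.5)
  v4 <- encode_visual(w, g, test_cases(4))
  expect_equal(v4[5 * 15 + 5 + 1], 0.5)

  ## hand precedence on an overlapping square
  w3 <- make_world(c(5, 5), c(10, 13), matrix(c(5L, 5L), 1))
  expect_equal(encode_visual(w3, g, case_config())[5 * 15 + 5 + 1], 0.5)
})

test_that("proprioceptive groups are one-hot, constant within a block", {
  g <- grid_geometry()
  ## both hands in the central block activate the central unit of each group
  p <- encode_proprio(make_world(c(7, 7), c(6, 8)), g)
  expect_equal(p[4 + 1], 1)       # left group, block (1,1) -> unit 4 (0-based)
  expect_equal(p[9 + 4 + 1], 1)
  expect_equal(sum(p), 2)

  ## all 25 squares of block (0,0) give the identical encoding
  encs <- sapply(0:4, function(x) sapply(0:4, function(y)
    encode_proprio(make_world(c(x, y), c(7, 7)), g)))
  expect_true(all(apply(matrix(encs, nrow = 18), 1,
                        function(r) length(unique(r)) == 1)))

  ## one-hot property under fuzz
  set.seed(8)
  for (i in 1:50) {
    w <- make_world(c(sample(0:14, 1), sample(0:14, 1)),
                    c(sample(0:14, 1), sample(0:14, 1)))
    p <- encode_proprio(w, g)
    expect_equal(sum(p[1:9]), 1)
    expect_equal(sum(p[10:18]), 1)
  }
})

test_that("corollary discharge encodes direction only; case 7 silences it", {
  case <- case_config()
  ## rightward left-hand move
  cd <- encode_cd(c(1L, 0L, 0L, 0L), case)
  expect_equal(cd[1], 1)
  expect_equal(sum(cd[1:5]), 1)
  expect_equal(cd[10], 1)  # right hand did not move -> no-move unit
  ## no movement at all: both no-move units
  cd0 <- encode_cd(c(0L, 0L, 0L, 0L), case)
  expect_equal(which(cd0 == 1), c(5L, 10L))
  ## diagonal move activates two direction units
  cdd <- encode_cd(c(1L, -1L, 0L, 0L), case)
  expect_equal(which(cdd[1:5] == 1), c(1L, 2L))
  ## case 7: whole segment zero whatever the command
  expect_true(all(encode_cd(c(1L, -1L, -1L, 1L), test_cases(7)) == 0))
})

test_that("full input vector: length, sparse empty-world case, case identity", {
  g <- grid_geometry()
  w <- make_world(c(3, 14), c(10, 14))   # hands out of the field of view
  x <- build_input(w, c(0L, 0L, 0L, 0L), g, case_config())
  expect_length(x, 238)
  ## exactly 2 proprio + 2 no-move units nonzero
  expect_equal(sum(x != 0), 4)

  ## case 1 replicates the training coding exactly
  w2 <- make_world(c(3, 2), c(10, 5), matrix(c(5L, 5L), 1))
  cmd <- c(1L, 0L, 0L, -1L)
  x_train <- build_input(w2, cmd, g, case_config())
  x_case1 <- build_input(w2, cmd, g, test_cases(1))
  expect_identical(x_train, x_case1)

  ## case 7 differs from case 1 only in hand visual units and CD segment
  x_case7 <- build_input(w2, cmd, g, test_cases(7))
  diff_idx <- which(x_case1 != x_case7)
  lay <- input_layout(g)
  hand_units <- c(2 * 15 + 3 + 1, 5 * 15 + 10 + 1)
  cd_units <- (lay$cd_offset + 1):(lay$cd_offset + 10)
  expect_true(all(diff_idx %in% c(hand_units, cd_units)))
  expect_true(all(x_case7[cd_units] == 0))
})
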