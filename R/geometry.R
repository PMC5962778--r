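#' Grid-world geometry
#'
#' Constructs the discrete 2-D world in which the simulated hands and
#' distractor objects move. The movable area is a square grid of
#' `area_width` x `area_height` squares (default 15 x 15 squares of 4 cm,
#' i.e. 60 cm -- the span of an infant's outstretched arms). The area
#' partitions exactly into 3 x 3 proprioceptive blocks of
#' `block_size` x `block_size` squares; the field of view covers all columns
#' and the top `fov_rows` rows (the row nearest the body is outside it), and
#' the centre of the visual field is the central block.
#'
#' Coordinates are 0-based square indices, origin top-left, `x` = column,
#' `y` = row. The physical (cm) frame used by the motor-error equations has
#' its y axis pointing up, so that "upward" means decreasing row index.
#'
#' @param area_width,area_height extent of the movable area in squares.
#' @param square_size side of one square in cm.
#' @param block_size side of one proprioceptive block in squares; must divide
#'   the area into exactly 3 x 3 blocks.
#' @param fov_rows number of rows (from the top) inside the field of view.
#' @return an object of class `"hr_geometry"`: a list with the arguments plus
#'   derived fields `n_blocks` (blocks per axis, always 3), `d` (block pitch
#'   in cm), `x0`, `y0` (cm centre of the first block on each axis) and
#'   `n_visual` (number of field-of-view squares).
#' @examples
#' g <- grid_geometry()
#' g$d                      # 20 cm block pitch
#' g$n_visual               # 210 field-of-view squares
#' @export
grid_geometry <- function(area_width = 15L, area_height = 15L,
                          square_size = 4, block_size = 5L,
                          fov_rows = 14L) {
  area_width <- as.integer(area_width)
  area_height <- as.integer(area_height)
  block_size <- as.integer(block_size)
  fov_rows <- as.integer(fov_rows)
  if (area_width != area_height)
    stop("movable area must be square")
  if (area_width %% block_size != 0L || area_width %/% block_size != 3L)
    stop("area must partition into exactly 3 x 3 blocks")
  if (fov_rows < 2L * block_size || fov_rows > area_height)
    stop("field of view must contain the central block and fit in the area")
  g <- list(
    area_width = area_width, area_height = area_height,
    square_size = square_size, block_size = block_size,
    fov_rows = fov_rows,
    n_blocks = 3L,
    d = block_size * square_size,
    x0 = block_size * square_size / 2,
    y0 = block_size * square_size / 2,
    n_visual = area_width * fov_rows
  )
  class(g) <- "hr_geometry"
  g
}

#' @export
print.hr_geometry <- function(x, ...) {
  cat(sprintf("Grid world: %d x %d squares (%g cm), 3 x 3 blocks of %d squares (d = %g cm)\n",
              x$area_width, x$area_height, x$square_size * x$area_width,
              x$block_size, x$d))
  cat(sprintf("Field of view: %d columns x %d rows (%d squares); centre = central block\n",
              x$area_width, x$fov_rows, x$n_visual))
  invisible(x)
}

#' Is a position inside the centre of the visual field?
#'
#' The centre region is the central `block_size` x `block_size` block
#' (the orange 5 x 5 square region under the default geometry). A time step
#' counts as hand-regard success when at least one hand is inside it.
#'
#' @param pos integer vector `c(x, y)`, 0-based square coordinates.
#' @param geometry an [grid_geometry()] object.
#' @return logical.
#' @export
in_center <- function(pos, geometry) {
  bx <- pos[[1]] %/% geometry$block_size
  by <- pos[[2]] %/% geometry$block_size
  bx == 1L && by == 1L
}

#' Proprioceptively perceived hand position
#'
#' The simulated infant senses its hand only to block resolution: the
#' perceived position is the cm centre of the containing 20 x 20 cm block
#' (+/- 10 cm error per axis). Returned in the physical frame whose y axis
#' points up, which is the frame the motor-error equations are written in.
#'
#' @inheritParams in_center
#' @return named numeric `c(x, y)` in cm: one of the nine block centres
#'   `x0 + {0,1,2} d`, `y0 + {0,1,2} d`.
#' @export
perceived_block <- function(pos, geometry) {
  bx <- pos[[1]] %/% geometry$block_size
  by <- pos[[2]] %/% geometry$block_size
  c(x = geometry$x0 + bx * geometry$d,
    y = geometry$y0 + (geometry$n_blocks - 1L - by) * geometry$d)
}

## block indices (screen frame: by = 0 is the top row of blocks)
block_index <- function(pos, geometry) {
  c(pos[[1]] %/% geometry$block_size, pos[[2]] %/% geometry$block_size)
}

#' Place all entities at random
#'
#' Hands are placed uniformly over the whole movable area. Distractor
#' objects ("others") are placed over the whole area in the training phase
#' but inside the field of view in the test phase (where they are also kept
#' there by [step_other()]). Placement is repeated every 1000 steps by
#' [reposition()].
#'
#' All draws come from R's global RNG in a fixed order (left hand x, y;
#' right hand x, y; each other x, y), so runs replay exactly under a seed.
#'
#' @param geometry an [grid_geometry()] object.
#' @param case an [case_config()] object (supplies `n_others` and phase).
#' @return an `"hr_world"` list: `left`, `right` (integer `c(x, y)`),
#'   `others` (n x 2 integer matrix), `t` (step counter).
#' @export
init_world <- function(geometry, case) {
  n <- case$n_others
  avail <- if (case$phase == "test") geometry$area_width * geometry$fov_rows
           else geometry$area_width * geometry$area_height
  if (n > avail) stop("more 'others' than available squares")
  w <- list(left = draw_square(geometry, FALSE),
            right = draw_square(geometry, FALSE),
            others = draw_others(geometry, case),
            t = 0L)
  class(w) <- "hr_world"
  w
}

draw_square <- function(geometry, fov_only) {
  h <- if (fov_only) geometry$fov_rows else geometry$area_height
  c(as.integer(stats::runif(1) * geometry$area_width),
    as.integer(stats::runif(1) * h))
}

draw_others <- function(geometry, case) {
  n <- case$n_others
  m <- matrix(0L, nrow = n, ncol = 2)
  fov_only <- case$phase == "test"
  if (n > 0) for (i in seq_len(n)) m[i, ] <- draw_square(geometry, fov_only)
  m
}

#' Re-place all entities (every 1000 steps)
#'
#' @param world an `"hr_world"` object.
#' @inheritParams init_world
#' @return the world with fresh uniform positions; `t` preserved.
#' @export
reposition <- function(world, geometry, case) {
  world$left <- draw_square(geometry, FALSE)
  world$right <- draw_square(geometry, FALSE)
  world$others <- draw_others(geometry, case)
  world
}

#' Should a scheduled event fire at step t?
#'
#' Repositioning fires at t = 1000, 2000, ... (never at t = 0, where
#' [init_world()] has just placed everything); the distractor's random step
#' fires at t = 50, 100, .... A period of 0 disables the schedule.
#'
#' @param t time step.
#' @param period schedule period in steps.
#' @return logical.
#' @export
schedule_due <- function(t, period) {
  period > 0L && t > 0L && t %% period == 0L
}

#' Random one-square step of the distractor objects
#'
#' Every 50 steps each "other" proposes one uniformly random 4-neighbourhood
#' step (right, up, left, down). A proposal that would leave its allowed
#' region -- the whole area in training, the field of view in the test phase
#' -- is rejected and the object stays in place.
#'
#' @inheritParams reposition
#' @return the world with others moved.
#' @export
step_other <- function(world, geometry, case) {
  n <- nrow(world$others)
  if (n == 0) return(world)
  h <- if (case$phase == "test") geometry$fov_rows else geometry$area_height
  for (i in seq_len(n)) {
    dir <- as.integer(stats::runif(1) * 4)  # 0 right, 1 up, 2 left, 3 down
    dx <- c(1L, 0L, -1L, 0L)[dir + 1L]
    dy <- c(0L, -1L, 0L, 1L)[dir + 1L]
    nx <- world$others[i, 1] + dx
    ny <- world$others[i, 2] + dy
    if (nx >= 0L && nx < geometry$area_width && ny >= 0L && ny < h) {
      world$others[i, ] <- c(nx, ny)
    }
  }
  world
}

#' Apply a decoded movement command to the hands
#'
#' Each hand translates by at most one square per axis; coordinates are
#' clamped to the movable area (the hands are servo-controlled and cannot
#' leave it). The step counter advances by one.
#'
#' @param world an `"hr_world"` object.
#' @param cmd integer vector `c(dxL, dyL, dxR, dyR)`, each in -1..1
#'   (screen frame: dy = -1 is upward).
#' @param geometry an [grid_geometry()] object.
#' @return the updated world.
#' @export
apply_moves <- function(world, cmd, geometry) {
  stopifnot(all(abs(cmd) <= 1L))
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  world$left <- c(clamp(world$left[[1]] + cmd[[1]], 0L, geometry$area_width - 1L),
                  clamp(world$left[[2]] + cmd[[2]], 0L, geometry$area_height - 1L))
  world$right <- c(clamp(world$right[[1]] + cmd[[3]], 0L, geometry$area_width - 1L),
                   clamp(world$right[[2]] + cmd[[4]], 0L, geometry$area_height - 1L))
  world$t <- world$t + 1L
  world
}
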