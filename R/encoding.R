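#' Input-layer layout
#'
#' The input vector concatenates three segments in fixed order:
#' visual (one unit per field-of-view square, row-major), proprioceptive
#' (9 one-hot block units per hand: left then right) and corollary discharge
#' (per hand: right, up, left, down direction units plus a no-move unit;
#' left then right). Under the default geometry this is
#' 210 + 18 + 10 = 238 units.
#'
#' @param geometry an [grid_geometry()] object.
#' @return an `"hr_layout"` list with segment offsets (0-based) and sizes:
#'   `n_visual`, `proprio_offset`, `cd_offset`, `total`.
#' @export
input_layout <- function(geometry) {
  nv <- geometry$n_visual
  l <- list(n_visual = nv,
            proprio_offset = nv,
            n_proprio = 18L,
            cd_offset = nv + 18L,
            n_cd = 10L,
            total = nv + 28L)
  class(l) <- "hr_layout"
  l
}

#' Layout table (one row per unit segment)
#'
#' A machine-readable description of the input-vector layout, exportable as
#' JSON for downstream analysis.
#'
#' @inheritParams input_layout
#' @return data.frame with columns `segment`, `first`, `last` (1-based index
#'   range) and `meaning`.
#' @export
layout_table <- function(geometry) {
  l <- input_layout(geometry)
  data.frame(
    segment = c("visual", "proprio_left", "proprio_right",
                "cd_left", "cd_right"),
    first = c(1L, l$proprio_offset + 1L, l$proprio_offset + 10L,
              l$cd_offset + 1L, l$cd_offset + 6L),
    last = c(l$n_visual, l$proprio_offset + 9L, l$proprio_offset + 18L,
             l$cd_offset + 5L, l$cd_offset + 10L),
    meaning = c("one unit per field-of-view square, row-major from top-left",
                "one-hot block of the left hand (row-major over 3x3 blocks)",
                "one-hot block of the right hand",
                "left-hand movement direction: right, up, left, down, no-move",
                "right-hand movement direction: right, up, left, down, no-move"),
    stringsAsFactors = FALSE
  )
}

#' Test- and training-phase input coding
#'
#' In the training phase the hands are seen with visual value 0.5, a single
#' distractor with 0.2, and corollary discharge is on. The test phase probes
#' discrimination by varying the distractor's visual value (0.2 or 0.5) and
#' count (1, 5 or 20) -- cases 1-6 -- and, in case 7, by switching off both
#' the hands' visual input and the corollary discharge so that only
#' proprioception can guide the hand.
#'
#' @param hand_value visual input value of a hand square.
#' @param other_value visual input value of a distractor square.
#' @param n_others number of distractor objects.
#' @param cd_enabled is the corollary-discharge segment active?
#' @param phase `"training"` or `"test"`; in the test phase distractors are
#'   placed and kept inside the field of view.
#' @return an `"hr_case"` list.
#' @export
case_config <- function(hand_value = 0.5, other_value = 0.2, n_others = 1L,
                        cd_enabled = TRUE, phase = c("training", "test")) {
  phase <- match.arg(phase)
  stopifnot(n_others >= 0L)
  c_ <- list(hand_value = hand_value, other_value = other_value,
             n_others = as.integer(n_others), cd_enabled = cd_enabled,
             phase = phase)
  class(c_) <- "hr_case"
  c_
}

#' The seven test cases
#'
#' Cases 1-6 cross the distractor visual value (0.2, 0.5) with the
#' distractor count (1, 5, 20); case 1 replicates the training coding.
#' Case 7 equals case 1 except that the hands are invisible
#' (visual value 0) and corollary discharge is off.
#'
#' @param id case number 1-7, or `NULL` for the full list.
#' @return an `"hr_case"` (single id) or named list of them.
#' @export
test_cases <- function(id = NULL) {
  grid <- list(c(0.2, 1), c(0.2, 5), c(0.2, 20),
               c(0.5, 1), c(0.5, 5), c(0.5, 20))
  cases <- lapply(grid, function(g)
    case_config(hand_value = 0.5, other_value = g[1], n_others = g[2],
                cd_enabled = TRUE, phase = "test"))
  cases <- c(cases, list(case_config(hand_value = 0, other_value = 0.2,
                                     n_others = 1L, cd_enabled = FALSE,
                                     phase = "test")))
  names(cases) <- paste0("case", 1:7)
  if (is.null(id)) return(cases)
  if (!id %in% 1:7) stop("unknown case id: ", id)
  cases[[id]]
}

#' Encode the visual segment
#'
#' The field-of-view unit of a square holding a hand receives the case's
#' hand value, one holding a distractor its distractor value; all other
#' units are 0. Entities outside the field of view produce no activation.
#' When a hand and a distractor overlap the (visible) hand takes precedence.
#'
#' @param world an `"hr_world"` object.
#' @param geometry an [grid_geometry()] object.
#' @param case an [case_config()] object.
#' @return numeric vector of length `geometry$n_visual`.
#' @export
encode_visual <- function(world, geometry, case) {
  v <- numeric(geometry$n_visual)
  put <- function(v, pos, value) {
    if (value != 0 && pos[[2]] < geometry$fov_rows)
      v[pos[[2]] * geometry$area_width + pos[[1]] + 1L] <- value
    v
  }
  if (nrow(world$others) > 0)
    for (i in seq_len(nrow(world$others)))
      v <- put(v, world$others[i, ], case$other_value)
  v <- put(v, world$left, case$hand_value)
  v <- put(v, world$right, case$hand_value)
  v
}

#' Encode the proprioceptive segment
#'
#' Per hand, exactly one of nine block units is active (value 1): the unit
#' of the block returned by [perceived_block()]. Always on -- hand regard is
#' seen in blind infants, and proprioception is what lets the simulated
#' infant find its hand without vision.
#'
#' @inheritParams encode_visual
#' @return numeric vector of length 18 (left 9 then right 9).
#' @export
encode_proprio <- function(world, geometry) {
  p <- numeric(18L)
  bl <- block_index(world$left, geometry)
  br <- block_index(world$right, geometry)
  p[bl[2] * 3L + bl[1] + 1L] <- 1
  p[9L + br[2] * 3L + br[1] + 1L] <- 1
  p
}

#' Encode the corollary-discharge segment
#'
#' The simplified forward model reports only the direction of each hand's
#' most recent movement command (distances are always one square and are
#' ignored). Per hand: four direction units (right, up, left, down) matching
#' the nonzero axes of the command, and a no-move unit active iff both axes
#' are zero. With `cd_enabled = FALSE` (case 7) the whole segment is zero.
#'
#' @param prev_cmd integer `c(dxL, dyL, dxR, dyR)` (screen frame).
#' @param case an [case_config()] object.
#' @return numeric vector of length 10.
#' @export
encode_cd <- function(prev_cmd, case) {
  cd <- numeric(10L)
  if (!case$cd_enabled) return(cd)
  enc <- function(dx, dy) {
    u <- numeric(5L)
    if (dx == 1L) u[1] <- 1
    if (dy == -1L) u[2] <- 1
    if (dx == -1L) u[3] <- 1
    if (dy == 1L) u[4] <- 1
    if (dx == 0L && dy == 0L) u[5] <- 1
    u
  }
  cd[1:5] <- enc(prev_cmd[[1]], prev_cmd[[2]])
  cd[6:10] <- enc(prev_cmd[[3]], prev_cmd[[4]])
  cd
}

#' Build the full input vector for one time step
#'
#' Concatenates visual, proprioceptive and corollary-discharge segments in
#' the fixed layout order; length 238 under the default geometry.
#'
#' @inheritParams encode_visual
#' @param prev_cmd the movement command decoded at the previous step.
#' @return numeric vector of length `input_layout(geometry)$total`.
#' @export
build_input <- function(world, prev_cmd, geometry, case) {
  x <- c(encode_visual(world, geometry, case),
         encode_proprio(world, geometry),
         encode_cd(prev_cmd, case))
  if (length(x) != input_layout(geometry)$total)
    stop("input layout mismatch")
  x
}
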