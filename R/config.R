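#' Run configuration
#'
#' Bundles geometry, network size, trainer settings and all schedules into
#' one validated object. Two presets are shipped:
#'
#' * `"paper"` -- the full-scale study conditions: 15 x 15 squares (60 cm),
#'   5 x 5-square blocks, field of view 15 x 14 (238 input units), 48 hidden
#'   units, 5.5e7 training steps, checkpoints every 1e6 steps, a 1e4-step
#'   observation window every 5e5 steps (the 3 h / week observation ratio
#'   3/168), repositioning every 1000 steps, distractor step every 50 steps,
#'   1e5-step test windows (100 placements).
#' * `"scaled"` -- a desk-scale variant with identical structure: 9 x 9
#'   squares, 3 x 3-square blocks, field of view 9 x 8 (100 input units),
#'   16 hidden units, 1e6 training steps, checkpoints every 2.5e5 steps, a
#'   1e3-step window every 5e4 steps (same 0.02 ratio). The untrained
#'   baseline success rate is the same in both presets since the centre
#'   block covers 1/9 of the area either way.
#'
#' @param preset `"paper"` or `"scaled"`.
#' @param ... named overrides of any field (e.g. `total_steps`,
#'   `learning_rate`, `n_hidden`, `reposition_period`).
#' @return an `"hr_config"` list with elements `geometry` (an
#'   [grid_geometry()]), `n_hidden`, `learning_rate`, `update_period`,
#'   `threshold`, `init_range`, `total_steps`, `checkpoint_period`,
#'   `obs_interval`, `obs_window`, `reposition_period`, `other_move_period`,
#'   `test_window` and `training_case`.
#' @export
hr_config <- function(preset = c("scaled", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper") {
    list(geometry = grid_geometry(15L, 15L, 4, 5L, 14L),
         n_hidden = 48L,
         total_steps = 5.5e7, checkpoint_period = 1e6,
         obs_interval = 5e5, obs_window = 1e4,
         test_window = 1e5)
  } else {
    list(geometry = grid_geometry(9L, 9L, 4, 3L, 8L),
         n_hidden = 16L,
         total_steps = 1e6, checkpoint_period = 2.5e5,
         obs_interval = 5e4, obs_window = 1e3,
         test_window = 1e5)
  }
  cfg <- c(cfg, list(
    preset = preset,
    learning_rate = 0.1, update_period = 10L,
    threshold = 0.8, init_range = 0.1,
    reposition_period = 1000L, other_move_period = 50L,
    training_case = case_config()
  ))
  dots <- list(...)
  geo_args <- intersect(names(dots),
                        c("area_width", "area_height", "square_size",
                          "block_size", "fov_rows"))
  if (length(geo_args)) {
    ga <- c(list(area_width = cfg$geometry$area_width,
                 area_height = cfg$geometry$area_height,
                 square_size = cfg$geometry$square_size,
                 block_size = cfg$geometry$block_size,
                 fov_rows = cfg$geometry$fov_rows))
    ga[geo_args] <- dots[geo_args]
    cfg$geometry <- do.call(grid_geometry, ga)
    dots <- dots[setdiff(names(dots), geo_args)]
  }
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "hr_config"
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' Checks every cross-field invariant: the input layout total, schedule
#' divisibility, window sizes and threshold range. Returns the config
#' invisibly so it can be used in a pipeline; errors name the offending
#' field.
#'
#' @param cfg an `"hr_config"` object.
#' @return the validated config.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config invalid: ", msg, call. = FALSE)
  lay <- input_layout(cfg$geometry)
  chk(lay$total == cfg$geometry$n_visual + 28L, "input layout total")
  chk(cfg$n_hidden %% 2L == 0L, "n_hidden must split into two equal parts")
  chk(cfg$update_period >= 1L, "update_period must be >= 1")
  chk(cfg$threshold > 0 && cfg$threshold <= 1, "threshold must be in (0, 1]")
  chk(cfg$obs_window <= cfg$obs_interval,
      "obs_window must fit inside obs_interval")
  chk(cfg$checkpoint_period %% cfg$obs_interval == 0,
      "obs_interval must divide checkpoint_period")
  chk(cfg$total_steps %% cfg$checkpoint_period == 0,
      "checkpoint_period must divide total_steps")
  chk(cfg$reposition_period == 0 ||
        cfg$test_window %% cfg$reposition_period == 0,
      "reposition_period must divide test_window")
  invisible(cfg)
}

#' @export
print.hr_config <- function(x, ...) {
  cat(sprintf("hand-regard run config (preset '%s')\n", x$preset))
  print(x$geometry)
  cat(sprintf("network: %d inputs, %d hidden, 8 outputs; eta = %g, update every %d steps\n",
              input_layout(x$geometry)$total, x$n_hidden,
              x$learning_rate, x$update_period))
  cat(sprintf("training: %g steps, checkpoints every %g, %g-step window every %g steps\n",
              x$total_steps, x$checkpoint_period, x$obs_window, x$obs_interval))
  invisible(x)
}

#' Load a run configuration from a YAML or JSON file
#'
#' The file may set `preset` and any override accepted by [hr_config()];
#' geometry fields are given flat (e.g. `area_width: 9`). The result is
#' fully validated.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return an `"hr_config"` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  preset <- raw$preset %||% "scaled"
  raw$preset <- NULL
  do.call(hr_config, c(list(preset = preset), raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
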