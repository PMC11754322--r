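#' @useDynLib trajexplore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a 2-D movement trajectory
#'
#' A trajectory is an ordered sequence of planar positions, in the coordinate
#' units of the environment ("virtual meters", vm), optionally with aligned
#' timestamps and/or a known sampling rate.  All downstream measures operate
#' on this class.
#'
#' @param x,y Numeric coordinate vectors of equal length (at least 2 points).
#' @param times Optional numeric vector of timestamps in seconds, strictly
#'   increasing, aligned 1:1 with the points.
#' @param subject_id Identifier carried through QC reports and measure tables.
#' @param sample_rate_hz Optional known sampling rate (positive), used when no
#'   timestamps are available (e.g., logs from hardware without clocks).
#' @return An object of class `"trajectory"`: a list with elements `subject_id`,
#'   `xy` (n x 2 matrix), `times` (or `NULL`) and `sample_rate_hz` (or `NULL`).
#' @examples
#' tr <- trajectory(c(0, 3, 6), c(0, 4, 8), times = c(0, 0.1, 0.2))
#' tr
#' @export
trajectory <- function(x, y, times = NULL, subject_id = "subject",
                       sample_rate_hz = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("degenerate trajectory: fewer than 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all coordinates must be finite")
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != length(x))
      stop("times must align 1:1 with points")
    if (any(!is.finite(times)) || any(diff(times) <= 0))
      stop("times must be finite and strictly increasing")
  }
  if (!is.null(sample_rate_hz)) {
    sample_rate_hz <- as.numeric(sample_rate_hz)
    if (length(sample_rate_hz) != 1 || !is.finite(sample_rate_hz) ||
        sample_rate_hz <= 0)
      stop("sample_rate_hz must be a single positive number")
  }
  structure(
    list(subject_id = as.character(subject_id),
         xy = cbind(x = x, y = y),
         times = times,
         sample_rate_hz = sample_rate_hz),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$xy)
  cat(sprintf("<trajectory '%s': %d samples", x$subject_id, n))
  if (!is.null(x$times))
    cat(sprintf(", %.1f s", x$times[n] - x$times[1]))
  if (!is.null(x$sample_rate_hz))
    cat(sprintf(", %g Hz", x$sample_rate_hz))
  cat(">\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ..., asp = 1, type = "l") {
  plot(x$xy[, 1], x$xy[, 2], type = type, asp = asp,
       xlab = "x (vm)", ylab = "y (vm)", main = x$subject_id, ...)
  invisible(x)
}

n_points <- function(traj) nrow(traj$xy)

# sampling rate, preferring the declared value, else inferred from timestamps
traj_rate <- function(traj) {
  if (!is.null(traj$sample_rate_hz)) return(traj$sample_rate_hz)
  if (!is.null(traj$times)) {
    n <- length(traj$times)
    return((n - 1) / (traj$times[n] - traj$times[1]))
  }
  NULL
}

#' Describe an environment: bounds, occupancy grid and landmarks
#'
#' @param name Environment label.
#' @param bounds Numeric `(xmin, ymin, xmax, ymax)` in vm.
#' @param bin_size Side length (vm) of the square occupancy-grid cells used by
#'   area covered and roaming entropy.  Cells are anchored at
#'   `(xmin, ymin)` and half-open.
#' @param k_norm Normalization constant for roaming entropy: the number of
#'   bins the environment offers (e.g., its total size in bins, or the number
#'   of unique bins a whole cohort explored).  `NULL` defers the choice to
#'   [cohort_measures()], which then uses the cohort's unique-bin count.
#' @param landmarks `NULL` or a data.frame with columns `id`, `x`, `y`.
#' @return An object of class `"env_spec"`.
#' @examples
#' env <- env_spec("toy", c(0, 0, 140, 140), bin_size = 14, k_norm = 100)
#' @export
env_spec <- function(name, bounds, bin_size, k_norm = NULL, landmarks = NULL) {
  bounds <- as.numeric(bounds)
  if (length(bounds) != 4 || any(!is.finite(bounds)))
    stop("bounds must be finite (xmin, ymin, xmax, ymax)")
  if (bounds[3] <= bounds[1] || bounds[4] <= bounds[2])
    stop("bounds must satisfy xmax > xmin and ymax > ymin")
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a single positive number")
  if (!is.null(k_norm)) {
    k_norm <- as.integer(k_norm)
    if (is.na(k_norm) || k_norm < 1) stop("k_norm must be a positive integer")
  }
  if (!is.null(landmarks)) {
    landmarks <- as.data.frame(landmarks)
    if (!all(c("id", "x", "y") %in% names(landmarks)))
      stop("landmarks need columns id, x, y")
    if (!all(is.finite(landmarks$x)) || !all(is.finite(landmarks$y)))
      stop("landmark coordinates must be finite")
    landmarks$id <- as.character(landmarks$id)
  }
  structure(
    list(name = as.character(name), bounds = bounds, bin_size = bin_size,
         k_norm = k_norm, landmarks = landmarks),
    class = "env_spec"
  )
}

#' @export
print.env_spec <- function(x, ...) {
  cat(sprintf("<environment '%s': [%g, %g] x [%g, %g] vm, bin %g, k %s, %d landmarks>\n",
              x$name, x$bounds[1], x$bounds[3], x$bounds[2], x$bounds[4],
              x$bin_size,
              if (is.null(x$k_norm)) "cohort" else as.character(x$k_norm),
              if (is.null(x$landmarks)) 0L else nrow(x$landmarks)))
  invisible(x)
}

#' Measure extraction parameters
#'
#' Bundles every tunable constant of the measure suite.  Defaults are the
#' settings for a NEMO-like free-exploration environment: landmark discs of
#' radius 20 vm, revisiting places of radius 14 vm, flight simplification at
#' epsilon 6 vm with a 160-degree turnaround cutoff, step-scale turnarounds at
#' 180 degrees, 20 divider sizes between 0.5x and 10x the median step for the
#' fractal dimension, and a 10 Hz resampling target.
#'
#' @param landmark_radius Radius (vm) of the disc around a landmark within
#'   which it counts as visited.
#' @param revisit_radius Radius (vm) of the greedy place discs for the
#'   revisiting measure.
#' @param rediscretize_step Constant step (vm) for spatial rediscretization
#'   (sinuosity).  `NULL` means "use the pooled median nonzero step length"
#'   (per trajectory when measures are computed singly).
#' @param rdp_epsilon Maximum deviation (vm) allowed by the flight-scale
#'   polyline simplification.
#' @param flight_turn_cutoff Turning angle (degrees) on the flight-scale
#'   polyline at or above which a turnaround is counted.
#' @param step_turn_cutoff Step-scale turnaround cutoff (degrees); matched
#'   with a 0.5-degree tolerance since floating-point headings rarely reverse
#'   exactly.
#' @param fd_n_steps Number of divider sizes for the fractal dimension.
#' @param fd_min_factor,fd_max_factor Range of divider sizes as multiples of
#'   the median nonzero step length.
#' @param pause_epsilon Step length (vm) at or below which a step counts as a
#'   pause.
#' @param target_hz Common sampling rate (Hz) trajectories are resampled to.
#' @return An object of class `"measure_params"` (a named list).
#' @export
measure_params <- function(landmark_radius = 20, revisit_radius = 14,
                           rediscretize_step = NULL, rdp_epsilon = 6,
                           flight_turn_cutoff = 160, step_turn_cutoff = 180,
                           fd_n_steps = 20, fd_min_factor = 0.5,
                           fd_max_factor = 10, pause_epsilon = 1e-9,
                           target_hz = 10) {
  p <- list(landmark_radius = landmark_radius, revisit_radius = revisit_radius,
            rediscretize_step = rediscretize_step, rdp_epsilon = rdp_epsilon,
            flight_turn_cutoff = flight_turn_cutoff,
            step_turn_cutoff = step_turn_cutoff, fd_n_steps = fd_n_steps,
            fd_min_factor = fd_min_factor, fd_max_factor = fd_max_factor,
            pause_epsilon = pause_epsilon, target_hz = target_hz)
  pos <- c("landmark_radius", "revisit_radius", "rdp_epsilon", "pause_epsilon",
           "target_hz")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("%s must be positive", nm))
  if (!is.null(p$rediscretize_step) && p$rediscretize_step <= 0)
    stop("rediscretize_step must be positive")
  if (p$flight_turn_cutoff <= 0 || p$flight_turn_cutoff > 180)
    stop("flight_turn_cutoff must be in (0, 180]")
  if (p$fd_min_factor >= p$fd_max_factor)
    stop("fd_min_factor must be smaller than fd_max_factor")
  if (p$fd_n_steps < 3) stop("fd_n_steps must be at least 3")
  structure(p, class = "measure_params")
}

#' Named parameter profiles
#'
#' `"nemo"` is the free-exploration island profile (bin 14 vm, rediscretization
#' step 0.48 vm); `"silcton"` is the goal-directed campus profile (bin 15 vm,
#' step 0.50 vm).  All other constants are shared.
#'
#' @param profile `"nemo"` or `"silcton"`.
#' @return A list with elements `bin_size` and `params` (a [measure_params()]).
#' @export
param_profile <- function(profile = c("nemo", "silcton")) {
  profile <- match.arg(profile)
  switch(profile,
    nemo = list(bin_size = 14, params = measure_params(rediscretize_step = 0.48)),
    silcton = list(bin_size = 15, params = measure_params(rediscretize_step = 0.50))
  )
}

#' Read a trajectory from a delimited text file
#'
#' Rows are taken in file order: the reader never reorders, drops or filters
#' samples.  Game logs are typically 3-D; choose the two horizontal axes via
#' `column_map` (e.g., `c(x = "X", y = "Z")`) — the vertical axis is not read.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the roles `x`, `y` and
#'   optionally `t` (time in seconds) to file column names.
#' @param delimiter Field separator.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param sample_rate_hz Optional known sampling rate for files without a time
#'   column.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, column_map = c(x = "x", y = "y"),
                            delimiter = ",", subject_id = NULL,
                            sample_rate_hz = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (!all(c("x", "y") %in% names(column_map)))
    stop("column_map must name columns for roles 'x' and 'y'")
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (role in names(column_map)) {
    col <- column_map[[role]]
    if (!col %in% names(df))
      stop(sprintf("format error: column '%s' (role '%s') not found in %s",
                   col, role, path))
  }
  num <- function(col) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad))
        stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                     col, bad[1]))
      v <- v2
    }
    v
  }
  if (nrow(df) < 2)
    stop(sprintf("degenerate input: %s has fewer than 2 data rows", path))
  x <- num(column_map[["x"]])
  y <- num(column_map[["y"]])
  times <- if ("t" %in% names(column_map)) num(column_map[["t"]]) else NULL
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  trajectory(x, y, times = times, subject_id = subject_id,
             sample_rate_hz = sample_rate_hz)
}

#' Read an environment description and measure parameters from YAML
#'
#' The config is a flat YAML document with keys `name`, `bounds`
#' (`[xmin, ymin, xmax, ymax]`), `bin_size`, optional `k_norm`, optional
#' `landmarks` (list of `{id, x, y}` entries), and an optional `params` block
#' overriding [measure_params()] defaults.
#'
#' @param path Path to a YAML config file.
#' @return A list with elements `env` ([env_spec()]) and `params`
#'   ([measure_params()]).
#' @export
read_environment <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  for (key in c("bounds", "bin_size"))
    if (is.null(cfg[[key]]))
      stop(sprintf("config error: missing key '%s' in %s", key, path))
  lm <- NULL
  if (!is.null(cfg$landmarks)) {
    lm <- do.call(rbind, lapply(cfg$landmarks, function(l) {
      # YAML 1.1 treats a bare `y` key as boolean TRUE; accept both spellings
      yv <- if (!is.null(l[["y"]])) l[["y"]] else l[["TRUE"]]
      if (is.null(l$id) || is.null(l$x) || is.null(yv))
        stop("config error: each landmark needs id, x and y")
      data.frame(id = as.character(l$id), x = as.numeric(l$x),
                 y = as.numeric(yv), stringsAsFactors = FALSE)
    }))
  }
  env <- env_spec(name = if (is.null(cfg$name)) "environment" else cfg$name,
                  bounds = unlist(cfg$bounds), bin_size = cfg$bin_size,
                  k_norm = cfg$k_norm, landmarks = lm)
  params <- do.call(measure_params, if (is.null(cfg$params)) list() else cfg$params)
  list(env = env, params = params)
}

measure_columns <- c(
  "path_length", "pausing", "area_covered", "roaming_entropy",
  "min_convex_polygon", "fractal_dimension", "sinuosity",
  "landmark_visits", "landmark_revisits", "revisiting",
  "turnarounds", "flight_turnarounds", "area_efficiency",
  "landmark_efficiency")

#' Write / read a cohort measure table
#'
#' One row per subject, one column per measure, in a fixed column order
#' (`subject_id` first).  Values round-trip losslessly at full double
#' precision.
#'
#' @param rows A data.frame of measure rows (as returned by
#'   [compute_measures()] / [cohort_measures()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measure_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) < 1) stop("empty measure table")
  if (anyDuplicated(rows$subject_id))
    stop("duplicate subject_id in measure table")
  missing_cols <- setdiff(c("subject_id", measure_columns), names(rows))
  if (length(missing_cols))
    stop(sprintf("measure table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")))
  out <- rows[, c("subject_id", measure_columns)]
  for (nm in measure_columns)
    out[[nm]] <- trimws(formatC(out[[nm]], digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measure_table
#' @export
read_measure_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$subject_id <- as.character(df$subject_id)
  for (nm in setdiff(names(df), "subject_id")) df[[nm]] <- as.numeric(df[[nm]])
  df
}
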