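#' Infer a sampling rate from a point count and a known session length
#'
#' Logs from machines without clocks carry no timestamps; when the session
#' duration is known (e.g., a fixed 150 s task), the mean rate is the number
#' of logged points divided by that duration.
#'
#' @param n_points Number of logged samples (>= 2).
#' @param total_time Session duration in seconds (> 0).
#' @return Sampling rate in Hz.
#' @examples
#' infer_sampling_rate(3000, 150)  # 20 Hz
#' @export
infer_sampling_rate <- function(n_points, total_time) {
  if (n_points < 2) stop("need at least 2 points")
  if (!is.numeric(total_time) || total_time <= 0)
    stop("total_time must be positive")
  n_points / total_time
}

#' Step lengths of a trajectory
#'
#' Euclidean distances between consecutive samples; length `n - 1`.
#'
#' @param traj A [trajectory()].
#' @return Numeric vector of distances in vm.
#' @export
step_lengths <- function(traj) {
  xy <- traj$xy
  sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
}

#' Turning angles of a trajectory
#'
#' The angle between consecutive displacement vectors: 0 degrees for no change
#' in heading, 180 degrees for a complete reversal.  Zero-length displacements
#' carry no heading; with `skip_zero_steps` they are removed before angles are
#' formed (the default), so angles bridge across pauses.
#'
#' @param traj A [trajectory()] with at least 3 points.
#' @param skip_zero_steps Drop zero-length displacements first.
#' @param signed Return signed angles in radians (counterclockwise positive)
#'   instead of absolute angles in degrees.  The signed form feeds the
#'   sinuosity index.
#' @return Numeric vector of angles: degrees in `[0, 180]`, or signed radians
#'   in `(-pi, pi]` when `signed = TRUE`.  Empty when every displacement is
#'   zero.
#' @export
turning_angles <- function(traj, skip_zero_steps = TRUE, signed = FALSE) {
  xy <- traj$xy
  if (nrow(xy) < 3) stop("need at least 3 points for turning angles")
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  len <- sqrt(dx^2 + dy^2)
  if (skip_zero_steps) {
    nz <- len > 0
    dx <- dx[nz]; dy <- dy[nz]
  }
  if (length(dx) < 2) return(numeric(0))
  h <- atan2(dy, dx)
  a <- diff(h)
  a <- atan2(sin(a), cos(a))  # wrap to (-pi, pi]
  if (signed) a else abs(a) * 180 / pi
}

#' Quality-control parameters
#'
#' @param cov_outlier_iqr_mult Cohort-level cutoff: a subject's step-length
#'   coefficient of variation is flagged when it exceeds Q3 plus this multiple
#'   of the cohort IQR.
#' @param lag_step_mult A step is a "large lag" when longer than this multiple
#'   of the trajectory's median nonzero step.
#' @param lag_fraction_cutoff Maximum tolerated share of lag steps.
#' @param min_movement_seconds Minimum total time in motion.
#' @param min_sampling_hz Minimum acceptable sampling rate.
#' @return An object of class `"qc_params"`.
#' @export
qc_params <- function(cov_outlier_iqr_mult = 3, lag_step_mult = 3,
                      lag_fraction_cutoff = 0.001, min_movement_seconds = 30,
                      min_sampling_hz = 10) {
  p <- list(cov_outlier_iqr_mult = cov_outlier_iqr_mult,
            lag_step_mult = lag_step_mult,
            lag_fraction_cutoff = lag_fraction_cutoff,
            min_movement_seconds = min_movement_seconds,
            min_sampling_hz = min_sampling_hz)
  if (any(unlist(p) <= 0)) stop("all QC parameters must be positive")
  if (p$lag_fraction_cutoff >= 1) stop("lag_fraction_cutoff must be in (0, 1)")
  structure(p, class = "qc_params")
}

#' Screen one trajectory for recording-quality problems
#'
#' Computes the per-subject screening quantities: the coefficient of variation
#' of nonzero step lengths (a proxy for within-session sampling-rate
#' variability when movement speed is fixed), the fraction of steps longer
#' than `lag_step_mult` times the median nonzero step (recording lags), and
#' the total time in motion.  A subject is flagged when movement time falls
#' below `min_movement_seconds` (`"low_movement"`), when the lag fraction
#' exceeds the cutoff (`"high_lag"`), when the sampling rate is below
#' `min_sampling_hz` (`"low_rate"`), or when there is no movement at all
#' (`"no_movement"`).  CoV outlier flagging is relative to a cohort and lives
#' in [cohort_screen()]; here only the raw CoV is reported.
#'
#' @param traj A [trajectory()].
#' @param total_time Optional session duration (seconds) used to infer the
#'   sampling rate when the trajectory carries none.
#' @param qc A [qc_params()].
#' @return A one-row data.frame: `subject_id`, `sampling_rate_hz`,
#'   `cov_step_length`, `lag_fraction`, `movement_seconds`, `excluded`,
#'   `reasons` (semicolon-joined codes, empty when not excluded).
#' @export
qc_screen <- function(traj, total_time = NULL, qc = qc_params()) {
  n <- n_points(traj)
  rate <- if (!is.null(total_time)) infer_sampling_rate(n, total_time)
          else traj_rate(traj)
  if (is.null(rate))
    stop("unknown sampling rate: supply total_time, times or sample_rate_hz")
  steps <- step_lengths(traj)
  nz <- steps[steps > 0]
  reasons <- character(0)
  if (length(nz) == 0) {
    report <- data.frame(
      subject_id = traj$subject_id, sampling_rate_hz = rate,
      cov_step_length = NA_real_, lag_fraction = 0, movement_seconds = 0,
      excluded = TRUE, reasons = "no_movement", stringsAsFactors = FALSE)
    return(report)
  }
  cov <- stats::sd(nz) / mean(nz)
  med <- stats::median(nz)
  lag_fraction <- sum(steps > qc$lag_step_mult * med) / length(steps)
  movement_seconds <- length(nz) / rate
  if (movement_seconds < qc$min_movement_seconds)
    reasons <- c(reasons, "low_movement")
  if (lag_fraction > qc$lag_fraction_cutoff)
    reasons <- c(reasons, "high_lag")
  if (rate < qc$min_sampling_hz)
    reasons <- c(reasons, "low_rate")
  data.frame(
    subject_id = traj$subject_id, sampling_rate_hz = rate,
    cov_step_length = cov, lag_fraction = lag_fraction,
    movement_seconds = movement_seconds, excluded = length(reasons) > 0,
    reasons = paste(reasons, collapse = ";"), stringsAsFactors = FALSE)
}

#' Flag cohort-relative step-length variability outliers
#'
#' A subject's CoV of step lengths is an outlier when it exceeds the cohort's
#' third quartile by more than `cov_outlier_iqr_mult` interquartile ranges.
#' With fewer than 4 subjects the quartiles are not meaningful and the reports
#' pass through unchanged (with a warning).
#'
#' @param reports A data.frame of rows from [qc_screen()].
#' @param qc A [qc_params()].
#' @return The reports with `"cov_outlier"` appended to the reasons (and
#'   `excluded` set) for flagged subjects.
#' @export
cohort_screen <- function(reports, qc = qc_params()) {
  reports <- as.data.frame(reports)
  if (nrow(reports) < 4) {
    warning("fewer than 4 subjects: CoV outlier screen skipped")
    return(reports)
  }
  covs <- reports$cov_step_length
  q <- stats::quantile(covs, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  cutoff <- q[2] + qc$cov_outlier_iqr_mult * (q[2] - q[1])
  hit <- !is.na(covs) & covs > cutoff
  if (any(hit)) {
    reports$excluded[hit] <- TRUE
    reports$reasons[hit] <- ifelse(nzchar(reports$reasons[hit]),
                                   paste(reports$reasons[hit], "cov_outlier",
                                         sep = ";"),
                                   "cov_outlier")
  }
  reports
}

#' Trim leading idle time from a trajectory
#'
#' Removes samples recorded before the subject first moved (e.g., while
#' listening to instructions).  The last idle sample is retained so the first
#' movement step is part of the result.
#'
#' @param traj A [trajectory()].
#' @return A trimmed [trajectory()].
#' @export
trim_initial_idle <- function(traj) {
  steps <- step_lengths(traj)
  first_move <- which(steps > 0)[1]
  if (is.na(first_move))
    stop(sprintf("degenerate trajectory '%s': no movement at all",
                 traj$subject_id))
  if (first_move == 1) return(traj)
  keep <- first_move:n_points(traj)
  trajectory(traj$xy[keep, 1], traj$xy[keep, 2],
             times = traj$times[keep], subject_id = traj$subject_id,
             sample_rate_hz = traj$sample_rate_hz)
}

#' Resample a trajectory to a common sampling rate
#'
#' Positions are linearly interpolated per coordinate at uniform intervals
#' `1/target_hz` from the first to the last timestamp.  Trajectories without
#' timestamps but with a known `sample_rate_hz` are assigned synthetic
#' timestamps `(i - 1) / rate`.
#'
#' @param traj A [trajectory()].
#' @param target_hz Target sampling rate in Hz.
#' @return A [trajectory()] sampled at `target_hz` with timestamps.
#' @export
resample_temporal <- function(traj, target_hz = 10) {
  if (!is.numeric(target_hz) || target_hz <= 0)
    stop("target_hz must be positive")
  times <- traj$times
  if (is.null(times)) {
    if (is.null(traj$sample_rate_hz))
      stop("unknown timing: set times or sample_rate_hz before resampling")
    times <- (seq_len(n_points(traj)) - 1) / traj$sample_rate_hz
  }
  new_times <- seq(times[1], times[length(times)], by = 1 / target_hz)
  x <- stats::approx(times, traj$xy[, 1], xout = new_times)$y
  y <- stats::approx(times, traj$xy[, 2], xout = new_times)$y
  trajectory(x, y, times = new_times, subject_id = traj$subject_id,
             sample_rate_hz = target_hz)
}

#' Rediscretize a trajectory to constant step length
#'
#' Classic constant-step rediscretization: starting at the first vertex, each
#' successive point is the first location along the path at Euclidean distance
#' exactly `step` from the previous emitted point, so every emitted step has
#' length `step`.  The trailing piece shorter than one step is discarded.
#' Constant-step paths feed the sinuosity index and the divider-method
#' fractal dimension.
#'
#' @param traj A [trajectory()].
#' @param step Target step length in vm.
#' @return A [trajectory()] with constant step length (timestamps dropped:
#'   the rediscretized path is a spatial, not temporal, object).
#' @export
rediscretize_spatial <- function(traj, step) {
  if (!is.numeric(step) || step <= 0) stop("step must be positive")
  if (path_length(traj) < step)
    stop("degenerate input: path shorter than one step")
  xy <- cpp_rediscretize(traj$xy, step)
  trajectory(xy[, 1], xy[, 2], subject_id = traj$subject_id)
}

#' Flight-scale simplification (Ramer-Douglas-Peucker)
#'
#' Recursively keeps the vertex of maximum perpendicular distance from the
#' chord whenever that distance exceeds `epsilon`; endpoints are always
#' retained.  The surviving polyline is the trajectory at the scale of
#' flights: maximal runs of approximately constant heading, with all movement
#' detail below `epsilon` removed.
#'
#' @param traj A [trajectory()].
#' @param epsilon Maximum allowed deviation (vm) of the simplified polyline
#'   from the original samples.
#' @return A [trajectory()] whose vertices are a subsequence of the input
#'   vertices (timestamps of kept vertices are preserved).
#' @export
rdp_simplify <- function(traj, epsilon) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  keep <- cpp_rdp_keep(traj$xy, epsilon)
  trajectory(traj$xy[keep, 1], traj$xy[keep, 2],
             times = traj$times[keep], subject_id = traj$subject_id,
             sample_rate_hz = NULL)
}

#' Standard preprocessing: trim leading idle time, then resample
#'
#' @param traj A [trajectory()].
#' @param target_hz Target sampling rate in Hz.
#' @return A preprocessed [trajectory()].
#' @export
preprocess_trajectory <- function(traj, target_hz = 10) {
  trim_initial_idle(resample_temporal(traj, target_hz))
}
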