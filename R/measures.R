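#' Grid-bin occupancy sequence of a trajectory
#'
#' Assigns every sample to a square grid cell of side `bin_size`, anchored at
#' the lower-left corner of the environment bounds, with half-open cells
#' `[x0 + i*s, x0 + (i+1)*s)`.  Samples outside the bounds are clamped into
#' the nearest boundary cell and counted.  The run-length-compressed form of
#' the sample-wise sequence gives the bin *entries*: each transition into a
#' bin different from the previous sample's bin (the first sample counts as
#' an entry).
#'
#' @param traj A [trajectory()].
#' @param env An [env_spec()].
#' @return An object of class `"bin_sequence"`: list with `ij` (n x 2 integer
#'   matrix of zero-based cell indices), `id` (linear cell id per sample),
#'   `entries` (linear cell id per entry event), `n_cells` (grid size), and
#'   `n_clamped` (samples outside the bounds).
#' @export
bin_sequence <- function(traj, env) {
  b <- env$bounds; s <- env$bin_size
  nx <- ceiling((b[3] - b[1]) / s - 1e-9)
  ny <- ceiling((b[4] - b[2]) / s - 1e-9)
  x <- traj$xy[, 1]; y <- traj$xy[, 2]
  out_of_bounds <- x < b[1] | x > b[3] | y < b[2] | y > b[4]
  n_clamped <- sum(out_of_bounds)
  if (n_clamped > 0)
    warning(sprintf("%d sample(s) outside bounds clamped for '%s'",
                    n_clamped, traj$subject_id))
  i <- pmin(pmax(floor((x - b[1]) / s), 0), nx - 1)
  j <- pmin(pmax(floor((y - b[2]) / s), 0), ny - 1)
  id <- i + nx * j
  entries <- rle(id)$values
  structure(list(ij = cbind(i = as.integer(i), j = as.integer(j)),
                 id = id, entries = entries,
                 n_cells = as.integer(nx * ny), n_clamped = n_clamped),
            class = "bin_sequence")
}

#' Total path length
#'
#' @param traj A [trajectory()].
#' @return Sum of step lengths in vm.
#' @export
path_length <- function(traj) sum(step_lengths(traj))

#' Time spent without movement
#'
#' Number of zero-length steps (length at most `pause_epsilon`) divided by
#' the sampling rate.
#'
#' @param traj A [trajectory()] with a known sampling rate.
#' @param params A [measure_params()].
#' @return Pausing time in seconds.
#' @export
pausing <- function(traj, params = measure_params()) {
  rate <- traj_rate(traj)
  if (is.null(rate)) stop("pausing needs a known sampling rate")
  sum(step_lengths(traj) <= params$pause_epsilon) / rate
}

#' Area covered during exploration
#'
#' @param bins A [bin_sequence()].
#' @return Number of distinct grid bins visited.
#' @export
area_covered <- function(bins) length(unique(bins$id))

#' Roaming entropy of grid occupancy
#'
#' Shannon entropy of the per-sample bin occupancy frequencies, normalized by
#' `log(k_norm)`: 0 when a single bin holds all samples, 1 when occupancy is
#' uniform over exactly `k_norm` bins.  Occupancy is per sample, i.e.
#' time-weighted at a fixed sampling rate.
#'
#' @param bins A [bin_sequence()].
#' @param k_norm Normalization constant: the number of bins the environment
#'   offers (at least 2).
#' @return Roaming entropy in `[0, 1]`.
#' @export
roaming_entropy <- function(bins, k_norm) {
  if (is.null(k_norm) || k_norm < 2)
    stop("k_norm must be at least 2")
  p <- tabulate(match(bins$id, unique(bins$id)))
  p <- p / sum(p)
  -sum(p * log(p)) / log(k_norm) + 0  # + 0 avoids IEEE negative zero
}

#' Minimum convex polygon area
#'
#' Area of the convex hull of all sample points (the classic home-range
#' estimator); 0 when all points are collinear.
#'
#' @param traj A [trajectory()].
#' @return Hull area in vm squared.
#' @export
min_convex_polygon <- function(traj) {
  xy <- unique(traj$xy)
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' Fractal dimension of a trajectory (divider method)
#'
#' Measures the path with `fd_n_steps` divider sizes, log-spaced from
#' `fd_min_factor` to `fd_max_factor` times the median nonzero step length.
#' For each divider size `d`, the measured length `L(d)` is the constant-step
#' rediscretized length (number of emitted steps times `d`, plus the partial
#' last stride to the path's endpoint, which removes the systematic
#' shortening of up to one divider at coarse sizes).  The dimension is
#' `1 - slope` of the least-squares fit of `log L(d)` on `log d`: 1 for a
#' straight path, approaching 2 as the path fills the plane.  Divider sizes
#' larger than half the path length are dropped from the fit.
#'
#' @param traj A [trajectory()].
#' @param params A [measure_params()].
#' @return Fractal dimension (dimensionless, >= 1 up to fit tolerance).
#' @export
fractal_dimension <- function(traj, params = measure_params()) {
  steps <- step_lengths(traj)
  med <- stats::median(steps[steps > 0])
  total <- sum(steps)
  if (!is.finite(med) || total <= params$fd_max_factor * med)
    stop("path too short for the divider-size range")
  deltas <- exp(seq(log(params$fd_min_factor * med),
                    log(params$fd_max_factor * med),
                    length.out = params$fd_n_steps))
  last <- traj$xy[nrow(traj$xy), ]
  L <- vapply(deltas, function(d) {
    if (total < 2 * d) return(NA_real_)
    xy <- cpp_rediscretize(traj$xy, d)
    if (nrow(xy) < 2) return(NA_real_)
    tail_len <- sqrt(sum((last - xy[nrow(xy), ])^2))
    (nrow(xy) - 1) * d + tail_len
  }, numeric(1))
  ok <- is.finite(L) & L > 0
  if (sum(ok) < 3) stop("degenerate divider fit: fewer than 3 valid sizes")
  fit <- stats::lm(log(L[ok]) ~ log(deltas[ok]))
  1 - unname(stats::coef(fit)[2])
}

#' Sinuosity of a trajectory
#'
#' The tortuosity index for constant-step paths: `1.18 * sigma / sqrt(q)`,
#' where `q` is the rediscretization step and `sigma` the standard deviation
#' (radians) of the signed turning angles of the constant-step path.  Valid
#' for small-to-moderate turning-angle dispersion.
#'
#' @param traj A [trajectory()].
#' @param params A [measure_params()]; `rediscretize_step` of `NULL` uses the
#'   trajectory's median nonzero step length.
#' @return Sinuosity in rad * vm^(-1/2).
#' @export
sinuosity <- function(traj, params = measure_params()) {
  steps <- step_lengths(traj)
  q <- params$rediscretize_step
  if (is.null(q)) q <- stats::median(steps[steps > 0])
  rd <- rediscretize_spatial(traj, q)
  if (n_points(rd) < 3)
    stop("too few points after rediscretization for sinuosity")
  ang <- turning_angles(rd, signed = TRUE)
  sigma <- stats::sd(ang)
  if (is.na(sigma)) sigma <- 0  # a single turning angle carries no dispersion
  1.18 * sigma / sqrt(q)
}

#' Landmark visits, revisits and visiting efficiency
#'
#' A landmark counts as visited when the trajectory enters the disc of radius
#' `landmark_radius` around it; re-entry requires fully leaving the disc
#' first.  Visits is the number of distinct landmarks entered at least once;
#' revisits is the number of additional entries beyond the first per
#' landmark; efficiency is distinct landmarks per total entries (1 when no
#' landmark is ever re-entered, `NA` when no landmark is entered at all).
#'
#' @param traj A [trajectory()].
#' @param env An [env_spec()] with at least one landmark.
#' @param params A [measure_params()].
#' @return List with `landmark_visits`, `landmark_revisits`,
#'   `landmark_efficiency`, and `visit_log` (data.frame of entry events:
#'   `target_id`, `sample_index`).
#' @export
landmark_metrics <- function(traj, env, params = measure_params()) {
  lm <- env$landmarks
  if (is.null(lm) || nrow(lm) < 1) stop("environment has no landmarks")
  entries <- cpp_disc_entries(traj$xy, cbind(lm$x, lm$y),
                              params$landmark_radius)
  counts <- lengths(entries)
  total <- sum(counts)
  visits <- sum(counts > 0)
  log_df <- data.frame(
    target_id = rep(lm$id, counts),
    sample_index = unlist(entries, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(log_df)) log_df <- log_df[order(log_df$sample_index), , drop = FALSE]
  rownames(log_df) <- NULL
  list(landmark_visits = visits,
       landmark_revisits = total - visits,
       landmark_efficiency = if (total == 0) NA_real_ else visits / total,
       visit_log = log_df)
}

#' Average number of returns to already visited places
#'
#' Place centers are chosen greedily along the trajectory: the first sample
#' opens a place; every later sample farther than `revisit_radius` from all
#' existing places opens a new one.  Entries into each place's disc are
#' counted as for landmarks (full exit required before re-entry); the measure
#' is the mean over places of entries minus one, i.e. 0 when every place is
#' entered exactly once.
#'
#' @param traj A [trajectory()].
#' @param params A [measure_params()].
#' @return Mean return count (dimensionless, >= 0).
#' @export
revisiting <- function(traj, params = measure_params()) {
  idx <- cpp_greedy_centers(traj$xy, params$revisit_radius)
  centers <- traj$xy[idx, , drop = FALSE]
  entries <- cpp_disc_entries(traj$xy, centers, params$revisit_radius)
  mean(lengths(entries) - 1)
}

#' Step-scale turnarounds
#'
#' Counts step-scale turning angles at (or within 0.5 degrees of) the
#' reversal cutoff, skipping zero-length steps.  Sensitive to small-scale
#' movement such as strafing jitter; see [flight_turnarounds()] for the
#' flight-scale refinement.
#'
#' @param traj A [trajectory()].
#' @param params A [measure_params()].
#' @return Count of step-scale reversals.
#' @export
turnarounds <- function(traj, params = measure_params()) {
  ang <- turning_angles(traj, skip_zero_steps = TRUE)
  sum(ang >= params$step_turn_cutoff - 0.5)
}

#' Flight-scale turnarounds
#'
#' Simplifies the trajectory to the scale of flights with
#' [rdp_simplify()] at `rdp_epsilon`, then counts turning angles at or above
#' `flight_turn_cutoff` (default 160 degrees) on the simplified polyline.
#' Robust to sub-epsilon movement detail, so it reflects genuine long-range
#' reversals of heading.
#'
#' @param traj A [trajectory()].
#' @param params A [measure_params()].
#' @return Count of flight-scale reversals.
#' @export
flight_turnarounds <- function(traj, params = measure_params()) {
  fl <- rdp_simplify(traj, params$rdp_epsilon)
  if (n_points(fl) < 3) return(0L)
  ang <- turning_angles(fl, skip_zero_steps = TRUE)
  sum(ang >= params$flight_turn_cutoff)
}

#' Efficiency in covering an area
#'
#' Distinct bins visited divided by total bin entries: 1 when no bin is ever
#' re-entered, approaching 0 for heavy re-entry.
#'
#' @param bins A [bin_sequence()].
#' @return Area efficiency in `(0, 1]`.
#' @export
area_efficiency <- function(bins) {
  length(unique(bins$entries)) / length(bins$entries)
}

#' Compute all exploration measures for one trajectory
#'
#' Runs the full measure suite on a preprocessed (resampled, trimmed)
#' trajectory, sharing the bin sequence between the occupancy measures.
#' The step-scale turnarounds count is included alongside its flight-scale
#' refinement, giving 15 values per subject.
#'
#' @param traj A preprocessed [trajectory()].
#' @param env An [env_spec()]; `k_norm` of `NULL` falls back to the number of
#'   grid cells inside the bounds.
#' @param params A [measure_params()].
#' @return A one-row data.frame (`subject_id` plus the measure columns).
#' @export
compute_measures <- function(traj, env, params = measure_params()) {
  bins <- bin_sequence(traj, env)
  k <- if (is.null(env$k_norm)) bins$n_cells else env$k_norm
  lmk <- if (!is.null(env$landmarks) && nrow(env$landmarks) > 0)
    landmark_metrics(traj, env, params)
  else
    list(landmark_visits = NA_real_, landmark_revisits = NA_real_,
         landmark_efficiency = NA_real_)
  data.frame(
    subject_id = traj$subject_id,
    path_length = path_length(traj),
    pausing = pausing(traj, params),
    area_covered = area_covered(bins),
    roaming_entropy = roaming_entropy(bins, k),
    min_convex_polygon = min_convex_polygon(traj),
    fractal_dimension = fractal_dimension(traj, params),
    sinuosity = sinuosity(traj, params),
    landmark_visits = lmk$landmark_visits,
    landmark_revisits = lmk$landmark_revisits,
    revisiting = revisiting(traj, params),
    turnarounds = turnarounds(traj, params),
    flight_turnarounds = flight_turnarounds(traj, params),
    area_efficiency = area_efficiency(bins),
    landmark_efficiency = lmk$landmark_efficiency,
    stringsAsFactors = FALSE)
}

#' Compute the measure table for a cohort
#'
#' Applies [compute_measures()] to every trajectory.  When
#' `params$rediscretize_step` is `NULL`, the pooled median nonzero step
#' length across the cohort is used (the paper-style convention); when
#' `env$k_norm` is `NULL`, the number of unique bins explored by the whole
#' cohort is used as the entropy normalization constant.
#'
#' @param trajs List of preprocessed [trajectory()] objects.
#' @param env An [env_spec()].
#' @param params A [measure_params()].
#' @return A data.frame with one row per subject.
#' @export
cohort_measures <- function(trajs, env, params = measure_params()) {
  if (is.null(params$rediscretize_step)) {
    pooled <- unlist(lapply(trajs, function(tr) {
      s <- step_lengths(tr); s[s > 0]
    }))
    params$rediscretize_step <- stats::median(pooled)
  }
  if (is.null(env$k_norm)) {
    ids <- unlist(lapply(trajs, function(tr) unique(bin_sequence(tr, env)$id)))
    env$k_norm <- length(unique(ids))
  }
  do.call(rbind, lapply(trajs, compute_measures, env = env, params = params))
}
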