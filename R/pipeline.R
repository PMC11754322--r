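# resolve a list of trajectories from either a directory of CSVs or a list
resolve_trajectories <- function(input, column_map = c(x = "x", y = "y", t = "t"),
                                 sample_rate_hz = NULL) {
  if (is.character(input)) {
    files <- sort(list.files(input, pattern = "\\.(csv|tsv)$", full.names = TRUE))
    # keep only files that actually carry the mapped coordinate columns
    # (directories may hold sidecar tables such as traits or QC reports)
    has_xy <- vapply(files, function(f) {
      hdr <- names(utils::read.csv(f, nrows = 1))
      all(column_map[c("x", "y")] %in% hdr)
    }, logical(1))
    files <- files[has_xy]
    if (!length(files)) stop(sprintf("no trajectory files in %s", input))
    lapply(files, function(f) {
      hdr <- names(utils::read.csv(f, nrows = 1))
      cm <- column_map[names(column_map) %in% c("x", "y") |
                         column_map %in% hdr]
      read_trajectory(f, column_map = cm, sample_rate_hz = sample_rate_hz)
    })
  } else {
    stopifnot(all(vapply(input, inherits, logical(1), "trajectory")))
    input
  }
}

#' Run the quality-control screen over a cohort
#'
#' Applies [qc_screen()] per subject and [cohort_screen()] across subjects,
#' and summarizes the exclusion counts per reason.  Exclusion is advisory:
#' the report flags subjects, the caller decides what to drop.
#'
#' @param input Directory of trajectory CSVs or a list of [trajectory()]s.
#' @param qc A [qc_params()].
#' @param total_time Optional fixed session length (seconds) for rate
#'   inference.
#' @param out Optional CSV path for the report.
#' @return The QC report data.frame, with a `summary` attribute (exclusion
#'   counts per reason).
#' @export
run_qc <- function(input, qc = qc_params(), total_time = NULL, out = NULL) {
  trajs <- resolve_trajectories(input)
  reports <- do.call(rbind, lapply(trajs, qc_screen, total_time = total_time,
                                   qc = qc))
  if (nrow(reports) >= 4) reports <- cohort_screen(reports, qc)
  codes <- unlist(strsplit(reports$reasons[reports$excluded], ";"))
  attr(reports, "summary") <- if (length(codes)) table(codes) else table(character(0))
  if (!is.null(out)) utils::write.csv(reports, out, row.names = FALSE)
  reports
}

#' Preprocess a cohort and compute the measure table
#'
#' Resamples every trajectory to `params$target_hz`, trims leading idle time,
#' and computes all measures ([cohort_measures()], which also fixes the
#' pooled rediscretization step and the cohort entropy constant when those
#' are left open).
#'
#' @param input Directory of trajectory CSVs or a list of [trajectory()]s.
#' @param env An [env_spec()].
#' @param params A [measure_params()].
#' @param out Optional CSV path written via [write_measure_table()].
#' @return The measure data.frame.
#' @export
run_measures <- function(input, env, params = measure_params(), out = NULL) {
  trajs <- resolve_trajectories(input)
  pre <- lapply(trajs, preprocess_trajectory, target_hz = params$target_hz)
  tab <- cohort_measures(pre, env, params)
  if (!is.null(out)) write_measure_table(tab, out)
  tab
}

#' Cluster the exploration measures of a cohort
#'
#' The full variable-clustering stage: drop excluded measures (by default the
#' step-scale turnarounds, whose meaning the flight-scale variant replaces),
#' drop subjects with any missing value (count reported), flip the sign of
#' the inverted measures for readable loadings, standardize, cluster with
#' [varclust()], pick `k` (the kneedle suggestion unless given), and cut.
#'
#' @param measures Measure data.frame or CSV path from [run_measures()].
#' @param invert Measures negated for display/loadings (sign does not affect
#'   the tree).
#' @param exclude Measures left out of the clustering entirely.
#' @param k Number of clusters; `NULL` uses the kneedle suggestion.
#' @param sensitivity Kneedle sensitivity.
#' @param out_dir Optional directory; writes `similarity.csv`, `merges.json`,
#'   `heights.csv` and `loadings.csv`.
#' @return List with `tree` ([varclust()]), `solution` ([varclust_cut()]),
#'   `suggested_k`, `k`, `similarity`, `n_dropped` (incomplete subjects).
#' @export
run_cluster <- function(measures,
                        invert = c("pausing", "revisiting",
                                   "landmark_revisits", "flight_turnarounds"),
                        exclude = "turnarounds",
                        k = NULL, sensitivity = 1, out_dir = NULL) {
  if (is.character(measures)) measures <- read_measure_table(measures)
  m <- measures[, setdiff(names(measures), c("subject_id", exclude)),
                drop = FALSE]
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0)
    message(sprintf("dropping %d subject(s) with missing measure values",
                    n_dropped))
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3) stop("fewer than 3 complete subjects")
  m <- orient_measures(m, intersect(invert, names(m)))
  tree <- varclust(m)
  suggested <- suggest_k(tree, sensitivity = sensitivity)
  if (is.null(k)) {
    if (is.na(suggested))
      stop("no knee detected in the aggregation heights: supply k explicitly")
    k <- suggested
  }
  solution <- varclust_cut(tree, k)
  sim <- similarity_matrix(m)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(sim),
                     file.path(out_dir, "similarity.csv"))
    write_merges_json(tree, file.path(out_dir, "merges.json"))
    utils::write.csv(aggregation_heights(tree),
                     file.path(out_dir, "heights.csv"), row.names = FALSE)
    utils::write.csv(loadings_table(solution),
                     file.path(out_dir, "loadings.csv"), row.names = FALSE)
  }
  list(tree = tree, solution = solution, suggested_k = suggested, k = k,
       similarity = sim, n_dropped = n_dropped)
}

#' Simulate a cohort and write it to disk
#'
#' Writes one trajectory CSV per agent (`t,x,y` columns), the environment
#' config as YAML, and the ground-truth trait table.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The [simulate_cohort()] result, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  for (tr in cohort$trajectories) {
    n <- nrow(tr$xy)
    utils::write.csv(
      data.frame(t = (seq_len(n) - 1) / config$hz,
                 x = tr$xy[, 1], y = tr$xy[, 2]),
      file.path(out_dir, paste0(tr$subject_id, ".csv")), row.names = FALSE)
  }
  env <- config$env
  lm_list <- if (is.null(env$landmarks)) NULL else
    lapply(seq_len(nrow(env$landmarks)), function(i)
      list(id = env$landmarks$id[i], x = env$landmarks$x[i],
           y = env$landmarks$y[i]))
  yaml::write_yaml(list(name = env$name, bounds = as.list(env$bounds),
                        bin_size = env$bin_size, k_norm = env$k_norm,
                        landmarks = lm_list),
                   file.path(out_dir, "environment.yaml"))
  utils::write.csv(cohort$traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)
  invisible(cohort)
}
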