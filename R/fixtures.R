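# sample a polyline at roughly `by` vm per step (exact vertices kept per leg)
sample_polyline <- function(waypoints, by = 0.5) {
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(nrow(waypoints) - 1)) {
    a <- waypoints[i, ]; b <- waypoints[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    m <- max(1, ceiling(len / by))
    t <- seq(0, 1, length.out = m + 1)
    if (i > 1) t <- t[-1]
    xs <- c(xs, a[1] + t * (b[1] - a[1]))
    ys <- c(ys, a[2] + t * (b[2] - a[2]))
  }
  cbind(xs, ys)
}

#' Deterministic fixture trajectories
#'
#' A small library of analytically understood paths used throughout the test
#' suite and useful for sanity-checking parameter settings:
#' `straight_line` (100 vm, unit steps), `unit_square_loop` (the four corners
#' of the unit square), `comb_5_teeth` (a corridor walk entering five dead
#' ends, with deterministic sub-epsilon jitter of amplitude 1 vm riding on
#' every sample — the flight-scale path has exactly five reversals),
#' `circle` (radius 50 vm), `out_and_back` (a 60 vm corridor walked both
#' ways: one reversal), and `dense_random_walk` (a seeded confined correlated
#' random walk).
#'
#' @param seed Seed for the random-walk fixture.
#' @return Named list of [trajectory()] objects, all declared at 10 Hz.
#' @export
fixture_trajectories <- function(seed = 1) {
  tenhz <- function(xy, id)
    trajectory(xy[, 1], xy[, 2], subject_id = id, sample_rate_hz = 10)

  straight <- cbind(seq(0, 100, by = 1), 0)

  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))

  # comb: walk right along a baseline, turning into five long dead-end
  # corridors; the down-leg is offset 0.8 vm so the reversal angle is ~179
  tooth_x <- c(10, 30, 50, 70, 90)
  wp <- matrix(c(0, 0), 1, 2)
  for (tx in tooth_x) {
    wp <- rbind(wp, c(tx, 0), c(tx, 40), c(tx + 0.8, 0))
  }
  wp <- rbind(wp, c(100, 0))
  comb <- sample_polyline(wp, by = 0.5)
  i <- seq_len(nrow(comb))
  comb_jit <- comb + cbind(1.0 * cos(1.3 * i), 1.0 * sin(0.9 * i))

  th <- seq(0, 2 * pi, length.out = 721)
  circle <- cbind(50 * cos(th), 50 * sin(th))

  oab <- rbind(sample_polyline(rbind(c(0, 0), c(60, 0)), by = 0.5),
               sample_polyline(rbind(c(60, 0), c(0, 0)), by = 0.5)[-1, ])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- 2000
  h <- cumsum(stats::rnorm(n, 0, 0.6))
  walk <- cbind(cumsum(c(0, 0.5 * cos(h))), cumsum(c(0, 0.5 * sin(h))))

  list(straight_line = tenhz(straight, "straight_line"),
       unit_square_loop = tenhz(square, "unit_square_loop"),
       comb_5_teeth = tenhz(comb_jit, "comb_5_teeth"),
       comb_5_teeth_clean = tenhz(comb, "comb_5_teeth_clean"),
       circle = tenhz(circle, "circle"),
       out_and_back = tenhz(oab, "out_and_back"),
       dense_random_walk = tenhz(walk, "dense_random_walk"))
}
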