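test_that("sampling-rate inference divides points by play time", {
  expect_equal(infer_sampling_rate(3000, 150), 20)
  expect_equal(infer_sampling_rate(1500, 150), 10)
  expect_error(infer_sampling_rate(100, 0), "positive")
})

test_that("step lengths and turning angles match direct geometry", {
  tr <- trajectory(c(0, 3, 3), c(0, 4, 4))
  expect_equal(step_lengths(tr), c(5, 0))
  xy <- random_polyline(100, seed = 4)
  tr <- trajectory(xy[, 1], xy[, 2])
  brute <- vapply(2:100, function(i) sqrt(sum((xy[i, ] - xy[i - 1, ])^2)),
                  numeric(1))
  expect_equal(step_lengths(tr), brute)

  straight <- trajectory(0:5, rep(0, 6))
  expect_equal(turning_angles(straight), rep(0, 4))
  corner <- trajectory(c(0, 1, 1), c(0, 0, 1))
  expect_equal(turning_angles(corner), 90)
  oab <- trajectory(c(0, 1, 0), c(0, 0, 0))
  expect_equal(turning_angles(oab), 180)
  pausey <- trajectory(c(0, 1, 1, 2), c(0, 0, 0, 0))
  expect_equal(turning_angles(pausey, skip_zero_steps = TRUE), 0)
  expect_length(turning_angles(trajectory(c(0, 0, 0), c(0, 0, 0))), 0)
})

test_that("qc screen computes CoV, lag fraction and movement time", {
  # constant nonzero steps: no variability
  tr <- trajectory(0:100, rep(0, 101), sample_rate_hz = 10)
  rep1 <- qc_screen(tr)
  expect_equal(rep1$cov_step_length, 0)
  expect_equal(rep1$lag_fraction, 0)
  expect_equal(rep1$movement_seconds, 10)
  expect_true(rep1$excluded)                 # 10 s < 30 s of movement
  expect_match(rep1$reasons, "low_movement")

  # exactly one of 1000 steps is 4x the median
  x <- cumsum(c(0, rep(1, 999), 4))
  tr <- trajectory(x, rep(0, length(x)), sample_rate_hz = 10)
  expect_equal(qc_screen(tr)$lag_fraction, 0.001)

  # 250 nonzero steps at 10 Hz -> 25 s of movement -> excluded
  x <- cumsum(c(0, rep(1, 250), rep(0, 100)))
  tr <- trajectory(x, rep(0, length(x)), sample_rate_hz = 10)
  r <- qc_screen(tr)
  expect_equal(r$movement_seconds, 25)
  expect_true(r$excluded)

  # all idle
  tr <- trajectory(rep(1, 50), rep(2, 50), sample_rate_hz = 10)
  r <- qc_screen(tr)
  expect_equal(r$movement_seconds, 0)
  expect_identical(r$reasons, "no_movement")

  # lag fraction equals a brute-force count on random steps
  set.seed(7)
  xy <- random_polyline(400, seed = 7)
  tr <- trajectory(xy[, 1], xy[, 2], sample_rate_hz = 10)
  s <- step_lengths(tr)
  expect_equal(qc_screen(tr)$lag_fraction,
               sum(s > 3 * median(s[s > 0])) / length(s))
})

test_that("cohort screen flags only extreme CoV outliers", {
  base <- trajectory(0:400, rep(0, 401), sample_rate_hz = 10)
  reports <- do.call(rbind, lapply(1:50, function(i) {
    r <- qc_screen(base); r$subject_id <- paste0("s", i); r
  }))
  reports$cov_step_length <- rep(0.05, 50)
  expect_false(any(cohort_screen(reports)$excluded))  # identical CoVs: no flags
  reports$cov_step_length[17] <- 0.5
  flagged <- cohort_screen(reports)
  expect_identical(which(grepl("cov_outlier", flagged$reasons)), 17L)
  expect_warning(cohort_screen(reports[1:3, ]), "fewer than 4")
})

test_that("initial idle trimming keeps the last idle sample", {
  x <- c(rep(0, 50), 1:10)
  tr <- trajectory(x, rep(0, 60), sample_rate_hz = 10)
  out <- trim_initial_idle(tr)
  expect_equal(nrow(out$xy), 11)            # 1 idle anchor + 10 moving
  expect_equal(unname(out$xy[1, 1]), 0)
  expect_equal(step_lengths(out)[1], 1)
  moving <- trajectory(0:5, rep(0, 6))
  expect_identical(trim_initial_idle(moving)$xy, moving$xy)
  expect_error(trim_initial_idle(trajectory(rep(1, 5), rep(1, 5))),
               "no movement")
})

test_that("temporal resampling is exact for constant velocity and matches
           an independent interpolation oracle", {
  tr <- trajectory(c(0, 10), c(0, 20), times = c(0, 1))
  out <- resample_temporal(tr, 10)
  expect_equal(nrow(out$xy), 11)
  expect_equal(out$xy[, 2], 2 * out$xy[, 1])        # on the segment
  expect_equal(unname(out$xy[, 1]), seq(0, 10, 1))

  # aligned identity
  tr <- trajectory(0:9, (0:9)^2, times = (0:9) / 10)
  out <- resample_temporal(tr, 10)
  expect_equal(out$xy, tr$xy, tolerance = 1e-12)

  # 20 Hz sawtooth to 10 Hz vs brute-force bracketed interpolation
  t20 <- (0:40) / 20
  saw <- trajectory(t20 * 3, rep(c(0, 1), length.out = 41), times = t20)
  out <- resample_temporal(saw, 10)
  brute <- function(tq, tv, v) {
    i <- max(which(tv <= tq + 1e-12))
    if (i == length(tv)) return(v[i])
    v[i] + (v[i + 1] - v[i]) * (tq - tv[i]) / (tv[i + 1] - tv[i])
  }
  for (k in seq_along(out$times)) {
    expect_equal(unname(out$xy[k, 1]), brute(out$times[k], t20, saw$xy[, 1]),
                 tolerance = 1e-10)
    expect_equal(unname(out$xy[k, 2]), brute(out$times[k], t20, saw$xy[, 2]),
                 tolerance = 1e-10)
  }
  expect_error(resample_temporal(trajectory(0:3, 0:3), 10), "unknown timing")
})

test_that("rediscretization emits exactly constant steps and follows the path", {
  tr <- trajectory(c(0, 10), c(0, 0))
  out <- rediscretize_spatial(tr, 1)
  expect_equal(nrow(out$xy), 11)
  expect_equal(step_lengths(out), rep(1, 10), tolerance = 1e-9)

  # L-shaped path against the arc-length root-finding oracle
  lshape <- trajectory(c(0, 5, 5), c(0, 0, 5))
  out <- rediscretize_spatial(lshape, 0.7)
  ref <- oracle_rediscretize(lshape$xy, 0.7)
  expect_equal(nrow(out$xy), nrow(ref))
  expect_lt(max(abs(out$xy - ref)), 1e-6)

  # random walks: constant steps, endpoints near the originals
  for (seed in 1:5) {
    xy <- random_polyline(60, seed = seed)
    tr <- trajectory(xy[, 1], xy[, 2])
    step <- 0.8
    out <- rediscretize_spatial(tr, step)
    expect_lt(max(abs(step_lengths(out) - step)), 1e-9)
    expect_equal(out$xy[1, ], tr$xy[1, ])
    ref <- oracle_rediscretize(xy, step)
    expect_equal(nrow(out$xy), nrow(ref))
    expect_lt(max(abs(out$xy - ref)), 1e-6)
  }
  expect_error(rediscretize_spatial(trajectory(c(0, 0.1), c(0, 0)), 1),
               "shorter than one step")
})

test_that("RDP simplification matches brute-force recursion and its bound", {
  flat <- trajectory(seq(0, 99), rep(0, 100))
  expect_equal(nrow(rdp_simplify(flat, 6)$xy), 2)

  zig_small <- trajectory(0:50, rep(c(0, 1), length.out = 51))
  expect_equal(nrow(rdp_simplify(zig_small, 6)$xy), 2)

  zig_big <- trajectory(0:50, rep(c(0, 10), length.out = 51))
  out <- rdp_simplify(zig_big, 6)
  expect_gt(nrow(out$xy), 2)       # super-epsilon apexes survive
  expect_equal(nrow(out$xy), sum(oracle_rdp_keep(zig_big$xy, 6)))

  perp <- function(p, a, b) {
    d <- b - a; len <- sqrt(sum(d^2))
    if (len == 0) sqrt(sum((p - a)^2))
    else abs(d[2] * (p[1] - a[1]) - d[1] * (p[2] - a[2])) / len
  }
  for (seed in 1:10) {
    xy <- random_polyline(80, seed = 100 + seed, scale = 3)
    eps <- runif(1, 0.5, 4)
    keep_ref <- oracle_rdp_keep(xy, eps)
    out <- rdp_simplify(trajectory(xy[, 1], xy[, 2]), eps)
    expect_identical(nrow(out$xy), sum(keep_ref))
    expect_equal(out$xy, unname(xy[keep_ref, ]), ignore_attr = TRUE)
    # every removed vertex lies within eps of the simplified polyline
    kept <- which(keep_ref)
    for (i in which(!keep_ref)) {
      lo <- max(kept[kept < i]); hi <- min(kept[kept > i])
      expect_lte(perp(xy[i, ], xy[lo, ], xy[hi, ]), eps + 1e-9)
    }
  }
})
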