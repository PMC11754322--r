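toy_env <- function(size = 100, bin = 10, k = NULL, landmarks = NULL)
  env_spec("toy", c(0, 0, size, size), bin, k_norm = k, landmarks = landmarks)

test_that("bin sequence assigns half-open cells and run-length entries", {
  env <- toy_env()
  inside <- trajectory(c(1, 2, 3), c(1, 2, 3), sample_rate_hz = 10)
  bs <- bin_sequence(inside, env)
  expect_equal(area_covered(bs), 1)
  expect_length(bs$entries, 1)

  # straight horizontal crossing of all 10 cells in a row
  x <- seq(0.5, 99.5, by = 0.5)
  cross <- trajectory(x, rep(5, length(x)), sample_rate_hz = 10)
  bs <- bin_sequence(cross, env)
  expect_equal(area_covered(bs), 10)
  expect_length(bs$entries, 10)

  # out-and-back over 3 cells: 3 distinct bins, 5 entries
  x <- c(seq(5, 25, 2.5), seq(22.5, 5, -2.5))
  oab <- trajectory(x, rep(5, length(x)), sample_rate_hz = 10)
  bs <- bin_sequence(oab, env)
  expect_equal(area_covered(bs), 3)
  expect_length(bs$entries, 5)
  expect_equal(area_efficiency(bs), 3 / 5)

  # random trajectory against the per-sample scan oracle
  xy <- 50 + random_polyline(300, seed = 12, scale = 4)
  tr <- trajectory(xy[, 1], xy[, 2], sample_rate_hz = 10)
  suppressWarnings({
    bs <- bin_sequence(tr, env)
    ref <- oracle_bins(tr$xy, env$bounds, env$bin_size)
  })
  expect_equal(bs$id, ref$id)
  expect_equal(bs$entries, ref$entries)
})

test_that("path length and pausing follow their definitions", {
  expect_equal(path_length(trajectory(c(0, 3), c(0, 4))), 5)
  square <- trajectory(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(path_length(square), 4)
  xy <- random_polyline(200, seed = 3)
  tr <- trajectory(xy[, 1], xy[, 2], sample_rate_hz = 10)
  expect_equal(path_length(tr), sum(step_lengths(tr)))

  x <- cumsum(c(0, rep(1, 50), rep(0, 30), rep(1, 20)))
  tr <- trajectory(x, rep(0, length(x)), sample_rate_hz = 10)
  expect_equal(pausing(tr), 3)
  expect_equal(pausing(trajectory(0:10, rep(0, 11), sample_rate_hz = 10)), 0)
})

test_that("roaming entropy hits its closed-form anchors", {
  env <- toy_env()
  one_bin <- trajectory(c(1, 2, 1, 2), c(1, 1, 2, 2), sample_rate_hz = 10)
  expect_equal(roaming_entropy(bin_sequence(one_bin, env), 100), 0)

  # equal occupancy of exactly k bins -> 1
  centers <- expand.grid(x = seq(5, 95, 10), y = seq(5, 95, 10))
  xy <- centers[rep(seq_len(100), each = 3), ]
  tr <- trajectory(xy$x, xy$y, sample_rate_hz = 10)
  expect_equal(roaming_entropy(bin_sequence(tr, env), 100), 1, tolerance = 1e-12)

  # two bins, 50/50, k = 100
  xy <- rbind(matrix(rep(c(5, 5), 10), ncol = 2, byrow = TRUE),
              matrix(rep(c(15, 5), 10), ncol = 2, byrow = TRUE))
  tr <- trajectory(xy[, 1], xy[, 2], sample_rate_hz = 10)
  expect_equal(roaming_entropy(bin_sequence(tr, env), 100), log(2) / log(100),
               tolerance = 1e-12)
  expect_error(roaming_entropy(bin_sequence(tr, env), 1), "at least 2")
})

test_that("minimum convex polygon equals the gift-wrapping oracle", {
  sq <- trajectory(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(min_convex_polygon(sq), 1)
  expect_equal(min_convex_polygon(trajectory(0:5, 0:5)), 0)
  for (seed in 1:20) {
    set.seed(seed)
    xy <- matrix(rnorm(400), ncol = 2)
    tr <- trajectory(xy[, 1], xy[, 2])
    expect_equal(min_convex_polygon(tr), oracle_hull_area(xy),
                 tolerance = 1e-9)
  }
})

test_that("fractal dimension is 1 for lines, >1 for confined walks,
           and isometry-invariant", {
  fx <- fixture_trajectories()
  expect_equal(fractal_dimension(fx$straight_line), 1, tolerance = 0.02)
  d <- fractal_dimension(fx$dense_random_walk)
  expect_gt(d, 1)
  expect_lte(d, 2)
  # rotation + translation
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- fx$dense_random_walk$xy %*% R + matrix(c(31, -17), 2001, 2, byrow = TRUE)
  rot <- trajectory(xy[, 1], xy[, 2], sample_rate_hz = 10)
  expect_equal(fractal_dimension(rot), d, tolerance = 1e-6)
})

test_that("sinuosity matches its formula and scales linearly in sigma", {
  fx <- fixture_trajectories()
  expect_equal(sinuosity(fx$straight_line, measure_params(rediscretize_step = 1)), 0)

  # constant-step path with signed turning angles (a, -a, 0): sd is exactly a
  build <- function(a, q) {
    h <- cumsum(c(0, a, -a, 0))
    xy <- rbind(c(0, 0), cbind(cumsum(q * cos(h)), cumsum(q * sin(h))))
    trajectory(xy[, 1], xy[, 2], sample_rate_hz = 10)
  }
  tr <- build(0.2, 0.5)
  expect_equal(sinuosity(tr, measure_params(rediscretize_step = 0.5)),
               1.18 * 0.2 / sqrt(0.5), tolerance = 1e-6)
  s1 <- sinuosity(build(0.1, 0.5), measure_params(rediscretize_step = 0.5))
  s2 <- sinuosity(build(0.2, 0.5), measure_params(rediscretize_step = 0.5))
  expect_equal(s2 / s1, 2, tolerance = 1e-4)
})

test_that("landmark metrics count entries with full-exit re-entry", {
  lms <- data.frame(id = c("A", "B", "C"), x = c(0, 100, 200), y = 0)
  env <- env_spec("lm", c(-50, -50, 250, 50), 10, k_norm = 100, landmarks = lms)
  p <- measure_params()  # radius 20

  # single pass by all three
  x <- seq(-40, 240, by = 2)
  tr <- trajectory(x, rep(0, length(x)), sample_rate_hz = 10)
  m <- landmark_metrics(tr, env, p)
  expect_equal(m$landmark_visits, 3)
  expect_equal(m$landmark_revisits, 0)
  expect_equal(m$landmark_efficiency, 1)

  # enter A, leave fully, re-enter A
  x <- c(seq(-45, 0, 5), seq(0, 30, 5), seq(30, 0, -5))
  tr <- trajectory(x, rep(0, length(x)), sample_rate_hz = 10)
  m <- landmark_metrics(tr, env, p)
  expect_equal(m$landmark_visits, 1)
  expect_equal(m$landmark_revisits, 1)
  expect_equal(m$landmark_efficiency, 0.5)

  # never near any landmark: efficiency undefined
  far <- trajectory(c(120, 130, 140), c(45, 45, 45), sample_rate_hz = 10)
  m <- landmark_metrics(far, env, p)
  expect_equal(m$landmark_visits, 0)
  expect_true(is.na(m$landmark_efficiency))

  # random fixture vs per-sample inside/outside scan
  set.seed(21)
  xy <- cbind(runif(500, -50, 250), runif(500, -50, 50))
  tr <- trajectory(xy[, 1], xy[, 2], sample_rate_hz = 10)
  m <- landmark_metrics(tr, env, p)
  brute_entries <- 0
  for (k in 1:3) {
    inside <- sqrt((xy[, 1] - lms$x[k])^2 + (xy[, 2] - lms$y[k])^2) <= 20
    brute_entries <- brute_entries + sum(inside & !c(FALSE, inside[-500]))
  }
  expect_equal(m$landmark_visits + m$landmark_revisits, brute_entries)
  expect_equal(nrow(m$visit_log), brute_entries)
})

test_that("revisiting counts mean returns to greedily placed discs", {
  p <- measure_params()  # revisit radius 14
  # monotone straight line: every place entered once
  line <- trajectory(seq(0, 300, 0.5), rep(0, 601), sample_rate_hz = 10)
  expect_equal(revisiting(line, p), 0)

  # out-and-back corridor: every interior place entered twice
  x <- c(seq(0, 300, 0.5), seq(299.5, 0, -0.5))
  oab <- trajectory(x, rep(0, length(x)), sample_rate_hz = 10)
  r <- revisiting(oab, p)
  expect_gt(r, 0.85)
  expect_lte(r, 1)
  # brute-force entry counting over the same greedy centers
  centers_x <- x[1]
  for (xx in x) if (all(abs(xx - centers_x) > 14)) centers_x <- c(centers_x, xx)
  brute <- vapply(centers_x, function(cx) {
    inside <- abs(x - cx) <= 14
    sum(inside & !c(FALSE, inside[-length(inside)])) - 1
  }, numeric(1))
  expect_equal(r, mean(brute))

  # k traversals of one loop: about k - 1 returns everywhere
  th <- seq(0, 6 * pi, length.out = 1201)  # 3 loops
  loop <- trajectory(60 * cos(th), 60 * sin(th), sample_rate_hz = 10)
  expect_equal(revisiting(loop, p), 2, tolerance = 0.35)
})

test_that("flight turnarounds detect dead-end reversals that the step-scale
           count misses", {
  fx <- fixture_trajectories()
  p <- measure_params()
  expect_identical(flight_turnarounds(fx$comb_5_teeth, p), 5L)
  expect_identical(flight_turnarounds(fx$comb_5_teeth_clean, p), 5L)
  expect_identical(flight_turnarounds(fx$circle, p), 0L)
  expect_identical(flight_turnarounds(fx$out_and_back, p), 1L)
  # a straight line with sub-epsilon zigzag simplifies to nothing
  zig <- trajectory(seq(0, 50, 0.5), rep(c(0, 1), length.out = 101),
                    sample_rate_hz = 10)
  expect_identical(flight_turnarounds(zig, p), 0L)

  # step-scale count: misses the comb reversals under jitter
  expect_false(turnarounds(fx$comb_5_teeth, p) == 5)
  # single clean out-and-back is exactly one step-scale reversal
  expect_identical(turnarounds(fx$out_and_back, p), 1L)
  expect_identical(turnarounds(fx$circle, p), 0L)
})

test_that("flight turnarounds are invariant to sub-epsilon jitter;
           step-scale turnarounds are not", {
  fx <- fixture_trajectories()
  p <- measure_params()
  clean <- fx$comb_5_teeth_clean
  i <- seq_len(nrow(clean$xy))
  jit <- trajectory(clean$xy[, 1] + 1.2 * sin(1.7 * i),
                    clean$xy[, 2] + 1.2 * cos(0.8 * i),
                    sample_rate_hz = 10)  # amplitude < epsilon / 4
  expect_identical(flight_turnarounds(jit, p), flight_turnarounds(clean, p))
  expect_false(turnarounds(jit, p) == turnarounds(clean, p))
})

test_that("compute_measures is deterministic and self-consistent", {
  env <- make_environment(n_landmarks = 9)
  fx <- fixture_trajectories()
  p <- measure_params(rediscretize_step = 0.5)
  suppressWarnings({  # the walk may wander outside the bounds (clamped)
    row1 <- compute_measures(fx$dense_random_walk, env, p)
    row2 <- compute_measures(fx$dense_random_walk, env, p)
  })
  expect_identical(row1, row2)
  bs <- suppressWarnings(bin_sequence(fx$dense_random_walk, env))
  expect_equal(row1$path_length, path_length(fx$dense_random_walk))
  expect_equal(row1$area_covered, area_covered(bs))
  expect_equal(row1$roaming_entropy, roaming_entropy(bs, env$k_norm))
  expect_equal(row1$sinuosity, sinuosity(fx$dense_random_walk, p))
  expect_equal(row1$revisiting, revisiting(fx$dense_random_walk, p))

  sl <- compute_measures(fx$straight_line, env, p)
  expect_equal(sl$path_length, 100)
  expect_equal(sl$pausing, 0)
  expect_equal(sl$sinuosity, 0)
  expect_equal(sl$fractal_dimension, 1, tolerance = 0.02)
  expect_equal(sl$turnarounds, 0)
  expect_equal(sl$area_efficiency, 1)
})
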