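test_that("physical scaling applies the calibration per axis", {
  cal <- calibration(0.48, dz = 0.5, dt = 60)
  traj <- data.frame(frame = 2, x = 10, y = 10, z = 4)
  p <- to_physical(traj, cal)
  expect_equal(p$time, 120)
  expect_equal(c(p$x, p$y, p$z), c(4.8, 4.8, 2.0))

  # identity calibration leaves pixel coordinates unchanged
  set.seed(21)
  tr <- rand_traj(8)
  pi <- to_physical(tr, unit_cal())
  expect_equal(cbind(pi$x, pi$y, pi$z), cbind(tr$x, tr$y, tr$z))

  # pairwise physical distances match the brute-force per-pair oracle
  d <- oracle_pair_dists(tr, cal)
  pm <- as.matrix(to_physical(tr, cal)[, c("x", "y", "z")])
  expect_equal(as.matrix(dist(pm)), d, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("life span counts recorded observations, including bridged gaps", {
  tr20 <- rand_traj(20)
  expect_identical(life_span(tr20), 20L)
  expect_identical(nrow(segment_metrics(tr20, unit_cal())), 19L)
  expect_identical(life_span(line_traj(2)), 2L)
  gapped <- data.frame(frame = c(0, 2, 3), x = 0:2, y = 0, z = 0)
  expect_identical(life_span(gapped), 3L)
})

test_that("trajectory length sums segment lengths and bounds the chord", {
  tr <- data.frame(frame = 0:1, x = c(0, 3), y = c(0, 4), z = 0)
  expect_equal(trajectory_length(tr, unit_cal()), 5)
  tr2 <- data.frame(frame = 0:2, x = c(0, 1, 1), y = c(0, 0, 1), z = 0)
  expect_equal(trajectory_length(tr2, unit_cal()), 2)

  set.seed(31)
  for (i in 1:25) {
    tr <- rand_traj(10)
    cal <- calibration(runif(1, 0.1, 2), runif(1, 0.1, 2),
                       runif(1, 0.1, 2), runif(1, 1, 100))
    len <- trajectory_length(tr, cal)
    expect_equal(len, oracle_path_length(tr, cal), tolerance = 1e-12)
    # triangle inequality against the straight-line chord
    chord <- oracle_pair_dists(tr, cal)[1, nrow(tr)]
    expect_gte(len, chord - 1e-12)
  }
})

test_that("bounding boxes are exact, order-invariant and handle degeneracy", {
  bb <- bounding_box(rbind(c(0, 0, 0), c(2, 3, 4)))
  expect_equal(bb$volume, 24)
  expect_equal(bb$dims, c(2, 3, 4))

  col <- bounding_box(cbind(c(0, 1, 2.5), 0, 0))
  expect_equal(col$dims, c(2.5, 0, 0))
  expect_equal(col$volume, 0)

  set.seed(41)
  for (i in 1:25) {
    pts <- matrix(rnorm(50 * 3), ncol = 3)
    bb <- bounding_box(pts)
    ob <- oracle_bbox(pts)
    expect_equal(bb$min_corner, ob$min, tolerance = 0)
    expect_equal(bb$max_corner, ob$max, tolerance = 0)
    expect_equal(bb$volume, ob$volume, tolerance = 1e-12)
    # translation equivariance and point-order invariance
    shift <- rnorm(3)
    bb2 <- bounding_box(sweep(pts[sample(nrow(pts)), ], 2, -shift))
    expect_equal(bb2$min_corner, bb$min_corner + shift, tolerance = 1e-12)
    expect_equal(bb2$volume, bb$volume, tolerance = 1e-9)
  }
})

test_that("segment durations use the frame gap, lowering gapped velocities", {
  cal <- calibration(1, dz = 1, dt = 60)
  tr <- data.frame(frame = 0:1, x = c(0, 3), y = c(0, 4), z = 0)
  sm <- segment_metrics(tr, cal)
  expect_equal(sm$length, 5)
  expect_equal(sm$velocity, 5 / 60)

  still <- stationary_traj(5)
  sms <- segment_metrics(still, cal)
  expect_identical(nrow(sms), 4L)
  expect_equal(sms$velocity, rep(0, 4))

  gap <- data.frame(frame = c(0, 2), x = c(0, 1), y = 0, z = 0)
  smg <- segment_metrics(gap, cal)
  expect_equal(smg$duration, 120)
  expect_equal(smg$velocity, 1 / 120, tolerance = 1e-12)
})

test_that("trajectory metrics match a two-pass oracle; constant speed has zero variance", {
  cal <- calibration(1, dz = 1, dt = 10)
  const <- line_traj(6, d = 2)
  m <- trajectory_metrics(const, cal)
  expect_equal(m$velocity_variance, 0)
  expect_equal(m$mean_velocity, 0.2)

  set.seed(51)
  for (i in 1:20) {
    tr <- rand_traj(sample(3:15, 1))
    m <- trajectory_metrics(tr, cal)
    v <- segment_metrics(tr, cal)$velocity
    mu <- 0; for (vi in v) mu <- mu + vi / length(v)
    s2 <- 0; for (vi in v) s2 <- s2 + (vi - mu)^2 / length(v)
    expect_equal(m$mean_velocity, mu, tolerance = 1e-12)
    expect_equal(m$velocity_variance, s2, tolerance = 1e-12)
    expect_identical(m$life_span - 1L, length(v))
  }
})

test_that("calibration rescaling scales lengths, volumes and velocities as dimensional analysis demands", {
  set.seed(61)
  tr <- rand_traj(12)
  cal <- calibration(0.48, dz = 0.5, dt = 60)
  k <- 2.5
  cal_k <- calibration(cal$dx * k, cal$dy * k, cal$dz * k, cal$dt)
  expect_equal(trajectory_length(tr, cal_k), k * trajectory_length(tr, cal),
               tolerance = 1e-12)
  expect_equal(trajectory_bbox(tr, cal_k)$volume,
               k^3 * trajectory_bbox(tr, cal)$volume, tolerance = 1e-9)
  cal_t <- calibration(cal$dx, cal$dy, cal$dz, cal$dt * k)
  expect_equal(segment_metrics(tr, cal_t)$velocity,
               segment_metrics(tr, cal)$velocity / k, tolerance = 1e-12)
})

test_that("population summaries honor the weighted-mean and variance formulas", {
  cal <- unit_cal()
  set.seed(71)
  trajs <- as_set(rand_traj(5), rand_traj(8), rand_traj(4))
  mt <- trajectory_metrics_table(trajs, cal)

  # equal weights reduce to the unweighted summary
  s_eq <- population_summary(mt, weights = rep(2, nrow(mt)))
  expect_equal(s_eq$weighted_mean, s_eq$mean, tolerance = 1e-12)
  expect_equal(s_eq$weighted_variance, s_eq$variance, tolerance = 1e-12)

  # weight (1, 0) selects the first value
  mt2 <- mt[1:2, ]
  s10 <- population_summary(mt2, weights = c(1, 0))
  expect_equal(s10$weighted_mean[s10$metric == "mean_velocity"],
               mt2$mean_velocity[1])

  # random weights match the brute-force formulas
  w <- runif(nrow(mt))
  s <- population_summary(mt, weights = w)
  expect_equal(s$weighted_mean[1], oracle_wmean(mt$mean_velocity, w),
               tolerance = 1e-12)
  expect_equal(s$weighted_variance[2], oracle_wvar(mt$bbox_volume, w),
               tolerance = 1e-12)
  expect_error(population_summary(mt, weights = rep(0, nrow(mt))),
               "all weights are zero")
})

test_that("percent histograms sum to 100 and never drop out-of-range values", {
  h <- percent_histogram(c(2, 2, 2), c(1, 3))
  expect_equal(h$percent[h$bin_low == 1], 100)

  h2 <- percent_histogram(c(0.5, 0.6, 0.7, 1.5), c(0, 1, 2))
  expect_equal(h2$percent[is.finite(h2$bin_low) & is.finite(h2$bin_high)],
               c(75, 25))

  set.seed(81)
  vals <- rnorm(200, sd = 3)
  edges <- c(-2, -1, 0, 1, 2)
  h3 <- percent_histogram(vals, edges)
  expect_equal(sum(h3$percent), 100, tolerance = 1e-9)
  # per-bin counts match an exhaustive membership check
  for (b in seq_len(length(edges) - 1L)) {
    inb <- 0
    for (v in vals) {
      upper_ok <- if (b == length(edges) - 1L) v <= edges[b + 1]
                  else v < edges[b + 1]
      if (v >= edges[b] && upper_ok) inb <- inb + 1
    }
    expect_identical(h3$count[h3$bin_low == edges[b] &
                              h3$bin_high == edges[b + 1]], as.integer(inb))
  }
  expect_identical(h3$count[1], sum(vals < -2))
  expect_identical(h3$count[nrow(h3)], sum(vals > 2))
})
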