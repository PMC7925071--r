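test_that("MSD curves follow the origin-anchored definition", {
  cal <- unit_cal()
  # stationary bead: MSD identically zero
  mc <- msd_curve(stationary_traj(8), cal)
  expect_equal(mc$msd, rep(0, 7))
  expect_identical(mc$m, 1:7)

  # straight line, unit step: closed form d^2 (m+1)(2m+1)/6
  ml <- msd_curve(line_traj(10, d = 1), cal)
  expect_equal(ml$msd, (ml$m + 1) * (2 * ml$m + 1) / 6, tolerance = 1e-12)
  expect_equal(ml$msd[1:3], c(1, 2.5, 14 / 3), tolerance = 1e-12)

  # MSD(1) is exactly the squared first step
  set.seed(91)
  for (i in 1:10) {
    tr <- rand_traj(6)
    cal2 <- calibration(runif(1, 0.2, 1), runif(1, 0.2, 1),
                        runif(1, 0.2, 1), 60)
    mc <- msd_curve(tr, cal2)
    expect_equal(mc$msd[1], oracle_pair_dists(tr, cal2)[1, 2]^2,
                 tolerance = 1e-12)
    # direct-summation oracle at every m
    for (m in mc$m) expect_equal(mc$msd[m], oracle_msd(tr, cal2, m),
                                 tolerance = 1e-12)
  }
})

test_that("MSD is invariant under global translation and rotation", {
  set.seed(101)
  tr <- rand_traj(9)
  cal <- unit_cal()
  base <- msd_curve(tr, cal)$msd
  # translation
  tr_t <- tr; tr_t$x <- tr$x + 5; tr_t$y <- tr$y - 3; tr_t$z <- tr$z + 1
  expect_equal(msd_curve(tr_t, cal)$msd, base, tolerance = 1e-12)
  # random rotation (isotropic calibration)
  qr_R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_R) < 0) qr_R[, 1] <- -qr_R[, 1]
  rot <- as.matrix(tr[, c("x", "y", "z")]) %*% qr_R
  tr_r <- data.frame(frame = tr$frame, x = rot[, 1], y = rot[, 2], z = rot[, 3])
  expect_equal(msd_curve(tr_r, cal)$msd, base, tolerance = 1e-9)
})

test_that("pooled polynomial fits equal the normal-equations solution", {
  # noiseless linear data: exact recovery, zero curvature
  m <- rep(1:6, 2)
  lin <- data.frame(trajectory = rep(1:2, each = 6), m = m, msd = 2 + 3 * m)
  f <- msd_fit(lin)
  expect_equal(unname(coef(f)), c(2, 3, 0), tolerance = 1e-9)

  quad <- data.frame(trajectory = 1, m = 1:8, msd = 1 + (1:8) + 0.5 * (1:8)^2)
  fq <- msd_fit(quad)
  expect_equal(unname(coef(fq)), c(1, 1, 0.5), tolerance = 1e-9)
  expect_lt(fq$rss, 1e-16)

  # noisy pooled curves against the independent normal-equations oracle
  set.seed(111)
  mm <- rep(1:12, 20)
  noisy <- data.frame(trajectory = rep(1:20, each = 12), m = mm,
                      msd = 0.3 + 0.8 * mm + 0.02 * mm^2 + rnorm(240, sd = 0.5))
  fn <- msd_fit(noisy)
  expect_equal(unname(coef(fn)), oracle_polyfit(noisy$m, noisy$msd, 2),
               tolerance = 1e-8)

  # rank error with fewer than 3 distinct m values
  flat <- data.frame(trajectory = 1, m = c(1, 1, 2, 2), msd = c(1, 1, 2, 2))
  expect_error(msd_fit(flat), "distinct m")
})

test_that("motion classification separates linear from ballistic MSD trends", {
  m <- rep(1:10, 3)
  lin <- data.frame(trajectory = rep(1:3, each = 10), m = m, msd = 0.1 + 2 * m)
  cl <- classify_motion(msd_fit(lin))
  expect_identical(cl$label, "diffusive")
  expect_lt(cl$curvature_ratio, 1e-9)

  # ballistic: straight-line closed form is quadratic in m
  ball <- msd_curve(line_traj(12, d = 1), unit_cal())
  ball$trajectory <- 1
  clb <- classify_motion(msd_fit(ball))
  expect_identical(clb$label, "non_diffusive")
  # closed form d^2(m+1)(2m+1)/6 = d^2(2m^2+3m+1)/6: a2/a1 = 2/3 exactly
  expect_equal(clb$curvature_ratio, (2 / 6) * max(ball$m) / (3 / 6),
               tolerance = 1e-6)

  # fully stationary population: degenerate fit labeled diffusive, r = 0
  still <- msd_curves(as_set(stationary_traj(6), stationary_traj(5)), unit_cal())
  cls <- classify_motion(msd_fit(still))
  expect_identical(cls$label, "diffusive")
  expect_equal(cls$curvature_ratio, 0)
})

test_that("diffusion estimation inverts the 3 D dt (m+1) closed form", {
  cal <- calibration(1, dz = 1, dt = 60)
  D <- 0.01
  m <- rep(1:15, 4)
  curves <- data.frame(trajectory = rep(1:4, each = 15), m = m,
                       msd = 3 * D * cal$dt * (m + 1))
  est <- estimate_diffusion(curves, cal)
  expect_equal(est$D, D, tolerance = 1e-9)
  expect_false(est$negative_slope)

  # negative slope is reported as-is with a warning flag
  neg <- data.frame(trajectory = 1, m = 1:5, msd = 5 - (1:5))
  expect_warning(en <- estimate_diffusion(neg, cal), "negative")
  expect_true(en$negative_slope)
  expect_lt(en$D, 0)
})

test_that("group summaries use the t-interval over per-trajectory means", {
  cal <- unit_cal()
  # identical curves: zero-width interval
  tr <- line_traj(6)
  curves <- msd_curves(as_set(tr, tr, tr), cal)
  g <- group_msd_summary(curves, "a")
  expect_equal(g$ci_low, g$ci_high, tolerance = 1e-12)
  expect_true(g$ci_defined)

  # hand-computed 3-value group: textbook t-interval arithmetic
  vals <- c(1, 2, 4)   # per-trajectory mean MSDs
  curves3 <- data.frame(trajectory = 1:3, m = 1, msd = vals)
  g3 <- group_msd_summary(curves3, "g")
  half <- qt(0.975, df = 2) * sd(vals) / sqrt(3)
  expect_equal(g3$mean_msd, mean(vals))
  expect_equal(g3$ci_high - g3$mean_msd, half, tolerance = 1e-12)

  # single-trajectory group: mean reported, interval flagged undefined
  g1 <- group_msd_summary(data.frame(trajectory = 1, m = 1:2, msd = c(1, 3)),
                          "solo")
  expect_false(g1$ci_defined)
  expect_equal(g1$mean_msd, 2)

  # higher-D group has higher mean MSD (simulation ordering)
  agree <- 0L
  for (rep in 1:10) {
    lo <- simulate_beads(scene_config(n_beads = 30, n_frames = 10, d0 = 0.002,
                                      nx = 64, ny = 64, nz = 20, n_blobs = 0,
                                      seed = 200 + rep),
                         make_density_field(scene_config(n_blobs = 0,
                                                         nx = 64, ny = 64,
                                                         nz = 20, seed = 1)))
    hi <- simulate_beads(scene_config(n_beads = 30, n_frames = 10, d0 = 0.02,
                                      nx = 64, ny = 64, nz = 20, n_blobs = 0,
                                      seed = 300 + rep),
                         make_density_field(scene_config(n_blobs = 0,
                                                         nx = 64, ny = 64,
                                                         nz = 20, seed = 1)))
    cal_s <- calibration(0.48, dz = 0.5, dt = 60)
    c_lo <- msd_curves(ground_truth_trajectories(lo), cal_s)
    c_hi <- msd_curves(ground_truth_trajectories(hi), cal_s)
    m_lo <- group_msd_summary(c_lo, "lo")$mean_msd
    m_hi <- group_msd_summary(c_hi, "hi")$mean_msd
    if (m_hi > m_lo) agree <- agree + 1L
  }
  expect_gte(agree, 10L * 0.95)
})
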