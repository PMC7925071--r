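test_that("box densities reproduce the exhaustive voxel-scan mean", {
  cal <- calibration(0.48, dz = 0.5, dt = 60)
  # uniform intensity: density c for any box
  ctx <- density_context(uniform_bacteria_stack(0.37, cal = cal))
  bb <- bounding_box(rbind(c(0.2, 0.4, 0.3), c(2.9, 3.1, 2.2)))
  expect_equal(box_density(ctx, bb, frames = 0:2)$mean_intensity, 0.37)

  # box covering exactly half the voxels at c, the rest 0
  vox <- array(0, c(1, 4, 4, 4))
  vox[1, , , 1:2] <- 0.8            # half the volume along x
  st <- calibrated_stack(vox, calibration(1, dz = 1, dt = 1), "bacteria")
  ctx2 <- density_context(st, pad = 0)
  full <- bounding_box(rbind(c(-0.5, -0.5, -0.5), c(3.5, 3.5, 3.5)))
  expect_equal(box_density(ctx2, full, frames = 0)$mean_intensity, 0.4)

  # random stacks and boxes against the brute-force oracle
  set.seed(121)
  for (i in 1:30) {
    d4 <- c(sample(2:3, 1), sample(3:6, 1), sample(3:6, 1), sample(3:6, 1))
    cal_r <- calibration(runif(1, 0.3, 1), runif(1, 0.3, 1),
                         runif(1, 0.3, 1), 60)
    st_r <- calibrated_stack(array(runif(prod(d4)), d4), cal_r, "bacteria")
    pad <- runif(1, 0, 0.6)
    ctx_r <- density_context(st_r, pad = pad)
    ext <- c(d4[4] * cal_r$dx, d4[3] * cal_r$dy, d4[2] * cal_r$dz)
    lo <- runif(3, -0.05, 0.7) * ext
    hi <- lo + runif(3, 0.1, 0.9) * ext
    frames <- sort(sample(0:(d4[1] - 1), sample(d4[1], 1)))
    got <- box_density(ctx_r, bounding_box(rbind(lo, hi)), frames)
    want <- oracle_box_density(st_r, pmin(lo, hi), pmax(lo, hi), frames, pad)
    expect_equal(got$mean_intensity, want, tolerance = 1e-12)
  }

  # box entirely outside the stack errors
  far <- bounding_box(rbind(c(100, 100, 100), c(101, 101, 101)))
  expect_error(box_density(ctx2, far, frames = 0), "outside")
})

test_that("segment densities pad degenerate boxes and straddle boundaries correctly", {
  cal <- calibration(1, dz = 1, dt = 1)
  # uniform region: any segment density equals the constant
  ctx <- density_context(uniform_bacteria_stack(0.55, n_frames = 4, nz = 8,
                                                ny = 8, nx = 8,
                                                cal = cal))
  tr <- data.frame(frame = 0:2, x = c(2, 3, 4), y = 3, z = 4)
  expect_equal(segment_density(ctx, tr, cal, 1)$mean_intensity, 0.55)

  # zero-displacement segment: density of the pad-sized box around the point
  vox <- array(0, c(2, 6, 6, 6)); vox[, 3, 3, 3] <- 0.9
  stp <- calibrated_stack(vox, cal, "bacteria")
  ctxp <- density_context(stp, pad = 0.5)
  still <- data.frame(frame = 0:1, x = 2, y = 2, z = 2)
  ds <- segment_density(ctxp, still, cal, 1)
  expect_equal(ds$n_voxels, 1L)                 # pad 0.5 um < 1 voxel
  expect_equal(ds$mean_intensity, 0.9)

  # segment straddling a sharp density boundary matches the brute-force mean
  vox2 <- array(0.1, c(2, 6, 6, 6)); vox2[, , , 4:6] <- 0.7
  st2 <- calibrated_stack(vox2, cal, "bacteria")
  ctx2 <- density_context(st2, pad = 0.5)
  seg <- data.frame(frame = 0:1, x = c(1.6, 4.4), y = c(1, 3), z = c(1, 2))
  got <- segment_density(ctx2, seg, cal, 1)$mean_intensity
  want <- oracle_box_density(st2, c(1.6, 1, 1), c(4.4, 3, 2), 0:1, 0.5)
  expect_equal(got, want, tolerance = 1e-12)

  # only the bacteria channel is accepted as a density source
  bead_st <- calibrated_stack(array(0.5, c(1, 2, 2, 2)), cal, "bead")
  expect_error(density_context(bead_st), "bacteria")
})

test_that("density weighting is the normalized product and reduces to identity when uniform", {
  # uniform density: weighted velocities equal raw velocities exactly
  v <- c(0.1, 0.3, 0.2)
  w_uniform <- weighted_segment_velocities(v, rep(0.4, 3))
  expect_identical(w_uniform$weighted_velocity, v)

  # rho = (2, 0), v = (1, 1): mean density 1, weighted (2, 0)
  w2 <- weighted_segment_velocities(c(1, 1), c(2, 0))
  expect_equal(w2$weighted_velocity, c(2, 0))

  # random inputs match the direct formula
  set.seed(131)
  for (i in 1:20) {
    vi <- runif(6); ri <- runif(6)
    wi <- weighted_segment_velocities(vi, ri)
    expect_equal(wi$weighted_velocity, vi * ri / mean(ri), tolerance = 1e-12)
  }

  # zero mean density: flagged undefined, raw pairs preserved
  w0 <- weighted_segment_velocities(c(1, 2), c(0, 0))
  expect_true(attr(w0, "undefined"))
  expect_true(all(is.na(w0$weighted_velocity)))
  expect_equal(w0$velocity, c(1, 2))
})

test_that("trajectory-scale weighted velocities report both statistics", {
  v <- c(0.2, 0.4, 0.6); r <- c(1, 2, 3)
  wsv <- weighted_segment_velocities(v, r)
  tw <- trajectory_weighted_velocity(wsv)
  expect_equal(tw$mean_weighted_velocity, mean(v * r / mean(r)),
               tolerance = 1e-12)
  expect_equal(tw$density_weighted_mean, sum(r * v) / sum(r),
               tolerance = 1e-12)
  # single segment: equals that segment's weighted value
  one <- weighted_segment_velocities(0.3, 0.7)
  expect_equal(trajectory_weighted_velocity(one)$mean_weighted_velocity, 0.3)
  # uniform density: both reduce to the unweighted mean
  wu <- weighted_segment_velocities(v, rep(5, 3))
  expect_equal(trajectory_weighted_velocity(wu)$mean_weighted_velocity,
               mean(v))
})

test_that("velocity-density regressions recover generating parameters", {
  set.seed(141)
  rho <- runif(40, 0, 2)
  # exact linear data
  fl <- regress_velocity_density(rho, 1 - 0.5 * rho)
  expect_equal(fl$linear$intercept, 1, tolerance = 1e-6)
  expect_equal(fl$linear$slope, -0.5, tolerance = 1e-6)
  expect_lt(fl$linear$rss, 1e-12)

  # exact exponential data
  fe <- regress_velocity_density(rho, 2 * exp(-rho))
  expect_equal(fe$exponential$A, 2, tolerance = 1e-3)
  expect_equal(fe$exponential$b, -1, tolerance = 1e-3)

  # all non-positive velocities: exponential skipped with a flag
  f0 <- regress_velocity_density(rho[1:10], rep(0, 10))
  expect_true(f0$exp_skipped)
  expect_null(f0$exponential)

  # degenerate collinear input: rank error
  expect_error(regress_velocity_density(rep(1, 5), runif(5)), "rank")
})

test_that("the two-scale density report tabulates every scale and model", {
  set.seed(151)
  rho <- runif(30); v <- 0.5 * exp(-rho) + rnorm(30, sd = 0.01)
  seg <- regress_velocity_density(rho, v)
  trj <- regress_velocity_density(rho[1:10], v[1:10])
  rep <- density_dependence_report(seg, trj)
  expect_identical(nrow(rep), 4L)   # 2 scales x 2 models
  expect_setequal(unique(rep$scale), c("segment", "trajectory"))
  expect_setequal(unique(rep$model), c("linear", "exponential"))
})
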