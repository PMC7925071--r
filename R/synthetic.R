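#' Synthetic 4D scene configuration
#'
#' Parameters of a ground-truth biofilm bead scene: Brownian beads
#' (optionally with density-dependent mobility) diffusing inside a
#' heterogeneous density field, imaged as a two-channel 4D stack. Defaults
#' emulate the bead-assay acquisition: 0.48 um pixels, 0.5 um z steps, 36 z
#' slices (~18 um of biofilm), 20 frames of 60 s, and 50 one-micrometre
#' beads (within the 40-140 working range); the lateral field is a
#' 128 x 128-pixel sub-region (~61 um) of a full 512 x 512 acquisition.
#'
#' @param n_beads number of beads.
#' @param d0 baseline diffusion coefficient, um^2/s.
#' @param k density-mobility coupling (>= 0): local diffusion is
#'   `D = d0 * exp(-k * rho)` with rho the normalized density in `[0, 1]`;
#'   `k = 0` gives homogeneous Brownian motion.
#' @param nx,ny,nz stack extents in pixels/slices.
#' @param n_frames number of frames.
#' @param dx,dy,dz,dt calibration (um, um, um, s).
#' @param bead_radius bead radius, um.
#' @param psf_xy,psf_z Gaussian PSF sigmas, um.
#' @param bead_intensity rendered peak intensity of a bead (on `[0, 1]`).
#' @param noise_sd Gaussian noise sigma on `[0, 1]` intensities (peak SNR =
#'   `bead_intensity / noise_sd`; default 50).
#' @param n_blobs number of Gaussian density blobs in the bacteria field.
#' @param background uniform background density level in `[0, 1]`.
#' @param bacteria_scale intensity scale of the rendered bacteria channel.
#' @param elongate_z if `TRUE`, fast-moving beads are rendered with a
#'   z-elongated PSF, mimicking the elliptical bead shapes produced when a
#'   bead moves during sequential z-slice capture.
#' @param seed integer; fixes the full scene (field, paths, noise).
#' @return An object of class `"scene_config"`.
#' @export
scene_config <- function(n_beads = 50, d0 = 0.005, k = 0,
                         nx = 128, ny = 128, nz = 36, n_frames = 20,
                         dx = 0.48, dy = 0.48, dz = 0.5, dt = 60,
                         bead_radius = 0.5, psf_xy = 0.35, psf_z = 0.6,
                         bead_intensity = 0.8, noise_sd = 0.016,
                         n_blobs = 6, background = 0.1,
                         bacteria_scale = 0.6, elongate_z = FALSE,
                         seed = 1L) {
  cfg <- list(n_beads = n_beads, d0 = d0, k = k, nx = nx, ny = ny, nz = nz,
              n_frames = n_frames, dx = dx, dy = dy, dz = dz, dt = dt,
              bead_radius = bead_radius, psf_xy = psf_xy, psf_z = psf_z,
              bead_intensity = bead_intensity, noise_sd = noise_sd,
              n_blobs = n_blobs, background = background,
              bacteria_scale = bacteria_scale, elongate_z = elongate_z,
              seed = as.integer(seed))
  phys <- c(n_beads, nx, ny, nz, n_frames, dx, dy, dz, dt, bead_radius,
            psf_xy, psf_z, bead_intensity)
  stopifnot(all(phys > 0), d0 >= 0, k >= 0, noise_sd >= 0, background >= 0)
  cfg$box <- c(nx * dx, ny * dy, nz * dz)   # um
  structure(cfg, class = "scene_config")
}

#' Calibration object of a scene configuration
#' @param cfg a [scene_config()].
#' @return the scene's [calibration()].
#' @export
scene_calibration <- function(cfg) calibration(cfg$dx, cfg$dy, cfg$dz, cfg$dt)

#' Seeded heterogeneous density field
#'
#' A normalized 3D field on the voxel grid emulating thicker and thinner
#' regions of a biofilm: a uniform background plus a sum of seeded random 3D
#' Gaussian blobs, rescaled so values lie in `[0, 1]` (with zero blobs the
#' field is the uniform background level).
#'
#' @param cfg a [scene_config()].
#' @return 3D array (z, y, x) with values in `[0, 1]`.
#' @export
make_density_field <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  xs <- (seq_len(cfg$nx) - 1) * cfg$dx
  ys <- (seq_len(cfg$ny) - 1) * cfg$dy
  zs <- (seq_len(cfg$nz) - 1) * cfg$dz
  field <- array(cfg$background, dim = c(cfg$nz, cfg$ny, cfg$nx))
  if (cfg$n_blobs >= 1) {
    for (b in seq_len(cfg$n_blobs)) {
      ctr <- stats::runif(3) * cfg$box            # (x, y, z) um
      sig <- stats::runif(3, min = 3, max = 9)    # blob scales, um
      amp <- stats::runif(1, 0.5, 1)
      gx <- exp(-(xs - ctr[1])^2 / (2 * sig[1]^2))
      gy <- exp(-(ys - ctr[2])^2 / (2 * sig[2]^2))
      gz <- exp(-(zs - ctr[3])^2 / (2 * sig[3]^2))
      blob <- amp * (gz %o% gy %o% gx)
      field <- field + blob
    }
  }
  mx <- max(field)
  if (mx > 1) field <- field / mx
  field
}

field_at <- function(field, cfg, pos_um) {
  # nearest-voxel-center lookup of the density at a physical position
  ix <- pmin(pmax(round(pos_um[1] / cfg$dx), 0), cfg$nx - 1) + 1
  iy <- pmin(pmax(round(pos_um[2] / cfg$dy), 0), cfg$ny - 1) + 1
  iz <- pmin(pmax(round(pos_um[3] / cfg$dz), 0), cfg$nz - 1) + 1
  field[iz, iy, ix]
}

reflect <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Simulate Brownian bead paths in a density field
#'
#' Each bead takes per-frame Gaussian steps with per-axis variance
#' `2 * D_local * dt`, where `D_local = d0 * exp(-k * rho)` is evaluated at
#' the bead's current voxel; `k = 0` gives homogeneous diffusion. Boundaries
#' are reflecting, so beads stay inside the imaged volume and the ground
#' truth remains fully observable (real beads can leave and re-enter focus;
#' this is a documented simplification).
#'
#' @param cfg a [scene_config()].
#' @param field a density field from [make_density_field()].
#' @return An object of class `"ground_truth"`: list with `paths` (per bead,
#'   data frame `frame, x, y, z` in um), `d_local` (beads x frames-1 matrix
#'   of local D used for each step), `field`, `cfg`.
#' @export
simulate_beads <- function(cfg, field) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed + 1L)
  margin <- cfg$bead_radius
  paths <- vector("list", cfg$n_beads)
  d_local <- matrix(NA_real_, cfg$n_beads, max(cfg$n_frames - 1L, 1L))
  for (b in seq_len(cfg$n_beads)) {
    pos <- matrix(NA_real_, cfg$n_frames, 3L)
    pos[1L, ] <- margin + stats::runif(3) * (cfg$box - 2 * margin)
    if (cfg$n_frames > 1L) for (f in 2:cfg$n_frames) {
      rho <- field_at(field, cfg, pos[f - 1L, ])
      D <- cfg$d0 * exp(-cfg$k * rho)
      d_local[b, f - 1L] <- D
      step <- stats::rnorm(3, sd = sqrt(2 * D * cfg$dt))
      pos[f, ] <- reflect(pos[f - 1L, ] + step, 0, cfg$box)
    }
    paths[[b]] <- data.frame(frame = 0:(cfg$n_frames - 1L),
                             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L])
  }
  structure(list(paths = paths, d_local = d_local, field = field, cfg = cfg),
            class = "ground_truth")
}

#' Ground-truth paths as a trajectory set in pixel units
#'
#' Converts the simulated micrometre paths to the 0-based pixel/slice units
#' of the trajectory interchange dialect (divide by the voxel dimensions), so
#' the ground truth can flow through the same analysis path as tracker
#' output.
#'
#' @param truth a `"ground_truth"`.
#' @return a `trajectory_set`.
#' @export
ground_truth_trajectories <- function(truth) {
  cfg <- truth$cfg
  tab <- do.call(rbind, lapply(seq_along(truth$paths), function(b) {
    p <- truth$paths[[b]]
    data.frame(trajectory = b, frame = p$frame,
               x = p$x / cfg$dx, y = p$y / cfg$dy, z = p$z / cfg$dz)
  }))
  trajectory_set(tab)
}

#' Render a ground-truth scene to two image channels
#'
#' Beads are rendered as anisotropic 3D Gaussian spots (PSF sigmas
#' `psf_xy`, `psf_z`); the bacteria channel is the density field scaled by
#' `bacteria_scale`. Both channels receive seeded Gaussian noise and are
#' clipped to `[0, 1]`. With `elongate_z` the PSF of a bead is stretched
#' axially in proportion to its displacement that frame, emulating the
#' elliptical bead images caused by movement during sequential z-slice
#' capture.
#'
#' @param truth a `"ground_truth"` from [simulate_beads()].
#' @return list with `bead` and `bacteria`, both `calibrated_stack`s.
#' @export
render_scene <- function(truth) {
  cfg <- truth$cfg
  set.seed(cfg$seed + 2L)
  cal <- scene_calibration(cfg)
  nf <- cfg$n_frames
  bead_vox <- array(0, dim = c(nf, cfg$nz, cfg$ny, cfg$nx))
  xs <- (seq_len(cfg$nx) - 1) * cfg$dx
  ys <- (seq_len(cfg$ny) - 1) * cfg$dy
  zs <- (seq_len(cfg$nz) - 1) * cfg$dz

  for (f in seq_len(nf)) {
    vol <- array(0, dim = c(cfg$nz, cfg$ny, cfg$nx))
    for (b in seq_along(truth$paths)) {
      p <- truth$paths[[b]][f, ]
      sz <- cfg$psf_z
      if (cfg$elongate_z && f > 1L) {
        prev <- truth$paths[[b]][f - 1L, ]
        disp <- sqrt((p$x - prev$x)^2 + (p$y - prev$y)^2 + (p$z - prev$z)^2)
        sz <- cfg$psf_z * (1 + disp / cfg$bead_radius)
      }
      sxy <- sqrt(cfg$psf_xy^2 + (cfg$bead_radius / 2)^2)
      szz <- sqrt(sz^2 + (cfg$bead_radius / 2)^2)
      xr <- which(abs(xs - p$x) <= 4 * sxy)
      yr <- which(abs(ys - p$y) <= 4 * sxy)
      zr <- which(abs(zs - p$z) <= 4 * szz)
      if (!length(xr) || !length(yr) || !length(zr)) next
      gx <- exp(-(xs[xr] - p$x)^2 / (2 * sxy^2))
      gy <- exp(-(ys[yr] - p$y)^2 / (2 * sxy^2))
      gz <- exp(-(zs[zr] - p$z)^2 / (2 * szz^2))
      vol[zr, yr, xr] <- vol[zr, yr, xr] + cfg$bead_intensity * (gz %o% gy %o% gx)
    }
    bead_vox[f, , , ] <- vol
  }
  if (cfg$noise_sd > 0) {
    bead_vox <- bead_vox +
      stats::rnorm(length(bead_vox), sd = cfg$noise_sd)
  }
  bead_vox <- pmin(pmax(bead_vox, 0), 1)

  bact_vox <- array(rep(truth$field * cfg$bacteria_scale, nf),
                    dim = c(cfg$nz, cfg$ny, cfg$nx, nf))
  bact_vox <- aperm(bact_vox, c(4L, 1L, 2L, 3L))
  if (cfg$noise_sd > 0) {
    bact_vox <- bact_vox + stats::rnorm(length(bact_vox), sd = cfg$noise_sd)
  }
  bact_vox <- pmin(pmax(bact_vox, 0), 1)

  list(bead = calibrated_stack(bead_vox, cal, "bead"),
       bacteria = calibrated_stack(bact_vox, cal, "bacteria"))
}

#' Noiseless bacteria-channel stack from a ground truth
#'
#' Builds the bacterial-channel `calibrated_stack` directly from the scene's
#' density field (scaled by `bacteria_scale`, replicated over frames, no
#' noise, no bead rendering). Useful for density analyses of ground-truth
#' paths where the imaging step is not under study.
#'
#' @param truth a `"ground_truth"`.
#' @return a `calibrated_stack` with `channel == "bacteria"`.
#' @export
density_stack <- function(truth) {
  cfg <- truth$cfg
  arr <- aperm(array(rep(truth$field * cfg$bacteria_scale, cfg$n_frames),
                     c(dim(truth$field), cfg$n_frames)), c(4L, 1L, 2L, 3L))
  calibrated_stack(arr, scene_calibration(cfg), "bacteria")
}

#' Simulate and render a full scene
#'
#' Convenience wrapper running [make_density_field()], [simulate_beads()] and
#' [render_scene()] in order under the configured seed.
#'
#' @param cfg a [scene_config()].
#' @param render if `FALSE`, skip rendering (ground truth only).
#' @return list with `truth` and (when rendered) `stacks`.
#' @export
simulate_scene <- function(cfg, render = TRUE) {
  field <- make_density_field(cfg)
  truth <- simulate_beads(cfg, field)
  out <- list(truth = truth)
  if (render) out$stacks <- render_scene(truth)
  out
}

#' Write a complete scene fixture to disk
#'
#' Emits the bead and bacteria TIFF stacks, the ground-truth trajectory CSV
#' in the plain interchange dialect (pixel units), and a YAML echo of the
#' scene configuration — everything needed to run the full toolchain on
#' synthetic data.
#'
#' @param truth a `"ground_truth"`.
#' @param stacks the [render_scene()] output.
#' @param out_dir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_scene <- function(truth, stacks, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create ", out_dir, call. = FALSE)
  paths <- c(bead = file.path(out_dir, "bead.tif"),
             bacteria = file.path(out_dir, "bacteria.tif"),
             truth = file.path(out_dir, "truth_trajectories.csv"),
             config = file.path(out_dir, "scene_config.yaml"))
  write_stack(stacks$bead, paths[["bead"]])
  write_stack(stacks$bacteria, paths[["bacteria"]])
  write_trajectories(ground_truth_trajectories(truth), paths[["truth"]])
  cfg <- truth$cfg
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), "box")], paths[["config"]])
  invisible(paths)
}
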