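#' Particle detection and linking configuration
#'
#' Defaults are pinned to the published tracker settings used for bead
#' movies: detection radius 3 pixels, non-particle discrimination cutoff
#' 0.003, percentile 0.12, link range 2 frames, maximum displacement 10
#' pixels, Brownian dynamics (squared-displacement link cost).
#'
#' @param radius particle radius in pixels (detection neighborhood).
#' @param cutoff non-particle discrimination score threshold.
#' @param percentile top intensity fraction retained as candidates, in (0, 1].
#' @param link_range maximum frame gap bridged when linking (>= 1).
#' @param max_displacement maximum link displacement in pixels.
#' @return An object of class `"linker_config"`.
#' @export
linker_config <- function(radius = 3, cutoff = 0.003, percentile = 0.12,
                          link_range = 2, max_displacement = 10) {
  stopifnot(radius > 0, cutoff > 0, percentile > 0, percentile <= 1,
            link_range >= 1, max_displacement > 0)
  structure(list(radius = radius, cutoff = cutoff, percentile = percentile,
                 link_range = as.integer(link_range),
                 max_displacement = max_displacement),
            class = "linker_config")
}

# --- separable 3D filters -------------------------------------------------
# Apply a 1D kernel along dimension `along` of a 3D array (z, y, x) with
# replicate padding, as a shift-and-add so every tap is one vectorized
# operation over the whole volume.
sep_filter_1d <- function(arr, kernel, along) {
  d <- dim(arr)
  perm <- c(along, setdiff(1:3, along))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- matrix(a, nrow = dp[1L])
  h <- (length(kernel) - 1L) %/% 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (s in -h:h) {
    rows <- pmin(pmax(seq_len(n) + s, 1L), n)   # replicate edges
    out <- out + kernel[s + h + 1L] * m[rows, , drop = FALSE]
  }
  aperm(array(out, dp), order(perm))
}

gaussian_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

gauss3 <- function(arr, sigma) {
  for (a in 1:3) arr <- sep_filter_1d(arr, gaussian_kernel(sigma), a)
  arr
}

boxmean3 <- function(arr, half_width) {
  k <- rep(1, 2L * half_width + 1L) / (2L * half_width + 1L)
  for (a in 1:3) arr <- sep_filter_1d(arr, k, a)
  arr
}

# Running maximum over a (2h+1) window along one dimension, via shifted pmax
# with replicate edges.
running_max_1d <- function(arr, h, along) {
  d <- dim(arr)
  perm <- c(along, setdiff(1:3, along))
  a <- aperm(arr, perm)
  dp <- dim(a)
  m <- matrix(a, nrow = dp[1L])
  out <- m
  n <- nrow(m)
  for (s in seq_len(h)) {
    up <- m[pmin(seq_len(n) + s, n), , drop = FALSE]
    down <- m[pmax(seq_len(n) - s, 1L), , drop = FALSE]
    out <- pmax(out, up, down)
  }
  aperm(array(out, dp), order(perm))
}

dilate3 <- function(arr, h) {
  for (a in 1:3) arr <- running_max_1d(arr, h, a)
  arr
}

#' Detect bright spots in one 3D frame volume
#'
#' A feature-point detector in the Crocker-Grier style: the volume is
#' intensity-normalized to `[0, 1]`, smoothed with a Gaussian at the noise
#' scale, background-subtracted with a boxcar mean at twice the particle
#' radius, and local maxima within the particle radius are taken as
#' candidates. Candidates are kept if their filtered intensity lies in the
#' top `percentile` of positive filtered voxels, then scored by integrated
#' normalized intensity (m0) over the radius neighborhood and rejected below
#' `cutoff` (non-particle discrimination). Surviving spots are refined to
#' sub-voxel positions by the intensity-weighted centroid over the radius
#' neighborhood. A flat volume yields an empty detection list.
#'
#' All distances are in pixel/slice index units (the anisotropic z axis is
#' handled in index units, with physical calibration applied downstream).
#'
#' @param volume 3D numeric array ordered (z, y, x).
#' @param cfg a [linker_config()].
#' @return data frame with 0-based sub-voxel positions `x, y, z`, and
#'   `score`; zero rows if nothing is detected.
#' @export
detect_particles <- function(volume, cfg = linker_config()) {
  stopifnot(length(dim(volume)) == 3L)
  r <- as.integer(ceiling(cfg$radius))
  rng <- range(volume)
  if (rng[2] - rng[1] <= 0) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      score = numeric(0)))
  }
  norm <- (volume - rng[1]) / (rng[2] - rng[1])
  sm <- gauss3(norm, sigma = 1)
  bg <- boxmean3(norm, half_width = 2L * r)
  filt <- pmax(sm - bg, 0)

  mx <- dilate3(filt, r)
  cand <- which(filt > 0 & filt >= mx, arr.ind = TRUE)  # (z, y, x) indices
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      score = numeric(0)))
  vals <- filt[cand]
  thr <- stats::quantile(filt[filt > 0], probs = 1 - cfg$percentile,
                         names = FALSE)
  keep <- vals >= thr
  cand <- cand[keep, , drop = FALSE]
  vals <- vals[keep]
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      score = numeric(0)))

  d <- dim(filt)
  nc <- nrow(cand)
  m0 <- numeric(nc)
  cx <- numeric(nc); cy <- numeric(nc); cz <- numeric(nc)
  for (i in seq_len(nc)) {
    zi <- cand[i, 1L]; yi <- cand[i, 2L]; xi <- cand[i, 3L]
    zr <- max(1L, zi - r):min(d[1L], zi + r)
    yr <- max(1L, yi - r):min(d[2L], yi + r)
    xr <- max(1L, xi - r):min(d[3L], xi + r)
    w <- filt[zr, yr, xr, drop = FALSE]
    msum <- sum(w)
    # mean (not sum) so spots whose neighborhood is clipped at the volume
    # boundary are not penalized in the discrimination score
    m0[i] <- msum / length(w)
    cz[i] <- sum((zr - 1L) * rowSums(matrix(w, length(zr)))) / msum
    cx[i] <- sum((xr - 1L) * rowSums(matrix(aperm(w, c(3L, 1L, 2L)),
                                            length(xr)))) / msum
    cy[i] <- sum((yr - 1L) * rowSums(matrix(aperm(w, c(2L, 1L, 3L)),
                                            length(yr)))) / msum
  }
  # non-particle discrimination: product of the normalized zeroth-order
  # moment and normalized peak intensity; genuine spots score O(1), noise
  # maxima orders of magnitude lower, so the cutoff separates them.
  score <- (m0 / max(m0)) * (vals / max(vals))
  ok <- score >= cfg$cutoff
  if (!any(ok))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      score = numeric(0)))
  det <- cbind(x = cx[ok], y = cy[ok], z = cz[ok])
  score <- score[ok]; peak <- vals[ok]

  # enforce minimal separation: of any pair closer than radius, keep brighter
  ord <- order(-peak)
  det <- det[ord, , drop = FALSE]
  score <- score[ord]
  keep_idx <- integer(0)
  for (i in seq_len(nrow(det))) {
    if (length(keep_idx)) {
      prev <- det[keep_idx, , drop = FALSE]
      dd2 <- (prev[, 1L] - det[i, 1L])^2 + (prev[, 2L] - det[i, 2L])^2 +
             (prev[, 3L] - det[i, 3L])^2
      if (any(dd2 < cfg$radius^2)) next
    }
    keep_idx <- c(keep_idx, i)
  }
  out <- data.frame(x = det[keep_idx, 1L], y = det[keep_idx, 2L],
                    z = det[keep_idx, 3L], score = score[keep_idx])
  rownames(out) <- NULL
  out
}

# --- optimal assignment ---------------------------------------------------
# Jonker-Volgenant / Hungarian shortest-augmenting-path solver for the
# square linear assignment problem; O(n^3). Returns, for each row, the
# assigned column index. Written here because no installed package provides
# weighted bipartite assignment; verified against brute-force enumeration in
# the test suite.
lap_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  BIG <- 1e300
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1)        # column potentials; index 1 = virtual column
  p <- integer(n + 1)        # p[j]: row assigned to column j-1 (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(BIG, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used)
      cur <- cost[i0, free - 1L] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        idx <- free[upd]
        minv[idx] <- cur[upd]
        way[idx] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) ans[p[j]] <- j - 1L
  ans
}

#' Link detections into trajectories (Brownian dynamics)
#'
#' Frame-by-frame globally optimal linking: for each frame, active track ends
#' (tracks whose last detection lies within `link_range` frames) compete for
#' the new detections under squared-displacement cost (the Brownian-motion
#' cost), solved exactly as a linear assignment problem with a rejection
#' cost of `max_displacement^2`, so candidate links longer than
#' `max_displacement` are excluded and a track end or detection may stay
#' unmatched. Unmatched detections open new tracks; gaps up to `link_range`
#' frames are bridged. Tracks with a single detection are discarded.
#'
#' @param detections data frame with columns `frame` (0-based), `x, y, z`
#'   (pixel units).
#' @param cfg a [linker_config()].
#' @return a `trajectory_set` (ids in order of track creation).
#' @export
link_particles <- function(detections, cfg = linker_config()) {
  stopifnot(all(c("frame", "x", "y", "z") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  if (length(frames) < 2L) stop("need detections in >= 2 frames", call. = FALSE)
  BIG <- 1e12
  d0 <- cfg$max_displacement^2   # rejection cost
  tracks <- list()               # each: list(pts = data.frame, last = frame)
  last_frame <- numeric(0)

  for (t in frames) {
    det <- detections[detections$frame == t, c("x", "y", "z"), drop = FALSE]
    nd <- nrow(det)
    cand <- which(last_frame >= t - cfg$link_range & last_frame < t)
    nt <- length(cand)
    assigned_det <- integer(0)

    if (nt > 0L && nd > 0L) {
      ends <- t(vapply(tracks[cand], function(tr)
        as.numeric(tr$pts[nrow(tr$pts), c("x", "y", "z")]), numeric(3)))
      C <- outer(ends[, 1], det$x, "-")^2 +
           outer(ends[, 2], det$y, "-")^2 +
           outer(ends[, 3], det$z, "-")^2
      C[C > d0] <- BIG
      n <- nt + nd
      M <- matrix(d0, n, n)
      M[seq_len(nt), seq_len(nd)] <- C
      M[(nt + 1):n, (nd + 1):n] <- 0
      a <- lap_solve(M)
      for (i in seq_len(nt)) {
        j <- a[i]
        if (j <= nd && M[i, j] < BIG && M[i, j] <= d0) {
          ti <- cand[i]
          tracks[[ti]]$pts <- rbind(tracks[[ti]]$pts,
                                    cbind(frame = t, det[j, , drop = FALSE]))
          last_frame[ti] <- t
          assigned_det <- c(assigned_det, j)
        }
      }
    }
    new_det <- setdiff(seq_len(nd), assigned_det)
    for (j in new_det) {
      tracks[[length(tracks) + 1L]] <-
        list(pts = cbind(frame = t, det[j, , drop = FALSE]))
      last_frame[length(tracks)] <- t
    }
  }

  keep <- vapply(tracks, function(tr) nrow(tr$pts) >= 2L, logical(1))
  tracks <- tracks[keep]
  if (length(tracks) == 0L) {
    return(structure(list(), class = "trajectory_set", n_dropped_single = sum(!keep)))
  }
  tab <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    d <- tracks[[i]]$pts
    rownames(d) <- NULL
    cbind(trajectory = i, d)
  }))
  structure(
    unclass(trajectory_set(tab)),
    class = "trajectory_set",
    n_dropped_single = sum(!keep))
}

#' Track a bead-channel stack end to end
#'
#' Runs [detect_particles()] on every frame volume and [link_particles()] on
#' the pooled detections, logging per-frame detection counts.
#'
#' @param stack a `calibrated_stack` (bead channel).
#' @param cfg a [linker_config()].
#' @param verbose print per-frame detection counts.
#' @return list with `trajectories` (a `trajectory_set`) and `detections`
#'   (the pooled detection table).
#' @export
track_stack <- function(stack, cfg = linker_config(), verbose = FALSE) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- dim(stack$voxels)
  det_list <- vector("list", d[1L])
  for (f in seq_len(d[1L])) {
    vol <- array(stack$voxels[f, , , ], dim = d[2:4])
    det <- detect_particles(vol, cfg)
    if (nrow(det)) det$frame <- f - 1L
    det_list[[f]] <- det
    if (verbose) message("frame ", f - 1L, ": ", nrow(det), " detections")
  }
  det_all <- do.call(rbind, det_list[vapply(det_list, nrow, integer(1)) > 0])
  if (is.null(det_all) || length(unique(det_all$frame)) < 2L) {
    return(list(trajectories = structure(list(), class = "trajectory_set",
                                         n_dropped_single = 0L),
                detections = det_all %||% data.frame()))
  }
  trajs <- link_particles(det_all, cfg)
  list(trajectories = trajs, detections = det_all)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
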