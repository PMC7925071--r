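# Independent brute-force oracles and tiny fixture builders. Everything here
# is deliberately written as plain loops / closed forms, separate from the
# package's vectorized implementations.

unit_cal <- function() calibration(1, 1, 1, 1)

rand_traj <- function(n, max_frame_gap = 1L, scale = 10) {
  gaps <- sample(seq_len(max_frame_gap), n - 1L, replace = TRUE)
  data.frame(frame = cumsum(c(0L, gaps)),
             x = stats::runif(n, 0, scale),
             y = stats::runif(n, 0, scale),
             z = stats::runif(n, 0, scale))
}

line_traj <- function(n, d = 1) {
  data.frame(frame = 0:(n - 1L), x = d * (0:(n - 1L)), y = 0, z = 0)
}

stationary_traj <- function(n, at = c(2, 3, 4)) {
  data.frame(frame = 0:(n - 1L), x = at[1], y = at[2], z = at[3])
}

as_set <- function(...) {
  trs <- list(...)
  tab <- do.call(rbind, lapply(seq_along(trs), function(i)
    cbind(trajectory = i, trs[[i]])))
  trajectory_set(tab)
}

# per-pair physical distances, one pair at a time
oracle_pair_dists <- function(traj, cal) {
  n <- nrow(traj)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dx <- (traj$x[i] - traj$x[j]) * cal$dx
    dy <- (traj$y[i] - traj$y[j]) * cal$dy
    dz <- (traj$z[i] - traj$z[j]) * cal$dz
    out[i, j] <- sqrt(dx^2 + dy^2 + dz^2)
  }
  out
}

oracle_path_length <- function(traj, cal) {
  d <- oracle_pair_dists(traj, cal)
  tot <- 0
  for (i in seq_len(nrow(traj) - 1L)) tot <- tot + d[i, i + 1L]
  tot
}

oracle_bbox <- function(points) {
  mn <- c(Inf, Inf, Inf); mx <- c(-Inf, -Inf, -Inf)
  for (i in seq_len(nrow(points))) for (a in 1:3) {
    if (points[i, a] < mn[a]) mn[a] <- points[i, a]
    if (points[i, a] > mx[a]) mx[a] <- points[i, a]
  }
  list(min = mn, max = mx, dims = mx - mn, volume = prod(mx - mn))
}

oracle_msd <- function(traj, cal, m) {
  p0 <- c(traj$x[1] * cal$dx, traj$y[1] * cal$dy, traj$z[1] * cal$dz)
  s <- 0
  for (i in seq_len(m)) {
    pi <- c(traj$x[i + 1] * cal$dx, traj$y[i + 1] * cal$dy,
            traj$z[i + 1] * cal$dz)
    s <- s + sum((pi - p0)^2)
  }
  s / m
}

oracle_wmean <- function(x, w) {
  num <- 0; den <- 0
  for (i in seq_along(x)) { num <- num + w[i] * x[i]; den <- den + w[i] }
  num / den
}

oracle_wvar <- function(x, w) {
  m <- oracle_wmean(x, w)
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * (x[i] - m)^2
    den <- den + w[i]
  }
  num / den
}

# normal-equations polynomial least squares
oracle_polyfit <- function(m, y, degree) {
  X <- outer(m, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# exhaustive voxel-scan density oracle, replicating the documented contract:
# inflate axes below pad, voxel centers in [lo, hi), clip to stack, nearest
# center fallback, average over frames.
oracle_box_density <- function(stack, box_min, box_max, frames, pad) {
  cal <- stack$calibration
  d4 <- dim(stack$voxels)
  lo <- box_min; hi <- box_max
  for (a in 1:3) if (hi[a] - lo[a] < pad) {
    mid <- (lo[a] + hi[a]) / 2
    lo[a] <- mid - pad / 2; hi[a] <- mid + pad / 2
  }
  steps <- c(cal$dx, cal$dy, cal$dz)
  ext <- c(d4[4], d4[3], d4[2])
  sel <- vector("list", 3)
  for (a in 1:3) {
    tol <- 1e-9 * max(1, abs(lo[a]), abs(hi[a]))
    js <- integer(0)
    for (j in seq_len(ext[a])) {
      ctr <- (j - 1) * steps[a]
      if (ctr >= lo[a] - tol && ctr < hi[a] - tol) js <- c(js, j)
    }
    if (length(js) == 0L) {
      j <- round((lo[a] + hi[a]) / 2 / steps[a]) + 1
      js <- min(max(j, 1), ext[a])
    }
    sel[[a]] <- js
  }
  tot <- 0; cnt <- 0
  for (f in frames + 1L) for (zi in sel[[3]]) for (yi in sel[[2]])
    for (xi in sel[[1]]) {
      tot <- tot + stack$voxels[f, zi, yi, xi]
      cnt <- cnt + 1
    }
  tot / cnt
}

# brute-force optimal assignment by permutation enumeration (n <= 7)
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v)) out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  pm <- perms(seq_len(n))
  costs <- apply(pm, 1, function(pr) sum(cost[cbind(seq_len(n), pr)]))
  min(costs)
}

# place a Gaussian spot in a (z, y, x) volume at 0-based position, index units
add_spot <- function(vol, x, y, z, sigma = 1.2, amp = 1) {
  d <- dim(vol)
  for (zi in seq_len(d[1])) for (yi in seq_len(d[2])) for (xi in seq_len(d[3])) {
    r2 <- (xi - 1 - x)^2 + (yi - 1 - y)^2 + (zi - 1 - z)^2
    vol[zi, yi, xi] <- vol[zi, yi, xi] + amp * exp(-r2 / (2 * sigma^2))
  }
  vol
}

uniform_bacteria_stack <- function(value, n_frames = 3, nz = 6, ny = 8, nx = 8,
                                   cal = calibration(0.48, dz = 0.5, dt = 60)) {
  calibrated_stack(array(value, c(n_frames, nz, ny, nx)), cal, "bacteria")
}
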