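#' Convert a trajectory to physical coordinates
#'
#' Positions are scaled per axis by the voxel dimensions and frames by the
#' frame interval: a point (frame f, pixel x, y, z) maps to time `f * dt`
#' seconds at `(x * dx, y * dy, z * dz)` micrometres.
#'
#' @param traj one trajectory: data frame with columns `frame, x, y, z`.
#' @param cal a [calibration()] object.
#' @return data frame with columns `time` (s) and `x, y, z` (um).
#' @export
to_physical <- function(traj, cal) {
  cal <- as_calibration(cal)
  data.frame(time = traj$frame * cal$dt,
             x = traj$x * cal$dx,
             y = traj$y * cal$dy,
             z = traj$z * cal$dz)
}

phys_matrix <- function(traj, cal) {
  p <- to_physical(traj, cal)
  cbind(x = p$x, y = p$y, z = p$z)
}

#' Trajectory life span
#'
#' The number of frames in which the trajectory was followed, counted as the
#' number of recorded observations. A track followed through 20 frames has
#' life span 20 and 19 segments. When the linker bridges a missing frame the
#' bridged frame is not counted, so life spans slightly under-count total
#' association time (broken tracks are never stitched).
#'
#' @param traj one trajectory (data frame with `frame, x, y, z`).
#' @return integer number of observations (>= 2 for any stored trajectory).
#' @export
life_span <- function(traj) nrow(traj)

#' Total trajectory path length
#'
#' Sum of Euclidean lengths of the consecutive 3D displacement segments, in
#' micrometres. Always at least the straight-line start-to-end distance.
#'
#' @inheritParams to_physical
#' @return length in um.
#' @export
trajectory_length <- function(traj, cal) {
  p <- phys_matrix(traj, cal)
  if (nrow(p) < 2L) stop("trajectory_length needs >= 2 points", call. = FALSE)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Axis-aligned minimal bounding box of a point set
#'
#' The minimal axis-aligned box containing the points, in micrometres. Its
#' volume summarizes the region a bead explored. Degenerate axes (all points
#' sharing a coordinate) are kept at zero extent — raw volumes run down to
#' 0 um^3; padding for use as an integration region is applied only in the
#' density machinery ([box_density()]).
#'
#' @param points numeric matrix (n x 3) of physical positions in um.
#' @return An object of class `"bounding_box"`: list with `min_corner`,
#'   `max_corner`, `dims` (um), `volume` (um^3).
#' @export
bounding_box <- function(points) {
  points <- rbind(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 1L)
  mn <- apply(points, 2L, min)
  mx <- apply(points, 2L, max)
  dims <- mx - mn
  structure(list(min_corner = unname(mn), max_corner = unname(mx),
                 dims = unname(dims), volume = prod(dims)),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("bounding box: %.3g x %.3g x %.3g um, volume %.4g um^3\n",
              x$dims[1], x$dims[2], x$dims[3], x$volume))
  invisible(x)
}

#' Bounding box of a trajectory
#' @inheritParams to_physical
#' @return A `"bounding_box"`.
#' @export
trajectory_bbox <- function(traj, cal) bounding_box(phys_matrix(traj, cal))

#' Per-segment metrics of a trajectory
#'
#' One record per consecutive observation pair. Duration is the frame gap
#' times the frame interval, so a segment bridging a linker gap (e.g. frames
#' 0 to 2) spans the full elapsed time and its velocity is lowered rather
#' than inflated.
#'
#' @inheritParams to_physical
#' @return data frame with columns `segment` (1-based index), `start_frame`,
#'   `end_frame`, `length` (um), `duration` (s), `velocity` (um/s).
#' @export
segment_metrics <- function(traj, cal) {
  cal <- as_calibration(cal)
  if (nrow(traj) < 2L) stop("segment_metrics needs >= 2 points", call. = FALSE)
  p <- phys_matrix(traj, cal)
  len <- sqrt(rowSums(diff(p)^2))
  dur <- diff(traj$frame) * cal$dt
  data.frame(segment = seq_along(len),
             start_frame = traj$frame[-nrow(traj)],
             end_frame = traj$frame[-1L],
             length = len, duration = dur, velocity = len / dur)
}

#' Per-trajectory summary metrics
#'
#' Life span, total path length, bounding box, and the mean and population
#' variance (divide-by-n) of the segment velocities. The population
#' convention is used because the segments are the complete set of observed
#' displacements, not a sample; a sample-variance mirror is a one-line change.
#'
#' @inheritParams to_physical
#' @return list with `life_span`, `trajectory_length`, `bbox`
#'   (a `"bounding_box"`), `mean_velocity`, `velocity_variance`.
#' @export
trajectory_metrics <- function(traj, cal) {
  seg <- segment_metrics(traj, cal)
  v <- seg$velocity
  list(life_span = life_span(traj),
       trajectory_length = sum(seg$length),
       bbox = trajectory_bbox(traj, cal),
       mean_velocity = mean(v),
       velocity_variance = mean((v - mean(v))^2))
}

#' Metrics table for a whole trajectory set
#'
#' @param trajs a `trajectory_set`.
#' @param cal a [calibration()] object.
#' @return data frame, one row per trajectory: `trajectory, life_span,
#'   trajectory_length, bbox_x, bbox_y, bbox_z, bbox_volume, mean_velocity,
#'   velocity_variance`.
#' @export
trajectory_metrics_table <- function(trajs, cal) {
  rows <- lapply(names(trajs), function(id) {
    m <- trajectory_metrics(trajs[[id]], cal)
    data.frame(trajectory = id, life_span = m$life_span,
               trajectory_length = m$trajectory_length,
               bbox_x = m$bbox$dims[1], bbox_y = m$bbox$dims[2],
               bbox_z = m$bbox$dims[3], bbox_volume = m$bbox$volume,
               mean_velocity = m$mean_velocity,
               velocity_variance = m$velocity_variance)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trajectory = character(0), life_span = integer(0),
               trajectory_length = numeric(0), bbox_x = numeric(0),
               bbox_y = numeric(0), bbox_z = numeric(0),
               bbox_volume = numeric(0), mean_velocity = numeric(0),
               velocity_variance = numeric(0))
  out$trajectory <- utils::type.convert(as.character(out$trajectory), as.is = TRUE)
  rownames(out) <- NULL
  out
}

#' Segment metrics table for a whole trajectory set
#' @inheritParams trajectory_metrics_table
#' @return data frame: `trajectory` plus the [segment_metrics()] columns.
#' @export
segment_metrics_table <- function(trajs, cal) {
  rows <- lapply(names(trajs), function(id)
    cbind(trajectory = id, segment_metrics(trajs[[id]], cal)))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trajectory = character(0), segment = integer(0),
               start_frame = numeric(0), end_frame = numeric(0),
               length = numeric(0), duration = numeric(0), velocity = numeric(0))
  out$trajectory <- utils::type.convert(as.character(out$trajectory), as.is = TRUE)
  rownames(out) <- NULL
  out
}

#' Weighted and unweighted population summaries
#'
#' Mean and population variance of per-trajectory mean velocity and bounding
#' box volume, optionally with density weights: weighted mean
#' \eqn{\sum w_i x_i / \sum w_i} and weighted variance
#' \eqn{\sum w_i (x_i - \bar x_w)^2 / \sum w_i}.
#'
#' @param metrics a [trajectory_metrics_table()] data frame.
#' @param weights optional non-negative per-trajectory weights (e.g. local
#'   cellular densities); must not be all zero.
#' @return data frame, one row per metric, with `mean`, `variance` and (when
#'   weights are given) `weighted_mean`, `weighted_variance`.
#' @export
population_summary <- function(metrics, weights = NULL) {
  stopifnot(nrow(metrics) >= 1L)
  vars <- c(mean_velocity = "mean_velocity", bbox_volume = "bbox_volume")
  out <- data.frame(metric = names(vars),
                    mean = NA_real_, variance = NA_real_)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(metrics), all(weights >= 0))
    if (sum(weights) == 0)
      stop("weighted mean undefined: all weights are zero", call. = FALSE)
    out$weighted_mean <- NA_real_
    out$weighted_variance <- NA_real_
  }
  for (i in seq_along(vars)) {
    x <- metrics[[vars[i]]]
    out$mean[i] <- mean(x)
    out$variance[i] <- mean((x - mean(x))^2)
    if (!is.null(weights)) {
      wm <- sum(weights * x) / sum(weights)
      out$weighted_mean[i] <- wm
      out$weighted_variance[i] <- sum(weights * (x - wm)^2) / sum(weights)
    }
  }
  out
}

#' Percent-of-total histogram
#'
#' Bins values into `[e_i, e_{i+1})` intervals (last bin closed above) and
#' reports each bin as a percentage of all values. Values outside the edges
#' are counted in explicit underflow/overflow rows — never dropped silently —
#' so the percentages always sum to 100.
#'
#' @param values numeric vector (non-empty).
#' @param bin_edges strictly increasing numeric vector of edges.
#' @return data frame with `bin_low, bin_high, count, percent`; the first and
#'   last rows are the `-Inf`/`Inf` under/overflow bins.
#' @export
percent_histogram <- function(values, bin_edges) {
  stopifnot(length(values) >= 1L, length(bin_edges) >= 2L,
            all(diff(bin_edges) > 0))
  k <- length(bin_edges) - 1L
  lows <- c(-Inf, bin_edges[-length(bin_edges)], bin_edges[length(bin_edges)])
  highs <- c(bin_edges[1L], bin_edges[-1L], Inf)
  counts <- integer(k + 2L)
  counts[1L] <- sum(values < bin_edges[1L])
  counts[k + 2L] <- sum(values > bin_edges[k + 1L])
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  inside <- idx >= 1L & idx <= k & values <= bin_edges[k + 1L]
  tabulated <- tabulate(idx[inside], nbins = k)
  counts[2:(k + 1L)] <- tabulated
  data.frame(bin_low = lows, bin_high = highs, count = counts,
             percent = 100 * counts / length(values))
}

#' Default histogram bin edges mirroring the figure axis ranges
#'
#' Life-span bins are 1 frame wide over 2..`max_frames`; bounding-box volume
#' bins are log-spaced over 1-6000 um^3 (the observed range in fluid
#' biofilms).
#'
#' @param what `"life_span"` or `"bbox_volume"`.
#' @param max_frames upper life-span edge (default 20 frames).
#' @return numeric vector of bin edges.
#' @export
default_bin_edges <- function(what = c("life_span", "bbox_volume"),
                              max_frames = 20) {
  what <- match.arg(what)
  switch(what,
         life_span = seq(1.5, max_frames + 0.5, by = 1),
         bbox_volume = 10^seq(0, log10(6000), length.out = 13))
}
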