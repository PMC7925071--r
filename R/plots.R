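#' Percent-of-total histogram bar plot
#'
#' Bar chart of a [percent_histogram()] table (percent of total trajectories
#' per bin); the under/overflow bins are drawn only when occupied.
#'
#' @param ph a [percent_histogram()] data frame.
#' @param xlab x-axis label.
#' @param ... passed to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot_percent_histogram <- function(ph, xlab = "value", ...) {
  keep <- is.finite(ph$bin_low) & is.finite(ph$bin_high) | ph$count > 0
  ph <- ph[keep, , drop = FALSE]
  labs <- sprintf("%.3g-%.3g", ph$bin_low, ph$bin_high)
  mids <- graphics::barplot(ph$percent, names.arg = labs, las = 2,
                            ylab = "% of total trajectories", xlab = xlab,
                            cex.names = 0.7, ...)
  invisible(mids)
}

# isometric projection used for the 3D trajectory plot
iso_project <- function(p) {
  ca <- cos(pi / 6); sa <- sin(pi / 6)
  cbind(u = (p[, 1] - p[, 2]) * ca, v = (p[, 1] + p[, 2]) * sa + p[, 3])
}

#' Draw a trajectory inside its bounding box
#'
#' Isometric 3D rendering of one trajectory path with its minimal bounding
#' box; the per-axis box extents (um) and the life span (frames) are
#' annotated, mirroring the trajectory-visualization figures.
#'
#' @param traj one trajectory (data frame with `frame, x, y, z`).
#' @param cal a [calibration()] object.
#' @param main plot title.
#' @return the trajectory's `"bounding_box"`, invisibly.
#' @export
plot_trajectory3d <- function(traj, cal, main = "trajectory") {
  p <- phys_matrix(traj, cal)
  bb <- bounding_box(p)
  corners <- as.matrix(expand.grid(bb$min_corner[1] + c(0, bb$dims[1]),
                                   bb$min_corner[2] + c(0, bb$dims[2]),
                                   bb$min_corner[3] + c(0, bb$dims[3])))
  pc <- iso_project(corners)
  pp <- iso_project(p)
  rng_u <- range(pc[, 1], pp[, 1]); rng_v <- range(pc[, 2], pp[, 2])
  plot(NA, xlim = rng_u, ylim = rng_v, asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = main)
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                 c(1, 3), c(2, 4), c(5, 7), c(6, 8),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  for (e in seq_len(nrow(edges)))
    graphics::segments(pc[edges[e, 1], 1], pc[edges[e, 1], 2],
                       pc[edges[e, 2], 1], pc[edges[e, 2], 2],
                       col = "grey60")
  graphics::lines(pp[, 1], pp[, 2], col = "blue", lwd = 1.5)
  graphics::points(pp[1, 1], pp[1, 2], pch = 16, col = "darkgreen")
  graphics::points(pp[nrow(pp), 1], pp[nrow(pp), 2], pch = 16, col = "red")
  graphics::legend("topleft", bty = "n", cex = 0.8, legend = c(
    sprintf("x: %.2f um", bb$dims[1]),
    sprintf("y: %.2f um", bb$dims[2]),
    sprintf("z: %.2f um", bb$dims[3]),
    sprintf("%d frames", life_span(traj))))
  invisible(bb)
}

#' Export figures from an analysis bundle
#'
#' Writes a static PNG per style: `"msd"` (pooled MSD scatter with the
#' quadratic trend), `"histogram"` (life span and bounding-box volume
#' percent histograms), `"trajectory3d"` (the two longest trajectories in
#' their bounding boxes), `"density"` (velocity-versus-density scatter with
#' linear and exponential regressions; requires density results).
#'
#' @param analysis a [analyze_trajectories()] bundle.
#' @param trajs the `trajectory_set` the bundle was computed from (needed for
#'   `"trajectory3d"`).
#' @param style one of `"msd"`, `"histogram"`, `"trajectory3d"`, `"density"`.
#' @param file output PNG path.
#' @return `file`, invisibly.
#' @export
plot_analysis <- function(analysis, trajs, style, file) {
  styles <- c("msd", "histogram", "trajectory3d", "density")
  if (!style %in% styles)
    stop("unknown plot style '", style, "'; use one of: ",
         paste(styles, collapse = ", "), call. = FALSE)
  stopifnot(inherits(analysis, "bead_analysis"))
  grDevices::png(file, width = 1200, height = 600, res = 120)
  on.exit(grDevices::dev.off())
  switch(style,
    msd = plot(analysis$msd_fit, main = "pooled MSD with quadratic trend"),
    histogram = {
      graphics::par(mfrow = c(1, 2))
      plot_percent_histogram(analysis$tables$life_span_histogram,
                             xlab = "life span (frames)",
                             main = "trajectory life spans")
      plot_percent_histogram(analysis$tables$bbox_volume_histogram,
                             xlab = expression(bounding ~ box ~ (mu * m^3)),
                             main = "bounding box volumes")
    },
    trajectory3d = {
      graphics::par(mfrow = c(1, 2))
      mt <- analysis$tables$trajectory_metrics
      ord <- order(-mt$trajectory_length)
      pick <- as.character(mt$trajectory[ord[seq_len(min(2, nrow(mt)))]])
      for (id in pick)
        plot_trajectory3d(trajs[[id]], analysis$calibration,
                          main = paste("trajectory", id))
    },
    density = {
      if (is.null(analysis$regression_segment))
        stop("density plot requires an analysis with a bacteria stack",
             call. = FALSE)
      plot(analysis$regression_segment,
           main = "segment velocity vs local density")
    })
  invisible(file)
}
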