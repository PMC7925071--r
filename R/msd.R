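#' Origin-anchored mean-squared-displacement curve of one trajectory
#'
#' Computes \deqn{MSD(m) = \frac{1}{m}\sum_{i=1}^{m} \lVert x_i - x_0
#' \rVert^2,} where \eqn{x_i} is the 3D physical position at the i-th
#' observation, \eqn{x_0} the first observation, and m runs from 1 to the
#' segment count (life span - 1). This origin-anchored statistic is
#' deliberately different from the sliding-window time-lag MSD of standard
#' microrheology: it tracks the growth of displacement from the starting
#' point over the course of each trajectory, and linear growth in m indicates
#' diffusive (Brownian) motion. The displacement norm is the 3D Euclidean
#' norm; the index runs over observations, so bridged frame gaps collapse
#' (consistent with [life_span()]).
#'
#' For straight-line motion with constant step d per observation the closed
#' form is \eqn{MSD(m) = d^2 (m+1)(2m+1)/6}; for 3D Brownian motion with
#' diffusion coefficient D the ensemble mean is \eqn{3 D \Delta t (m+1)}.
#'
#' @param traj one trajectory (data frame with `frame, x, y, z`).
#' @param cal a [calibration()] object.
#' @return data frame with columns `m` and `msd` (um^2), one row per segment.
#' @export
msd_curve <- function(traj, cal) {
  p <- phys_matrix(traj, cal)
  if (nrow(p) < 2L) stop("msd_curve needs >= 2 points", call. = FALSE)
  d2 <- rowSums(sweep(p[-1L, , drop = FALSE], 2L, p[1L, ])^2)
  m <- seq_along(d2)
  data.frame(m = m, msd = cumsum(d2) / m)
}

#' MSD curves for a whole trajectory set
#' @param trajs a `trajectory_set`.
#' @inheritParams msd_curve
#' @return data frame with columns `trajectory, m, msd`.
#' @export
msd_curves <- function(trajs, cal) {
  rows <- lapply(names(trajs), function(id)
    cbind(trajectory = id, msd_curve(trajs[[id]], cal)))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trajectory = character(0), m = integer(0), msd = numeric(0))
  out$trajectory <- utils::type.convert(as.character(out$trajectory), as.is = TRUE)
  rownames(out) <- NULL
  out
}

#' Least-squares polynomial trend of pooled MSD curves
#'
#' Fits \eqn{MSD = a_0 + a_1 m + a_2 m^2} (or the linear sub-model) by
#' ordinary least squares to all (m, MSD) points pooled across trajectories,
#' unweighted — every recorded point counts once, so long trajectories
#' contribute more points. The quadratic trend summarizes the average
#' movement pattern of all beads in a biofilm: a primarily linear trend
#' (small curvature) indicates diffusive behavior.
#'
#' @param curves output of [msd_curves()] (or [msd_curve()]).
#' @param degree 2 (quadratic, default) or 1 (linear).
#' @return An object of class `"msd_fit"`: coefficients `a0, a1, a2`,
#'   residual sum of squares `rss`, pooled point count `n`, largest lag
#'   `m_max`, the underlying `lm` fit, and the pooled points.
#' @seealso [classify_motion()], [estimate_diffusion()]
#' @export
msd_fit <- function(curves, degree = 2L) {
  stopifnot(degree %in% c(1L, 2L))
  m <- curves$m; y <- curves$msd
  if (length(m) < degree + 1L)
    stop("need at least ", degree + 1L, " pooled (m, MSD) points", call. = FALSE)
  if (length(unique(m)) < degree + 1L)
    stop("rank-deficient fit: fewer than ", degree + 1L,
         " distinct m values", call. = FALSE)
  fit <- if (degree == 2L) stats::lm(y ~ m + I(m^2)) else stats::lm(y ~ m)
  cf <- unname(stats::coef(fit))
  structure(list(a0 = cf[1L], a1 = cf[2L],
                 a2 = if (degree == 2L) cf[3L] else 0,
                 degree = degree,
                 rss = sum(stats::residuals(fit)^2),
                 n = length(m), m_max = max(m),
                 lm = fit, points = data.frame(m = m, msd = y)),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD %s trend fit on %d pooled points (m up to %d)\n",
              if (x$degree == 2L) "quadratic" else "linear", x$n, x$m_max))
  cat(sprintf("  MSD(m) = %.4g + %.4g m%s   [um^2]\n", x$a0, x$a1,
              if (x$degree == 2L) sprintf(" + %.4g m^2", x$a2) else ""))
  cat(sprintf("  RSS = %.4g\n", x$rss))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(a0 = object$a0, a1 = object$a1, a2 = object$a2)
}

#' @export
predict.msd_fit <- function(object, m, ...) {
  object$a0 + object$a1 * m + object$a2 * m^2
}

#' @export
plot.msd_fit <- function(x, ...) {
  plot(x$points$m, x$points$msd, pch = 16, cex = 0.4,
       col = grDevices::grey(0.55), xlab = "m (segments)",
       ylab = expression(MSD ~ (mu * m^2)), ...)
  mm <- seq(0, x$m_max, length.out = 200)
  graphics::lines(mm, predict(x, mm), col = "red", lwd = 2)
  invisible(x)
}

#' Classify pooled bead motion as diffusive or not
#'
#' A linear MSD-versus-m trend indicates diffusive (Brownian) movement. The
#' decision statistic is the curvature ratio
#' \eqn{r = |a_2| m_{max} / \max(|a_1|, \epsilon)}: the relative contribution
#' of the quadratic term at the largest lag. Motion is labeled diffusive when
#' `r < threshold`. A fully degenerate fit (all MSD values 0, a stationary
#' population) is labeled diffusive with r = 0.
#'
#' @param fit an [msd_fit()] of degree 2.
#' @param threshold curvature ratio above which motion is non-diffusive
#'   (default 0.25; a convention, the visual judgement made on MSD plots).
#' @param eps guard against division by a vanishing linear term.
#' @return list with `label` (`"diffusive"` or `"non_diffusive"`),
#'   `curvature_ratio`, `threshold`.
#' @export
classify_motion <- function(fit, threshold = 0.25, eps = 1e-12) {
  stopifnot(inherits(fit, "msd_fit"))
  r <- abs(fit$a2) * fit$m_max / max(abs(fit$a1), eps)
  list(label = if (r < threshold) "diffusive" else "non_diffusive",
       curvature_ratio = r, threshold = threshold)
}

#' Estimate the diffusion coefficient from pooled MSD curves
#'
#' Under the origin-anchored MSD definition, 3D Brownian motion with
#' diffusion coefficient D gives ensemble-mean \eqn{MSD(m) = 3 D \Delta t
#' (m+1)}, i.e. slope \eqn{3 D \Delta t} in m. A pooled linear fit
#' `MSD ~ m` therefore yields \eqn{\hat D = a_1 / (3 \Delta t)}.
#'
#' @param curves output of [msd_curves()].
#' @param cal a [calibration()] object (supplies the frame interval).
#' @return list with `D` (um^2/s), `se` (standard error from the fit),
#'   `slope`, and `negative_slope` flag (sub-resolution movement; D is
#'   reported as-is with a warning).
#' @export
estimate_diffusion <- function(curves, cal) {
  cal <- as_calibration(cal)
  fit <- msd_fit(curves, degree = 1L)
  slope <- fit$a1
  se_slope <- tryCatch(
    suppressWarnings(summary(fit$lm)$coefficients["m", "Std. Error"]),
    error = function(e) NA_real_)
  neg <- slope < 0
  if (neg) warning("negative MSD slope: sub-resolution movement", call. = FALSE)
  list(D = slope / (3 * cal$dt), se = se_slope / (3 * cal$dt),
       slope = slope, negative_slope = neg)
}

#' Group-level MSD summary with confidence intervals
#'
#' Reduces each trajectory to its mean MSD value, then summarizes each group
#' (dataset/biofilm) by the group mean and a two-sided 95% t-distribution
#' confidence interval over trajectories. A single-trajectory group reports
#' its mean with the interval flagged undefined.
#'
#' @param curves a [msd_curves()] data frame.
#' @param groups vector assigning each row of `curves` to a group; a single
#'   name is recycled.
#' @param conf confidence level (default 0.95).
#' @return data frame: `group, n_trajectories, mean_msd, ci_low, ci_high,
#'   ci_defined`.
#' @export
group_msd_summary <- function(curves, groups, conf = 0.95) {
  if (length(groups) == 1L) groups <- rep(groups, nrow(curves))
  stopifnot(length(groups) == nrow(curves))
  key <- paste(groups, curves$trajectory, sep = "\r")
  per_traj <- tapply(curves$msd, key, mean)
  traj_group <- vapply(strsplit(names(per_traj), "\r", fixed = TRUE),
                       `[[`, character(1), 1L)
  rows <- lapply(unique(traj_group), function(g) {
    x <- as.numeric(per_traj[traj_group == g])
    n <- length(x)
    if (n >= 2L) {
      half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(x) / sqrt(n)
      data.frame(group = g, n_trajectories = n, mean_msd = mean(x),
                 ci_low = mean(x) - half, ci_high = mean(x) + half,
                 ci_defined = TRUE)
    } else {
      data.frame(group = g, n_trajectories = n, mean_msd = mean(x),
                 ci_low = NA_real_, ci_high = NA_real_, ci_defined = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
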