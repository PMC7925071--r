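#' Full trajectory analysis bundle
#'
#' One call reproducing every quantity class of the bead-movement analysis:
#' per-trajectory metrics (length, life span, bounding box, velocity
#' statistics), per-segment metrics, origin-anchored MSD curves with pooled
#' quadratic and linear trend fits, diffusive-motion classification, a
#' diffusion-coefficient estimate, percent-of-total histograms, and — when a
#' bacterial-channel stack is supplied — segment and trajectory local
#' densities, density-weighted velocities, weighted population summaries and
#' velocity-versus-density regressions at both scales.
#'
#' @param trajs a `trajectory_set` (from [read_trajectories()] or
#'   [track_stack()]).
#' @param cal a [calibration()] object.
#' @param bacteria optional `calibrated_stack` of the bacterial channel.
#' @param diffusive_threshold curvature-ratio threshold for
#'   [classify_motion()].
#' @param density_pad box padding in um for [density_context()].
#' @param life_span_edges,volume_edges histogram bin edges (defaults from
#'   [default_bin_edges()]).
#' @param background density background floor (see [box_density()]).
#' @return An object of class `"bead_analysis"`: list with `tables` (named
#'   data frames ready for [write_results()]), `msd_fit`, `msd_fit_linear`,
#'   `motion`, `diffusion`, and (with density) `regression_segment`,
#'   `regression_trajectory`, plus `calibration`.
#' @export
analyze_trajectories <- function(trajs, cal, bacteria = NULL,
                                 diffusive_threshold = 0.25,
                                 density_pad = 0.5,
                                 life_span_edges = NULL,
                                 volume_edges = NULL,
                                 background = 0) {
  cal <- as_calibration(cal)
  stopifnot(inherits(trajs, "trajectory_set"))
  if (length(trajs) == 0L) {
    empty <- trajectory_metrics_table(trajs, cal)
    return(structure(list(tables = list(trajectory_metrics = empty),
                          calibration = cal),
                     class = "bead_analysis"))
  }

  metrics <- trajectory_metrics_table(trajs, cal)
  segments <- segment_metrics_table(trajs, cal)
  curves <- msd_curves(trajs, cal)

  fit2 <- msd_fit(curves, degree = 2L)
  fit1 <- msd_fit(curves, degree = 1L)
  motion <- classify_motion(fit2, threshold = diffusive_threshold)
  diffusion <- suppressWarnings(estimate_diffusion(curves, cal))

  if (is.null(life_span_edges))
    life_span_edges <- default_bin_edges("life_span",
                                         max_frames = max(metrics$life_span))
  if (is.null(volume_edges))
    volume_edges <- default_bin_edges("bbox_volume")

  tables <- list(
    trajectory_metrics = metrics,
    segment_metrics = segments,
    msd_curves = curves,
    msd_fit = data.frame(degree = c(2L, 1L),
                         a0 = c(fit2$a0, fit1$a0),
                         a1 = c(fit2$a1, fit1$a1),
                         a2 = c(fit2$a2, 0),
                         rss = c(fit2$rss, fit1$rss),
                         n = c(fit2$n, fit1$n)),
    motion_class = data.frame(label = motion$label,
                              curvature_ratio = motion$curvature_ratio,
                              threshold = motion$threshold,
                              D = diffusion$D, D_se = diffusion$se),
    life_span_histogram = percent_histogram(metrics$life_span, life_span_edges),
    bbox_volume_histogram = percent_histogram(metrics$bbox_volume, volume_edges),
    population_summary = population_summary(metrics))

  out <- structure(list(tables = tables, msd_fit = fit2, msd_fit_linear = fit1,
                        motion = motion, diffusion = diffusion,
                        calibration = cal),
                   class = "bead_analysis")

  if (!is.null(bacteria)) {
    ctx <- density_context(bacteria, pad = density_pad)
    seg_rows <- lapply(names(trajs), function(id) {
      traj <- trajs[[id]]
      seg <- segment_metrics(traj, cal)
      rho <- segment_densities(ctx, traj, cal, background = background)
      wsv <- weighted_segment_velocities(seg$velocity, rho)
      cbind(trajectory = id, segment = seg$segment, wsv)
    })
    seg_density <- do.call(rbind, seg_rows)
    seg_density$trajectory <-
      utils::type.convert(as.character(seg_density$trajectory), as.is = TRUE)
    rownames(seg_density) <- NULL

    traj_rows <- lapply(names(trajs), function(id) {
      sd <- seg_density[seg_density$trajectory ==
                          utils::type.convert(id, as.is = TRUE), ]
      tw <- trajectory_weighted_velocity(sd)
      bb <- trajectory_bbox(trajs[[id]], cal)
      frames <- trajs[[id]]$frame
      full_rho <- box_density(ctx, bb, frames, background = background)
      data.frame(trajectory = id,
                 mean_weighted_velocity = tw$mean_weighted_velocity,
                 density_weighted_mean = tw$density_weighted_mean,
                 trajectory_density = full_rho$mean_intensity)
    })
    traj_density <- do.call(rbind, traj_rows)
    traj_density$trajectory <-
      utils::type.convert(as.character(traj_density$trajectory), as.is = TRUE)
    rownames(traj_density) <- NULL

    reg_seg <- tryCatch(
      regress_velocity_density(seg_density$density, seg_density$velocity),
      error = function(e) NULL)
    reg_traj <- tryCatch(
      regress_velocity_density(traj_density$trajectory_density,
                               metrics$mean_velocity),
      error = function(e) NULL)

    tables$segment_density <- seg_density
    tables$trajectory_density <- traj_density
    tables$population_summary <-
      population_summary(metrics, weights = traj_density$trajectory_density)
    if (!is.null(reg_seg) && !is.null(reg_traj))
      tables$density_regressions <- density_dependence_report(reg_seg, reg_traj)
    out$tables <- tables
    out$regression_segment <- reg_seg
    out$regression_trajectory <- reg_traj
  }
  out
}

#' @export
print.bead_analysis <- function(x, ...) {
  mt <- x$tables$trajectory_metrics
  cat(sprintf("bead_analysis: %d trajectories\n", nrow(mt)))
  if (nrow(mt)) {
    cat(sprintf("  life spans %d-%d frames; mean velocity %.4g um/s\n",
                min(mt$life_span), max(mt$life_span),
                mean(mt$mean_velocity)))
    cat(sprintf("  motion: %s (curvature ratio %.3g), D = %.4g um^2/s\n",
                x$motion$label, x$motion$curvature_ratio, x$diffusion$D))
    if (!is.null(x$regression_segment)) {
      cat("  segment-scale ")
      print(x$regression_segment)
    }
  }
  invisible(x)
}

#' Read a run configuration file
#'
#' YAML (or flat `key: value`) file holding the calibration (`dx, dy, dz,
#' dt`), stack geometry (`n_z`, `page_order`), trajectory `dialect`, tracker
#' settings (`radius, cutoff, percentile, link_range, max_displacement`),
#' and analysis settings (`diffusive_threshold`, `density_pad`). Calibration
#' keys are required — they are never defaulted.
#'
#' @param path YAML file.
#' @return list with elements `calibration` (a [calibration()]), `n_z`,
#'   `page_order`, `dialect`, `tracker` (a [linker_config()]),
#'   `diffusive_threshold`, `density_pad`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("dx", "dy", "dz", "dt")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("config is missing required calibration key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cal <- calibration(raw$dx, raw$dy, raw$dz, raw$dt)
  tracker_args <- raw[intersect(names(raw), names(formals(linker_config)))]
  list(calibration = cal,
       n_z = raw$n_z %||% NULL,
       page_order = raw$page_order %||% "frame_major",
       dialect = raw$dialect %||% "mosaic",
       tracker = do.call(linker_config, tracker_args),
       diffusive_threshold = raw$diffusive_threshold %||% 0.25,
       density_pad = raw$density_pad %||% 0.5)
}

write_config_echo <- function(cfg_list, out_dir) {
  p <- file.path(out_dir, "config_echo.yaml")
  yaml::write_yaml(cfg_list, p)
  invisible(p)
}
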