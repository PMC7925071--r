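#' Physical calibration of a 4D acquisition
#'
#' Bundles the voxel dimensions and frame interval that convert pixel/slice
#' coordinates and frame indices into micrometres and seconds. Trajectory
#' files and image stacks are always stored in pixel units; every physical
#' quantity in the package is computed after scaling by a `calibration`
#' object. There is no default calibration: omitting it is an error, never a
#' silent assumption of unit voxels.
#'
#' @param dx x voxel size, micrometres per pixel.
#' @param dy y voxel size, micrometres per pixel (defaults to `dx`).
#' @param dz z step, micrometres per slice.
#' @param dt frame interval, seconds per frame.
#'
#' @return An object of class `"calibration"`: a list with elements
#'   `dx`, `dy`, `dz`, `dt`.
#'
#' @examples
#' cal <- calibration(dx = 0.48, dz = 0.5, dt = 60)
#' cal
#' @export
calibration <- function(dx, dy = dx, dz, dt) {
  vals <- c(dx = dx, dy = dy, dz = dz, dt = dt)
  if (!is.numeric(vals) || length(vals) != 4L ||
      any(!is.finite(vals)) || any(vals <= 0)) {
    stop("calibration values dx, dy, dz, dt must all be finite and > 0",
         call. = FALSE)
  }
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 dz = as.numeric(dz), dt = as.numeric(dt)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: voxel %g x %g x %g um, frame interval %g s\n",
              x$dx, x$dy, x$dz, x$dt))
  invisible(x)
}

as_calibration <- function(x) {
  if (inherits(x, "calibration")) return(x)
  if (is.list(x) && all(c("dx", "dy", "dz", "dt") %in% names(x)))
    return(calibration(x$dx, x$dy, x$dz, x$dt))
  stop("a calibration object (see calibration()) is required", call. = FALSE)
}
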