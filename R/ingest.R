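#' Read bead trajectories from a CSV table
#'
#' Reads a trajectory table in either the Mosaic-plugin export dialect or the
#' package's plain interchange dialect and returns one trajectory per distinct
#' id. Coordinates are kept in 0-based pixel/slice units exactly as stored;
#' physical scaling happens downstream via [calibration()].
#'
#' The `"plain"` dialect requires exact lower-case column names
#' `trajectory, frame, x, y, z`. The `"mosaic"` dialect tolerates header
#' variants: the id column is any column whose (case-insensitive) name
#' contains `"trajectory"`, the frame column any containing `"frame"`, and
#' the coordinate columns match `x`, `y`, `z` case-insensitively after
#' trimming. Extra columns (intensity moments etc.) are ignored.
#'
#' Tracks observed in a single frame carry no kinematic information and are
#' dropped with a message reporting the count; the shortest surviving life
#' span is therefore 2 frames.
#'
#' @param path path to a CSV file.
#' @param dialect `"mosaic"` or `"plain"`.
#'
#' @return A `trajectory_set`: a named list of data frames, one per
#'   trajectory, each with columns `frame, x, y, z` sorted by frame, plus an
#'   attribute `n_dropped_single` (number of single-point tracks discarded).
#' @seealso [write_trajectories()], [trajectory_metrics_table()]
#' @export
read_trajectories <- function(path, dialect = c("mosaic", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- trimws(names(df))
  lower <- tolower(nm)

  locate <- function(role, match_fun) {
    hit <- which(match_fun(lower))
    if (length(hit) == 0L)
      stop(sprintf("trajectory table is missing the required '%s' column", role),
           call. = FALSE)
    hit[1L]
  }
  if (dialect == "plain") {
    cols <- vapply(c("trajectory", "frame", "x", "y", "z"), function(cn)
      locate(cn, function(l) l == cn), integer(1))
  } else {
    cols <- c(
      trajectory = locate("trajectory", function(l) grepl("trajectory", l, fixed = TRUE)),
      frame      = locate("frame", function(l) grepl("frame", l, fixed = TRUE)),
      x          = locate("x", function(l) l == "x"),
      y          = locate("y", function(l) l == "y"),
      z          = locate("z", function(l) l == "z"))
  }
  tab <- df[, cols]
  names(tab) <- c("trajectory", "frame", "x", "y", "z")
  for (cn in c("frame", "x", "y", "z")) {
    tab[[cn]] <- as.numeric(tab[[cn]])
    if (anyNA(tab[[cn]]) || any(!is.finite(tab[[cn]])))
      stop("non-numeric or non-finite values in column '", cn, "'", call. = FALSE)
  }
  if (any(tab$frame < 0)) stop("negative frame indices", call. = FALSE)
  if (anyDuplicated(tab[, c("trajectory", "frame")]))
    stop("duplicate (trajectory, frame) pairs in trajectory table", call. = FALSE)
  trajectory_set(tab)
}

#' Build a trajectory set from a long-format table
#'
#' @param tab data frame with columns `trajectory, frame, x, y, z`
#'   (pixel/slice units, 0-based frames).
#' @return A `trajectory_set` (see [read_trajectories()]).
#' @export
trajectory_set <- function(tab) {
  stopifnot(all(c("trajectory", "frame", "x", "y", "z") %in% names(tab)))
  pieces <- split(tab[, c("frame", "x", "y", "z")], tab$trajectory)
  pieces <- lapply(pieces, function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  single <- vapply(pieces, nrow, integer(1)) < 2L
  n_dropped <- sum(single)
  if (n_dropped > 0L) {
    message(n_dropped, " single-point track(s) dropped")
    pieces <- pieces[!single]
  }
  structure(pieces, class = "trajectory_set", n_dropped_single = n_dropped)
}

#' @export
print.trajectory_set <- function(x, ...) {
  np <- vapply(x, nrow, integer(1))
  cat(sprintf("trajectory_set: %d trajectories, %d points total\n",
              length(x), sum(np)))
  if (length(x))
    cat(sprintf("  life spans: %d-%d frames (median %g)\n",
                min(np), max(np), stats::median(np)))
  nd <- attr(x, "n_dropped_single")
  if (!is.null(nd) && nd > 0) cat(sprintf("  (%d single-point tracks dropped)\n", nd))
  invisible(x)
}

#' Flatten a trajectory set to a long-format table
#' @param trajs a `trajectory_set`.
#' @return data frame with columns `trajectory, frame, x, y, z`.
#' @export
trajectories_to_table <- function(trajs) {
  if (length(trajs) == 0L)
    return(data.frame(trajectory = numeric(0), frame = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0)))
  ids <- names(trajs)
  out <- do.call(rbind, lapply(seq_along(trajs), function(i)
    cbind(trajectory = ids[i], trajs[[i]])))
  out$trajectory <- utils::type.convert(as.character(out$trajectory), as.is = TRUE)
  rownames(out) <- NULL
  out
}

#' Write trajectories in the plain interchange dialect
#'
#' @param trajs a `trajectory_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  write_table_precise(trajectories_to_table(trajs), path)
  invisible(path)
}

#' Read a single-channel 4D image stack from a multi-page TIFF
#'
#' Pages are interpreted frame-major (all z slices of frame 1, then frame 2,
#' ...; the ImageJ hyperstack export default) unless `page_order = "z_major"`.
#' Intensities are returned on the normalized `[0, 1]` scale that
#' [tiff::readTIFF()] applies to 8/16-bit data; density statistics downstream
#' are relative-intensity quantities, so the absolute scale is immaterial.
#'
#' @param path multi-page grayscale TIFF.
#' @param calibration a [calibration()] object (required; never defaulted).
#' @param role channel role, `"bead"` or `"bacteria"`.
#' @param n_z number of z slices per frame.
#' @param page_order `"frame_major"` (default) or `"z_major"`.
#'
#' @return A `calibrated_stack`: list with `voxels` (4D array ordered
#'   frame, z, y, x), `calibration`, `channel`.
#' @export
read_stack <- function(path, calibration, role = c("bead", "bacteria"), n_z,
                       page_order = c("frame_major", "z_major")) {
  role <- match.arg(role)
  page_order <- match.arg(page_order)
  calibration <- as_calibration(calibration)
  if (!file.exists(path)) stop("stack file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse accidental RGB
    p
  })
  if (!is.numeric(pages[[1]]))
    stop("non-numeric pixel data in ", path, call. = FALSE)
  n_pages <- length(pages)
  if (n_pages %% n_z != 0L)
    stop(sprintf("page count %d is not divisible by n_z = %d", n_pages, n_z),
         call. = FALSE)
  n_frames <- n_pages %/% n_z
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(unlist(pages, use.names = FALSE), dim = c(ny, nx, n_z, n_frames))
  if (page_order == "z_major")  # pages vary frame fastest
    arr <- array(unlist(pages, use.names = FALSE), dim = c(ny, nx, n_frames, n_z))
  vox <- if (page_order == "frame_major") aperm(arr, c(4L, 3L, 1L, 2L))
         else aperm(arr, c(3L, 4L, 1L, 2L))
  calibrated_stack(vox, calibration, role)
}

#' Construct a calibrated 4D stack in memory
#'
#' @param voxels 4D numeric array ordered (frame, z, y, x); finite, >= 0.
#' @param calibration a [calibration()] object.
#' @param channel `"bead"` or `"bacteria"`.
#' @return A `calibrated_stack`.
#' @export
calibrated_stack <- function(voxels, calibration, channel = c("bead", "bacteria")) {
  channel <- match.arg(channel)
  calibration <- as_calibration(calibration)
  if (length(dim(voxels)) != 4L || any(dim(voxels) < 1L))
    stop("voxels must be a 4D array with all extents >= 1", call. = FALSE)
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("voxel intensities must be finite and >= 0", call. = FALSE)
  structure(list(voxels = voxels, calibration = calibration, channel = channel),
            class = "calibrated_stack")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("calibrated_stack (%s channel): %d frames x %d z x %d y x %d x\n",
              x$channel, d[1], d[2], d[3], d[4]))
  print(x$calibration)
  invisible(x)
}

#' Write a calibrated stack as a multi-page TIFF
#'
#' Pages are written frame-major at 32 bits per sample; intensities must lie
#' in `[0, 1]` (stored precision ~ 2.3e-10).
#'
#' @param stack a `calibrated_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  if (max(stack$voxels) > 1)
    stop("stack intensities must be in [0, 1] for TIFF storage", call. = FALSE)
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (f in seq_len(d[1])) for (z in seq_len(d[2])) {
    pages[[k]] <- matrix(stack$voxels[f, z, , ], d[3], d[4])
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate")
  invisible(path)
}

# Full-precision CSV writer: %.17g round-trips IEEE doubles exactly through
# read.csv, so read(write(x)) == x holds at stored precision.
write_table_precise <- function(df, path) {
  out <- df
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a bundle of result tables to CSV files
#'
#' One file `<name>.csv` per table, written at full float precision
#' (re-readable losslessly with [read_results()]). Empty tables produce a
#' header-only file, not an error.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory, created if absent.
#' @return character vector of file paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(tables) > 0, !is.null(names(tables)))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (!is.data.frame(tb)) next
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_table_precise(tb, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a result table written by [write_results()]
#' @param path CSV path.
#' @return data frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
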