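#' Voxel calibration
#'
#' Physical size of a voxel and the frame interval of a time-lapse
#' acquisition. Lengths are in micrometres, time in seconds. The axial
#' spacing defaults to 0.7 µm and the frame interval to 15 s, matching
#' typical confocal z-stack series of embryonic muscle tips (5–7 sections
#' at 0.7 µm, one stack every 15 s); the in-plane pixel size has no safe
#' default and must always be supplied.
#'
#' @param dx µm per pixel along x.
#' @param dy µm per pixel along y (defaults to \code{dx}).
#' @param dz µm per z-slice.
#' @param dt seconds per frame.
#' @return An object of class \code{filo_calibration}: a list with fields
#'   \code{dx}, \code{dy}, \code{dz}, \code{dt}.
#' @examples
#' voxel_calibration(dx = 0.1)
#' @export
voxel_calibration <- function(dx, dy = dx, dz = 0.7, dt = 15) {
  vals <- c(dx = dx, dy = dy, dz = dz, dt = dt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all calibration fields must be strictly positive and finite")
  }
  structure(list(dx = dx, dy = dy, dz = dz, dt = dt),
            class = "filo_calibration")
}

#' @export
print.filo_calibration <- function(x, ...) {
  cat(sprintf("<voxel calibration> dx=%g dy=%g dz=%g um, dt=%g s\n",
              x$dx, x$dy, x$dz, x$dt))
  invisible(x)
}

is_calibration <- function(x) inherits(x, "filo_calibration")

#' @rdname voxel_calibration
#' @param x object to coerce (a \code{filo_calibration} or a named list).
#' @export
as_voxel_calibration <- function(x) {
  if (is_calibration(x)) return(x)
  if (is.list(x) && all(c("dx", "dy", "dz", "dt") %in% names(x))) {
    return(voxel_calibration(x$dx, x$dy, x$dz, x$dt))
  }
  abort("cannot interpret object as a voxel calibration")
}

# physical step sizes per index step, in path coordinate order (z, y, x)
cal_steps <- function(calibration) {
  c(calibration$dz, calibration$dy, calibration$dx)
}

# Path lengths of an ordered voxel path (n x 3 matrix, columns z, y, x).
# Voxel length uses index-space distances, physical length anisotropic
# calibrated distances.
path_length_vox <- function(path) {
  if (nrow(path) < 2) return(0)
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

# Moving-average smoothing of a voxel path (endpoints kept fixed).
# Digitised centrelines oscillate between neighbouring z-slices; on
# anisotropic grids every spurious slice crossing adds ~dz of length, so
# physical lengths are measured on a smoothed copy of the path. The
# z-coordinate is smoothed over a wider window than x/y: filopodia run
# nearly parallel to the imaging plane, so genuine axial slopes vary over
# micrometres while thinning jitter alternates voxel to voxel, and the
# wider window removes the jitter without erasing a real slice
# transition (the net z-displacement is preserved).
smooth_path <- function(path, window = 5L, z_window = 15L) {
  n <- nrow(path)
  if (n <= 2) return(path)
  out <- path * 1.0
  run_mean <- function(v, w, idx) {
    h <- w %/% 2
    vapply(idx, function(i) mean(v[max(1, i - h):min(n, i + h)]), numeric(1))
  }
  # z smoothed everywhere (clipped windows at the ends); xy endpoints are
  # pinned so the tip position and in-plane length are preserved
  if (z_window > 1) out[, 1] <- run_mean(path[, 1], z_window, seq_len(n))
  if (window > 1) {
    out[2:(n - 1), 2] <- run_mean(path[, 2], window, 2:(n - 1))
    out[2:(n - 1), 3] <- run_mean(path[, 3], window, 2:(n - 1))
  }
  out
}

path_length_um <- function(path, calibration, smooth = TRUE) {
  if (nrow(path) < 2) return(0)
  if (smooth) path <- smooth_path(path)
  d <- sweep(diff(path), 2, cal_steps(calibration), `*`)
  sum(sqrt(rowSums(d^2)))
}

# Mean non-normalized direction vector of a path: average of consecutive
# calibrated displacement vectors, base -> tip, in (z, y, x) order.
path_direction <- function(path, calibration) {
  if (nrow(path) < 2) return(c(0, 0, 0))
  d <- sweep(diff(path), 2, cal_steps(calibration), `*`)
  colMeans(d)
}
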