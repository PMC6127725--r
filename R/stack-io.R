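#' Time-lapse image stack
#'
#' Container for a calibrated 4D fluorescence recording, indexed
#' \code{(t, z, y, x)}. Intensities must be finite and non-negative.
#'
#' @param voxels 4D numeric array with dimensions (T, Z, Y, X).
#' @param calibration a \code{\link{voxel_calibration}}.
#' @return An object of class \code{filo_stack} with fields \code{voxels}
#'   and \code{calibration}.
#' @export
timelapse_stack <- function(voxels, calibration) {
  if (length(dim(voxels)) != 4L) {
    abort("voxels must be a 4D array indexed (t, z, y, x)")
  }
  if (any(!is.finite(voxels)) || any(voxels < 0)) {
    abort("stack intensities must be finite and non-negative")
  }
  structure(list(voxels = voxels,
                 calibration = as_voxel_calibration(calibration)),
            class = "filo_stack")
}

#' @export
print.filo_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<time-lapse stack> T=%d Z=%d Y=%d X=%d\n", d[1], d[2], d[3], d[4]))
  print(x$calibration)
  invisible(x)
}

#' Extract one frame of a stack as a (Z, Y, X) volume
#' @param stack a \code{filo_stack}.
#' @param t frame index (1-based).
#' @return 3D numeric array (Z, Y, X).
#' @export
stack_frame <- function(stack, t) {
  d <- dim(stack$voxels)
  if (t < 1 || t > d[1]) abort(sprintf("frame %d out of range 1..%d", t, d[1]))
  array(stack$voxels[t, , , ], dim = d[2:4])
}

#' Read a multi-page TIFF as a calibrated 4D stack
#'
#' Pages are interpreted frame-major: page \eqn{(t-1) Z + z} holds frame
#' \eqn{t}, slice \eqn{z}. TIFF files rarely carry reliable axis metadata,
#' so the frame and slice counts must be declared explicitly (a single-page
#' file defaults to T = 1, Z = 1).
#'
#' @param path TIFF file path.
#' @param frames,slices declared T and Z; their product must equal the page
#'   count.
#' @param calibration a \code{\link{voxel_calibration}} (required: pixel
#'   size is not recoverable from plain TIFF).
#' @return A \code{\link{timelapse_stack}}.
#' @export
read_stack <- function(path, frames = NULL, slices = NULL, calibration) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n <- length(pages)
  if (is.null(frames) && is.null(slices)) {
    if (n == 1L) { frames <- 1L; slices <- 1L }
    else abort("frames and slices must be declared for multi-page TIFFs")
  }
  if (is.null(frames) || is.null(slices)) {
    abort("declare both frames and slices (or neither, for single-page files)")
  }
  if (frames * slices != n) {
    abort(sprintf("%d pages cannot be arranged as %d frames x %d slices",
                  n, frames, slices))
  }
  yx <- dim(pages[[1]])
  voxels <- array(0, dim = c(frames, slices, yx[1], yx[2]))
  for (t in seq_len(frames)) {
    for (z in seq_len(slices)) {
      voxels[t, z, , ] <- pages[[(t - 1L) * slices + z]]
    }
  }
  timelapse_stack(voxels, calibration)
}

#' Write a stack as a 16-bit multi-page TIFF
#'
#' Intensities are rounded to integers and clamped to the 16-bit range, so
#' integer-valued stacks round-trip exactly through
#' \code{\link{read_stack}}.
#'
#' @param stack a \code{filo_stack}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$voxels)
  pages <- vector("list", d[1] * d[2])
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      v <- round(pmin(pmax(stack$voxels[t, z, , ], 0), 65535))
      pages[[(t - 1L) * d[2] + z]] <- v / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

# ---- segment / track tables ------------------------------------------------

path_matrix <- function(x) {
  m <- matrix(as.integer(x), ncol = 3)
  colnames(m) <- c("z", "y", "x")
  m
}

#' Build a segment table
#'
#' @param frame integer frame index per segment (1-based).
#' @param segment_id integer id, unique within its frame.
#' @param path list of n-by-3 integer matrices of 0-based (z, y, x) voxel
#'   indices, ordered along the segment.
#' @return A tibble with class \code{filo_segments}.
#' @export
segment_table <- function(frame = integer(), segment_id = integer(),
                          path = list()) {
  tab <- tibble::tibble(frame = as.integer(frame),
                        segment_id = as.integer(segment_id),
                        path = lapply(path, path_matrix))
  validate_segments(tab)
  class(tab) <- c("filo_segments", class(tab))
  tab
}

validate_segments <- function(tab, bounds = NULL) {
  if (anyDuplicated(tab[c("frame", "segment_id")])) {
    abort("duplicated (frame, segment_id) in segment table")
  }
  for (p in tab$path) {
    if (any(p < 0)) abort("voxel indices must be 0-based non-negative")
    if (!is.null(bounds) && any(sweep(p, 2, bounds, `>=`))) {
      abort("voxel index outside declared bounds")
    }
  }
  invisible(tab)
}

#' Write / read segment tables (JSON)
#'
#' The on-disk form stores only frames, ids and integer voxel paths, so a
#' round trip is lossless including coordinate order.
#'
#' @param table a \code{\link{segment_table}}.
#' @param path file path.
#' @param bounds optional (Z, Y, X) bounds checked on write and read.
#' @return \code{read_segments} returns the table; \code{write_segments}
#'   returns \code{path} invisibly.
#' @export
write_segments <- function(table, path, bounds = NULL) {
  validate_segments(table, bounds)
  doc <- list(
    type = "filotrack-segments",
    bounds = if (is.null(bounds)) NULL else as.integer(bounds),
    segments = purrr::pmap(table, function(frame, segment_id, path, ...) {
      list(frame = frame, segment_id = segment_id,
           path = unname(apply(path, 1, as.integer, simplify = FALSE)))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "filotrack-segments")) {
    abort("not a filotrack segment file")
  }
  segs <- doc$segments
  tab <- segment_table(
    frame = purrr::map_int(segs, "frame"),
    segment_id = purrr::map_int(segs, "segment_id"),
    path = purrr::map(segs, function(s) {
      do.call(rbind, lapply(s$path, function(v) as.integer(unlist(v))))
    })
  )
  bounds <- if (is.null(doc$bounds)) NULL else as.integer(unlist(doc$bounds))
  validate_segments(tab, bounds)
  tab
}

#' Write / read track tables (JSON)
#'
#' Tracks are stored as integer voxel paths per (track, frame); derived
#' lengths and directions are recomputed from the stored calibration on
#' read, so a write/read round trip reproduces the table exactly.
#'
#' @param tracks a track table from \code{\link{track_movie}}.
#' @param path file path.
#' @return \code{read_tracks} returns the track table; \code{write_tracks}
#'   returns \code{path} invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (anyDuplicated(tracks$track_id)) abort("track ids must be unique")
  calibration <- attr(tracks, "calibration")
  if (is.null(calibration)) abort("track table lacks a calibration attribute")
  doc <- list(
    type = "filotrack-tracks",
    calibration = calibration[c("dx", "dy", "dz", "dt")],
    tracks = purrr::map2(tracks$track_id, tracks$data, function(id, d) {
      list(track_id = id,
           instances = purrr::pmap(d[c("frame", "instance_id", "path")],
             function(frame, instance_id, path) {
               list(frame = frame, instance_id = instance_id,
                    path = unname(apply(path, 1, as.integer, simplify = FALSE)))
             }))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "filotrack-tracks")) abort("not a filotrack track file")
  calibration <- as_voxel_calibration(lapply(doc$calibration, as.numeric))
  long <- purrr::map_dfr(doc$tracks, function(tr) {
    tibble::tibble(
      track_id = as.integer(tr$track_id),
      frame = purrr::map_int(tr$instances, "frame"),
      instance_id = purrr::map_int(tr$instances, "instance_id"),
      path = purrr::map(tr$instances, function(i) {
        path_matrix(do.call(rbind, lapply(i$path, function(v) as.integer(unlist(v)))))
      })
    )
  })
  build_track_table(long, calibration)
}

#' Flat per-track summary as CSV
#'
#' @param tracks a track table.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_track_summary <- function(tracks, path) {
  write.csv(track_summary(tracks), path, row.names = FALSE)
  invisible(path)
}

# ---- YAML configuration ----------------------------------------------------

#' Read a pipeline configuration file
#'
#' YAML file with optional sections \code{calibration}, \code{segmentation},
#' \code{tracking}, \code{filter}, \code{simulate}; every field defaults to
#' the package default when absent.
#'
#' @param path YAML file path.
#' @return Named list of configuration objects.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$calibration)) {
    out$calibration <- do.call(voxel_calibration, cfg$calibration)
  }
  out$segmentation <- do.call(segmentation_config,
                              cfg$segmentation %||% list())
  out$tracking <- do.call(tracking_config, cfg$tracking %||% list())
  out$filter <- do.call(filter_config, cfg$filter %||% list())
  if (!is.null(cfg$simulate)) out$simulate <- cfg$simulate
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
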