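#' Detect filopodium segments in every frame
#'
#' Runs the per-frame segmentation chain — superpixel foreground
#' extraction, Hessian vesselness, vesselness-output segmentation, 3D
#' binary closing, small-region removal, skeletonization, cell-body
#' masking and branch decomposition — and returns the extracted line
#' segments together with the per-frame cell-body masks.
#'
#' @param stack a \code{\link{timelapse_stack}}.
#' @param config a \code{\link{segmentation_config}}.
#' @param frames frames to process (default: all).
#' @param verbose print per-frame progress.
#' @return List with \code{segments} (a \code{\link{segment_table}} over
#'   all frames) and \code{bodies} (list of cell-body masks by frame).
#' @export
detect_segments <- function(stack, config = segmentation_config(),
                            frames = NULL, verbose = FALSE) {
  d <- dim(stack$voxels)
  if (is.null(frames)) frames <- seq_len(d[1])
  seg_list <- list()
  bodies <- vector("list", d[1])
  for (t in frames) {
    vol <- stack_frame(stack, t)
    fg <- segment_pixels(vol, config)
    body <- find_cell_body(vol, config)
    # vesselness of the foreground-gated intensities: the pixel
    # segmentation supplies the gate while the intensity amplitudes keep
    # the structureness term discriminative against residual noise
    v <- frangi_filter(vol * fg, config, stack$calibration)
    vmask <- segment_vesselness(v, config)
    vmask <- remove_small_objects(vmask, config$min_region_voxels)
    skel <- skeletonize_frame(vmask)
    skel <- mask_skeleton(skel, body)
    segs <- split_segments(skel, frame = t, prune_spurs = config$prune_spur_vox)
    seg_list[[length(seg_list) + 1]] <- segs
    bodies[[t]] <- body
    if (verbose) message(sprintf("frame %d: %d segments", t, nrow(segs)))
  }
  segments <- dplyr::bind_rows(seg_list)
  class(segments) <- unique(c("filo_segments", class(segments)))
  list(segments = segments, bodies = bodies)
}

#' Full reconstruction pipeline: stack to tracks
#'
#' Convenience wrapper: \code{\link{detect_segments}}, curation via an
#' edit script (default \code{\link{auto_accept}}), and
#' \code{\link{track_movie}}.
#'
#' @param stack a \code{\link{timelapse_stack}}.
#' @param seg_config a \code{\link{segmentation_config}}.
#' @param track_config a \code{\link{tracking_config}}.
#' @param edits optional edit-command tibble.
#' @param verbose print progress.
#' @return A track table (see \code{\link{track_movie}}).
#' @export
run_pipeline <- function(stack, seg_config = segmentation_config(),
                         track_config = tracking_config(), edits = NULL,
                         verbose = FALSE) {
  det <- detect_segments(stack, seg_config, verbose = verbose)
  instances <- apply_edits(det$segments, edits, cell_body = det$bodies,
                           calibration = stack$calibration)
  track_movie(instances, track_config)
}
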