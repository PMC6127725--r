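#' Edit scripts: the curation contract
#'
#' Automatic skeleton extraction over-segments: fragments of one
#' filopodium appear as several line segments and spurious detections
#' (noise, neighbouring cells) appear as segments of their own. Curation
#' is expressed as an ordered script of commands, the same contract an
#' interactive editor would emit:
#' \itemize{
#'   \item \code{edit_remove(frame, segment_id)} — discard a segment;
#'   \item \code{edit_merge(frame, segment_ids, instance_id)} — join
#'     segments of one frame into a single filopodium;
#'   \item \code{edit_accept(frame, segment_id, instance_id)} — promote a
#'     segment to a filopodium unchanged.
#' }
#' Segments not referenced by any command are accepted automatically with
#' fresh instance ids.
#'
#' @param frame frame index (1-based).
#' @param segment_id,segment_ids segment id(s) within that frame.
#' @param instance_id id of the resulting filopodium instance (unique
#'   within the frame).
#' @return A one-row edit-command tibble; combine rows with
#'   \code{dplyr::bind_rows}.
#' @name edit_script
NULL

edit_cmd <- function(frame, op, segment_ids, instance_id) {
  tibble::tibble(frame = as.integer(frame), op = op,
                 segment_ids = list(as.integer(segment_ids)),
                 instance_id = as.integer(instance_id))
}

#' @rdname edit_script
#' @export
edit_remove <- function(frame, segment_id) {
  edit_cmd(frame, "remove", segment_id, NA_integer_)
}

#' @rdname edit_script
#' @export
edit_merge <- function(frame, segment_ids, instance_id) {
  if (length(segment_ids) < 2) abort("merge needs at least two segment ids")
  edit_cmd(frame, "merge", segment_ids, instance_id)
}

#' @rdname edit_script
#' @export
edit_accept <- function(frame, segment_id, instance_id) {
  edit_cmd(frame, "accept", segment_id, instance_id)
}

empty_edits <- function() {
  tibble::tibble(frame = integer(), op = character(),
                 segment_ids = list(), instance_id = integer())
}

#' Default curation: accept every segment
#'
#' Script used for unattended runs and benchmarks: each segment becomes
#' its own filopodium instance (instance id = segment id), no merges or
#' removals. Applying the result is idempotent.
#'
#' @param segments a \code{\link{segment_table}}.
#' @return An edit-command tibble.
#' @export
auto_accept <- function(segments) {
  if (nrow(segments) == 0) return(empty_edits())
  dplyr::bind_rows(purrr::map2(segments$frame, segments$segment_id,
                               function(f, id) edit_accept(f, id, id)))
}

#' Write / read edit scripts (JSON)
#'
#' @param edits an edit-command tibble.
#' @param path file path.
#' @return \code{read_edit_script} returns the tibble;
#'   \code{write_edit_script} returns \code{path} invisibly.
#' @export
write_edit_script <- function(edits, path) {
  doc <- list(type = "filotrack-edits",
              commands = purrr::pmap(edits, function(frame, op, segment_ids,
                                                     instance_id) {
                cmd <- list(frame = frame, op = op,
                            segment_ids = as.list(segment_ids))
                if (!is.na(instance_id)) cmd$instance_id <- instance_id
                cmd
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_edit_script
#' @export
read_edit_script <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "filotrack-edits")) abort("not a filotrack edit script")
  if (length(doc$commands) == 0) return(empty_edits())
  dplyr::bind_rows(lapply(doc$commands, function(cmd) {
    edit_cmd(cmd$frame, cmd$op, as.integer(unlist(cmd$segment_ids)),
             cmd$instance_id %||% NA_integer_)
  }))
}

# ---- applying edits --------------------------------------------------------

instance_row <- function(frame, instance_id, path, calibration, anchor) {
  # orient base -> tip: base is the endpoint nearer the anchor
  ends <- path[c(1, nrow(path)), , drop = FALSE]
  d_ends <- .rows_min_dist(ends * 1.0, anchor, rep(1, 3))
  if (d_ends[2] < d_ends[1]) path <- path[nrow(path):1, , drop = FALSE]
  n <- nrow(path)
  lv <- path_length_vox(path)
  lu <- path_length_um(path, calibration)
  dir <- path_direction(path, calibration)
  base_pt <- path[1, ]; tip_pt <- path[n, ]
  pmat <- path
  tibble::tibble(
    frame = as.integer(frame), instance_id = as.integer(instance_id),
    path = list(pmat), n_vox = n, length_vox = lv, length_um = lu,
    base = list(base_pt), tip = list(tip_pt),
    direction = list(dir)
  )
}

# anchor point set for base orientation: cell-body voxels when available,
# otherwise the centroid of the frame's segment voxels
frame_anchor <- function(cell_body, seg_paths) {
  if (!is.null(cell_body) && any(cell_body)) {
    d <- dim(cell_body)
    i0 <- which(cell_body) - 1L
    return(cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2])) * 1.0)
  }
  all_vox <- do.call(rbind, seg_paths)
  matrix(colMeans(all_vox), 1)
}

chain_segments <- function(paths, ids, merge_gap) {
  chain <- paths[[1]]
  remaining <- paths[-1]
  rem_ids <- ids[-1]
  while (length(remaining) > 0) {
    best <- list(d = Inf)
    for (j in seq_along(remaining)) {
      p <- remaining[[j]]
      for (chain_end in c(1L, 2L)) {     # 1 = head of chain, 2 = tail
        ce <- if (chain_end == 1L) chain[1, ] else chain[nrow(chain), ]
        for (seg_end in c(1L, 2L)) {
          se <- if (seg_end == 1L) p[1, ] else p[nrow(p), ]
          dd <- sqrt(sum((ce - se)^2))
          if (dd < best$d) best <- list(d = dd, j = j, chain_end = chain_end,
                                        seg_end = seg_end)
        }
      }
    }
    if (best$d > merge_gap) {
      abort(sprintf(
        "segments %s cannot be chained: nearest endpoints %.2f voxels apart (merge_gap = %g)",
        paste(c(ids[1], rem_ids), collapse = ", "), best$d, merge_gap))
    }
    p <- remaining[[best$j]]
    if (best$seg_end == 2L) p <- p[nrow(p):1, , drop = FALSE]
    if (best$chain_end == 1L) {
      # attach before the head: reverse the incoming piece onto the front
      p <- p[nrow(p):1, , drop = FALSE]
      if (all(p[nrow(p), ] == chain[1, ])) p <- p[-nrow(p), , drop = FALSE]
      chain <- rbind(p, chain)
    } else {
      if (all(p[1, ] == chain[nrow(chain), ])) p <- p[-1, , drop = FALSE]
      chain <- rbind(chain, p)
    }
    remaining <- remaining[-best$j]
    rem_ids <- rem_ids[-best$j]
  }
  chain
}

#' Apply an edit script to extracted segments
#'
#' Executes remove/merge/accept commands and turns the surviving segments
#' into filopodium instances: merged segments are concatenated by greedy
#' nearest-endpoint chaining, every instance path is oriented base to tip
#' (base = endpoint nearest the cell-body mask), and path lengths (voxel
#' and calibrated micrometre) plus the mean non-normalised direction
#' vector are computed. Unreferenced segments are auto-accepted.
#'
#' @param segments a \code{\link{segment_table}}.
#' @param edits an edit-command tibble (see \code{\link{edit_script}});
#'   defaults to accepting everything.
#' @param cell_body logical mask (single frame shape) or a list of masks
#'   indexed by frame; used to orient paths. \code{NULL} falls back to the
#'   segment centroid of the frame.
#' @param calibration a \code{\link{voxel_calibration}}.
#' @param merge_gap maximum endpoint distance (voxels) bridged by a merge.
#' @return A tibble of filopodium instances (class \code{filo_instances})
#'   with columns \code{frame}, \code{instance_id}, \code{path},
#'   \code{n_vox}, \code{length_vox}, \code{length_um}, \code{base},
#'   \code{tip}, \code{direction}.
#' @export
apply_edits <- function(segments, edits = NULL, cell_body = NULL,
                        calibration = voxel_calibration(1, 1, 1, 1),
                        merge_gap = 5) {
  calibration <- as_voxel_calibration(calibration)
  if (is.null(edits)) edits <- auto_accept(segments)
  out <- list()
  seg_key <- paste(segments$frame, segments$segment_id)

  # validate references and single consumption
  used <- character()
  for (i in seq_len(nrow(edits))) {
    ids <- edits$segment_ids[[i]]
    keys <- paste(edits$frame[i], ids)
    missing <- keys[!keys %in% seg_key]
    if (length(missing)) {
      abort(sprintf("edit references unknown segment(s): %s",
                    paste(missing, collapse = "; ")))
    }
    dup <- keys[keys %in% used]
    if (length(dup)) {
      abort(sprintf("segment(s) consumed twice by edits: %s",
                    paste(dup, collapse = "; ")))
    }
    used <- c(used, keys)
  }
  # auto-accept untouched segments
  untouched <- !(seg_key %in% used)
  if (any(untouched)) {
    auto <- segments[untouched, ]
    extra <- dplyr::bind_rows(purrr::map2(auto$frame, auto$segment_id,
                                          function(f, id) edit_accept(f, id, id)))
    # avoid instance-id collisions with explicit commands in the same frame
    for (i in seq_len(nrow(extra))) {
      taken <- c(edits$instance_id[edits$frame == extra$frame[i]],
                 extra$instance_id[seq_len(i - 1)][extra$frame[seq_len(i - 1)] ==
                                                     extra$frame[i]])
      taken <- taken[!is.na(taken)]
      if (extra$instance_id[i] %in% taken) {
        extra$instance_id[i] <- max(taken) + 1L
      }
    }
    edits <- dplyr::bind_rows(edits, extra)
  }

  keep <- edits[edits$op != "remove", ]
  if (nrow(keep) > 0 && anyDuplicated(keep[c("frame", "instance_id")])) {
    abort("instance ids must be unique within a frame")
  }
  body_for_frame <- function(f) {
    if (is.null(cell_body)) return(NULL)
    if (is.list(cell_body)) cell_body[[f]] else cell_body
  }
  for (f in sort(unique(keep$frame))) {
    cmds <- keep[keep$frame == f, ]
    seg_f <- segments[segments$frame == f, ]
    anchor <- frame_anchor(body_for_frame(f), seg_f$path)
    for (i in seq_len(nrow(cmds))) {
      ids <- cmds$segment_ids[[i]]
      paths <- seg_f$path[match(ids, seg_f$segment_id)]
      path <- if (length(paths) == 1) paths[[1]] else {
        chain_segments(paths, ids, merge_gap)
      }
      out[[length(out) + 1]] <- instance_row(f, cmds$instance_id[i], path,
                                             calibration, anchor)
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    frame = integer(), instance_id = integer(), path = list(),
    n_vox = integer(), length_vox = numeric(), length_um = numeric(),
    base = list(), tip = list(), direction = list())
  res <- dplyr::arrange(res, .data$frame, .data$instance_id)
  attr(res, "calibration") <- calibration
  class(res) <- c("filo_instances", class(res))
  res
}
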