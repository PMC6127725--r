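#' Tracking configuration
#'
#' Parameters of the greedy cross-frame linking step. Defaults follow the
#' reference procedure: candidates searched over the preceding five time
#' points within a 25-pixel cutoff radius, combined score
#' \eqn{S = 0.46\,M_L + 0.6\,M_D} (weights as published, deliberately not
#' renormalised to sum to one).
#'
#' @param lookback_frames how many preceding frames are searched for
#'   link candidates; a track absent for this many frames ends.
#' @param cutoff_radius_px candidate cutoff: minimum voxel-path distance
#'   in pixel (index) units.
#' @param weight_length,weight_direction score weights for the length
#'   measure \eqn{M_L} and direction measure \eqn{M_D}.
#' @param calibrated_distance when \code{TRUE}, z steps are scaled by the
#'   voxel aspect ratio (dz/dx) in the candidate search; the published
#'   procedure states its cutoff in raw pixels, so the default leaves z
#'   unscaled.
#' @param candidate_mode \code{"most-recent"} compares against each
#'   track's most recent instance inside the window (default);
#'   \code{"any-within-window"} admits a candidate when any instance of
#'   the track inside the window is within the cutoff.
#' @return A list of class \code{filo_track_config}.
#' @export
tracking_config <- function(lookback_frames = 5L, cutoff_radius_px = 25,
                            weight_length = 0.46, weight_direction = 0.6,
                            calibrated_distance = FALSE,
                            candidate_mode = c("most-recent",
                                               "any-within-window")) {
  candidate_mode <- match.arg(candidate_mode)
  stopifnot(lookback_frames >= 1, cutoff_radius_px > 0,
            weight_length >= 0, weight_direction >= 0)
  structure(list(lookback_frames = as.integer(lookback_frames),
                 cutoff_radius_px = cutoff_radius_px,
                 weight_length = weight_length,
                 weight_direction = weight_direction,
                 calibrated_distance = calibrated_distance,
                 candidate_mode = candidate_mode),
            class = "filo_track_config")
}

#' Path-length difference measure
#'
#' \eqn{M_L = |L_c - L_p| / \max\{L_c, L_p\}}: 0 for identical lengths,
#' approaching 1 for very dissimilar ones; symmetric in its arguments.
#'
#' @param l_current,l_previous path lengths (µm), strictly positive.
#' @return Value in [0, 1].
#' @export
length_measure <- function(l_current, l_previous) {
  if (any(c(l_current, l_previous) <= 0)) {
    abort("path lengths must be strictly positive")
  }
  abs(l_current - l_previous) / pmax(l_current, l_previous)
}

#' Average-direction difference measure
#'
#' \eqn{M_D = (1 - \cos\theta)/2} for the angle \eqn{\theta} between the
#' mean non-normalised direction vectors of the two filopodia: 0 for
#' parallel, 1 for antiparallel, 0.5 for orthogonal. Vector magnitudes
#' cancel, so normalisation is immaterial. A zero vector carries no
#' directional information and scores 0.5 with a warning.
#'
#' @param d_current,d_previous direction vectors (any common length).
#' @return Value in [0, 1].
#' @export
direction_measure <- function(d_current, d_previous) {
  nc <- sqrt(sum(d_current^2)); np <- sqrt(sum(d_previous^2))
  if (nc == 0 || np == 0) {
    warn("zero direction vector: direction measure is uninformative (0.5)")
    return(0.5)
  }
  ct <- sum(d_current * d_previous) / (nc * np)
  ct <- min(1, max(-1, ct))
  (1 - ct) / 2
}

empty_candidates <- function() {
  tibble::tibble(instance_id = integer(), track_id = integer(),
                 dist = numeric(), M_L = numeric(), M_D = numeric(),
                 S = numeric())
}

#' Find link candidates for one frame
#'
#' A (instance, track) pair is a candidate when the minimum Euclidean
#' distance between any voxel of the instance's path and any voxel of the
#' track's reference instance(s) is within the cutoff radius. Each
#' candidate carries the length measure \eqn{M_L}, direction measure
#' \eqn{M_D} and score \eqn{S = w_L M_L + w_D M_D}.
#'
#' @param current filopodium instances of the frame being linked
#'   (a \code{filo_instances} tibble).
#' @param history one row per candidate track: columns \code{track_id},
#'   \code{frame}, \code{path}, \code{length_um}, \code{direction}
#'   (its most recent instance, or several rows per track in
#'   any-within-window mode).
#' @param config a \code{\link{tracking_config}}.
#' @param calibration used only when \code{calibrated_distance} is set.
#' @return Tibble of candidates: \code{instance_id}, \code{track_id},
#'   \code{dist}, \code{M_L}, \code{M_D}, \code{S}.
#' @export
find_candidates <- function(current, history, config = tracking_config(),
                            calibration = NULL) {
  if (nrow(current) == 0 || nrow(history) == 0) return(empty_candidates())
  w <- c(1, 1, 1)
  if (config$calibrated_distance && !is.null(calibration)) {
    w <- c(calibration$dz / calibration$dx, calibration$dy / calibration$dx, 1)
  }
  rows <- list()
  for (i in seq_len(nrow(current))) {
    pc <- current$path[[i]] * 1.0
    for (j in seq_len(nrow(history))) {
      pp <- history$path[[j]] * 1.0
      d <- min(.rows_min_dist(pc, pp, w))
      if (d > config$cutoff_radius_px) next
      ml <- length_measure(current$length_um[i], history$length_um[j])
      md <- direction_measure(current$direction[[i]], history$direction[[j]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        instance_id = current$instance_id[i],
        track_id = history$track_id[j],
        dist = d, M_L = ml, M_D = md,
        S = config$weight_length * ml + config$weight_direction * md)
    }
  }
  if (length(rows) == 0) return(empty_candidates())
  out <- dplyr::bind_rows(rows)
  # in any-within-window mode a track may appear several times; keep its
  # best-scoring pairing per (instance, track)
  out <- dplyr::arrange(out, .data$S, .data$M_L)
  out <- dplyr::distinct(out, .data$instance_id, .data$track_id,
                         .keep_all = TRUE)
  dplyr::arrange(out, .data$instance_id, .data$track_id)
}

#' Greedy score-ordered matching for one frame
#'
#' Candidate pairs are sorted by score, lowest first (ties broken by
#' \eqn{M_L}, then instance id, then track id, for determinism) and
#' linked iteratively: a pair links only if neither its instance nor its
#' track has been linked in this frame already.
#'
#' @param candidates tibble from \code{\link{find_candidates}}.
#' @return Tibble of linked pairs: \code{instance_id}, \code{track_id}.
#' @export
link_frame <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(tibble::tibble(instance_id = integer(), track_id = integer()))
  }
  ord <- order(candidates$S, candidates$M_L, candidates$instance_id,
               candidates$track_id)
  used_i <- integer(); used_t <- integer()
  links <- list()
  for (k in ord) {
    ii <- candidates$instance_id[k]; tt <- candidates$track_id[k]
    if (ii %in% used_i || tt %in% used_t) next
    used_i <- c(used_i, ii); used_t <- c(used_t, tt)
    links[[length(links) + 1]] <- tibble::tibble(instance_id = ii,
                                                 track_id = tt)
  }
  dplyr::bind_rows(links)
}

#' Link filopodium instances across a movie into identity tracks
#'
#' Frames are processed in order. For each frame, candidates against the
#' tracks active inside the lookback window are scored and matched
#' greedily (\code{\link{find_candidates}}, \code{\link{link_frame}});
#' unmatched instances found new tracks. Tracks may carry gaps of up to
#' \code{lookback_frames - 1} frames.
#'
#' @param instances a \code{filo_instances} tibble covering all frames.
#' @param config a \code{\link{tracking_config}}.
#' @param frames frame range to process; defaults to the full span of
#'   \code{instances}.
#' @return A track table (class \code{filo_tracks}): one row per track
#'   with \code{track_id}, \code{birth_frame}, \code{last_frame},
#'   \code{lifetime_frames}, \code{max_length_um} and a nested \code{data}
#'   tibble of per-frame instances.
#' @export
track_movie <- function(instances, config = tracking_config(), frames = NULL) {
  calibration <- attr(instances, "calibration") %||% voxel_calibration(1, 1, 1, 1)
  if (nrow(instances) == 0) {
    return(build_track_table(
      tibble::tibble(track_id = integer(), frame = integer(),
                     instance_id = integer(), path = list()), calibration))
  }
  if (is.null(frames)) frames <- seq(min(instances$frame), max(instances$frame))
  long <- list()
  last_frame_of <- integer() # indexed by track id
  latest_row_of <- integer() # row index in `long` of each track's newest instance
  rows_of <- list()          # all row indices per track (for any-within-window)
  next_id <- 1L
  for (t in frames) {
    cur <- instances[instances$frame == t, ]
    active <- which(last_frame_of >= t - config$lookback_frames &
                      last_frame_of < t)
    history <- if (length(active)) {
      if (config$candidate_mode == "most-recent") {
        dplyr::bind_rows(lapply(active, function(tr) {
          r <- long[[latest_row_of[tr]]]
          tibble::tibble(track_id = tr, frame = r$frame, path = r$path,
                         length_um = r$length_um, direction = r$direction)
        }))
      } else {
        dplyr::bind_rows(lapply(active, function(tr) {
          rws <- rows_of[[tr]]
          rws <- rws[vapply(rws, function(k) long[[k]]$frame, numeric(1)) >=
                       t - config$lookback_frames]
          dplyr::bind_rows(lapply(rws, function(k) {
            r <- long[[k]]
            tibble::tibble(track_id = tr, frame = r$frame, path = r$path,
                           length_um = r$length_um, direction = r$direction)
          }))
        }))
      }
    } else NULL
    links <- if (is.null(history) || nrow(cur) == 0) {
      tibble::tibble(instance_id = integer(), track_id = integer())
    } else {
      link_frame(find_candidates(cur, history, config, calibration))
    }
    for (i in seq_len(nrow(cur))) {
      iid <- cur$instance_id[i]
      tr <- links$track_id[match(iid, links$instance_id)]
      if (is.na(tr)) { # newly created filopodium
        tr <- next_id
        next_id <- next_id + 1L
        rows_of[[tr]] <- integer()
      }
      long[[length(long) + 1]] <- list(track_id = tr, frame = t,
                                       instance_id = iid,
                                       path = list(cur$path[[i]]),
                                       length_um = cur$length_um[i],
                                       direction = list(cur$direction[[i]]))
      last_frame_of[tr] <- t
      latest_row_of[tr] <- length(long)
      rows_of[[tr]] <- c(rows_of[[tr]], length(long))
    }
  }
  long_tbl <- tibble::tibble(
    track_id = vapply(long, `[[`, integer(1), "track_id"),
    frame = vapply(long, function(r) as.integer(r$frame), integer(1)),
    instance_id = vapply(long, function(r) as.integer(r$instance_id), integer(1)),
    path = lapply(long, function(r) r$path[[1]])
  )
  build_track_table(long_tbl, calibration)
}

# Assemble the per-track table from long (track_id, frame, instance_id,
# path) rows; derived lengths and directions are always recomputed from
# the paths so that serialisation round-trips exactly.
build_track_table <- function(long, calibration) {
  calibration <- as_voxel_calibration(calibration)
  if (nrow(long) > 0) {
    long$length_um <- vapply(long$path, path_length_um, numeric(1), calibration)
    long$direction <- lapply(long$path, path_direction, calibration)
    long <- dplyr::arrange(long, .data$track_id, .data$frame)
    nested <- tidyr::nest(long, data = c("frame", "instance_id", "path",
                                         "length_um", "direction"))
    out <- dplyr::mutate(
      nested,
      birth_frame = purrr::map_int(.data$data, ~min(.x$frame)),
      last_frame = purrr::map_int(.data$data, ~max(.x$frame)),
      lifetime_frames = purrr::map_int(.data$data, nrow),
      max_length_um = purrr::map_dbl(.data$data, ~max(.x$length_um)))
    out <- dplyr::select(out, "track_id", "birth_frame", "last_frame",
                         "lifetime_frames", "max_length_um", "data")
    out <- dplyr::arrange(out, .data$track_id)
  } else {
    out <- tibble::tibble(track_id = integer(), birth_frame = integer(),
                          last_frame = integer(), lifetime_frames = integer(),
                          max_length_um = numeric(), data = list())
  }
  attr(out, "calibration") <- calibration
  class(out) <- c("filo_tracks", class(out))
  out
}

#' Flat per-track summary
#'
#' @param tracks a track table.
#' @return Tibble with one row per track and no nested columns.
#' @export
track_summary <- function(tracks) {
  tibble::as_tibble(tracks[c("track_id", "birth_frame", "last_frame",
                             "lifetime_frames", "max_length_um")])
}
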