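#' Synthetic movie configuration
#'
#' Parameters of the ground-truthed generator. The defaults emulate a
#' typical recording of an embryonic muscle tip: 60 frames at 15-s
#' intervals (a 15-minute window), 6 z-sections at 0.7 µm, 256x256
#' pixels at 0.08 µm (63x/1.4 NA confocal sampling), one bright
#' ellipsoidal cell body with up to 8 thin (~2-voxel apparent radius,
#' i.e. 0.16 µm lateral blur) filopodia growing and retracting from its
#' surface, maximum lengths 3–10 µm, on a noisy background with a
#' signal-to-noise ratio near 10.
#'
#' @param frames,slices,height,width stack dimensions (T, Z, Y, X).
#' @param calibration a \code{\link{voxel_calibration}}.
#' @param body list: \code{center} (z, y, x voxels; default mid-volume,
#'   x at 35\% width), \code{radii} (voxels), \code{intensity},
#'   \code{edge} (softness, voxels).
#' @param n_filopodia number of filopodia.
#' @param length_dist \code{"uniform"} (range \code{length_range}) or
#'   \code{"exponential"} (\code{length_offset} + Exp(\code{length_rate}))
#'   for the true maximum lengths (µm).
#' @param length_range,length_rate,length_offset parameters of the
#'   maximum-length distribution.
#' @param growth_um_per_frame elongation/retraction speed.
#' @param plateau_frames frames spent at maximum length.
#' @param tube_radius Gaussian cross-section sigma of a filopodium
#'   (xy pixels).
#' @param tube_sigma_z axial cross-section sigma (z-voxels), wider than
#'   the in-plane radius as in confocal optics.
#' @param tube_intensity peak intensity above background.
#' @param background,body_intensity,noise_sd intensity model; Gaussian
#'   noise, optionally Poisson (\code{poisson = TRUE}).
#' @param drift_px per-frame tip drift bound (pixels) from direction
#'   jitter.
#' @param bend_sd curvature scale of filopodium bending (1/µm).
#' @param min_visible_um filopodia shorter than this are neither rendered
#'   nor listed in the truth.
#' @param filopodia optional list of per-filopodium overrides, each a
#'   list with any of \code{anchor} (z, y, x voxels), \code{phi}
#'   (xy direction, radians), \code{psi} (elevation, radians),
#'   \code{max_length_um}, \code{birth}; when given, \code{n_filopodia}
#'   is its length.
#' @param branched render a short side branch halfway along each
#'   filopodium (exercises branch decomposition; the truth keeps the main
#'   path only).
#' @param seed RNG seed; a fixed seed makes the output bit-identical.
#' @return A list of class \code{filo_sim_config}.
#' @export
sim_config <- function(frames = 60L, slices = 6L, height = 256L, width = 256L,
                       calibration = voxel_calibration(dx = 0.08),
                       body = list(), n_filopodia = 8L,
                       length_dist = c("uniform", "exponential"),
                       length_range = c(3, 10), length_rate = 0.5,
                       length_offset = 3,
                       growth_um_per_frame = 0.5, plateau_frames = 4L,
                       tube_radius = 2, tube_sigma_z = 0.8,
                       tube_intensity = 190, background = 10,
                       body_intensity = 150, noise_sd = 19, poisson = FALSE,
                       drift_px = 2, bend_sd = 0.01, min_visible_um = 0.3,
                       filopodia = NULL, branched = FALSE, seed = 1L) {
  length_dist <- match.arg(length_dist)
  stopifnot(frames >= 1, slices >= 1, height > 8, width > 8,
            tube_radius >= 0.5, noise_sd >= 0, n_filopodia >= 0)
  body_def <- list(center = c((slices + 1) / 2, height / 2, width * 0.35),
                   radii = c(2.2, 55, 45), intensity = body_intensity,
                   edge = 1.5)
  body <- utils::modifyList(body_def, body)
  if (!is.null(filopodia)) n_filopodia <- length(filopodia)
  structure(list(frames = as.integer(frames), slices = as.integer(slices),
                 height = as.integer(height), width = as.integer(width),
                 calibration = as_voxel_calibration(calibration),
                 body = body, n_filopodia = as.integer(n_filopodia),
                 length_dist = length_dist, length_range = length_range,
                 length_rate = length_rate, length_offset = length_offset,
                 growth_um_per_frame = growth_um_per_frame,
                 plateau_frames = as.integer(plateau_frames),
                 tube_radius = tube_radius, tube_sigma_z = tube_sigma_z,
                 tube_intensity = tube_intensity, background = background,
                 noise_sd = noise_sd, poisson = poisson,
                 drift_px = drift_px, bend_sd = bend_sd,
                 min_visible_um = min_visible_um,
                 filopodia = filopodia, branched = branched,
                 seed = as.integer(seed)),
            class = "filo_sim_config")
}

# triangular growth profile: grow at `rate` to Lmax, dwell, retract
profile_length <- function(age, lmax, rate, plateau) {
  g <- max(1L, ceiling(lmax / rate))
  if (age < 0) return(0)
  if (age < g) return((age + 1) / g * lmax)
  if (age < g + plateau) return(lmax)
  lmax * max(0, 1 - (age - g - plateau + 1) / g)
}

#' Simulate a ground-truthed filopodia movie
#'
#' Rasterises a bright ellipsoidal cell body with thin, dynamic tubular
#' protrusions of known identity, length and direction (Gaussian
#' cross-section, anisotropy-aware) onto a noisy background, and records
#' the per-frame truth: centreline voxel path, analytic path length and
#' mean direction of every filopodium, plus the body mask. Deterministic
#' under a fixed seed. Trajectories leaving the volume are clipped and
#' flagged.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with elements \code{stack} (a
#'   \code{\link{timelapse_stack}}) and \code{truth} (class
#'   \code{filo_truth}: tibbles \code{instances} and \code{filopodia},
#'   the \code{body_mask}, and the calibration).
#' @export
simulate_movie <- function(config = sim_config()) {
  set.seed(config$seed)
  cal <- config$calibration
  Tn <- config$frames; Z <- config$slices; Y <- config$height; X <- config$width
  steps <- cal_steps(cal) # µm per index step (z, y, x)

  # --- body field and mask (static) ---
  cz <- config$body$center[1]; cyy <- config$body$center[2]; cxx <- config$body$center[3]
  rz <- config$body$radii[1]; ry <- config$body$radii[2]; rx <- config$body$radii[3]
  zi <- (seq_len(Z) - cz) / rz
  yi <- (seq_len(Y) - cyy) / ry
  xi <- (seq_len(X) - cxx) / rx
  rho <- sqrt(outer(outer(zi^2, yi^2, `+`), xi^2, `+`))
  body_field <- config$body$intensity / (1 + exp((rho - 1) * 8 / config$body$edge))
  body_mask <- rho <= 1

  # --- per-filopodium static draws ---
  nf <- config$n_filopodia
  draw_len <- function() switch(config$length_dist,
    uniform = runif(1, config$length_range[1], config$length_range[2]),
    exponential = config$length_offset + rexp(1, config$length_rate))
  filos <- vector("list", nf)
  # default anchors stratified around the tip: filopodia fan out rather
  # than stacking on one surface point
  phi_grid <- if (nf > 1) seq(-70, 70, length.out = nf) else 0
  phi_grid <- sample(phi_grid)
  for (i in seq_len(nf)) {
    ov <- if (!is.null(config$filopodia)) config$filopodia[[i]] else list()
    lmax <- ov$max_length_um %||% draw_len()
    phi <- ov$phi %||% ((phi_grid[i] + runif(1, -4, 4)) * pi / 180)
    psi <- ov$psi %||% (runif(1, -5, 5) * pi / 180)
    g <- max(1L, ceiling(lmax / config$growth_um_per_frame))
    life <- 2L * g + config$plateau_frames
    birth <- ov$birth %||% sample.int(max(1L, Tn - min(life, Tn - 2L)), 1)
    # unit direction in µm coordinates (z, y, x)
    u <- c(sin(psi), sin(phi) * cos(psi), cos(phi) * cos(psi))
    anchor <- ov$anchor
    if (is.null(anchor)) {
      # intersection of the ray from the body centre with the ellipsoid,
      # in index coordinates
      u_idx <- u / steps
      tt <- 1 / sqrt(sum((u_idx / c(rz, ry, rx))^2))
      anchor <- config$body$center + tt * u_idx
    }
    # bending: curvature in the xy-plane, perpendicular to u
    v <- c(0, -u[3], u[2]); nv <- sqrt(sum(v^2))
    v <- if (nv > 0) v / nv else c(0, 1, 0)
    filos[[i]] <- list(id = i, lmax = lmax, birth = birth, life = life,
                       phi = phi, psi = psi, u = u, v = v,
                       anchor = anchor, kappa = rnorm(1, 0, config$bend_sd),
                       jitter = rnorm(Tn, 0,
                                      config$drift_px * cal$dx / max(lmax, 1)))
  }

  sig_xy <- config$tube_radius
  sig_z <- config$tube_sigma_z
  rpx <- ceiling(3 * sig_xy); rz_st <- max(1L, ceiling(2.5 * sig_z))

  stamp <- function(field, pz, py, px, amp) {
    z0 <- max(1L, floor(pz) - rz_st); z1 <- min(Z, ceiling(pz) + rz_st)
    y0 <- max(1L, floor(py) - rpx); y1 <- min(Y, ceiling(py) + rpx)
    x0 <- max(1L, floor(px) - rpx); x1 <- min(X, ceiling(px) + rpx)
    if (z0 > z1 || y0 > y1 || x0 > x1) return(field)
    dz2 <- ((z0:z1 - pz) / sig_z)^2
    dy2 <- ((y0:y1 - py) / sig_xy)^2
    dx2 <- ((x0:x1 - px) / sig_xy)^2
    g <- amp * exp(-0.5 * (outer(outer(dz2, dy2, `+`), dx2, `+`)))
    sub <- field[z0:z1, y0:y1, x0:x1, drop = FALSE]
    field[z0:z1, y0:y1, x0:x1] <- pmax(sub, g)
    field
  }

  # polyline of filopodium f at arc lengths s (µm), in index coordinates
  polyline_idx <- function(f, s_vec, phi_t) {
    u <- c(sin(f$psi), sin(phi_t) * cos(f$psi), cos(phi_t) * cos(f$psi))
    pts_um <- outer(s_vec, u) + 0.5 * f$kappa * outer(s_vec^2, f$v)
    sweep(pts_um, 2, steps, `/`) +
      matrix(f$anchor, nrow = length(s_vec), ncol = 3, byrow = TRUE)
  }

  voxels <- array(0, dim = c(Tn, Z, Y, X))
  inst_rows <- list()
  clipped <- logical(nf)
  ds <- 0.05 # µm arc-length sampling step

  for (t in seq_len(Tn)) {
    field <- array(0, dim = c(Z, Y, X))
    for (f in filos) {
      age <- t - f$birth
      L <- profile_length(age, f$lmax, config$growth_um_per_frame,
                          config$plateau_frames)
      if (L < config$min_visible_um) next
      phi_t <- f$phi + sum(f$jitter[seq_len(t)])
      s_vec <- seq(0, L, by = ds)
      pts <- polyline_idx(f, s_vec, phi_t)
      inb <- pts[, 1] >= 1 & pts[, 1] <= Z & pts[, 2] >= 1 & pts[, 2] <= Y &
             pts[, 3] >= 1 & pts[, 3] <= X
      if (!all(inb)) {
        clipped[f$id] <- TRUE
        keep <- cumprod(inb) > 0 # clip at the first exit
        pts <- pts[keep, , drop = FALSE]
        if (nrow(pts) < 2) next
      }
      for (k in seq(1, nrow(pts), by = 10)) { # stamp every 0.5 px
        field <- stamp(field, pts[k, 1], pts[k, 2], pts[k, 3],
                       config$tube_intensity)
      }
      field <- stamp(field, pts[nrow(pts), 1], pts[nrow(pts), 2],
                     pts[nrow(pts), 3], config$tube_intensity)
      if (config$branched && L > 2) {
        mid <- pts[floor(nrow(pts) / 2), ]
        bphi <- phi_t + 40 * pi / 180
        bu <- c(0, sin(bphi), cos(bphi)) / steps
        bl <- 0.3 * L
        for (s in seq(0, bl, by = 10 * ds)) {
          p <- mid + s * bu
          if (p[1] >= 1 && p[1] <= Z && p[2] >= 1 && p[2] <= Y &&
              p[3] >= 1 && p[3] <= X) {
            field <- stamp(field, p[1], p[2], p[3], config$tube_intensity)
          }
        }
      }
      # truth: 0-based voxel path, deduplicated, analytic length
      vox <- round(pts) - 1
      if (nrow(vox) > 1) {
        dup <- c(FALSE, rowSums(abs(diff(vox)) != 0) == 0)
        vox <- vox[!dup, , drop = FALSE]
      }
      if (nrow(vox) < 2) next # sub-voxel stub: nothing to record
      seg_d <- sweep(diff(pts), 2, steps, `*`)
      inst_rows[[length(inst_rows) + 1]] <- tibble::tibble(
        frame = t, id = f$id, path = list(path_matrix(vox)),
        length_um = sum(sqrt(rowSums(seg_d^2))))
    }
    img <- config$background + pmax(body_field, field)
    if (config$noise_sd > 0) img <- img + rnorm(length(img), 0, config$noise_sd)
    if (config$poisson) img <- img + (stats::rpois(length(img), pmax(img, 0)) - img)
    voxels[t, , , ] <- pmax(img, 0)
  }

  instances <- if (length(inst_rows)) dplyr::bind_rows(inst_rows) else
    tibble::tibble(frame = integer(), id = integer(), path = list(),
                   length_um = numeric())
  filopodia <- tibble::tibble(
    id = vapply(filos, function(f) as.integer(f$id), integer(1)),
    max_length_um = vapply(filos, `[[`, numeric(1), "lmax"),
    birth = vapply(filos, function(f) as.integer(f$birth), integer(1)),
    lifetime = vapply(filos, function(f) as.integer(f$life), integer(1)),
    clipped = clipped)
  truth <- structure(list(instances = instances, filopodia = filopodia,
                          body_mask = body_mask, calibration = cal),
                     class = "filo_truth")
  list(stack = timelapse_stack(voxels, cal), truth = truth)
}

#' Convert generator truth to filopodium instances
#'
#' Builds a \code{filo_instances} tibble from the true centreline voxel
#' paths (lengths and directions recomputed from the rasterised paths,
#' exactly as the detection pipeline would report them), e.g. to feed the
#' tracker with perfect detections.
#'
#' @param truth a \code{filo_truth}.
#' @return A \code{filo_instances} tibble; instance ids equal true ids.
#' @export
truth_to_instances <- function(truth) {
  cal <- truth$calibration
  rows <- purrr::pmap(truth$instances, function(frame, id, path, length_um) {
    instance_row(frame, id, path, cal,
                 frame_anchor(truth$body_mask, list(path)))
  })
  res <- if (length(rows)) dplyr::bind_rows(rows) else apply_edits(segment_table())
  res <- dplyr::arrange(res, .data$frame, .data$instance_id)
  attr(res, "calibration") <- cal
  class(res) <- unique(c("filo_instances", class(res)))
  res
}

coverage_frac <- function(a, b, radius) {
  # fraction of rows of a within `radius` of some row of b (index space)
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  mean(.rows_min_dist(a * 1.0, b * 1.0, c(1, 1, 1)) <= radius)
}

#' Score reconstructed tracks against generator truth
#'
#' Per-frame detection recall and precision by centreline-coverage
#' matching, identity accuracy over linked frame pairs, and per-filopodium
#' maximum-length error statistics.
#'
#' A truth filopodium counts as recovered in a frame when at least half of
#' its centreline voxels lie within \code{match_radius} of a single
#' detected instance; a detected instance counts as a true detection when
#' at least half its voxels lie near any truth centreline. Identity
#' accuracy is the fraction of consecutive same-track instance pairs whose
#' best-covering truth ids agree. Length errors compare each truth
#' filopodium's maximum rasterised-centreline length with the largest
#' detected-instance length attributed to it (by coverage), so they
#' measure length reconstruction independently of linking mistakes —
#' identity errors are reported separately as \code{identity_accuracy}.
#'
#' @param tracks a track table.
#' @param truth a \code{filo_truth} with the same calibration.
#' @param match_radius matching radius in voxels.
#' @param eval_min_length_um truth filopodia are evaluated in frames
#'   where their current length reaches this bound (default 3 µm, the
#'   quantification cut-off below which reconstruction is known to be
#'   noisy).
#' @return One-row tibble: \code{recall}, \code{precision},
#'   \code{identity_accuracy}, \code{length_bias_um},
#'   \code{length_rmse_um}, and supporting counts.
#' @export
score_against_truth <- function(tracks, truth, match_radius = 3,
                                eval_min_length_um = 3) {
  cal_t <- attr(tracks, "calibration")
  if (!is.null(cal_t) &&
      any(abs(unlist(cal_t) - unlist(truth$calibration)) > 1e-9)) {
    abort("tracks and truth have different calibrations")
  }
  cal <- truth$calibration
  det <- if (nrow(tracks)) tidyr::unnest(tracks[c("track_id", "data")], "data")
         else tibble::tibble(track_id = integer(), frame = integer(),
                             path = list())
  tr_len <- dplyr::mutate(truth$instances,
                          raster_um = vapply(.data$path, path_length_um,
                                             numeric(1), cal))
  frames <- sort(unique(tr_len$frame))
  n_truth <- 0L; n_recovered <- 0L
  n_det <- 0L; n_det_true <- 0L
  det$truth_id <- NA_integer_
  for (f in frames) {
    tf <- tr_len[tr_len$frame == f, ]
    dfr <- which(det$frame == f)
    truth_all <- do.call(rbind, tf$path)
    for (k in dfr) {
      n_det <- n_det + 1L
      if (!is.null(truth_all) &&
          coverage_frac(det$path[[k]], truth_all, match_radius) >= 0.5) {
        n_det_true <- n_det_true + 1L
      }
      covs <- vapply(tf$path, function(tp)
        coverage_frac(det$path[[k]], tp, match_radius), numeric(1))
      if (length(covs) && max(covs) >= 0.5) {
        det$truth_id[k] <- tf$id[which.max(covs)]
      }
    }
    tf_eval <- tf[tf$raster_um >= eval_min_length_um, ]
    for (i in seq_len(nrow(tf_eval))) {
      n_truth <- n_truth + 1L
      covered <- any(vapply(dfr, function(k)
        coverage_frac(tf_eval$path[[i]], det$path[[k]], match_radius) >= 0.5,
        logical(1)))
      if (covered) n_recovered <- n_recovered + 1L
    }
  }
  # also count detections in frames without any truth as false positives
  extra <- det$frame[!det$frame %in% frames]
  n_det <- n_det + length(extra)

  # identity accuracy over consecutive linked pairs
  pairs_total <- 0L; pairs_correct <- 0L
  for (tr in unique(det$track_id)) {
    rows <- det[det$track_id == tr, ]
    rows <- rows[order(rows$frame), ]
    ids <- rows$truth_id
    for (i in seq_len(nrow(rows) - 1)) {
      if (is.na(ids[i]) || is.na(ids[i + 1])) next
      pairs_total <- pairs_total + 1L
      if (ids[i] == ids[i + 1]) pairs_correct <- pairs_correct + 1L
    }
  }
  # per-filopodium maximum-length errors (instance-level attribution)
  errs <- numeric(0)
  truth_max <- dplyr::summarise(dplyr::group_by(tr_len, .data$id),
                                max_um = max(.data$raster_um))
  truth_max <- truth_max[truth_max$max_um >= eval_min_length_um, ]
  for (i in seq_len(nrow(truth_max))) {
    mapped <- !is.na(det$truth_id) & det$truth_id == truth_max$id[i]
    if (!any(mapped)) next
    est <- max(det$length_um[mapped])
    errs <- c(errs, est - truth_max$max_um[i])
  }
  tibble::tibble(
    recall = if (n_truth) n_recovered / n_truth else NA_real_,
    precision = if (n_det) n_det_true / n_det else NA_real_,
    identity_accuracy = if (pairs_total) pairs_correct / pairs_total else NA_real_,
    length_bias_um = if (length(errs)) mean(errs) else NA_real_,
    length_rmse_um = if (length(errs)) sqrt(mean(errs^2)) else NA_real_,
    n_truth_instances = n_truth, n_detected_instances = n_det,
    n_identity_pairs = pairs_total, n_matched_filopodia = length(errs))
}
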