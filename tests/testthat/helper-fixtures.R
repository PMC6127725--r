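# Shared fixtures and independent oracles, built in code.

# solid circular tube along x: radius r voxels, spanning x0..x1
make_tube_mask <- function(dims = c(9, 11, 50), r = 2, x0 = 5, x1 = 44,
                           yc = 6, zc = 5) {
  m <- array(FALSE, dims)
  for (x in x0:x1) for (y in seq_len(dims[2])) for (z in seq_len(dims[1])) {
    if ((y - yc)^2 + (z - zc)^2 <= r^2) m[z, y, x] <- TRUE
  }
  m
}

make_ball_mask <- function(dims = c(21, 21, 21), r = 8, c0 = c(11, 11, 11)) {
  m <- array(FALSE, dims)
  for (x in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[1])) {
      if ((z - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2 <= r^2) m[z, y, x] <- TRUE
    }
  m
}

# analytic Gaussian-cross-section cylinder along x (intensity volume)
make_tube_volume <- function(dims = c(15, 31, 31), sigma = 1.5,
                             yc = 16, zc = 8) {
  v <- array(0, dims)
  for (z in seq_len(dims[1])) for (y in seq_len(dims[2])) {
    v[z, y, ] <- exp(-((y - yc)^2 + (z - zc)^2) / (2 * sigma^2))
  }
  v
}

make_blob_volume <- function(dims = c(15, 31, 31), sigma = 4,
                             c0 = c(8, 16, 16)) {
  v <- array(0, dims)
  for (x in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[1])) {
      v[z, y, x] <- exp(-((z - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2) /
                          (2 * sigma^2))
    }
  v
}

# independent connected-component labelling + size filter (26-neighbourhood)
oracle_remove_small <- function(mask, min_vox) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(mask)
  for (i in idx) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      z <- (v - 1) %% d[1] + 1
      y <- ((v - 1) %/% d[1]) %% d[2] + 1
      x <- (v - 1) %/% (d[1] * d[2]) + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        nz <- z + dz; ny <- y + dy; nx <- x + dx
        if (nz < 1 || nz > d[1] || ny < 1 || ny > d[2] ||
            nx < 1 || nx > d[3]) next
        w <- nz + d[1] * (ny - 1) + d[1] * d[2] * (nx - 1)
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0L])
  out <- array(FALSE, d)
  if (cur > 0) out[lab > 0L & sizes[pmax(lab, 1L)] >= min_vox] <- TRUE
  out
}

# independent greedy matching: sort by score (lowest first) and link
oracle_link <- function(cand) {
  cand <- cand[order(cand$S, cand$M_L, cand$instance_id, cand$track_id), ]
  used_i <- c(); used_t <- c(); out <- NULL
  for (k in seq_len(nrow(cand))) {
    if (cand$instance_id[k] %in% used_i || cand$track_id[k] %in% used_t) next
    used_i <- c(used_i, cand$instance_id[k])
    used_t <- c(used_t, cand$track_id[k])
    out <- rbind(out, cand[k, c("instance_id", "track_id")])
  }
  out
}

# brute-force min distance between all voxel pairs of two paths
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  }
  best
}

# a straight-line voxel path along a given axis direction
straight_path <- function(n, origin = c(0, 0, 0), step = c(0, 0, 1)) {
  t(vapply(seq_len(n) - 1, function(i) origin + i * step, numeric(3)))
}

# instances tibble built through the public segment/edit route
instances_from_paths <- function(frame, paths,
                                 calibration = voxel_calibration(1, 1, 1, 1)) {
  segs <- segment_table(frame = rep(frame, length(paths)),
                        segment_id = seq_along(paths), path = paths)
  apply_edits(segs, calibration = calibration)
}

# minimal per-track table for quantification tests
toy_tracks <- function(max_length_um, lifetime_frames) {
  tibble::tibble(track_id = seq_along(max_length_um),
                 birth_frame = 1L,
                 last_frame = as.integer(lifetime_frames),
                 lifetime_frames = as.integer(lifetime_frames),
                 max_length_um = max_length_um)
}
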