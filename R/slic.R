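# Greyscale SLIC clustering on a single 2D plane.
#
# Standard k-means in (intensity, y, x) feature space with the spatial
# term scaled by compactness / S (S = expected cluster spacing), without
# connectivity enforcement. Intensities are rescaled to [0, 100] so the
# compactness values customary for 8-bit-ish images keep their meaning:
# with few clusters the intensity term dominates and the partition acts
# as a noise-robust multi-level threshold, which is what the foreground
# extraction steps rely on.
#
# Returns an integer label matrix (1..k); a constant plane returns all 0
# (no labels assigned).
slic_gray <- function(img, k, compactness, max_iter = 10) {
  rng <- range(img)
  if (!is.finite(rng[1]) || !is.finite(rng[2])) {
    abort("image intensities must be finite")
  }
  if (rng[2] <= rng[1]) {
    return(matrix(0L, nrow(img), ncol(img)))
  }
  I <- (img - rng[1]) / (rng[2] - rng[1]) * 100
  ny_img <- nrow(img); nx_img <- ncol(img)
  n <- ny_img * nx_img
  S <- sqrt(n / k)

  # seed centres evenly across the intensity range (a regular spatial grid
  # collapses to spatial tiles when bright structures occupy a tiny
  # fraction of the plane); spatial seeds at the centroid of each seed's
  # nearest-intensity pixels
  yy <- matrix(rep(seq_len(ny_img), nx_img), ny_img, nx_img)
  xx <- matrix(rep(seq_len(nx_img), each = ny_img), ny_img, nx_img)
  cI <- (seq_len(k) - 0.5) / k * 100
  seed_lab <- pmin(pmax(ceiling(I / 100 * k), 1L), k)
  cy <- numeric(k); cx <- numeric(k)
  for (j in seq_len(k)) {
    sel <- seed_lab == j
    if (any(sel)) {
      cy[j] <- mean(yy[sel]); cx[j] <- mean(xx[sel])
      cI[j] <- mean(I[sel])
    } else {
      cy[j] <- (ny_img + 1) / 2; cx[j] <- (nx_img + 1) / 2
    }
  }

  m2 <- (compactness / S)^2
  lab <- matrix(1L, ny_img, nx_img)
  for (it in seq_len(max_iter)) {
    best <- matrix(Inf, ny_img, nx_img)
    for (j in seq_len(k)) {
      d <- (I - cI[j])^2 + m2 * ((yy - cy[j])^2 + (xx - cx[j])^2)
      upd <- d < best
      best[upd] <- d[upd]
      lab[upd] <- j
    }
    moved <- 0
    for (j in seq_len(k)) {
      sel <- lab == j
      if (!any(sel)) next
      nI <- mean(I[sel]); nyc <- mean(yy[sel]); nxc <- mean(xx[sel])
      moved <- moved + abs(nI - cI[j]) + abs(nyc - cy[j]) + abs(nxc - cx[j])
      cI[j] <- nI; cy[j] <- nyc; cx[j] <- nxc
    }
    if (moved < 1e-6) break
  }
  lab
}
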