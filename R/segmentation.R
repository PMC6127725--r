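#' Segmentation configuration
#'
#' Parameters of the per-frame foreground / cell-body / vesselness stages.
#' Defaults follow the reference pipeline for confocal recordings of
#' myotube tips: 3 superpixel labels, aggressive blur (sigma 5 px),
#' adaptive thresholding over a 999-pixel Gaussian-weighted neighbourhood
#' (clamped to the image), erosion with a 5-pixel disk, superpixel
#' compactness 10 on the vesselness output, and removal of 3D regions
#' under 200 voxels.
#'
#' @param slic_labels number of superpixel clusters (k).
#' @param blur_sigma Gaussian blur sigma (pixels) for body detection.
#' @param adaptive_block side of the Gaussian-weighted neighbourhood
#'   (pixels, odd); clamped to the largest odd size that fits the image.
#' @param adaptive_offset_frac threshold offset as a fraction of the
#'   blurred plane's intensity range; guards against flat background noise
#'   crossing a zero-offset adaptive threshold.
#' @param erosion_radius disk radius (pixels) eroding the body mask.
#' @param body_open_radius disk radius of a binary opening applied to the
#'   thresholded body mask before erosion; removes blurred filopodial
#'   ridges (whose thresholded width is about four blur sigmas) while
#'   leaving the much wider cell body intact. Defaults to twice
#'   \code{blur_sigma}.
#' @param closing_radius ball radius (voxels) of the 3D binary closing
#'   that heals broken lines in the vesselness mask.
#' @param min_region_voxels 3D connected regions with fewer voxels are
#'   discarded.
#' @param prune_spur_vox skeleton side branches of at most this many
#'   voxels are pruned during segment extraction (0 disables).
#' @param slic_compactness compactness of the vesselness-output
#'   superpixels.
#' @param background how background superpixel labels are chosen:
#'   \code{"contrast"} (default) keeps only labels whose mean intensity
#'   exceeds the dimmest label's mean by \code{bright_frac} of the
#'   label-mean spread — on fluorescence frames this retains the cell and
#'   its protrusions while rejecting clusters that merely split the
#'   background noise; \code{"lowest-mean"} drops only the single dimmest
#'   label; \code{"none"} keeps every labelled pixel.
#' @param bright_frac bright-line label selection on the vesselness
#'   output: a label is foreground when its mean vesselness exceeds the
#'   lowest label mean by this fraction of the spread between the lowest
#'   and highest label means. Separates genuine ridge labels from
#'   low-score clusters that merely partition the noise floor.
#' @param min_vesselness absolute floor on the mean vesselness of a
#'   foreground label; frames containing no tubular structure then
#'   produce an empty mask instead of promoting their noise ceiling.
#' @param scales Gaussian-derivative scales (xy pixels) of the Hessian.
#' @param alpha,beta,c vesselness exponential weights; \code{c = NA}
#'   resolves per scale to half the maximum Hessian Frobenius norm.
#' @param anisotropy scale z-derivatives by the voxel aspect ratio
#'   (dz/dx) when a calibration is available.
#' @return A list of class \code{filo_seg_config}.
#' @export
segmentation_config <- function(slic_labels = 3L, blur_sigma = 5,
                                adaptive_block = 999L,
                                adaptive_offset_frac = 0.1,
                                erosion_radius = 5L,
                                body_open_radius = NULL,
                                closing_radius = 1L,
                                min_region_voxels = 200L,
                                prune_spur_vox = 6L,
                                slic_compactness = 10,
                                background = c("contrast", "lowest-mean",
                                               "none"),
                                bright_frac = 0.25, min_vesselness = 0.05,
                                scales = c(1, 1.5, 2),
                                alpha = 0.5, beta = 0.5, c = NA,
                                anisotropy = FALSE) {
  background <- match.arg(background)
  if (is.null(body_open_radius)) body_open_radius <- ceiling(2 * blur_sigma)
  stopifnot(slic_labels >= 2, blur_sigma > 0, adaptive_block >= 1,
            adaptive_block %% 2 == 1, erosion_radius >= 1,
            body_open_radius >= 0,
            closing_radius >= 0, min_region_voxels >= 1,
            slic_compactness > 0, bright_frac >= 0, bright_frac < 1,
            min_vesselness >= 0, min_vesselness < 1,
            length(scales) >= 1, all(scales > 0),
            alpha > 0, beta > 0, is.na(c) || c > 0)
  structure(list(slic_labels = as.integer(slic_labels),
                 blur_sigma = blur_sigma,
                 adaptive_block = as.integer(adaptive_block),
                 adaptive_offset_frac = adaptive_offset_frac,
                 erosion_radius = as.integer(erosion_radius),
                 body_open_radius = as.integer(body_open_radius),
                 closing_radius = as.integer(closing_radius),
                 min_region_voxels = as.integer(min_region_voxels),
                 prune_spur_vox = as.integer(prune_spur_vox),
                 slic_compactness = slic_compactness,
                 background = background, bright_frac = bright_frac,
                 min_vesselness = min_vesselness,
                 scales = scales, alpha = alpha, beta = beta, c = c,
                 anisotropy = anisotropy),
            class = "filo_seg_config")
}

as_volume <- function(x) {
  if (is.matrix(x)) array(x, dim = c(1L, nrow(x), ncol(x))) else x
}

# separable Gaussian smoothing of a (Z, Y, X) volume, per-axis sigmas
gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,
         "2" = (x^2 - sigma^2) / sigma^4 * g)
}

smooth_gauss <- function(vol, sigma_zyx) {
  d <- dim(vol)
  for (ax in 0:2) {
    if (d[ax + 1] > 1 && sigma_zyx[ax + 1] > 0) {
      vol <- .conv_axis(vol, d, gauss_kernel(sigma_zyx[ax + 1]), ax)
    }
  }
  vol
}

disk_offsets <- function(r) {
  g <- expand.grid(dz = 0L, dy = -r:r, dx = -r:r)
  as.matrix(g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE])
}

ball_offsets <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  as.matrix(g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE])
}

#' Superpixel foreground extraction
#'
#' Clusters each z-plane into a small number of superpixel labels (SLIC
#' without connectivity enforcement) and calls every pixel outside the
#' background label foreground. With the default three labels this acts
#' as a noise-robust multi-level threshold able to resolve thin
#' filopodia.
#'
#' @param frame single-frame volume (Z, Y, X) or 2D matrix.
#' @param config a \code{\link{segmentation_config}}.
#' @return Logical mask with the shape of \code{frame}.
#' @export
segment_pixels <- function(frame, config = segmentation_config()) {
  was2d <- is.matrix(frame)
  vol <- as_volume(frame)
  if (any(!is.finite(vol))) abort("frame intensities must be finite")
  d <- dim(vol)
  out <- array(FALSE, d)
  degenerate <- TRUE
  for (z in seq_len(d[1])) {
    plane <- matrix(vol[z, , ], d[2], d[3])
    lab <- slic_gray(plane, config$slic_labels, config$slic_compactness)
    if (all(lab == 0L)) next # constant plane: all background
    degenerate <- FALSE
    if (config$background == "none") {
      out[z, , ] <- lab > 0L
    } else {
      means <- vapply(seq_len(max(lab)),
                      function(j) mean(plane[lab == j]), numeric(1))
      means[!is.finite(means)] <- min(means[is.finite(means)])
      fg_labels <- if (config$background == "lowest-mean") {
        setdiff(seq_along(means), which.min(means))
      } else { # contrast
        cut <- min(means) + config$bright_frac * (max(means) - min(means))
        which(means > cut)
      }
      out[z, , ] <- lab %in% fg_labels
    }
  }
  if (degenerate) warn("constant frame: returning all-background mask")
  if (was2d) matrix(out[1, , ], d[2], d[3]) else out
}

#' Cell-body mask
#'
#' Identifies the bright cell interior so that skeleton parts inside it
#' can be discarded: per z-plane, aggressive Gaussian blurring, adaptive
#' thresholding against a large Gaussian-weighted neighbourhood mean, and
#' erosion with a disk stencil.
#'
#' @inheritParams segment_pixels
#' @return Logical mask with the shape of \code{frame}.
#' @export
find_cell_body <- function(frame, config = segmentation_config()) {
  was2d <- is.matrix(frame)
  vol <- as_volume(frame)
  d <- dim(vol)
  block <- min(config$adaptive_block, d[2], d[3])
  if (block %% 2 == 0) block <- block - 1L
  sigma_local <- max((block - 1) / 6, 1)
  out <- array(FALSE, d)
  ds <- max(1L, floor(sigma_local / 6)) # decimation for the wide local mean
  for (z in seq_len(d[1])) {
    plane <- array(vol[z, , ], dim = c(1L, d[2], d[3]))
    blurred <- smooth_gauss(plane, c(0, config$blur_sigma, config$blur_sigma))
    if (ds > 1L) {
      yi <- seq(1L, d[2], by = ds); xi <- seq(1L, d[3], by = ds)
      small <- array(blurred[1, yi, xi], dim = c(1L, length(yi), length(xi)))
      small <- smooth_gauss(small, c(0, sigma_local / ds, sigma_local / ds))
      local_mean <- small[1, ceiling(seq_len(d[2]) / ds),
                          ceiling(seq_len(d[3]) / ds)]
    } else {
      local_mean <- smooth_gauss(blurred, c(0, sigma_local, sigma_local))[1, , ]
    }
    offset <- config$adaptive_offset_frac * diff(range(blurred))
    out[z, , ] <- blurred[1, , ] > local_mean + offset
  }
  if (config$body_open_radius > 0) {
    op <- disk_offsets(config$body_open_radius)
    out <- .morph3d(.morph3d(out, d, op, FALSE), d, op, TRUE)
  }
  out <- .morph3d(out, d, disk_offsets(config$erosion_radius), FALSE)
  if (was2d) matrix(out[1, , ], d[2], d[3]) else out
}

#' Hessian eigenvalues of a volume
#'
#' Gaussian-derivative Hessian at one scale, eigenvalues ordered by
#' absolute value per voxel, plus the tubularity ratios
#' \eqn{r_a = |\lambda_2|/|\lambda_3|},
#' \eqn{r_b = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}} and the Frobenius
#' norm \eqn{s}. The Hessian is gamma-normalised (multiplied by scale^2)
#' so responses are comparable across scales; z-derivatives are taken in
#' units of xy pixels when \code{anisotropy} and a calibration are given,
#' so that the strong axial anisotropy of confocal stacks does not
#' distort the eigenvalues.
#'
#' @param volume 3D array (Z, Y, X) with Z >= 3.
#' @param scale Gaussian scale in xy pixels.
#' @param calibration optional \code{\link{voxel_calibration}}.
#' @param anisotropy apply the dz/dx correction to z-derivatives.
#' @return List of class \code{filo_hessian_eigs} with per-voxel arrays
#'   \code{lam1}, \code{lam2}, \code{lam3}, \code{ra}, \code{rb}, \code{s}.
#' @export
hessian_eigenvalues <- function(volume, scale = 1,
                                calibration = NULL, anisotropy = TRUE) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3) abort("volume must be a 3D (Z, Y, X) array")
  if (d[1] < 3) {
    abort("Z < 3: too few slices for a 3D Hessian; analyse planes in 2D instead")
  }
  zscale <- if (anisotropy && !is.null(calibration)) {
    calibration$dz / calibration$dx
  } else 1
  sig <- c(max(scale / zscale, 0.7), scale, scale) # index-space sigmas (z,y,x)
  mode(volume) <- "double"

  deriv <- function(orders) { # orders along (z, y, x)
    v <- volume
    for (ax in 0:2) {
      v <- .conv_axis(v, d, gauss_kernel(sig[ax + 1], orders[ax + 1]), ax)
    }
    # convert z-derivatives from index units to xy-pixel units, then
    # gamma-normalise
    v * zscale^(-orders[1]) * scale^2
  }
  hzz <- deriv(c(2, 0, 0)); hyy <- deriv(c(0, 2, 0)); hxx <- deriv(c(0, 0, 2))
  hzy <- deriv(c(1, 1, 0)); hzx <- deriv(c(1, 0, 1)); hyx <- deriv(c(0, 1, 1))
  e <- .hessian_eigs(hzz, hyy, hxx, hzy, hzx, hyx)
  lam1 <- array(e$lam1, d); lam2 <- array(e$lam2, d); lam3 <- array(e$lam3, d)
  ra <- array(0, d); nz <- abs(lam3) > 0
  ra[nz] <- abs(lam2[nz]) / abs(lam3[nz])
  rb <- array(0, d); nz2 <- abs(lam2 * lam3) > 0
  rb[nz2] <- abs(lam1[nz2]) / sqrt(abs(lam2[nz2] * lam3[nz2]))
  s <- sqrt(lam1^2 + lam2^2 + lam3^2)
  structure(list(lam1 = lam1, lam2 = lam2, lam3 = lam3,
                 ra = ra, rb = rb, s = s, scale = scale),
            class = "filo_hessian_eigs")
}

#' Vesselness measure from Hessian eigenvalues
#'
#' Frangi-type tubularity score for bright curvilinear structures:
#' \deqn{V = (1 - e^{-r_a^2/2\alpha^2}) \; e^{-r_b^2/2\beta^2} \;
#'           (1 - e^{-s^2/2c^2})}
#' set to zero wherever \eqn{\lambda_2 > 0} or \eqn{\lambda_3 > 0} (a
#' bright tube has two strongly negative principal curvatures). Bounded
#' in [0, 1].
#'
#' @param eigs a \code{\link{hessian_eigenvalues}} result.
#' @param alpha,beta,c exponential weights; \code{c = NA} resolves to half
#'   the maximum Frobenius norm of the Hessian over the volume.
#' @return Numeric array of vesselness scores in [0, 1].
#' @export
vesselness <- function(eigs, alpha = 0.5, beta = 0.5, c = NA) {
  stopifnot(inherits(eigs, "filo_hessian_eigs"), alpha > 0, beta > 0,
            is.na(c) || c > 0)
  if (is.na(c)) c <- max(eigs$s) / 2
  if (!is.finite(c) || c <= 0) return(array(0, dim(eigs$s)))
  v <- (1 - exp(-eigs$ra^2 / (2 * alpha^2))) *
       exp(-eigs$rb^2 / (2 * beta^2)) *
       (1 - exp(-eigs$s^2 / (2 * c^2)))
  v[eigs$lam2 > 0 | eigs$lam3 > 0] <- 0
  v
}

#' Multi-scale vesselness of one frame
#'
#' Computes \code{\link{vesselness}} at each configured scale and takes
#' the per-voxel maximum.
#'
#' @param volume 3D array (Z, Y, X).
#' @param config a \code{\link{segmentation_config}}.
#' @param calibration optional \code{\link{voxel_calibration}}.
#' @return Numeric array of vesselness scores.
#' @export
frangi_filter <- function(volume, config = segmentation_config(),
                          calibration = NULL) {
  out <- NULL
  for (s in config$scales) {
    e <- hessian_eigenvalues(volume, s, calibration, config$anisotropy)
    v <- vesselness(e, config$alpha, config$beta, config$c)
    out <- if (is.null(out)) v else pmax(out, v)
  }
  out
}

#' Segment the vesselness output
#'
#' Superpixel clustering (compactness per configuration) of each plane of
#' the vesselness field identifies the bright-line labels; a 3D binary
#' closing then heals broken lines.
#'
#' @param vfield vesselness array (Z, Y, X).
#' @param config a \code{\link{segmentation_config}}.
#' @return Logical mask.
#' @export
segment_vesselness <- function(vfield, config = segmentation_config()) {
  vol <- as_volume(vfield)
  d <- dim(vol)
  out <- array(FALSE, d)
  for (z in seq_len(d[1])) {
    plane <- matrix(vol[z, , ], d[2], d[3])
    lab <- slic_gray(plane, config$slic_labels, config$slic_compactness)
    if (all(lab == 0L)) next
    means <- vapply(seq_len(max(lab)),
                    function(j) mean(plane[lab == j]), numeric(1))
    means[!is.finite(means)] <- min(means[is.finite(means)])
    cut <- max(min(means) + config$bright_frac * (max(means) - min(means)),
               config$min_vesselness)
    bright <- which(means > cut)
    out[z, , ] <- lab %in% bright
  }
  if (config$closing_radius > 0 && any(out)) {
    off <- ball_offsets(config$closing_radius)
    out <- .morph3d(.morph3d(out, d, off, TRUE), d, off, FALSE)
  }
  out
}

#' Remove small 3D connected regions
#'
#' Drops 26-connected regions with fewer than \code{min_region_voxels}
#' voxels; this operates on the whole z-stack of a frame, hence the
#' relatively high default of 200.
#'
#' @param mask logical 3D mask.
#' @param min_region_voxels regions strictly smaller than this are removed.
#' @return Logical mask of the same shape.
#' @export
remove_small_objects <- function(mask, min_region_voxels = 200L) {
  d <- dim(mask)
  if (!any(mask)) return(mask)
  lab <- .label_components(mask, d, 26L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= min_region_voxels
  out <- array(lab > 0L & keep[pmax(lab, 1L)], d)
  out
}
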