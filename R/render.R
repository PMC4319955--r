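## Synthetic confocal renderer: chromatin blobs, dextran influx, and
## kinetochore spots with Gaussian PSF, Poisson shot noise and Gaussian
## read noise. Stands in for real 3D+t acquisitions in image-level tests.

# separable Gaussian blur of a 3D array (z, y, x); sigma in voxels per axis
gauss_blur3 <- function(a, sigma_vox) {
  d <- dim(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    out <- array(0, d)
    n <- d[axis]
    for (off in -half:half) {    # zero-padded convolution along `axis`
      dst <- which(seq_len(n) + off >= 1 & seq_len(n) + off <= n)
      src <- dst + off
      w <- k[off + half + 1]
      if (axis == 1) {
        out[dst, , ] <- out[dst, , ] + w * a[src, , ]
      } else if (axis == 2) {
        out[, dst, ] <- out[, dst, ] + w * a[, src, ]
      } else {
        out[, , dst] <- out[, , dst] + w * a[, , src]
      }
    }
    a <- out
  }
  a
}

#' Default rendering parameters
#'
#' @param voxel_size_um Voxel size (z, y, x) in um.
#' @param shape Stack shape (z, y, x) in voxels.
#' @param psf_sigma_um PSF sigma (isotropic, um); 0 disables blurring.
#' @param photon_scale Photons per intensity unit for shot noise.
#' @param read_noise_sd Gaussian read noise SD (intensity units).
#' @param noise Master switch; `FALSE` renders the noiseless expectation.
#' @return Named list of parameters.
#' @export
render_params <- function(voxel_size_um = c(1, 0.5, 0.5),
                          shape = c(16, 64, 64),
                          psf_sigma_um = 0.3,
                          photon_scale = 100,
                          read_noise_sd = 0.5,
                          noise = TRUE) {
  list(voxel_size_um = voxel_size_um, shape = shape,
       psf_sigma_um = psf_sigma_um, photon_scale = photon_scale,
       read_noise_sd = read_noise_sd, noise = noise)
}

# rasterize a union of spheres into a (z,y,x) array (1 inside, 0 outside)
rasterize_spheres <- function(centers, radii, shape, voxel_size_um) {
  a <- array(0, shape)
  co <- lapply(1:3, function(ax) (seq_len(shape[ax]) - 0.5) *
                 voxel_size_um[ax])
  for (i in seq_len(nrow(centers))) {
    dz2 <- (co[[1]] - centers[i, 1])^2
    dy2 <- (co[[2]] - centers[i, 2])^2
    dx2 <- (co[[3]] - centers[i, 3])^2
    r2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
    a[r2 <= radii[i]^2] <- 1
  }
  a
}

# place Gaussian spots (amplitude at center) into a (z,y,x) array
rasterize_spots <- function(centers, amplitudes, sigma_um, shape,
                            voxel_size_um) {
  a <- array(0, shape)
  co <- lapply(1:3, function(ax) (seq_len(shape[ax]) - 0.5) *
                 voxel_size_um[ax])
  for (i in seq_len(nrow(centers))) {
    gz <- exp(-(co[[1]] - centers[i, 1])^2 / (2 * sigma_um^2))
    gy <- exp(-(co[[2]] - centers[i, 2])^2 / (2 * sigma_um^2))
    gx <- exp(-(co[[3]] - centers[i, 3])^2 / (2 * sigma_um^2))
    a <- a + amplitudes[i] * outer(outer(gz, gy), gx)
  }
  a
}

#' Render a three-channel scene
#'
#' Low-level renderer used by [render_stack()] and directly by tests:
#' channel 1 = chromatin (union of spherical blobs, blurred by the PSF),
#' channel 2 = dextran (uniform cytoplasm plus a nuclear sphere at the
#' stated influx fraction), channel 3 = spots (Gaussian kinetochore/MTOC
#' foci with per-spot amplitudes).
#'
#' @param chromatin_centers Matrix (z, y, x um) of blob centers (may have
#'   0 rows).
#' @param chromatin_volume_um3 Total chromatin volume; split equally over
#'   the blobs.
#' @param nucleus_center,nucleus_radius_um Nuclear sphere for the dextran
#'   channel.
#' @param dextran_fraction Nuclear dextran level as a fraction of the
#'   cytoplasmic plateau.
#' @param spot_centers Matrix (z, y, x um) of spot centers (may be NULL).
#' @param spot_amplitudes Per-spot amplitudes (recycled).
#' @param spot_sigma_um Spot Gaussian sigma.
#' @param params [render_params()].
#' @param time_min Time stamp for the stack.
#' @return A [voxel_stack()] with 3 channels.
#' @export
render_scene <- function(chromatin_centers, chromatin_volume_um3,
                         nucleus_center, nucleus_radius_um,
                         dextran_fraction,
                         spot_centers = NULL, spot_amplitudes = 1,
                         spot_sigma_um = 0.3,
                         params = render_params(), time_min = NA_real_) {
  shape <- params$shape
  vs <- params$voxel_size_um
  chrom <- array(0, shape)
  n_blob <- if (is.null(chromatin_centers)) 0 else nrow(chromatin_centers)
  if (n_blob > 0 && chromatin_volume_um3 > 0) {
    r <- (chromatin_volume_um3 / n_blob * 3 / (4 * pi))^(1 / 3)
    chrom <- 100 * rasterize_spheres(chromatin_centers,
                                     rep(r, n_blob), shape, vs)
  }
  dex <- array(0.2 * 100, shape)   # cytoplasm baseline
  nuc <- rasterize_spheres(rbind(nucleus_center), nucleus_radius_um,
                           shape, vs)
  dex <- dex + 100 * dextran_fraction * nuc
  spots <- array(0, shape)
  if (!is.null(spot_centers) && nrow(rbind(spot_centers)) > 0) {
    sc <- rbind(spot_centers)
    spots <- 100 * rasterize_spots(sc,
                                   rep_len(spot_amplitudes, nrow(sc)),
                                   spot_sigma_um, shape, vs)
  }
  if (params$psf_sigma_um > 0) {
    sig_vox <- params$psf_sigma_um / vs
    chrom <- gauss_blur3(chrom, sig_vox)
    dex <- gauss_blur3(dex, sig_vox)
  }
  if (isTRUE(params$noise)) {
    sc <- params$photon_scale
    addn <- function(x) {
      x <- stats::rpois(length(x), as.vector(x) * sc) / sc +
        stats::rnorm(length(x), 0, params$read_noise_sd)
      pmax(x, 0)
    }
    chrom <- array(addn(chrom), shape)
    dex <- array(addn(dex), shape)
    spots <- array(addn(spots), shape)
  }
  vals <- array(0, c(3, shape))
  vals[1, , , ] <- chrom
  vals[2, , , ] <- dex
  vals[3, , , ] <- spots
  voxel_stack(vals, vs, time_min)
}

#' Render the confocal stack of a simulated oocyte at one time point
#'
#' Looks up the oocyte's chromosome-volume and dextran traces at `t`,
#' takes chromosome centers from the track set (nearest frame; a single
#' nuclear blob before NEBD) and kinetochore positions for the spot
#' channel, and renders the three-channel scene.
#'
#' @param oocyte A `SimulatedOocyte` from [simulate_cohort()].
#' @param t Time in minutes within the recording.
#' @param params [render_params()].
#' @return A [voxel_stack()].
#' @export
render_stack <- function(oocyte, t, params = render_params()) {
  vol_tr <- oocyte$traces$chromosome_volume
  if (t < vol_tr$times[1] || t > vol_tr$times[length(vol_tr$times)]) {
    stop("t is outside the recording", call. = FALSE)
  }
  shape <- params$shape
  vs <- params$voxel_size_um
  center <- shape * vs / 2
  vol <- max(trace_value_at(vol_tr, t), 0)
  dex_tr <- normalize_minmax(oocyte$traces$dextran)
  dex_frac <- min(max(trace_value_at(dex_tr, t), 0), 1)

  tts <- track_times(oocyte$tracks)
  if (t >= tts[1]) {
    tf <- tts[which.min(abs(tts - t))]
    fr <- frame_matrix(oocyte$tracks, tf)
    # recenter the lab-frame coordinates into the stack
    ctr <- colMeans(fr)
    kc <- sweep(fr, 2, ctr)
    kc <- sweep(kc, 2, rev(center), "+")       # (x,y,z) -> stack center
    spots_zyx <- kc[, c(3, 2, 1), drop = FALSE]
    cc <- chromosome_centers(oocyte$tracks, tf)
    ch <- sweep(sweep(cc$centers, 2, ctr), 2, rev(center), "+")
    chrom_zyx <- ch[, c(3, 2, 1), drop = FALSE]
  } else {
    spots_zyx <- NULL
    chrom_zyx <- rbind(center)
  }
  render_scene(chrom_zyx, vol, center, 8, dex_frac,
               spot_centers = spots_zyx, spot_amplitudes = 1,
               spot_sigma_um = 0.3, params = params, time_min = t)
}
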