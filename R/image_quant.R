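## Voxel-level measurements: thresholded chromatin volume, nuclear
## intensity on a single confocal section, spot detection, and
## structure-relative fold enrichment.

# Otsu's threshold on a 256-bin histogram of the channel intensities.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (rng[2] <= rng[1]) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE), 256)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# 26-connected component count over a logical 3D array (z, y, x).
count_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  current <- 0L
  idx <- which(mask & lab == 0L)
  while (length(idx)) {
    current <- current + 1L
    seed <- idx[1]
    queue <- seed
    lab[seed] <- current
    while (length(queue)) {
      q <- arrayInd(queue, d)
      queue <- integer(0)
      for (r in seq_len(nrow(q))) {
        for (k in seq_len(nrow(nb))) {
          z <- q[r, 1] + nb[k, 1]; y <- q[r, 2] + nb[k, 2]
          x <- q[r, 3] + nb[k, 3]
          if (z >= 1 && z <= d[1] && y >= 1 && y <= d[2] &&
              x >= 1 && x <= d[3] && mask[z, y, x] && lab[z, y, x] == 0L) {
            lab[z, y, x] <- current
            queue <- c(queue, (x - 1L) * d[1] * d[2] + (y - 1L) * d[1] + z)
          }
        }
      }
    }
    idx <- which(mask & lab == 0L)
  }
  list(n = current, labels = lab)
}

#' Segment chromatin by intensity thresholding
#'
#' Voxels above the threshold form the chromatin mask; connected components
#' are labeled with 26-neighbor connectivity and the reported volume is the
#' total above-threshold volume over all components (whole-chromatin
#' measurement). The default threshold is Otsu's method per stack; a fixed
#' threshold is available for exact tests.
#'
#' @param stack A [voxel_stack()].
#' @param channel Channel index.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value Threshold intensity, required iff `method = "fixed"`.
#' @return A `SegmentationResult`: `mask` (logical z,y,x array),
#'   `n_components`, `volume_um3`, `threshold_used`, `empty` flag. An empty
#'   mask is a warning-flagged result, not an error (condensing chromatin
#'   can vanish at low exposure).
#' @export
segment_chromatin <- function(stack, channel = 1,
                              method = c("otsu", "fixed"),
                              fixed_value = NULL) {
  method <- match.arg(method)
  d <- dim(stack$values)
  if (channel < 1 || channel > d[1]) {
    stop("channel ", channel, " does not exist", call. = FALSE)
  }
  v <- stack$values[channel, , , ]
  if (is.null(dim(v))) v <- array(v, d[2:4])
  thr <- if (method == "fixed") {
    if (is.null(fixed_value)) {
      stop("fixed_value required for method = 'fixed'", call. = FALSE)
    }
    fixed_value
  } else {
    otsu_threshold(as.vector(v))
  }
  mask <- v > thr
  voxel_vol <- prod(stack$voxel_size_um)
  if (!any(mask)) {
    return(structure(list(mask = mask, n_components = 0L, volume_um3 = 0,
                          threshold_used = thr, empty = TRUE),
                     class = "SegmentationResult"))
  }
  cc <- count_components_26(mask)
  structure(list(mask = mask, n_components = cc$n,
                 volume_um3 = sum(mask) * voxel_vol,
                 threshold_used = thr, empty = FALSE),
            class = "SegmentationResult")
}

# voxel-center physical coordinates along each axis (z, y, x), um
axis_coords <- function(stack) {
  d <- dim(stack$values)
  lapply(1:3, function(a) (seq_len(d[a + 1]) - 0.5) * stack$voxel_size_um[a])
}

#' Mean nuclear intensity on the central confocal section
#'
#' Measures the mean intensity over the disk of given radius on the single
#' z-section through the nucleus center - deliberately 2D, matching how
#' nuclear dextran entry is quantified on one confocal section. A 3D
#' spherical variant is available via `mode = "sphere"`.
#'
#' @param stack A [voxel_stack()].
#' @param channel Channel index.
#' @param nucleus_center Physical (z, y, x) center in um.
#' @param nucleus_radius_um Radius in um.
#' @param mode `"disk"` (default, single section) or `"sphere"`.
#' @return Mean intensity over the probe region.
#' @export
measure_nuclear_intensity <- function(stack, channel, nucleus_center,
                                      nucleus_radius_um,
                                      mode = c("disk", "sphere")) {
  mode <- match.arg(mode)
  d <- dim(stack$values)
  co <- axis_coords(stack)
  if (mode == "disk") {
    zi <- which.min(abs(co[[1]] - nucleus_center[1]))
    dy <- outer(co[[2]] - nucleus_center[2], rep(1, d[4]))
    dx <- outer(rep(1, d[3]), co[[3]] - nucleus_center[3])
    sel <- dy^2 + dx^2 <= nucleus_radius_um^2
    if (!any(sel)) {
      stop("probe disk lies outside the stack", call. = FALSE)
    }
    plane <- stack$values[channel, zi, , ]
    if (is.null(dim(plane))) plane <- matrix(plane, d[3], d[4])
    return(mean(plane[sel]))
  }
  dz <- co[[1]] - nucleus_center[1]
  dy <- co[[2]] - nucleus_center[2]
  dx <- co[[3]] - nucleus_center[3]
  r2 <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")
  sel <- r2 <= nucleus_radius_um^2
  if (!any(sel)) stop("probe sphere lies outside the stack", call. = FALSE)
  v <- stack$values[channel, , , ]
  if (is.null(dim(v))) v <- array(v, d[2:4])
  mean(v[sel])
}

#' Detect bright spots in one channel
#'
#' Local maxima (26-neighborhood) above an intensity floor, merged within
#' `min_separation_um` (brightest wins), refined to intensity-weighted
#' centroids over a window of that radius. Detections are sorted
#' deterministically by z, then y, then x.
#'
#' @param stack A [voxel_stack()].
#' @param channel Channel index.
#' @param min_separation_um Minimum separation between detections (um).
#' @param intensity_floor Minimum peak intensity.
#' @return Matrix with columns `z_um`, `y_um`, `x_um` (possibly 0 rows).
#' @export
detect_spots <- function(stack, channel, min_separation_um,
                         intensity_floor) {
  stopifnot(min_separation_um > 0)
  d <- dim(stack$values)
  v <- stack$values[channel, , , ]
  if (is.null(dim(v))) v <- array(v, d[2:4])
  dd <- dim(v)
  cand <- which(v > intensity_floor)
  if (!length(cand)) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("z_um", "y_um", "x_um"))))
  }
  ci <- arrayInd(cand, dd)
  is_max <- vapply(seq_len(nrow(ci)), function(r) {
    z <- ci[r, 1]; y <- ci[r, 2]; x <- ci[r, 3]
    nbh <- v[max(1, z - 1):min(dd[1], z + 1),
             max(1, y - 1):min(dd[2], y + 1),
             max(1, x - 1):min(dd[3], x + 1)]
    v[z, y, x] >= max(nbh)
  }, logical(1))
  peaks <- ci[is_max, , drop = FALSE]
  if (!nrow(peaks)) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("z_um", "y_um", "x_um"))))
  }
  vs <- stack$voxel_size_um
  pk_um <- sweep(sweep(peaks, 2, 0.5), 2, vs, "*")
  inten <- v[peaks]
  # merge: brightest first, suppress anything within min_separation
  ord <- order(-inten, pk_um[, 1], pk_um[, 2], pk_um[, 3])
  keep <- logical(nrow(peaks))
  taken <- matrix(numeric(0), ncol = 3)
  for (r in ord) {
    p <- pk_um[r, ]
    if (nrow(taken) == 0 ||
        min(sqrt(rowSums(sweep(taken, 2, p)^2))) >= min_separation_um) {
      keep[r] <- TRUE
      taken <- rbind(taken, p)
    }
  }
  co <- axis_coords(stack)
  refined <- t(vapply(which(keep), function(r) {
    z <- peaks[r, 1]; y <- peaks[r, 2]; x <- peaks[r, 3]
    wz <- max(1, ceiling(min_separation_um / 2 / vs[1]))
    wy <- max(1, ceiling(min_separation_um / 2 / vs[2]))
    wx <- max(1, ceiling(min_separation_um / 2 / vs[3]))
    zr <- max(1, z - wz):min(dd[1], z + wz)
    yr <- max(1, y - wy):min(dd[2], y + wy)
    xr <- max(1, x - wx):min(dd[3], x + wx)
    sub <- v[zr, yr, xr, drop = FALSE]
    tot <- sum(sub)
    ii <- arrayInd(seq_along(sub), dim(sub))
    c(sum(co[[1]][zr][ii[, 1]] * sub) / tot,
      sum(co[[2]][yr][ii[, 2]] * sub) / tot,
      sum(co[[3]][xr][ii[, 3]] * sub) / tot)
  }, numeric(3)))
  colnames(refined) <- c("z_um", "y_um", "x_um")
  refined[order(refined[, 1], refined[, 2], refined[, 3]), , drop = FALSE]
}

# mean intensity within a spherical probe centered at point (z,y,x um)
probe_mean <- function(stack, channel, point, radius_um) {
  measure_nuclear_intensity(stack, channel, point, radius_um,
                            mode = "sphere")
}

#' Fold enrichment of a signal at target versus reference structures
#'
#' Mean of spherical-probe mean intensities at the target points divided
#' by the same quantity at the reference points (e.g. anaphase-midzone
#' signal normalized by prometaphase-kinetochore signal).
#'
#' @param stack A [voxel_stack()].
#' @param channel Channel index.
#' @param target_points,reference_points Matrices with columns (z, y, x)
#'   in um; both nonempty.
#' @param probe_radius_um Probe radius.
#' @return Enrichment ratio.
#' @export
measure_fold_enrichment <- function(stack, channel, target_points,
                                    reference_points, probe_radius_um) {
  target_points <- rbind(target_points)
  reference_points <- rbind(reference_points)
  if (!nrow(target_points) || !nrow(reference_points)) {
    stop("target and reference point lists must be nonempty", call. = FALSE)
  }
  tm <- mean(apply(target_points, 1, probe_mean, stack = stack,
                   channel = channel, radius_um = probe_radius_um))
  rm_ <- mean(apply(reference_points, 1, probe_mean, stack = stack,
                    channel = channel, radius_um = probe_radius_um))
  if (rm_ == 0) stop("undefined ratio: reference mean is zero",
                     call. = FALSE)
  tm / rm_
}
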