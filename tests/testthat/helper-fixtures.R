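# Shared fixtures: small synthetic objects built in code.

# a minimal 4-kinetochore, m-frame track table (two tight pairs far apart)
make_small_tracks <- function(m = 3, labeled = TRUE) {
  rows <- lapply(seq_len(m), function(k) {
    t <- (k - 1) * 10
    data.frame(
      time_min = t,
      kinetochore_id = 1:4,
      pair_id = if (labeled) c(1L, 1L, 2L, 2L) else NA_integer_,
      x_um = c(0, 1, 20, 21),
      y_um = c(0, 0, 0, 0),
      z_um = c(0, 0, 0, 0))
  })
  kinetochore_track_set(do.call(rbind, rows), oocyte_id = "toy")
}

# random rigid transform (rotation + translation) applied to a track set
rigid_transform_tracks <- function(track_set) {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- stats::rnorm(3, 0, 15)
  pos <- as.data.frame(track_set$positions)
  xyz <- as.matrix(pos[, c("x_um", "y_um", "z_um")])
  xyz2 <- t(R %*% t(xyz) + shift)
  pos$x_um <- xyz2[, 1]; pos$y_um <- xyz2[, 2]; pos$z_um <- xyz2[, 3]
  kinetochore_track_set(pos, oocyte_id = track_set$oocyte_id)
}

# piecewise-linear degradation trace on an hours axis
make_deg_trace <- function(T_start = 6, D_rate = 0.8 / 3, I_min = 0.2,
                           t_max = 13, dt = 1 / 6) {
  t <- seq(0, t_max, by = dt)
  v <- pmax(pmin(1 - D_rate * (t - T_start), 1), I_min)
  intensity_trace(t, v, stream = "securin")
}
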