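#' Threshold-crossing detection of an onset and end on a normalized trace
#'
#' Implements the defined-threshold rule used throughout the resumption
#' analysis: the onset is the first (linearly interpolated) crossing of the
#' lower threshold `lo` that stays beyond `lo` for at least `sustain`
#' subsequent frames; the end is the first crossing of the upper threshold
#' `hi` thereafter. Falling traces are analyzed as `1 - value`, so one
#' crossing routine serves both directions.
#'
#' @param trace An [intensity_trace()] normalized to the unit interval in
#'   the direction of change (use [normalize_minmax()]).
#' @param direction `"rising"` or `"falling"`.
#' @param lo,hi Fractional thresholds, `0 < lo < hi < 1`. Defaults 0.1/0.9.
#' @param sustain Number of frames the signal must stay beyond `lo` after
#'   the onset crossing (default 2). If the trace ends sooner, the frames
#'   that do exist must all stay beyond `lo`.
#' @return List with `t_onset`, `t_end` (minutes; `NA` when undefined) and
#'   `status`: `"detected"`, `"no_event"` (lo never crossed) or
#'   `"open_ended"` (onset found, hi never crossed).
#' @export
detect_onset_end <- function(trace, direction = c("rising", "falling"),
                             lo = 0.1, hi = 0.9, sustain = 2L) {
  stopifnot(inherits(trace, "IntensityTrace"))
  direction <- match.arg(direction)
  if (!(lo > 0 && lo < hi && hi < 1)) {
    stop("thresholds must satisfy 0 < lo < hi < 1", call. = FALSE)
  }
  v <- trace$values
  if (direction == "falling") v <- 1 - v
  tt <- trace$times
  n <- length(v)

  cross_time <- function(i, th) {
    # crossing within [tt[i], tt[i+1]] where v[i] <= th < v[i+1]
    if (v[i] == th) return(tt[i])
    tt[i] + (th - v[i]) / (v[i + 1] - v[i]) * (tt[i + 1] - tt[i])
  }

  onset_i <- NA_integer_
  for (i in seq_len(n - 1)) {
    if (v[i] <= lo && v[i + 1] > lo) {
      hold <- v[seq(i + 1, min(i + sustain, n))]
      if (all(hold > lo)) { onset_i <- i; break }
    }
  }
  if (is.na(onset_i)) {
    # never crosses lo (including traces already past lo at recording
    # start): no event
    return(list(t_onset = NA_real_, t_end = NA_real_, status = "no_event"))
  }
  t_onset <- cross_time(onset_i, lo)

  t_end <- NA_real_
  for (j in seq(onset_i, n - 1)) {
    if (v[j] <= hi && v[j + 1] > hi) { t_end <- cross_time(j, hi); break }
  }
  status <- if (is.na(t_end)) "open_ended" else "detected"
  list(t_onset = t_onset, t_end = t_end, status = status)
}

#' Centered moving-average smoothing of a trace
#'
#' Plain boxcar smoothing with a shrinking window at the edges; the
#' default pipeline applies it before monotone projection. A no-op for
#' `window <= 1`.
#'
#' @param trace An [intensity_trace()].
#' @param window Odd window size in frames (default 9).
#' @return The smoothed trace.
#' @export
smooth_trace <- function(trace, window = 9L) {
  k <- as.integer(window)
  if (k <= 1) return(trace)
  v <- trace$values
  n <- length(v)
  half <- k %/% 2
  cs <- cumsum(c(0, v))
  lo_i <- pmax(seq_len(n) - half, 1L)
  hi_i <- pmin(seq_len(n) + half, n)
  sm <- (cs[hi_i + 1] - cs[lo_i]) / (hi_i - lo_i + 1)
  intensity_trace(trace$times, sm, stream = trace$stream,
                  normalization = trace$normalization)
}

# Robust detection of a plateau-to-plateau transition: smooth, project
# onto the monotone shape, then two passes of normalize + threshold
# crossing. Pass 1 anchors the unit scale at the global extremes of the
# projected trace; pass 2 re-anchors at the plateau medians (before the
# provisional onset / after the provisional end), which removes the
# sensitivity of the thresholds to noise extremes. Identical to a single
# pass on noiseless transitions.
detect_transition <- function(trace, direction, lo = 0.1, hi = 0.9,
                              sustain = 2L, denoise = TRUE,
                              smooth_window = 9L) {
  tr <- trace
  if (denoise) {
    tr <- monotone_denoise(smooth_trace(tr, smooth_window), direction)
  }
  if (tr$normalization != "minmax01") tr1 <- normalize_minmax(tr)
  else tr1 <- tr
  e <- detect_onset_end(tr1, direction, lo = lo, hi = hi,
                        sustain = sustain)
  if (!denoise || e$status == "no_event") return(e)
  # anchor on the halves of the plateau windows farthest from the
  # transition, where the sigmoid tails have decayed
  t_first <- tr$times[1]; t_last <- tr$times[length(tr$times)]
  pre <- tr$values[tr$times < (t_first + e$t_onset) / 2]
  if (length(pre) < 5) pre <- tr$values[tr$times < e$t_onset]
  post <- if (is.na(e$t_end)) numeric(0) else
    tr$values[tr$times > (e$t_end + t_last) / 2]
  if (length(post) < 5 && !is.na(e$t_end)) {
    post <- tr$values[tr$times > e$t_end]
  }
  if (length(pre) < 5 || length(post) < 5) return(e)
  base <- stats::median(pre); top <- stats::median(post)
  vlo <- min(base, top); vhi <- max(base, top)
  if (vhi <= vlo) return(e)
  tr2 <- intensity_trace(tr$times, (tr$values - vlo) / (vhi - vlo),
                         stream = tr$stream, normalization = "minmax01")
  detect_onset_end(tr2, direction, lo = lo, hi = hi, sustain = sustain)
}

#' Monotone (isotonic) denoising of a transition trace
#'
#' Projects a trace onto the nearest non-decreasing (`"rising"`) or
#' non-increasing (`"falling"`) sequence by isotonic regression (pool
#' adjacent violators). For traces whose underlying signal is a monotone
#' transition to a plateau - dextran influx, chromosome-volume decrease,
#' kinase activation, lamin loss - this is the natural noise suppression
#' before threshold crossing: it guarantees a single crossing per level,
#' removes the early bias of a first crossing through noise, and leaves
#' noiseless monotone traces exactly unchanged.
#'
#' @param trace An [intensity_trace()].
#' @param direction `"rising"` or `"falling"`.
#' @return The projected trace.
#' @export
monotone_denoise <- function(trace, direction = c("rising", "falling")) {
  direction <- match.arg(direction)
  v <- if (direction == "falling") -trace$values else trace$values
  fit <- stats::isoreg(trace$times, v)$yf
  if (direction == "falling") fit <- -fit
  intensity_trace(trace$times, fit, stream = trace$stream,
                  normalization = trace$normalization)
}

#' Condensation-versus-permeabilization delay for one oocyte
#'
#' Detects the dextran-influx onset `t1` (operational definition of NEBD
#' onset: permeabilization is the first step of nuclear envelope breakdown)
#' on the rising dextran trace and the chromosome-condensation onset `t2`
#' on the falling volume trace, and reports `delay = t2 - t1`. A positive
#' delay means condensation starts after permeabilization (the unperturbed
#' regime); a negative delay means condensation starts first (the
#' PLK1-inhibited regime).
#'
#' @param volume_trace Chromosome-volume [intensity_trace()] (falling).
#' @param dextran_trace Nuclear-dextran [intensity_trace()] (rising).
#' @param lo,hi,sustain Threshold parameters passed to
#'   [detect_onset_end()].
#' @param denoise Apply [monotone_denoise()] before normalization and
#'   crossing detection (default TRUE; it is a no-op on noiseless
#'   monotone traces).
#' @return An `EventTimes` list: `t1`, `t1_end`, `t2`, `t2_end`, `delay`
#'   (all minutes, `NA` when undetected) and a character vector `flags`.
#'   Oocytes with an undefined delay carry the flag `"delay_undefined"` and
#'   are excluded from group means downstream.
#' @export
condensation_nebd_delay <- function(volume_trace, dextran_trace,
                                    lo = 0.1, hi = 0.9, sustain = 2L,
                                    denoise = TRUE,
                                    smooth_window = c(volume = 9L,
                                                      dextran = 5L)) {
  # smoothing windows are matched to each stream's transition speed:
  # dextran enters the nucleus in ~20 min, condensation takes 45-75 min,
  # so the volume trace tolerates (and needs) a wider window
  sw <- rep_len(as.integer(smooth_window), 2)
  e1 <- detect_transition(dextran_trace, "rising", lo = lo, hi = hi,
                          sustain = sustain, denoise = denoise,
                          smooth_window = sw[2])
  e2 <- detect_transition(volume_trace, "falling", lo = lo, hi = hi,
                          sustain = sustain, denoise = denoise,
                          smooth_window = sw[1])
  flags <- character(0)
  if (e1$status == "no_event") flags <- c(flags, "no_dextran_onset")
  if (e2$status == "no_event") flags <- c(flags, "no_condensation_onset")
  if (e1$status == "open_ended") flags <- c(flags, "dextran_open_ended")
  if (e2$status == "open_ended") flags <- c(flags, "condensation_open_ended")
  delay <- if (is.na(e1$t_onset) || is.na(e2$t_onset)) NA_real_
           else e2$t_onset - e1$t_onset
  if (is.na(delay)) flags <- c(flags, "delay_undefined")
  structure(list(t1 = e1$t_onset, t1_end = e1$t_end,
                 t2 = e2$t_onset, t2_end = e2$t_end,
                 delay = delay, flags = flags),
            class = "EventTimes")
}

#' Activation onset of a rising marker relative to NEBD
#'
#' First sustained crossing of `floor` on the min-max-normalized trace,
#' reported relative to the NEBD time (negative values mean activation
#' before NEBD). Used for MTOC-associated active-kinase signals, which
#' become detectable tens of minutes before NEBD.
#'
#' @param trace An [intensity_trace()]; normalized internally if raw.
#' @param t_nebd NEBD time in minutes on the trace's time axis.
#' @param floor Detection floor as a fraction of the normalized range
#'   (default 0.1).
#' @param sustain Sustain frames, as in [detect_onset_end()].
#' @param denoise Apply [monotone_denoise()] first (default TRUE).
#' @return Onset minus `t_nebd` in minutes, or `NA` (no event).
#' @export
activation_onset <- function(trace, t_nebd, floor = 0.1, sustain = 2L,
                             denoise = TRUE, smooth_window = 1L) {
  # only the onset is used; hi just needs to be a legal value above floor
  e <- detect_transition(trace, "rising", lo = floor,
                         hi = (1 + floor) / 2, sustain = sustain,
                         denoise = denoise, smooth_window = smooth_window)
  if (is.na(e$t_onset)) return(NA_real_)
  e$t_onset - t_nebd
}

#' Duration of a falling (disassembly) signal
#'
#' Time between the onset and the end of the fall of a nuclear-rim signal
#' (e.g. lamin B1), using the same threshold rule as all other events.
#'
#' @inheritParams detect_onset_end
#' @param trace Falling [intensity_trace()]; normalized internally if raw.
#' @param denoise Apply [monotone_denoise()] first (default TRUE).
#' @return Duration in minutes, or `NA` when no event / open-ended.
#' @export
disassembly_duration <- function(trace, lo = 0.1, hi = 0.9, sustain = 2L,
                                 denoise = TRUE, smooth_window = 9L) {
  e <- detect_transition(trace, "falling", lo = lo, hi = hi,
                         sustain = sustain, denoise = denoise,
                         smooth_window = smooth_window)
  if (e$status != "detected") return(NA_real_)
  e$t_end - e$t_onset
}
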