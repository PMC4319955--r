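#' Normalize a cytoplasmic reporter trace to 1 at a reference time
#'
#' Divides the raw trace by its (interpolated) value at `t_ref`; by default
#' the first sample, matching the convention of normalizing reporter
#' intensities to 1 at the start of imaging. The result is the I_norm trace
#' used for degradation fitting.
#'
#' @param trace Raw [intensity_trace()] of cytoplasmic reporter intensity.
#' @param t_ref Reference time (default: first sample).
#' @return Normalized trace.
#' @export
normalize_cytoplasmic <- function(trace, t_ref = NULL) {
  if (is.null(t_ref)) t_ref <- trace$times[1]
  normalize_to_reference(trace, t_ref)
}

#' Fit a degradation line to an I_norm trace
#'
#' The decline window is chosen automatically: samples between the last
#' time I_norm >= `hi` (default 0.9) and the first subsequent time I_norm
#' <= I_min + `lo_offset` (default 0.1), where I_min is the smoothed trace
#' minimum. An ordinary least-squares line is fitted on that window;
#' `D_rate` is the negative slope (per hour when times are hours) and
#' `T_start` is the time at which the fitted line attains I_norm = 1.0 by
#' extrapolation. A non-degrading trace (slope >= 0, or too few points in
#' the window) yields `fit_valid = FALSE` with `D_rate = 0`: a verdict, not
#' an error, since a flat reporter is the central inhibited phenotype.
#'
#' @param i_norm_trace Normalized [intensity_trace()]; times in hours.
#' @param hi Upper entry level of the decline window (default 0.9).
#' @param lo_offset Exit offset above the trace minimum (default 0.1).
#' @param min_points Minimum samples required in the window (default 4).
#' @param smoothing_window Running-median window for the minimum (default 3).
#' @return A `DegradationFit` list: `T_start`, `D_rate`, `I_min`, `t_min`,
#'   `fit_window`, `rmse`, `n_fit`, `fit_valid`.
#' @export
fit_degradation <- function(i_norm_trace, hi = 0.9, lo_offset = 0.1,
                            min_points = 4L, smoothing_window = 3L) {
  tt <- i_norm_trace$times
  v <- i_norm_trace$values
  mf <- minimum_fraction(i_norm_trace, smoothing_window = smoothing_window)
  i_min <- mf$value

  invalid <- function() {
    structure(list(T_start = NA_real_, D_rate = 0, I_min = i_min,
                   t_min = mf$time, fit_window = c(NA_real_, NA_real_),
                   rmse = NA_real_, n_fit = 0L, fit_valid = FALSE),
              class = "DegradationFit")
  }

  above <- which(v >= hi)
  if (length(above) == 0) {
    # the trace starts already below hi: enter at the first sample
    i_a <- 1L
  } else {
    i_a <- max(above)
  }
  below <- which(v <= i_min + lo_offset & seq_along(v) >= i_a)
  i_b <- if (length(below)) min(below) else length(v)
  if (i_b - i_a + 1L < min_points) return(invalid())
  win <- seq(i_a, i_b)
  fit <- stats::lm.fit(cbind(1, tt[win]), v[win])
  b <- unname(fit$coefficients[2]); a <- unname(fit$coefficients[1])
  if (!is.finite(b) || b >= 0) return(invalid())
  structure(list(T_start = (1 - a) / b,
                 D_rate = -b,
                 I_min = i_min,
                 t_min = mf$time,
                 fit_window = c(tt[i_a], tt[i_b]),
                 rmse = sqrt(mean(fit$residuals^2)),
                 n_fit = length(win),
                 fit_valid = TRUE),
            class = "DegradationFit")
}

#' @export
print.DegradationFit <- function(x, ...) {
  if (x$fit_valid) {
    cat(sprintf(
      "DegradationFit: T_start = %.3g h, D_rate = %.3g /h, I_min = %.3g\n",
      x$T_start, x$D_rate, x$I_min))
  } else {
    cat(sprintf("DegradationFit: no degradation (I_min = %.3g)\n", x$I_min))
  }
  invisible(x)
}

#' Minimum fraction of a normalized trace
#'
#' Minimum of the running-median-smoothed trace and the time at which it is
#' attained (first occurrence). The running median (default window 3) makes
#' the minimum robust to single-frame noise spikes.
#'
#' @param i_norm_trace Normalized [intensity_trace()].
#' @param smoothing_window Odd window size (default 3).
#' @return List with `value` and `time`.
#' @export
minimum_fraction <- function(i_norm_trace, smoothing_window = 3L) {
  v <- i_norm_trace$values
  k <- as.integer(smoothing_window)
  if (k > 1 && length(v) >= k) {
    sm <- stats::runmed(v, k, endrule = "median")
  } else {
    sm <- v
  }
  i <- which.min(sm)
  list(value = sm[i], time = i_norm_trace$times[i])
}

#' Classify the meiotic outcome of one oocyte
#'
#' Combines the degradation verdict with anaphase annotations (from
#' generator truth, or manual scoring for real data) into one of five
#' categories: `no_APC_activation` (no valid degradation fit),
#' `partial_activation_no_anaphase` (valid fit but no chromosome
#' segregation), `anaphase_no_PB` (segregation without first polar body),
#' `anaphase_decondense` (segregation followed by chromosome
#' decondensation, no polar body), and `normal_anaphase_PB`.
#'
#' @param fit A `DegradationFit`.
#' @param min_frac Minimum normalized reporter fraction.
#' @param segregation_flag Did chromosomes segregate?
#' @param pb_flag Was the first polar body extruded?
#' @param decondense_flag Did chromosomes decondense after segregation?
#' @param anaphase_threshold Maximum `min_frac` compatible with anaphase
#'   (default 0.3); used only as a sanity bound, the flags decide.
#' @return Category string.
#' @export
classify_outcome <- function(fit, min_frac, segregation_flag, pb_flag,
                             decondense_flag, anaphase_threshold = 0.3) {
  if (decondense_flag && !segregation_flag) {
    stop("contradictory flags: decondensation without segregation",
         call. = FALSE)
  }
  if (pb_flag && !segregation_flag) {
    stop("contradictory flags: polar body without segregation",
         call. = FALSE)
  }
  if (!segregation_flag) {
    if (!fit$fit_valid) return("no_APC_activation")
    return("partial_activation_no_anaphase")
  }
  if (decondense_flag) return("anaphase_decondense")
  if (!pb_flag) return("anaphase_no_PB")
  "normal_anaphase_PB"
}

#' Cohort-level degradation summary
#'
#' Fractions of each outcome category plus the mean and SD of the
#' degradation rate over oocytes with a valid fit.
#'
#' @param fits List of `DegradationFit` objects.
#' @param categories Character vector of per-oocyte categories (same
#'   length).
#' @return List with `fractions` (named, over all five categories),
#'   `n`, `n_valid`, `mean_D_rate`, `sd_D_rate`, and the anaphase fraction
#'   (`anaphase_no_PB` + `anaphase_decondense` + `normal_anaphase_PB`).
#' @export
cohort_rates <- function(fits, categories) {
  if (length(fits) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(length(fits) == length(categories))
  lev <- c("no_APC_activation", "partial_activation_no_anaphase",
           "anaphase_no_PB", "anaphase_decondense", "normal_anaphase_PB")
  fr <- table(factor(categories, levels = lev)) / length(categories)
  rates <- vapply(fits, function(f) if (f$fit_valid) f$D_rate else NA_real_,
                  0)
  valid <- rates[!is.na(rates)]
  list(fractions = as.numeric(fr) |> stats::setNames(lev),
       n = length(fits), n_valid = length(valid),
       mean_D_rate = if (length(valid)) mean(valid) else NA_real_,
       sd_D_rate = if (length(valid) > 1) stats::sd(valid) else NA_real_,
       anaphase_fraction = sum(as.numeric(fr)[3:5]))
}
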