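#' Intensity traces
#'
#' An `IntensityTrace` is a sampled time series of one measured quantity for
#' one oocyte: times in minutes (strictly increasing), values in measurement
#' units, the stream name, and its normalization state (`raw`, `minmax01`,
#' or `ref_time_unit`).
#'
#' @param times Numeric vector, minutes, strictly increasing.
#' @param values Numeric vector, same length as `times`.
#' @param stream Stream name (e.g. `"dextran"`, `"chromosome_volume"`).
#' @param normalization One of `"raw"`, `"minmax01"`, `"ref_time_unit"`.
#' @return An `IntensityTrace`.
#' @export
intensity_trace <- function(times, values, stream = "trace",
                            normalization = "raw") {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length", call. = FALSE)
  }
  if (length(times) < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(values))) {
    stop("times and values must be finite", call. = FALSE)
  }
  normalization <- match.arg(normalization,
                             c("raw", "minmax01", "ref_time_unit"))
  structure(list(times = times, values = values, stream = stream,
                 normalization = normalization),
            class = "IntensityTrace")
}

#' @export
print.IntensityTrace <- function(x, ...) {
  cat(sprintf("IntensityTrace '%s' [%s]: %d samples, t = %.6g..%.6g min\n",
              x$stream, x$normalization, length(x$times),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# Linear interpolation of a trace at time t (error outside support).
trace_value_at <- function(trace, t) {
  if (t < trace$times[1] || t > trace$times[length(trace$times)]) {
    stop(sprintf("time %.6g min outside trace support [%.6g, %.6g]",
                 t, trace$times[1], trace$times[length(trace$times)]),
         call. = FALSE)
  }
  stats::approx(trace$times, trace$values, xout = t)$y
}

#' Min-max normalization of a trace to the unit interval
#'
#' Affine rescale using the global minimum and maximum of the whole trace,
#' so that min maps to 0 and max to 1. Order-preserving.
#'
#' @param trace An [intensity_trace()].
#' @return The normalized trace (`normalization = "minmax01"`).
#' @export
normalize_minmax <- function(trace) {
  stopifnot(inherits(trace, "IntensityTrace"))
  rng <- range(trace$values)
  if (rng[2] <= rng[1]) {
    stop("degenerate trace: no dynamic range (constant values)",
         call. = FALSE)
  }
  intensity_trace(trace$times, (trace$values - rng[1]) / (rng[2] - rng[1]),
                  stream = trace$stream, normalization = "minmax01")
}

#' Normalize a trace to 1 at a reference time
#'
#' Divides all values by the (linearly interpolated) value at `t_ref`. Used
#' for chromosome-volume kinetics, where volumes are scaled to 1 at a fixed
#' pre-condensation time.
#'
#' @param trace An [intensity_trace()].
#' @param t_ref Reference time in minutes; must lie within the trace
#'   support and have a positive value there.
#' @return The normalized trace (`normalization = "ref_time_unit"`).
#' @export
normalize_to_reference <- function(trace, t_ref) {
  stopifnot(inherits(trace, "IntensityTrace"))
  ref <- trace_value_at(trace, t_ref)
  if (ref <= 0) {
    stop("reference value at t_ref is not positive; cannot divide",
         call. = FALSE)
  }
  intensity_trace(trace$times, trace$values / ref, stream = trace$stream,
                  normalization = "ref_time_unit")
}

#' Align all streams of one oocyte to its minimum chromosome volume
#'
#' Shifts the time axis of every trace so that the first time at which the
#' chromosome-volume trace attains its global minimum maps to 0 (ties are
#' resolved to the earliest occurrence).
#'
#' @param traces Named list of [intensity_trace()] objects; must contain
#'   `chromosome_volume`.
#' @return The list of traces with shifted time axes.
#' @export
align_to_min_volume <- function(traces) {
  if (!"chromosome_volume" %in% names(traces)) {
    stop("traces must include a 'chromosome_volume' stream", call. = FALSE)
  }
  vol <- traces$chromosome_volume
  t0 <- vol$times[which.min(vol$values)]   # which.min takes the first tie
  lapply(traces, function(tr) {
    intensity_trace(tr$times - t0, tr$values, stream = tr$stream,
                    normalization = tr$normalization)
  })
}
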