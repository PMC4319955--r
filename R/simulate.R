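## Synthetic oocyte cohort generator: intensity-trace streams.
## All generators use R's global RNG; simulate_cohort() seeds it per oocyte
## so cohorts are bit-reproducible from the scenario seed.

# Logistic ramp that crosses 10% of its range at t_on and 90% at
# t_on + width: the threshold-crossing detectors then recover t_on exactly
# (up to interpolation) on noiseless traces.
logistic_ramp <- function(t, t_on, width, from, to) {
  mid <- t_on + width / 2
  tau <- width / (2 * log(9))
  from + (to - from) / (1 + exp(-(t - mid) / tau))
}

rnorm1 <- function(ms) stats::rnorm(1, ms[["mean"]], ms[["sd"]])

#' Simulate dextran-influx and chromosome-condensation traces
#'
#' Dextran is a logistic rise from baseline to plateau whose 10%-crossing
#' is the drawn NEBD (permeabilization) onset; chromosome volume is a
#' logistic decrease from the initial volume to its condensed minimum whose
#' 10%-of-fall crossing is the drawn condensation onset. Both streams get
#' additive Gaussian noise (SD = `noise_frac` of the dynamic range).
#'
#' @param params Condition preset from [condition_preset()].
#' @param frame_interval Sampling interval in minutes.
#' @param duration Recording duration in hours.
#' @return List with `dextran` and `chromosome_volume`
#'   ([intensity_trace()]s) and `truth` (`t_nebd_onset`, `t_cond_onset`,
#'   `delay_true`, minutes after induction).
#' @export
simulate_resumption_traces <- function(params, frame_interval = 1,
                                       duration = 15) {
  if (params$noise_frac < 0) stop("noise SD must be >= 0", call. = FALSE)
  if (params$dextran_rise_min <= 0 || params$cond_fall_min <= 0) {
    stop("rise/fall durations must be positive", call. = FALSE)
  }
  t <- seq(0, duration * 60, by = frame_interval)
  t_nebd <- rnorm1(params$nebd_onset)
  delay <- rnorm1(params$delay)
  t_cond <- t_nebd + delay

  dex_base <- 0.05; dex_plateau <- 1
  dex <- logistic_ramp(t, t_nebd, params$dextran_rise_min,
                       dex_base, dex_plateau)
  dex <- dex + stats::rnorm(length(t),
                            sd = params$noise_frac * (dex_plateau - dex_base))

  v0 <- params$chrom_v0_um3
  vmin <- v0 * params$chrom_vmin_frac
  vol <- logistic_ramp(t, t_cond, params$cond_fall_min, v0, vmin)
  vol <- vol + stats::rnorm(length(t), sd = params$noise_frac * (v0 - vmin))

  list(dextran = intensity_trace(t, dex, "dextran"),
       chromosome_volume = intensity_trace(t, vol, "chromosome_volume"),
       truth = list(t_nebd_onset = t_nebd, t_cond_onset = t_cond,
                    delay_true = delay))
}

#' Simulate an APC/C-substrate degradation trace
#'
#' Piecewise-linear construction matching the line-fit estimator: the
#' normalized level is flat at 1 until the true degradation start, declines
#' linearly at the true rate to the true minimum fraction, and afterwards
#' either stays flat (arrested oocytes) or re-accumulates slowly (oocytes
#' that entered anaphase; reporter synthesis continues in meiosis II). A
#' multiplicative raw-intensity scale and additive noise are applied.
#'
#' @param params Condition preset.
#' @param t_nebd NEBD time of this oocyte (minutes after induction).
#' @param frame_interval Sampling interval (minutes).
#' @param duration Recording duration (hours).
#' @param stream Output stream name (default `"securin"`).
#' @return List with `trace` and `truth` (`T_start_true` in hours on the
#'   condition's reference axis, `D_rate_true` per hour, `I_min_true`,
#'   `deg_ref`, `t_ref_min`, segregation/PB/decondensation flags and
#'   `anaphase_flag`).
#' @export
simulate_degradation_trace <- function(params, t_nebd, frame_interval = 10,
                                       duration = 15, stream = "securin") {
  dg <- params$degradation
  t <- seq(0, duration * 60, by = frame_interval)
  scale <- stats::rnorm(1, params$securin_scale_mean,
                        params$securin_scale_sd)

  t_ref_min <- switch(dg$ref,
    nebd = t_nebd,
    drug = params$drug_addition_min,
    washout = params$washout_min)

  if (!isTRUE(dg$degrades)) {
    # inhibited phenotype: level virtually constant for the whole recording
    val <- rep(1, length(t))
    noise_sd <- params$noise_frac
    truth <- list(T_start_true = NA_real_, D_rate_true = 0,
                  I_min_true = 1, deg_ref = dg$ref, t_ref_min = t_ref_min,
                  segregation = FALSE, pb = FALSE, decondense = FALSE)
  } else {
    if (!is.null(dg$p_anaphase)) {
      # mixture condition (proteasome-washout + inhibitor)
      anaphase <- stats::runif(1) < dg$p_anaphase
      sub <- if (anaphase) dg$anaphase else dg$arrested
      T_start <- rnorm1(sub$T_start); D_rate <- rnorm1(sub$D_rate)
      I_min <- rnorm1(sub$I_min)
      seg <- anaphase
      pb <- FALSE
      dec <- anaphase &&
        stats::runif(1) < dg$p_decondense_total / dg$p_anaphase
    } else {
      T_start <- rnorm1(dg$T_start); D_rate <- rnorm1(dg$D_rate)
      I_min <- rnorm1(dg$I_min)
      seg <- stats::runif(1) < dg$p_segregation
      pb <- seg && stats::runif(1) < dg$p_pb
      dec <- FALSE
    }
    I_min <- min(max(I_min, 0), 1)
    if (D_rate < 0) D_rate <- 0
    t_start_abs <- t_ref_min + T_start * 60
    t_min_abs <- t_start_abs + (1 - I_min) / max(D_rate, 1e-9) * 60
    val <- rep(1, length(t))
    dec_idx <- t > t_start_abs & t <= t_min_abs
    val[dec_idx] <- 1 - D_rate / 60 * (t[dec_idx] - t_start_abs)
    post <- t > t_min_abs
    rise <- if (seg) 0.03 / 60 else 0   # reporter re-accumulation in MII
    val[post] <- pmin(I_min + rise * (t[post] - t_min_abs), 1)
    noise_sd <- params$noise_frac * (1 - I_min)
    truth <- list(T_start_true = T_start, D_rate_true = D_rate,
                  I_min_true = I_min, deg_ref = dg$ref,
                  t_ref_min = t_ref_min,
                  segregation = seg, pb = pb, decondense = dec)
  }
  truth$anaphase_flag <-
    if (!truth$segregation) "none"
    else if (truth$decondense) "segregation_decondense"
    else if (!truth$pb) "segregation_no_PB"
    else "normal"
  raw <- scale * (val + stats::rnorm(length(t), sd = noise_sd))
  list(trace = intensity_trace(t, raw, stream), truth = truth)
}

#' Simulate spindle volume and aspect-ratio traces
#'
#' The aspect ratio rises sigmoidally from 1 (apolar microtubule ball) to
#' its plateau, crossing the elongation-detection threshold of 1.5 exactly
#' at the drawn elongation time; the volume rises logistically to a
#' condition-dependent plateau (smaller under PLK1 inhibition).
#'
#' @inheritParams simulate_degradation_trace
#' @return List with `spindle_volume` and `spindle_aspect` traces (times in
#'   minutes after induction) and `truth` (`t_elongation`, hours
#'   post-NEBD).
#' @export
simulate_spindle_trace <- function(params, t_nebd, frame_interval = 10,
                                   duration = 15) {
  if (params$aspect_plateau <= 1.5) {
    stop("aspect plateau must exceed the detection threshold 1.5",
         call. = FALSE)
  }
  t <- seq(0, duration * 60, by = frame_interval)
  t_el <- rnorm1(params$t_elongation)             # h post-NEBD
  t_el_abs <- t_nebd + t_el * 60
  A <- params$aspect_plateau
  tau <- params$aspect_tau_h * 60
  # logistic centered so the 1.5 crossing is exactly at t_el_abs
  # aspect = 1 + (A-1) / (1 + exp(-(t - mid)/tau)); solve mid for 1.5
  frac <- (1.5 - 1) / (A - 1)
  mid <- t_el_abs + tau * log((1 - frac) / frac)
  aspect <- 1 + (A - 1) / (1 + exp(-(t - mid) / tau))
  aspect <- aspect + stats::rnorm(length(t),
                                  sd = params$noise_frac * (A - 1))
  Vp <- params$spindle_volume_um3
  vol <- Vp / (1 + exp(-(t - (t_nebd + params$volume_mid_h * 60)) /
                         (params$volume_tau_h * 60)))
  vol <- vol + stats::rnorm(length(t), sd = params$noise_frac * Vp)
  list(spindle_volume = intensity_trace(t, vol, "spindle_volume"),
       spindle_aspect = intensity_trace(t, aspect, "spindle_aspect"),
       truth = list(t_elongation = t_el))
}

# Active-PLK1 (MTOC) trace: logistic rise whose 10% crossing sits at the
# drawn offset relative to NEBD, reaching its maximum around NEBD.
simulate_pplk1_trace <- function(params, t_nebd, frame_interval = 5,
                                 duration = 15) {
  t <- seq(0, duration * 60, by = frame_interval)
  offset <- rnorm1(params$pplk1_offset)
  v <- logistic_ramp(t, t_nebd + offset, params$pplk1_rise_min, 0.02, 1)
  v <- 100 * (v + stats::rnorm(length(t), sd = params$noise_frac))
  list(trace = intensity_trace(t, v, "pplk1_mtoc"),
       truth = list(pplk1_offset = offset))
}

# Nuclear-rim lamin trace: linear fall starting near NEBD whose 10->90%
# fall time equals the drawn disassembly duration.
simulate_lamin_trace <- function(params, t_nebd, frame_interval = 1,
                                 duration = 15) {
  t <- seq(0, duration * 60, by = frame_interval)
  dur <- max(rnorm1(params$lamin_duration), 2)
  start <- t_nebd + params$lamin_lag_min +
    stats::rnorm(1, 0, params$lamin_fall_sd_min)
  ramp_len <- dur / 0.8   # 10->90% span of a linear ramp is 0.8 x length
  v <- rep(1, length(t))
  falling <- t > start & t < start + ramp_len
  v[falling] <- 1 - (t[falling] - start) / ramp_len
  v[t >= start + ramp_len] <- 0
  v <- 100 * (v + stats::rnorm(length(t), sd = params$noise_frac))
  list(trace = intensity_trace(t, v, "lamin"),
       truth = list(lamin_duration = dur, t_lamin_start = start))
}
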