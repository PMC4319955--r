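#' Condition presets for the synthetic oocyte cohort generator
#'
#' Each drug regimen used in the imaging experiments is encoded as a named
#' parameter set. Event-time means and SDs are the values reported for live
#' cohorts (minutes for meiotic-resumption events on the time axis of
#' induction of meiotic resumption; hours post-NEBD for spindle, belt and
#' degradation parameters). Parameters with no published value are package
#' defaults chosen once and documented in the methods vignette.
#'
#' @format A named list, one entry per condition. Access with
#'   [condition_preset()].
#' @name presets
NULL

#' Names of the supported experimental conditions
#' @return Character vector of condition names.
#' @export
meioquant_conditions <- function() {
  c("control", "bi2536", "flavopiridol", "reversine", "bi2536_reversine",
    "bi2536_at_metaphase", "mg132_washout_control", "mg132_washout_bi2536")
}

# Shared structural defaults (not condition-specific; see vignette).
.structural_defaults <- list(
  n_chromosomes      = 20,      # bivalents in mouse meiosis I
  dextran_rise_min   = 20,      # 10->90% rise time of nuclear dextran entry
  noise_frac         = 0.02,    # additive noise SD as fraction of dynamic range
  ring_radius_um     = 11,      # prometaphase belt ring radius
  ring_jitter_um     = 0.3,
  ball_radius_um     = 5,       # radial spread of the dispersed post-NEBD ball
  axial_init_sd_um   = 4,
  congression_min    = 30,      # per-chromosome congression ramp duration
  belt_spread_min    = 40,      # spread of membership-crossing times pre-belt
  ou_tau_min         = 20,      # oscillation relaxation time along the axis
  biorientation_lag_min = 20,   # dwell at the belt SD before alignment tightens
  adapt_tau_h        = 0.75,    # relaxation of the stationary SD after t_belt
  aspect_tau_h       = 0.2,     # steepness of the aspect-ratio sigmoid
  aspect_plateau     = 2.0,
  volume_tau_h       = 0.5,     # spindle volume growth time scale
  volume_mid_h       = 1.0,     # spindle volume half-rise (h post-NEBD)
  chrom_v0_um3       = 1500,    # pre-condensation chromatin volume
  chrom_vmin_frac    = 0.30,    # condensed/initial volume ratio
  securin_scale_mean = 1000,    # raw reporter intensity scale (a.u.)
  securin_scale_sd   = 100,
  pplk1_rise_min     = 20,
  lamin_fall_sd_min  = 5,
  anaphase_min_frac  = 0.30     # classification threshold on minimum fraction
)

# Per-condition parameter sets. Time axes:
#   *_min values: minutes after induction of meiotic resumption
#   *_h values:   hours after NEBD unless deg_ref says otherwise
.presets <- list(
  control = list(
    nebd_onset = c(mean = 60, sd = 10),
    delay      = c(mean = 3.8, sd = 1.7),   # condensation onset - NEBD onset
    cond_fall_min = 46,                     # condensation 10->90% fall time
    pplk1_offset  = c(mean = -20, sd = 5),  # activation onset rel. NEBD (min)
    lamin_duration = c(mean = 30, sd = 5),
    lamin_lag_min  = 0,
    t_elongation = c(mean = 2.4, sd = 0.4),
    spindle_volume_um3 = 1500,
    t_belt = c(mean = 2.5, sd = 0.2),
    eq_dist_belt_um = 2.4,                  # mean |axis position| at t_belt
    eq_dist_late_um = 1.8,                  # ... at t_belt + 2 h
    excursion_bound_um = 8,
    ikt_um = c(mean = 0.9, sd = 0.08),
    degradation = list(
      degrades = TRUE, ref = "nebd",
      T_start = c(mean = 6, sd = 0.5),
      D_rate  = c(mean = 0.8 / 3, sd = 0.03),
      I_min   = c(mean = 0.20, sd = 0.02),
      p_segregation = 1, p_pb = 1, p_decondense = 0
    )
  ),
  bi2536 = list(
    nebd_onset = c(mean = 95, sd = 12),
    delay      = c(mean = -8.0, sd = 5.5),
    cond_fall_min = 74,
    pplk1_offset  = c(mean = -20, sd = 5),
    lamin_duration = c(mean = 30, sd = 5),
    lamin_lag_min  = 0,
    t_elongation = c(mean = 3.7, sd = 0.8),
    spindle_volume_um3 = 800,
    t_belt = c(mean = 2.8, sd = 0.5),
    eq_dist_belt_um = 3.1,
    eq_dist_late_um = 5.2,
    excursion_bound_um = 16,
    ikt_um = c(mean = 0.6, sd = 0.08),
    degradation = list(
      degrades = FALSE, ref = "nebd",       # reporter flat for >= 12 h
      p_segregation = 0, p_pb = 0, p_decondense = 0
    )
  ),
  flavopiridol = list(
    # partial CDK1 inhibition: both onsets late, condensation delayed more
    nebd_onset = c(mean = 100, sd = 12),
    delay      = c(mean = 30, sd = 10),
    cond_fall_min = 74,
    pplk1_offset  = c(mean = -20, sd = 5),
    lamin_duration = c(mean = 60, sd = 10),
    lamin_lag_min  = 20,
    t_elongation = c(mean = 2.4, sd = 0.4),
    spindle_volume_um3 = 1500,
    t_belt = c(mean = 2.5, sd = 0.2),
    eq_dist_belt_um = 2.4,
    eq_dist_late_um = 1.8,
    excursion_bound_um = 8,
    ikt_um = c(mean = 0.9, sd = 0.08),
    degradation = list(
      degrades = TRUE, ref = "nebd",
      T_start = c(mean = 6, sd = 0.5),
      D_rate  = c(mean = 0.8 / 3, sd = 0.03),
      I_min   = c(mean = 0.20, sd = 0.02),
      p_segregation = 1, p_pb = 1, p_decondense = 0
    )
  ),
  reversine = list(
    nebd_onset = c(mean = 60, sd = 10),
    delay      = c(mean = 3.8, sd = 1.7),
    cond_fall_min = 46,
    pplk1_offset  = c(mean = -20, sd = 5),
    lamin_duration = c(mean = 30, sd = 5),
    lamin_lag_min  = 0,
    t_elongation = c(mean = 2.4, sd = 0.4),
    spindle_volume_um3 = 1500,
    t_belt = c(mean = 2.5, sd = 0.2),
    eq_dist_belt_um = 2.4,
    eq_dist_late_um = 1.8,
    excursion_bound_um = 8,
    ikt_um = c(mean = 0.9, sd = 0.08),
    degradation = list(
      degrades = TRUE, ref = "nebd",        # SAC loss: premature activation
      T_start = c(mean = 3.0, sd = 0.5),
      D_rate  = c(mean = 0.8 / 3, sd = 0.03),
      I_min   = c(mean = 0.20, sd = 0.02),
      p_segregation = 1, p_pb = 1, p_decondense = 0
    )
  ),
  bi2536_reversine = list(
    nebd_onset = c(mean = 95, sd = 12),
    delay      = c(mean = -8.0, sd = 5.5),
    cond_fall_min = 74,
    pplk1_offset  = c(mean = -20, sd = 5),
    lamin_duration = c(mean = 30, sd = 5),
    lamin_lag_min  = 0,
    t_elongation = c(mean = 3.7, sd = 0.8),
    spindle_volume_um3 = 800,
    t_belt = c(mean = 2.8, sd = 0.5),
    eq_dist_belt_um = 3.1,
    eq_dist_late_um = 5.2,
    excursion_bound_um = 16,
    ikt_um = c(mean = 0.6, sd = 0.08),
    degradation = list(
      degrades = TRUE, ref = "nebd",        # partial activation, no anaphase
      T_start = c(mean = 6, sd = 0.5),
      D_rate  = c(mean = 0.12, sd = 0.02),
      I_min   = c(mean = 0.50, sd = 0.05),
      p_segregation = 0, p_pb = 0, p_decondense = 0
    )
  ),
  bi2536_at_metaphase = list(
    # drug added at established metaphase I (6.5 h after induction)
    nebd_onset = c(mean = 60, sd = 10),
    delay      = c(mean = 3.8, sd = 1.7),
    cond_fall_min = 46,
    pplk1_offset  = c(mean = -20, sd = 5),
    lamin_duration = c(mean = 30, sd = 5),
    lamin_lag_min  = 0,
    t_elongation = c(mean = 2.4, sd = 0.4),
    spindle_volume_um3 = 1500,
    t_belt = c(mean = 2.5, sd = 0.2),
    eq_dist_belt_um = 2.4,
    eq_dist_late_um = 1.8,
    excursion_bound_um = 8,
    ikt_um = c(mean = 0.9, sd = 0.08),
    drug_addition_min = 390,
    degradation = list(
      degrades = TRUE, ref = "drug",        # times rel. drug addition (h)
      T_start = c(mean = 0.5, sd = 0.2),
      D_rate  = c(mean = 0.10, sd = 0.02),
      I_min   = c(mean = 0.45, sd = 0.05),
      p_segregation = 0, p_pb = 0, p_decondense = 0
    )
  ),
  mg132_washout_control = list(
    nebd_onset = c(mean = 60, sd = 10),
    delay      = c(mean = 3.8, sd = 1.7),
    cond_fall_min = 46,
    pplk1_offset  = c(mean = -20, sd = 5),
    lamin_duration = c(mean = 30, sd = 5),
    lamin_lag_min  = 0,
    t_elongation = c(mean = 2.4, sd = 0.4),
    spindle_volume_um3 = 1500,
    t_belt = c(mean = 2.5, sd = 0.2),
    eq_dist_belt_um = 2.4,
    eq_dist_late_um = 1.8,
    excursion_bound_um = 8,
    ikt_um = c(mean = 0.9, sd = 0.08),
    washout_min = 600,                      # 6 h culture + 4 h MG132 arrest
    degradation = list(
      degrades = TRUE, ref = "washout",     # times rel. MG132 washout (h)
      T_start = c(mean = 0.3, sd = 0.1),
      D_rate  = c(mean = 0.5, sd = 0.08),
      I_min   = c(mean = 0.15, sd = 0.02),
      p_segregation = 1, p_pb = 1, p_decondense = 0
    )
  ),
  mg132_washout_bi2536 = list(
    nebd_onset = c(mean = 60, sd = 10),
    delay      = c(mean = 3.8, sd = 1.7),
    cond_fall_min = 46,
    pplk1_offset  = c(mean = -20, sd = 5),
    lamin_duration = c(mean = 30, sd = 5),
    lamin_lag_min  = 0,
    t_elongation = c(mean = 2.4, sd = 0.4),
    spindle_volume_um3 = 1500,
    t_belt = c(mean = 2.5, sd = 0.2),
    eq_dist_belt_um = 2.4,
    eq_dist_late_um = 1.8,
    excursion_bound_um = 8,
    ikt_um = c(mean = 0.9, sd = 0.08),
    washout_min = 600,
    degradation = list(
      degrades = TRUE, ref = "washout",
      # mixture: 37% retain control-like degradation and segregate
      # (never extruding a polar body; 13% of all oocytes additionally
      # decondense); the rest degrade slowly and stay arrested
      p_anaphase = 0.37, p_decondense_total = 0.13,
      anaphase = list(
        T_start = c(mean = 0.3, sd = 0.1),
        D_rate  = c(mean = 0.5, sd = 0.08),
        I_min   = c(mean = 0.15, sd = 0.02)
      ),
      arrested = list(
        T_start = c(mean = 0.5, sd = 0.2),
        D_rate  = c(mean = 0.2, sd = 0.05),
        I_min   = c(mean = 0.35, sd = 0.05)
      )
    )
  )
)

#' Retrieve the full parameter set for one condition
#'
#' Merges the condition-specific preset with structural defaults shared by
#' all conditions. Override values (from [read_config()]) replace matching
#' entries.
#'
#' @param condition One of [meioquant_conditions()].
#' @param overrides Named list of parameter overrides; every name must match
#'   a documented parameter or an error is raised.
#' @return Named list of generator parameters.
#' @export
condition_preset <- function(condition, overrides = list()) {
  condition <- match.arg(condition, meioquant_conditions())
  p <- utils::modifyList(.structural_defaults, .presets[[condition]])
  p$condition <- condition
  if (length(overrides)) {
    bad <- setdiff(names(overrides), c(names(p), "degradation"))
    if (length(bad)) {
      stop("unknown generator parameter(s) in overrides: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    p <- utils::modifyList(p, overrides)
  }
  p
}
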