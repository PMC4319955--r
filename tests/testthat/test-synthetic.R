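test_that("cohorts are bit-reproducible from the scenario seed", {
  cfg <- scenario_config("control", n_oocytes = 2, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(cohort_tables(a), cohort_tables(b))
  c2 <- simulate_cohort(scenario_config("control", n_oocytes = 2,
                                        seed = 124))
  expect_false(identical(cohort_tables(a)$traces,
                         cohort_tables(c2)$traces))
})

test_that("resumption generator matches its preset moments and ordering", {
  # moment convergence at n = 500 within 3 standard errors
  params <- condition_preset("control")
  set.seed(77)
  delays <- replicate(500, simulate_resumption_traces(params)$truth$delay_true)
  expect_lt(abs(mean(delays) - 3.8), 3 * 1.7 / sqrt(500))
  expect_lt(abs(sd(delays) - 1.7), 3 * 1.7 / sqrt(2 * 499))
  # dextran onset precedes condensation in >= 90% of control oocytes
  # (Monte-Carlo check of the Normal(3.8, 1.7) delay: P(delay > 0) = 0.987)
  expect_gte(mean(delays > 0), 0.9)

  set.seed(78)
  params_bi <- condition_preset("bi2536")
  delays_bi <- replicate(300,
                         simulate_resumption_traces(params_bi)$truth$delay_true)
  expect_lt(abs(mean(delays_bi) + 8.0), 3 * 5.5 / sqrt(300))

  # flavopiridol: both onsets late relative to control, condensation
  # delayed more than permeabilization (positive, larger delay)
  set.seed(79)
  params_fl <- condition_preset("flavopiridol")
  tf <- replicate(100, unlist(simulate_resumption_traces(params_fl)$truth))
  tc <- replicate(100, unlist(simulate_resumption_traces(params)$truth))
  expect_gt(mean(tf["t_nebd_onset", ]), mean(tc["t_nebd_onset", ]))
  expect_gt(mean(tf["t_cond_onset", ]), mean(tc["t_cond_onset", ]))
  expect_gt(mean(tf["delay_true", ]), mean(tc["delay_true", ]))
})

test_that("noiseless resumption traces recover drawn onsets", {
  params <- condition_preset("control", list(noise_frac = 0))
  set.seed(4)
  for (i in 1:5) {
    s <- simulate_resumption_traces(params)
    ev <- condensation_nebd_delay(s$chromosome_volume, s$dextran)
    expect_lt(abs(ev$t1 - s$truth$t_nebd_onset), 1)
    expect_lt(abs(ev$t2 - s$truth$t_cond_onset), 1)
  }
  bad <- params; bad$noise_frac <- -1
  expect_error(simulate_resumption_traces(bad), "noise")
  bad2 <- params; bad2$dextran_rise_min <- 0
  expect_error(simulate_resumption_traces(bad2), "positive")
})

test_that("noiseless degradation traces give exact fits per condition", {
  params <- condition_preset("control", list(noise_frac = 0))
  set.seed(8)
  s <- simulate_degradation_trace(params, t_nebd = 60)
  k <- analyze_kinetics(s$trace, t_ref_min = 60)
  expect_equal(k$T_start, s$truth$T_start_true, tolerance = 1e-6)
  expect_equal(k$D_rate, s$truth$D_rate_true, tolerance = 1e-6)
  # I_min is exact up to the frame quantization of the kink
  expect_equal(k$I_min, s$truth$I_min_true, tolerance = 0.05)

  # inhibited phenotype: flat trace is a verdict, not an error
  params_bi <- condition_preset("bi2536", list(noise_frac = 0))
  s_bi <- simulate_degradation_trace(params_bi, t_nebd = 95)
  k_bi <- analyze_kinetics(s_bi$trace, t_ref_min = 95)
  expect_false(k_bi$fit_valid)
  expect_equal(k_bi$D_rate, 0)
  expect_equal(k_bi$category, "no_APC_activation")

  # partial activation plateau; draws pinned at the preset means so the
  # plateau is reached well inside the recording
  params_br <- condition_preset("bi2536_reversine", list(
    noise_frac = 0,
    degradation = list(T_start = c(mean = 6, sd = 0),
                       D_rate = c(mean = 0.12, sd = 0),
                       I_min = c(mean = 0.50, sd = 0))))
  s_br <- simulate_degradation_trace(params_br, t_nebd = 95)
  expect_equal(s_br$truth$anaphase_flag, "none")
  k_br <- analyze_kinetics(s_br$trace, t_ref_min = 95)
  expect_equal(k_br$I_min, s_br$truth$I_min_true, tolerance = 1e-6)
  expect_equal(k_br$category, "partial_activation_no_anaphase")

  bad <- params
  bad$degradation$I_min <- c(mean = 1.5, sd = 0)
  set.seed(8)
  s_bad <- simulate_degradation_trace(bad, t_nebd = 60)
  expect_lte(s_bad$truth$I_min_true, 1)   # clipped into [0, 1]
})

test_that("spindle traces cross the detection threshold at the drawn time", {
  params <- condition_preset("control", list(noise_frac = 0))
  set.seed(10)
  for (i in 1:4) {
    s <- simulate_spindle_trace(params, t_nebd = 60)
    asp <- s$spindle_aspect
    asp_h <- intensity_trace((asp$times - 60) / 60, asp$values)
    t_el <- spindle_elongation_time(asp_h)
    expect_lt(abs(t_el - s$truth$t_elongation), 10 / 60)
  }
  # SD = 0 pins every oocyte at the mean
  p0 <- condition_preset("control",
                         list(t_elongation = c(mean = 2.4, sd = 0),
                              noise_frac = 0))
  t2 <- replicate(3, simulate_spindle_trace(p0, 60)$truth$t_elongation)
  expect_true(all(t2 == 2.4))
  bad <- params; bad$aspect_plateau <- 1.2
  expect_error(simulate_spindle_trace(bad, 60), "plateau")
})

test_that("kinetochore tracks: truth fields, bounds, degenerate dynamics", {
  params <- condition_preset("control")
  set.seed(12)
  s <- simulate_kinetochore_tracks(params, t_nebd = 60)
  tts <- track_times(s$tracks)
  expect_equal(tts[1], 60)                      # tracks start at NEBD
  expect_equal(length(unique(s$tracks$positions$kinetochore_id)), 40L)
  # true axial positions never exceed the oscillation bound
  allc <- do.call(rbind, lapply(tts, function(t) {
    chromosome_centers(s$tracks, t)$centers
  }))
  ax_pos <- as.numeric(sweep(allc, 2, s$truth$center_lab) %*%
                         s$truth$axis_lab)
  expect_lte(max(abs(ax_pos)), params$excursion_bound_um + 1e-9)

  # degenerate dynamics: zero spread puts every center on the plane
  p0 <- condition_preset("control", list(
    eq_dist_belt_um = 0, eq_dist_late_um = 0, axial_init_sd_um = 0))
  set.seed(13)
  s0 <- simulate_kinetochore_tracks(p0, t_nebd = 60)
  tts0 <- track_times(s0$tracks)
  cc <- chromosome_centers(s0$tracks, tts0[length(tts0)])$centers
  ctr0 <- colMeans(cc)
  expect_lt(max(abs(as.numeric(sweep(cc, 2, ctr0) %*% s0$truth$axis_lab))),
            1e-8)

  bad <- params; bad$ou_tau_min <- 0
  expect_error(simulate_kinetochore_tracks(bad, 60), "relaxation")
})

test_that("inter-kinetochore distances are smaller under PLK1 inhibition", {
  set.seed(14)
  pc <- condition_preset("control"); pb <- condition_preset("bi2536")
  sc <- simulate_kinetochore_tracks(pc, 60)
  sb <- simulate_kinetochore_tracks(pb, 95)
  expect_gt(mean(sc$truth$ikt_true), mean(sb$truth$ikt_true))
  d <- interkinetochore_distances(sc$tracks, 60 + 270)
  expect_equal(sort(unname(d)), sort(unname(sc$truth$ikt_true)),
               tolerance = 1e-8)
})

test_that("mg132 washout mixture reproduces the anaphase fractions", {
  params <- condition_preset("mg132_washout_bi2536")
  set.seed(15)
  flags <- replicate(400, {
    simulate_degradation_trace(params, t_nebd = 60)$truth$anaphase_flag
  })
  p_ana <- mean(flags != "none")
  expect_lt(abs(p_ana - 0.37), 3 * sqrt(0.37 * 0.63 / 400))
  p_dec <- mean(flags == "segregation_decondense")
  expect_lt(abs(p_dec - 0.13), 3 * sqrt(0.13 * 0.87 / 400))
  expect_false(any(flags == "normal"))   # no polar body in this condition
})
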