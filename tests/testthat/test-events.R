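test_that("normalization operations match their closed forms", {
  tr <- intensity_trace(c(0, 1, 2), c(100, 300, 200))
  expect_equal(normalize_minmax(tr)$values, c(0, 1, 0.5))
  unit <- intensity_trace(c(0, 1, 2), c(0, 1, 0.5),
                          normalization = "minmax01")
  expect_equal(normalize_minmax(unit)$values, unit$values)  # idempotent
  expect_error(normalize_minmax(intensity_trace(0:2, c(5, 5, 5))),
               "degenerate")

  tr2 <- intensity_trace(c(0, 10), c(400, 200))
  expect_equal(normalize_to_reference(tr2, 0)$values, c(1, 0.5))
  tr3 <- intensity_trace(c(0, 10), c(100, 300))
  expect_equal(normalize_to_reference(tr3, 5)$values[1], 0.5)  # divisor 200
  expect_error(normalize_to_reference(tr3, -1), "outside")
})

test_that("alignment to minimum volume uses the earliest minimum", {
  vol <- intensity_trace(c(100, 110, 120), c(5, 3, 3),
                         stream = "chromosome_volume")
  dex <- intensity_trace(c(100, 110, 120), c(0, 1, 1), stream = "dextran")
  out <- align_to_min_volume(list(chromosome_volume = vol, dextran = dex))
  expect_equal(out$dextran$times, c(-10, 0, 10))  # tie at 110/120 -> 110
  mono <- intensity_trace(c(0, 10, 20), c(3, 2, 1),
                          stream = "chromosome_volume")
  out2 <- align_to_min_volume(list(chromosome_volume = mono))
  expect_equal(out2$chromosome_volume$times[3], 0)  # minimum at last sample
  expect_error(align_to_min_volume(list(dextran = dex)), "chromosome_volume")
})

test_that("detect_onset_end matches hand-computed crossings", {
  # step from 0 to 1 between samples at 4 and 5 min
  tt <- 0:10
  step <- intensity_trace(tt, as.numeric(tt >= 5),
                          normalization = "minmax01")
  e <- detect_onset_end(step, "rising")
  expect_equal(e$t_onset, 4.1)
  expect_equal(e$t_end, 4.9)
  # linear ramp 0 -> 1 over [0, 10]: onset at 10*lo, end at 10*hi
  ramp <- intensity_trace(tt, tt / 10, normalization = "minmax01")
  e2 <- detect_onset_end(ramp, "rising", lo = 0.1, hi = 0.9)
  expect_equal(e2$t_onset, 1)
  expect_equal(e2$t_end, 9)
  # constant zero trace: no event, not an error
  flat <- intensity_trace(tt, rep(0, 11), normalization = "minmax01")
  expect_equal(detect_onset_end(flat, "rising")$status, "no_event")
  # open-ended: crosses lo but never hi
  half <- intensity_trace(tt, pmin(tt / 10, 0.5),
                          normalization = "minmax01")
  e3 <- detect_onset_end(half, "rising")
  expect_equal(e3$status, "open_ended")
  expect_true(is.na(e3$t_end))
  expect_error(detect_onset_end(ramp, "rising", lo = 0.9, hi = 0.1),
               "thresholds")
})

test_that("detect_onset_end agrees with an exhaustive-scan oracle", {
  # oracle: scan all sample pairs for the first lo-crossing whose
  # following `sustain` samples stay above lo, and the first hi-crossing
  # at or after it; interpolate linearly
  oracle <- function(v, tt, lo, hi, sustain) {
    n <- length(v)
    t_on <- NA
    for (i in seq_len(n - 1)) {
      if (v[i] <= lo && v[i + 1] > lo &&
          all(v[seq(i + 1, min(i + sustain, n))] > lo)) {
        t_on <- tt[i] + (lo - v[i]) / (v[i + 1] - v[i]) * (tt[i + 1] - tt[i])
        t_end <- NA
        for (j in seq(i, n - 1)) {
          if (v[j] <= hi && v[j + 1] > hi) {
            t_end <- tt[j] + (hi - v[j]) / (v[j + 1] - v[j]) *
              (tt[j + 1] - tt[j])
            break
          }
        }
        return(c(t_on, t_end))
      }
    }
    c(NA, NA)
  }
  set.seed(21)
  for (rep in 1:25) {
    tt <- cumsum(runif(40, 0.5, 2))
    v <- pmin(pmax(cumsum(rnorm(40, 0.05, 0.12)), 0), 1)
    v[1] <- 0
    tr <- intensity_trace(tt, v, normalization = "minmax01")
    got <- detect_onset_end(tr, "rising", lo = 0.25, hi = 0.75,
                            sustain = 2L)
    want <- oracle(v, tt, 0.25, 0.75, 2L)
    expect_equal(got$t_onset, want[1])
    if (!is.na(want[1])) expect_equal(got$t_end, want[2])
  }
})

test_that("detected times are shift-equivariant and lo-monotone", {
  set.seed(22)
  tt <- seq(0, 60, by = 1)
  v <- 1 / (1 + exp(-(tt - 30) / 3))
  tr <- intensity_trace(tt, v, normalization = "minmax01")
  base <- detect_onset_end(tr, "rising")
  for (shift in c(-17.5, 4, 123)) {
    sh <- intensity_trace(tt + shift, v, normalization = "minmax01")
    e <- detect_onset_end(sh, "rising")
    expect_equal(e$t_onset, base$t_onset + shift)
    expect_equal(e$t_end, base$t_end + shift)
  }
  # raising lo never decreases the onset
  onsets <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.6),
                   function(lo) detect_onset_end(tr, "rising", lo = lo,
                                                 hi = 0.9)$t_onset, 0)
  expect_true(all(diff(onsets) >= 0))
})

test_that("delay sign convention and flags behave as specified", {
  mk <- function(t_dex, t_vol) {
    tt <- seq(0, 200, by = 1)
    dex <- intensity_trace(tt, 1 / (1 + exp(-(tt - t_dex - 10) / 4.55)),
                           stream = "dextran")
    vol <- intensity_trace(tt, 1 - 1 / (1 + exp(-(tt - t_vol - 23) / 10.5)),
                           stream = "chromosome_volume")
    condensation_nebd_delay(vol, dex)
  }
  ev <- mk(46, 50)
  expect_equal(ev$delay, ev$t2 - ev$t1)
  expect_gt(ev$delay, 0)
  ev2 <- mk(60, 52)
  expect_lt(ev2$delay, 0)
  # undetected onset flags the oocyte instead of erroring: a single-frame
  # spike never sustains, so the dextran onset is a no-event
  tt <- seq(0, 200, by = 1)
  spike <- rep(0, length(tt)); spike[100] <- 1
  dex_spike <- intensity_trace(tt, spike, stream = "dextran")
  vol <- intensity_trace(tt, 1 - 1 / (1 + exp(-(tt - 75) / 10.5)),
                         stream = "chromosome_volume")
  ev3 <- condensation_nebd_delay(vol, dex_spike, denoise = FALSE)
  expect_true(is.na(ev3$delay))
  expect_true(all(c("no_dextran_onset", "delay_undefined") %in% ev3$flags))
})

test_that("onset detection stays within 2 frames at default noise", {
  # >= 95% of 200 simulated control oocytes for both onsets
  params <- condition_preset("control")
  set.seed(23)
  ok1 <- ok2 <- logical(200)
  for (i in 1:200) {
    s <- simulate_resumption_traces(params)
    ev <- condensation_nebd_delay(s$chromosome_volume, s$dextran)
    ok1[i] <- abs(ev$t1 - s$truth$t_nebd_onset) <= 2
    ok2[i] <- abs(ev$t2 - s$truth$t_cond_onset) <= 2
  }
  expect_gte(mean(ok1), 0.95)
  expect_gte(mean(ok2), 0.95)
})

test_that("activation onset is reported relative to NEBD", {
  tt <- seq(0, 120, by = 1)
  v <- pmin(pmax((tt - 38) / 20, 0), 1)   # crosses 0.1 at t = 40
  tr <- intensity_trace(tt, v)
  expect_equal(activation_onset(tr, t_nebd = 60), -20, tolerance = 1e-6)
  expect_equal(activation_onset(tr, t_nebd = 40), 0, tolerance = 1e-6)
  flat <- intensity_trace(tt, rep(0, length(tt)),
                          normalization = "minmax01")
  expect_true(is.na(activation_onset(flat, 60, denoise = FALSE)))
})

test_that("disassembly duration matches the ramp closed form", {
  tt <- seq(0, 50, by = 1)
  v <- pmax(pmin(1 - (tt - 10) / 30, 1), 0)   # linear fall over [10, 40]
  tr <- intensity_trace(tt, v)
  expect_equal(disassembly_duration(tr, denoise = FALSE), 24)  # 30*(0.9-0.1)
  # step fall: duration = (hi - lo) * frame interval
  vstep <- as.numeric(tt < 5)
  expect_equal(disassembly_duration(intensity_trace(tt, vstep),
                                    denoise = FALSE), 0.8)
  rising <- intensity_trace(tt, tt / 50, normalization = "minmax01")
  expect_true(is.na(disassembly_duration(rising, denoise = FALSE)))
})
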