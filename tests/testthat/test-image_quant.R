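cube_stack <- function() {
  a <- array(0, c(1, 16, 16, 16))
  a[1, 5:9, 5:9, 5:9] <- 100
  voxel_stack(a, c(1, 1, 1))
}

test_that("chromatin segmentation matches analytic volumes", {
  zero <- voxel_stack(array(0, c(1, 8, 8, 8)), c(1, 1, 1))
  sg0 <- segment_chromatin(zero, 1, method = "fixed", fixed_value = 10)
  expect_equal(sg0$volume_um3, 0)
  expect_equal(sg0$n_components, 0L)
  expect_true(sg0$empty)

  sg <- segment_chromatin(cube_stack(), 1, method = "fixed",
                          fixed_value = 50)
  expect_equal(sg$volume_um3, 125)
  expect_equal(sg$n_components, 1L)

  # two disjoint 2x2x2 cubes; component count checked against an
  # exhaustive flood fill over a literal voxel list
  a <- array(0, c(1, 12, 12, 12))
  a[1, 2:3, 2:3, 2:3] <- 100
  a[1, 8:9, 8:9, 8:9] <- 100
  st <- voxel_stack(a, c(1, 1, 1))
  sg2 <- segment_chromatin(st, 1, method = "fixed", fixed_value = 50)
  expect_equal(sg2$volume_um3, 16)
  vox <- which(a[1, , , ] > 50, arr.ind = TRUE)
  # brute force: union components by 26-adjacency
  comp <- seq_len(nrow(vox))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(vox))) for (j in seq_len(nrow(vox))) {
      if (comp[i] != comp[j] && all(abs(vox[i, ] - vox[j, ]) <= 1)) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  expect_equal(sg2$n_components, length(unique(comp)))
  expect_error(segment_chromatin(st, 5), "channel")
  expect_error(segment_chromatin(st, 1, method = "fixed"), "fixed_value")
})

test_that("segmented volume is non-increasing in the threshold", {
  set.seed(51)
  a <- array(runif(1 * 10 * 10 * 10, 0, 100), c(1, 10, 10, 10))
  st <- voxel_stack(a, c(1, 1, 1))
  vols <- vapply(c(10, 30, 50, 70, 90), function(th) {
    segment_chromatin(st, 1, method = "fixed", fixed_value = th)$volume_um3
  }, 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("nuclear intensity: constant field, single voxel, range error", {
  a <- array(7.5, c(1, 8, 16, 16))
  st <- voxel_stack(a, c(1, 0.5, 0.5))
  expect_equal(measure_nuclear_intensity(st, 1, c(2, 4, 4), 2), 7.5)
  expect_equal(measure_nuclear_intensity(st, 1, c(2, 4, 4), 2,
                                         mode = "sphere"), 7.5)
  # radius so small the disk is one voxel
  a2 <- array(0, c(1, 4, 4, 4)); a2[1, 2, 2, 2] <- 99
  st2 <- voxel_stack(a2, c(1, 1, 1))
  expect_equal(measure_nuclear_intensity(st2, 1, c(1.5, 1.5, 1.5), 0.4), 99)
  expect_error(measure_nuclear_intensity(st2, 1, c(50, 50, 50), 0.4),
               "outside")
})

test_that("spot detection: empty, merging, and centroid accuracy", {
  zero <- voxel_stack(array(0, c(1, 8, 8, 8)), c(1, 1, 1))
  expect_equal(nrow(detect_spots(zero, 1, 1, 0.5)), 0)

  p <- render_params(voxel_size_um = c(0.5, 0.5, 0.5),
                     shape = c(24, 24, 24), psf_sigma_um = 0,
                     noise = FALSE)
  truth <- rbind(c(4.3, 5.1, 6.2), c(8.6, 3.4, 9.1))
  sc <- render_scene(NULL, 0, c(6, 6, 6), 2, 0, spot_centers = truth,
                     spot_sigma_um = 0.4, params = p)
  det <- detect_spots(sc, 3, min_separation_um = 2, intensity_floor = 5)
  expect_equal(nrow(det), 2)
  # brute-force intensity-weighted centroid over the whole channel is the
  # oracle for a single rendered spot
  one <- render_scene(NULL, 0, c(6, 6, 6), 2, 0,
                      spot_centers = rbind(c(4.3, 5.1, 6.2)),
                      spot_sigma_um = 0.4, params = p)
  v <- one$values[3, , , ]
  co <- lapply(1:3, function(ax) (seq_len(24) - 0.5) * 0.5)
  ii <- arrayInd(seq_along(v), dim(v))
  oracle <- c(sum(co[[1]][ii[, 1]] * v), sum(co[[2]][ii[, 2]] * v),
              sum(co[[3]][ii[, 3]] * v)) / sum(v)
  d1 <- detect_spots(one, 3, min_separation_um = 2, intensity_floor = 5)
  expect_lt(max(abs(d1[1, ] - oracle)), 0.25)          # within 0.5 voxel
  expect_lt(max(abs(d1[1, ] - c(4.3, 5.1, 6.2))), 0.25)

  # two spots closer than min_separation merge into one detection
  close <- render_scene(NULL, 0, c(6, 6, 6), 2, 0,
                        spot_centers = rbind(c(6, 6, 6), c(6, 6, 7)),
                        spot_sigma_um = 0.4, params = p)
  expect_equal(nrow(detect_spots(close, 3, min_separation_um = 3,
                                 intensity_floor = 5)), 1)
})

test_that("fold enrichment: identity, known ratio, scale invariance", {
  p <- render_params(voxel_size_um = c(0.5, 0.5, 0.5),
                     shape = c(24, 32, 32), psf_sigma_um = 0,
                     noise = FALSE)
  kt <- rbind(c(4, 4, 4), c(4, 10, 10))
  mz <- rbind(c(8, 12, 4), c(8, 4, 12))
  sc <- render_scene(NULL, 0, c(6, 8, 8), 2, 0,
                     spot_centers = rbind(kt, mz),
                     spot_amplitudes = c(1, 1, 12, 12),
                     spot_sigma_um = 0.4, params = p)
  expect_equal(measure_fold_enrichment(sc, 3, mz, kt, 1), 12,
               tolerance = 1e-6)
  expect_equal(measure_fold_enrichment(sc, 3, kt, kt, 1), 1,
               tolerance = 1e-12)
  sc2 <- sc; sc2$values <- sc$values * 37.5
  expect_equal(measure_fold_enrichment(sc2, 3, mz, kt, 1), 12,
               tolerance = 1e-6)
  dark <- voxel_stack(array(0, c(1, 8, 8, 8)), c(1, 1, 1))
  expect_error(measure_fold_enrichment(dark, 1, rbind(c(4, 4, 4)),
                                       rbind(c(2, 2, 2)), 1), "zero")
})

test_that("rendered chromatin volume tracks the generator trace", {
  cohort <- simulate_cohort(scenario_config("control", n_oocytes = 1,
                                            seed = 61))
  oo <- cohort[[1]]
  p <- render_params(voxel_size_um = c(1, 0.5, 0.5), shape = c(24, 72, 72),
                     psf_sigma_um = 0, noise = FALSE)
  t_eval <- oo$truth$t_nebd_onset + 180
  st <- render_stack(oo, t_eval, p)
  sg <- segment_chromatin(st, 1, method = "fixed", fixed_value = 50)
  v_true <- approx(oo$traces$chromosome_volume$times,
                   oo$traces$chromosome_volume$values, t_eval)$y
  expect_lt(abs(sg$volume_um3 - v_true) / v_true, 0.12)
  expect_error(render_stack(oo, -5, p), "outside")

  # dextran rendered at its trace fraction is recovered by the 2D probe
  dex_norm <- normalize_minmax(oo$traces$dextran)
  frac <- approx(dex_norm$times, dex_norm$values, t_eval)$y
  center <- p$shape * p$voxel_size_um / 2
  m_in <- measure_nuclear_intensity(st, 2, center, 4)
  cyto <- 0.2 * 100
  expect_equal((m_in - cyto) / 100, frac, tolerance = 0.05)
})
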