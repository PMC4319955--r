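test_that("homolog pairing matches distances, labels and a brute-force
           oracle", {
  ts <- make_small_tracks(m = 3)
  pairing <- pair_homologs(ts)
  expect_equal(unname(pairing[c("1", "2")]), c(1, 1))
  expect_equal(unname(pairing[c("3", "4")]), c(2, 2))

  # odd kinetochore count is a pairing error
  odd <- as.data.frame(ts$positions)
  odd <- odd[odd$kinetochore_id != 4, ]
  expect_error(pair_homologs(kinetochore_track_set(odd)), "even")

  # brute-force minimum-cost perfect matching on 6 kinetochores
  all_matchings <- function(ids) {
    if (length(ids) == 0) return(list(list()))
    a <- ids[1]
    out <- list()
    for (b in ids[-1]) {
      rest <- setdiff(ids, c(a, b))
      for (m in all_matchings(rest)) {
        out[[length(out) + 1]] <- c(list(c(a, b)), m)
      }
    }
    out
  }
  set.seed(31)
  for (rep in 1:5) {
    base <- matrix(runif(9, 0, 30), 3)
    pts <- rbind(base, base + matrix(rnorm(9, 0, 0.4), 3))
    rows <- do.call(rbind, lapply(0:2, function(k) {
      data.frame(time_min = k * 10, kinetochore_id = 1:6,
                 pair_id = NA_integer_,
                 x_um = pts[, 1] + rnorm(6, 0, 0.01),
                 y_um = pts[, 2] + rnorm(6, 0, 0.01),
                 z_um = pts[, 3] + rnorm(6, 0, 0.01))
    }))
    ts6 <- kinetochore_track_set(rows)
    got <- pair_homologs(ts6)
    # cost of a matching under the same time-averaged distance
    D <- Reduce(`+`, lapply(unique(rows$time_min), function(t) {
      as.matrix(dist(rows[rows$time_min == t, c("x_um", "y_um", "z_um")]))
    })) / 3
    cost <- function(m) sum(vapply(m, function(ab) D[ab[1], ab[2]], 0))
    best <- min(vapply(all_matchings(1:6), cost, 0))
    got_pairs <- split(as.integer(names(got)), got)
    expect_equal(cost(got_pairs), best, tolerance = 1e-9)
  }
})

test_that("noiseless synthetic pairing is 100% accurate", {
  params <- condition_preset("control")
  set.seed(32)
  s <- simulate_kinetochore_tracks(params, t_nebd = 60)
  truth_pairs <- s$tracks$positions[, c("kinetochore_id", "pair_id")]
  truth_map <- unique(as.data.frame(truth_pairs))
  got <- pair_homologs(s$tracks)
  # same partition: every true pair must map to one inferred pair id
  for (p in unique(truth_map$pair_id)) {
    kts <- as.character(truth_map$kinetochore_id[truth_map$pair_id == p])
    expect_equal(got[kts[1]], got[kts[2]], ignore_attr = TRUE)
  }
})

test_that("chromosome centers are pair midpoints with incomplete flags", {
  ts <- make_small_tracks()
  cc <- chromosome_centers(ts, 0)
  expect_equal(unname(cc$centers["1", ]), c(0.5, 0, 0))
  expect_equal(unname(cc$centers["2", ]), c(20.5, 0, 0))
  pos <- as.data.frame(ts$positions)
  cc2 <- chromosome_centers(kinetochore_track_set(pos[-1, ]), 0)
  expect_equal(nrow(cc2$centers), 1)
  expect_equal(cc2$incomplete, "1")
})

test_that("axis/equator estimation matches symmetric closed forms", {
  ang <- 2 * pi * (0:19) / 20
  circ <- cbind(10 * cos(ang), 10 * sin(ang), rep(3, 20))
  g <- estimate_axis_equator(circ)
  expect_equal(abs(g$axis), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(g$equator_point[3], 3)
  # alternating +/-2 um along the axis: mean |signed position| exactly 2
  alt <- cbind(10 * cos(ang), 10 * sin(ang), rep(c(2, -2), 10))
  g2 <- estimate_axis_equator(alt)
  d2 <- equator_distances(alt, g2)
  expect_equal(mean(d2$distance), 2, tolerance = 1e-9)
  expect_equal(abs(g2$axis[3]), 1, tolerance = 1e-9)
  expect_error(estimate_axis_equator(matrix(1, 5, 3)), "degenerate")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(estimate_axis_equator(line), "collinear")
})

test_that("equator distances are zero on-plane and rigid-invariant", {
  ang <- 2 * pi * (0:19) / 20
  pts <- cbind(10 * cos(ang), 10 * sin(ang), rnorm(20))
  g <- estimate_axis_equator(pts)
  on_plane <- pts - (pts %*% g$axis) %*% t(g$axis)
  gp <- estimate_axis_equator(on_plane)
  expect_lt(max(equator_distances(on_plane, gp)$distance), 1e-9)

  d0 <- equator_distances(pts, g)$distance
  set.seed(33)
  for (i in 1:20) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    pts2 <- t(R %*% t(pts)) + matrix(rnorm(3, 0, 10), 20, 3, byrow = TRUE)
    g2 <- estimate_axis_equator(pts2)
    expect_equal(sort(equator_distances(pts2, g2)$distance), sort(d0),
                 tolerance = 1e-8)
  }
})

test_that("belt membership is strictly greater than 0.707", {
  # opposite-point pairs keep the projected centroid exactly at the
  # origin, so normalized radial distance = radius / max radius = radius
  radii <- rep(c(1, 0.9, 0.8, 0.707, 0.5), each = 2)
  ang <- c(0, pi, 0.4, 0.4 + pi, 0.8, 0.8 + pi, 1.2, 1.2 + pi,
           1.6, 1.6 + pi)
  rows <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(time_min = 0, kinetochore_id = c(2 * i - 1, 2 * i),
               pair_id = i,
               x_um = radii[i] * cos(ang[i]),
               y_um = radii[i] * sin(ang[i]),
               z_um = c(0.001, -0.001))
  }))
  ts <- kinetochore_track_set(rows)
  res <- belt_analysis(ts, scan_from = 0)
  memb <- res$normalized_distances[["0"]] > res$threshold
  expect_equal(unname(memb),
               rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), each = 2))
  expect_equal(res$per_frame$belt_count, 6L)
})

test_that("t_belt equals a brute-force earliest-argmax oracle", {
  params <- condition_preset("control")
  set.seed(34)
  for (rep in 1:3) {
    s <- simulate_kinetochore_tracks(params, t_nebd = 60, duration = 8)
    res <- belt_analysis(s$tracks)
    # independent reimplementation of the membership definition
    tts <- track_times(s$tracks)
    counts <- vapply(tts, function(t) {
      cc <- chromosome_centers(s$tracks, t)$centers
      ctr <- colMeans(cc)
      X <- sweep(cc, 2, ctr)
      ax <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$vectors[, 3]
      proj <- X - (X %*% ax) %*% t(ax)
      r <- sqrt(rowSums(proj^2))
      sum(r / max(r) > 0.707)
    }, 0)
    keep <- tts - tts[1] >= 60
    t_expect <- tts[keep][which.max(counts[keep])]
    expect_equal(res$t_belt_min, t_expect)
  }
})

test_that("belt results are invariant under 100 random rigid motions", {
  params <- condition_preset("control")
  set.seed(35)
  s <- simulate_kinetochore_tracks(params, t_nebd = 60, duration = 4)
  base <- belt_analysis(s$tracks)
  for (i in 1:100) {
    ts2 <- rigid_transform_tracks(s$tracks)
    res <- belt_analysis(ts2)
    expect_equal(res$t_belt_min, base$t_belt_min)
    expect_equal(res$per_frame$belt_count, base$per_frame$belt_count)
  }
})

test_that("interkinetochore distances match hand values and skip
           incomplete pairs", {
  ts <- make_small_tracks()
  d <- interkinetochore_distances(ts, 0)
  expect_equal(as.numeric(d), c(1, 1))
  pos <- as.data.frame(ts$positions)
  ts2 <- kinetochore_track_set(pos[-1, ])
  d2 <- interkinetochore_distances(ts2, 0)
  expect_equal(names(d2), "2")
  expect_equal(attr(d2, "skipped"), "1")
  co <- rbind(data.frame(time_min = 0, kinetochore_id = 1:2, pair_id = 1,
                         x_um = 5, y_um = 5, z_um = 5))
  expect_equal(as.numeric(interkinetochore_distances(
    kinetochore_track_set(co), 0)), 0)
})

test_that("spindle elongation time and volume interpolation are exact", {
  tt <- seq(0, 4, by = 0.25)
  rise <- intensity_trace(tt, 1 + tt / 4)   # reaches 2 at 4 h
  expect_equal(spindle_elongation_time(rise, threshold = 1.5), 2)
  flat <- intensity_trace(tt, rep(1, length(tt)))
  expect_true(is.na(spindle_elongation_time(flat)))

  vol <- intensity_trace(c(5.5, 6.5), c(900, 1100))
  expect_equal(spindle_volume_at(vol, 6), 1000)
  exact <- intensity_trace(c(5, 6, 7), c(800, 1000, 1200))
  expect_equal(spindle_volume_at(exact, 6), 1000)
  expect_error(spindle_volume_at(exact, -1), "outside")
})
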