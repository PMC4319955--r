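#' Kinetochore track sets
#'
#' A `KinetochoreTrackSet` holds the 3D positions of all kinetochores of one
#' oocyte over time, plus the homolog-pair labels. Positions are stored as a
#' long-format `data.table` with columns `time_min`, `kinetochore_id`,
#' `pair_id`, `x_um`, `y_um`, `z_um`. Times are minutes on the on-disk axis
#' (since induction of meiotic resumption); tracks start at NEBD, when
#' individual kinetochores first become resolvable.
#'
#' @param positions A data.frame with the columns above (`pair_id` may be
#'   `NA` when unlabeled).
#' @param oocyte_id Identifier of the oocyte.
#' @return A `KinetochoreTrackSet`.
#' @export
kinetochore_track_set <- function(positions, oocyte_id = "oocyte") {
  req <- c("time_min", "kinetochore_id", "pair_id", "x_um", "y_um", "z_um")
  missing_cols <- setdiff(req, names(positions))
  if (length(missing_cols)) {
    stop("track table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt <- data.table::as.data.table(positions)[, req, with = FALSE]
  if (any(!is.finite(as.matrix(dt[, c("x_um", "y_um", "z_um")])))) {
    stop("kinetochore coordinates must be finite", call. = FALSE)
  }
  data.table::setkeyv(dt, c("time_min", "kinetochore_id"))
  # flag frames where any pair does not have exactly 2 members
  frame_ok <- dt[!is.na(pair_id),
                 .(ok = all(table(pair_id) == 2L)), by = time_min]
  flagged <- frame_ok[ok == FALSE, time_min]
  structure(list(positions = dt, oocyte_id = oocyte_id,
                 flagged_frames = flagged),
            class = "KinetochoreTrackSet")
}

#' @export
print.KinetochoreTrackSet <- function(x, ...) {
  cat(sprintf("KinetochoreTrackSet '%s': %d kinetochores, %d frames\n",
              x$oocyte_id, length(unique(x$positions$kinetochore_id)),
              length(unique(x$positions$time_min))))
  invisible(x)
}

#' Frame times of a track set
#' @param track_set A [kinetochore_track_set()].
#' @return Sorted vector of frame times (minutes).
#' @export
track_times <- function(track_set) sort(unique(track_set$positions$time_min))

# positions of one frame as a matrix with kinetochore ids as rownames
frame_matrix <- function(track_set, t) {
  fr <- track_set$positions[time_min == t]
  m <- as.matrix(fr[, c("x_um", "y_um", "z_um")])
  rownames(m) <- as.character(fr$kinetochore_id)
  m
}

#' Pair homologous kinetochores from positions alone
#'
#' Finds a perfect matching of kinetochores into homolog pairs that
#' minimizes the total time-averaged pairwise distance over the first
#' `n_frames` frames. Because sister-derived homologous kinetochores stay
#' within ~1 um of each other while different bivalents are several um
#' apart, a greedy nearest-pair matching followed by 2-swap refinement
#' attains the minimum-cost matching in this regime; exactness against a
#' brute-force enumeration is established in the test suite for small sets.
#' Ties are broken by lowest kinetochore id.
#'
#' @param track_set A [kinetochore_track_set()] (pairing labels ignored).
#' @param n_frames Number of initial frames averaged (default 5).
#' @return Named integer vector: pair id per kinetochore id.
#' @export
pair_homologs <- function(track_set, n_frames = 5L) {
  tts <- track_times(track_set)
  if (length(tts) < 3) stop("need at least 3 frames to pair", call. = FALSE)
  use <- tts[seq_len(min(n_frames, length(tts)))]
  ids <- sort(unique(track_set$positions$kinetochore_id))
  n <- length(ids)
  if (n < 2 || n %% 2 != 0) {
    stop("pairing requires an even number (>= 2) of kinetochores",
         call. = FALSE)
  }
  # time-averaged distance matrix over the first frames
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  cnt <- 0L
  for (t in use) {
    m <- frame_matrix(track_set, t)
    m <- m[as.character(ids), , drop = FALSE]
    D <- D + as.matrix(stats::dist(m))
    cnt <- cnt + 1L
  }
  D <- D / cnt

  # greedy: repeatedly take the globally closest unmatched couple
  unmatched <- seq_len(n)
  pairs <- list()
  Dw <- D
  diag(Dw) <- Inf
  while (length(unmatched) > 1) {
    sub <- Dw[unmatched, unmatched, drop = FALSE]
    k <- which(sub == min(sub), arr.ind = TRUE)
    # deterministic tie-break: lowest row then column index
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
    a <- unmatched[min(k)]; b <- unmatched[max(k)]
    pairs[[length(pairs) + 1]] <- c(a, b)
    unmatched <- setdiff(unmatched, c(a, b))
  }
  # 2-swap refinement: exchange partners while it lowers the total cost
  cost <- function(p) sum(vapply(p, function(ab) D[ab[1], ab[2]], 0))
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    np <- length(pairs)
    for (i in seq_len(np - 1)) {
      for (j in seq((i + 1), np)) {
        a <- pairs[[i]]; b <- pairs[[j]]
        base <- D[a[1], a[2]] + D[b[1], b[2]]
        alt1 <- D[a[1], b[1]] + D[a[2], b[2]]
        alt2 <- D[a[1], b[2]] + D[a[2], b[1]]
        if (alt1 < base - 1e-12 && alt1 <= alt2) {
          pairs[[i]] <- c(a[1], b[1]); pairs[[j]] <- c(a[2], b[2])
          improved <- TRUE
        } else if (alt2 < base - 1e-12) {
          pairs[[i]] <- c(a[1], b[2]); pairs[[j]] <- c(a[2], b[1])
          improved <- TRUE
        }
      }
    }
  }
  # assign pair ids ordered by lowest member kinetochore id
  ord <- order(vapply(pairs, min, 0))
  out <- integer(n); names(out) <- as.character(ids)
  for (pi in seq_along(ord)) {
    ab <- pairs[[ord[pi]]]
    out[as.character(ids[ab])] <- pi
  }
  out
}

#' Chromosome centers (kinetochore-pair midpoints) of one frame
#'
#' @param track_set A [kinetochore_track_set()] with `pair_id` labels.
#' @param t Frame time (must be an existing frame).
#' @return List with `centers` (matrix, one row per complete pair, rownames
#'   = pair id) and `incomplete` (pair ids with != 2 members, flagged and
#'   omitted).
#' @export
chromosome_centers <- function(track_set, t) {
  fr <- track_set$positions[time_min == t & !is.na(pair_id)]
  if (nrow(fr) == 0) stop("no labeled kinetochores at t = ", t, call. = FALSE)
  counts <- table(fr$pair_id)
  good <- names(counts)[counts == 2L]
  bad <- setdiff(names(counts), good)
  centers <- t(vapply(good, function(p) {
    colMeans(as.matrix(fr[pair_id == p, c("x_um", "y_um", "z_um")]))
  }, numeric(3)))
  list(centers = centers, incomplete = bad)
}

#' Estimate the spindle axis and chromosome-distribution equator
#'
#' The equator point is the centroid of the chromosome centers; the spindle
#' axis is the principal direction of least variance of the centers (for a
#' belt or metaphase plate, the plane normal), i.e. the eigenvector of the
#' smallest eigenvalue of the centered covariance. The equator plane passes
#' through the centroid with the axis as its normal. The axis sign is fixed
#' deterministically (positive z component, tie-broken by y then x).
#'
#' @param centers Numeric matrix (>= 3 rows, 3 columns) of chromosome
#'   centers in um.
#' @return List with unit vector `axis`, `equator_point`, and the
#'   eigenvalues `spread` (descending).
#' @export
estimate_axis_equator <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 3) stop("need >= 3 chromosome centers", call. = FALSE)
  ctr <- colMeans(centers)
  X <- sweep(centers, 2, ctr)
  if (all(abs(X) < 1e-12)) {
    stop("degenerate geometry: all chromosome centers identical",
         call. = FALSE)
  }
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  axis <- ev$vectors[, 3]
  # collinear centers leave the normal direction undefined
  if (ev$values[2] < 1e-10 * max(ev$values[1], 1e-300)) {
    stop("degenerate geometry: chromosome centers are collinear",
         call. = FALSE)
  }
  s <- sign(axis[3])
  if (s == 0) s <- sign(axis[2])
  if (s == 0) s <- sign(axis[1])
  if (s == 0) s <- 1
  axis <- axis * s
  list(axis = axis, equator_point = ctr, spread = ev$values)
}

#' Signed axis positions and distances of chromosomes from the equator
#'
#' @param centers Matrix of chromosome centers (um).
#' @param geometry Result of [estimate_axis_equator()].
#' @return List with `signed` (signed position along the axis, um) and
#'   `distance` (absolute value).
#' @export
equator_distances <- function(centers, geometry) {
  signed <- as.numeric(sweep(as.matrix(centers), 2, geometry$equator_point)
                       %*% geometry$axis)
  list(signed = signed, distance = abs(signed))
}

#' Prometaphase-belt analysis of a track set
#'
#' Per frame, chromosome centers are projected onto the equator plane; the
#' radial distance of each chromosome from the projected centroid is
#' normalized by that frame's most distal chromosome. A chromosome belongs
#' to the prometaphase belt iff its normalized radial distance is strictly
#' greater than 0.707. The belt-formation time `t_belt` is the earliest
#' frame at which the belt count attains its global maximum over the
#' recording.
#'
#' @param track_set A [kinetochore_track_set()].
#' @param threshold Strict normalized-distance threshold (default 0.707).
#' @param scan_from Earliest time (minutes on the track axis, relative to
#'   track start) included in the `t_belt` scan; the axis/equator estimate
#'   is meaningless while chromosomes are still a dispersed ball, so the
#'   scan starts 60 min after track start by default.
#' @return A `BeltResult` list: per-frame table (`time_min`, `belt_count`,
#'   `n_chromosomes`), list of normalized distances per frame, `t_belt_min`
#'   (absolute trace time) and `t_belt` in hours after track start (=NEBD),
#'   plus flagged frames (< 3 chromosomes, excluded from the scan).
#' @export
belt_analysis <- function(track_set, threshold = 0.707, scan_from = 60) {
  tts <- track_times(track_set)
  t0 <- tts[1]
  rows <- list(); norm_dists <- list(); flagged <- numeric(0)
  for (t in tts) {
    cc <- chromosome_centers(track_set, t)
    if (nrow(cc$centers) < 3) { flagged <- c(flagged, t); next }
    geom <- estimate_axis_equator(cc$centers)
    X <- sweep(cc$centers, 2, geom$equator_point)
    ax <- geom$axis
    inplane <- X - (X %*% ax) %*% t(ax)
    r <- sqrt(rowSums(inplane^2))
    rn <- r / max(r)
    member <- rn > threshold
    rows[[length(rows) + 1]] <- data.frame(
      time_min = t, belt_count = sum(member), n_chromosomes = length(rn))
    norm_dists[[as.character(t)]] <- rn
  }
  per_frame <- do.call(rbind, rows)
  scan <- per_frame[per_frame$time_min - t0 >= scan_from, , drop = FALSE]
  if (nrow(scan) == 0) scan <- per_frame
  t_belt_min <- scan$time_min[which.max(scan$belt_count)]  # earliest max
  structure(list(per_frame = per_frame, normalized_distances = norm_dists,
                 t_belt_min = t_belt_min,
                 t_belt = (t_belt_min - t0) / 60,
                 flagged_frames = flagged, threshold = threshold),
            class = "BeltResult")
}

#' Spindle axis pooled over a time window
#'
#' Least-variance principal direction of chromosome centers pooled over
#' all frames in `[t_from, t_to]`, each frame centered at its own
#' centroid. Pooling is the preferred way to fix the axis for late-time
#' measurements: after biorientation defects (PLK1 inhibition) the axial
#' spread can rival the belt radius, so a single late frame no longer
#' determines the axis, while the frames around belt formation do.
#'
#' @param track_set A [kinetochore_track_set()].
#' @param t_from,t_to Window bounds (minutes, absolute track time).
#' @return Unit axis vector (sign fixed as in [estimate_axis_equator()]),
#'   with the conditioning ratio lambda2/lambda3 as attribute `gap`.
#' @export
pooled_axis <- function(track_set, t_from, t_to) {
  tts <- track_times(track_set)
  use <- tts[tts >= t_from & tts <= t_to]
  if (!length(use)) use <- tts[which.min(abs(tts - t_from))]
  pooled <- do.call(rbind, lapply(use, function(t) {
    cc <- chromosome_centers(track_set, t)$centers
    sweep(cc, 2, colMeans(cc))
  }))
  ev <- eigen(crossprod(pooled) / nrow(pooled), symmetric = TRUE)
  axis <- ev$vectors[, 3]
  s <- sign(axis[3])
  if (s == 0) s <- sign(axis[2])
  if (s == 0) s <- sign(axis[1])
  if (s == 0) s <- 1
  structure(axis * s, gap = ev$values[2] / max(ev$values[3], 1e-12))
}

#' Lock the spindle geometry for late-time measurements
#'
#' Fixes a reference axis and equator point for all frames after belt
#' formation. The axis comes from [pooled_axis()] over the
#' best-conditioned of several candidate windows starting at `t_from`
#' (largest ratio of the middle to the smallest pooled eigenvalue); the
#' equator point is the mean of the per-frame centroids over all frames
#' from `t_from` on. Both pools are justified because the recordings are
#' drift-free (real movies are drift-registered before analysis) and the
#' spindle position is stationary on this time scale.
#'
#' @param track_set A [kinetochore_track_set()].
#' @param t_from Belt-formation time (minutes, absolute track time).
#' @param windows Candidate axis-window lengths in minutes.
#' @return List with `axis`, `equator_point` and the chosen `window`.
#' @export
locked_geometry <- function(track_set, t_from,
                            windows = c(30, 60, 120, 240)) {
  cands <- lapply(windows, function(w) pooled_axis(track_set, t_from,
                                                   t_from + w))
  gaps <- vapply(cands, function(a) attr(a, "gap"), 0)
  axis <- as.numeric(cands[[which.max(gaps)]])
  tts <- track_times(track_set)
  use <- tts[tts >= t_from]
  ctrs <- t(vapply(use, function(t) {
    colMeans(chromosome_centers(track_set, t)$centers)
  }, numeric(3)))
  list(axis = axis, equator_point = colMeans(ctrs),
       window = windows[which.max(gaps)])
}

#' Inter-kinetochore distances of homologous pairs at one time
#'
#' Euclidean distance between the two kinetochores of each bivalent at the
#' frame nearest to `t`; a tension proxy for kinetochore-microtubule
#' attachment.
#'
#' @param track_set A [kinetochore_track_set()] with pair labels.
#' @param t Target time in minutes (nearest frame used).
#' @return Named numeric vector of distances (um) per pair id; incomplete
#'   pairs are skipped with a warning attribute `skipped`.
#' @export
interkinetochore_distances <- function(track_set, t) {
  tts <- track_times(track_set)
  tf <- tts[which.min(abs(tts - t))]
  fr <- track_set$positions[time_min == tf & !is.na(pair_id)]
  counts <- table(fr$pair_id)
  good <- names(counts)[counts == 2L]
  out <- vapply(good, function(p) {
    m <- as.matrix(fr[pair_id == p, c("x_um", "y_um", "z_um")])
    sqrt(sum((m[1, ] - m[2, ])^2))
  }, 0)
  attr(out, "skipped") <- setdiff(names(counts), good)
  attr(out, "frame_time") <- tf
  out
}

#' Spindle elongation time from an aspect-ratio trace
#'
#' First sustained crossing of the aspect-ratio threshold (default 1.5) on
#' the trace of spindle length/width, linearly interpolated. The trace's
#' time axis is preserved (the pipeline feeds hours post-NEBD).
#'
#' @param aspect_trace An [intensity_trace()] whose times are hours and
#'   values are aspect ratios starting near 1.
#' @param threshold Aspect-ratio detection threshold (default 1.5).
#' @param sustain Frames the ratio must stay above threshold (default 2).
#' @return Crossing time in the trace's units, or `NA` (never crosses:
#'   metaphase-arrest-like spindle).
#' @export
spindle_elongation_time <- function(aspect_trace, threshold = 1.5,
                                    sustain = 2L) {
  v <- aspect_trace$values
  tt <- aspect_trace$times
  n <- length(v)
  for (i in seq_len(n - 1)) {
    if (v[i] <= threshold && v[i + 1] > threshold) {
      hold <- v[seq(i + 1, min(i + sustain, n))]
      if (all(hold > threshold)) {
        return(tt[i] + (threshold - v[i]) / (v[i + 1] - v[i]) *
                 (tt[i + 1] - tt[i]))
      }
    }
  }
  if (v[1] > threshold) return(tt[1])
  NA_real_
}

#' Spindle volume at a given time
#'
#' Linear interpolation of the spindle-volume trace at `t` (e.g. 6 h after
#' NEBD, the standard comparison point).
#'
#' @param volume_trace An [intensity_trace()] of spindle volume (um^3).
#' @param t Time in the trace's units; must be within support.
#' @return Volume in um^3.
#' @export
spindle_volume_at <- function(volume_trace, t) {
  trace_value_at(volume_trace, t)
}
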