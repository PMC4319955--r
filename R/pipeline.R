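## End-to-end analysis: traces + tracks -> events.csv, geometry.csv,
## kinetics.csv. All detection parameters are exposed with the package
## defaults documented in the methods vignette.

#' Event analysis of one oocyte's traces
#'
#' Runs dextran/condensation onset detection, activation onset of the
#' MTOC kinase marker, and lamin disassembly duration, when the
#' corresponding streams are present.
#'
#' @param traces Named list of [intensity_trace()] for one oocyte.
#' @param lo,hi,sustain Threshold parameters ([detect_onset_end()]).
#' @return One-row data.frame: `t1`, `t1_end`, `t2`, `t2_end`, `delay`,
#'   `pplk1_onset`, `lamin_duration`, `flags` (semicolon-joined).
#' @export
analyze_events <- function(traces, lo = 0.1, hi = 0.9, sustain = 2L) {
  out <- data.frame(t1 = NA_real_, t1_end = NA_real_, t2 = NA_real_,
                    t2_end = NA_real_, delay = NA_real_,
                    pplk1_onset = NA_real_, lamin_duration = NA_real_,
                    flags = "")
  flags <- character(0)
  if (all(c("dextran", "chromosome_volume") %in% names(traces))) {
    ev <- condensation_nebd_delay(traces$chromosome_volume,
                                  traces$dextran,
                                  lo = lo, hi = hi, sustain = sustain)
    out$t1 <- ev$t1; out$t1_end <- ev$t1_end
    out$t2 <- ev$t2; out$t2_end <- ev$t2_end
    out$delay <- ev$delay
    flags <- c(flags, ev$flags)
  }
  if ("pplk1_mtoc" %in% names(traces) && !is.na(out$t1)) {
    out$pplk1_onset <- activation_onset(traces$pplk1_mtoc, out$t1,
                                        floor = lo, sustain = sustain)
    if (is.na(out$pplk1_onset)) flags <- c(flags, "no_pplk1_onset")
  }
  if ("lamin" %in% names(traces)) {
    out$lamin_duration <- disassembly_duration(traces$lamin, lo = lo,
                                               hi = hi, sustain = sustain)
    if (is.na(out$lamin_duration)) flags <- c(flags, "no_lamin_event")
  }
  out$flags <- paste(flags, collapse = ";")
  out
}

#' Geometry analysis of one oocyte
#'
#' Belt formation time, chromosome-equator distances at belt formation and
#' two hours later, the post-belt maximum |axis position|, mean
#' inter-kinetochore distance at metaphase (t_belt + 2 h), and spindle
#' elongation time / volume when the spindle streams are available.
#'
#' @param track_set A [kinetochore_track_set()].
#' @param traces Optional named list of traces (`spindle_aspect`,
#'   `spindle_volume`, times in minutes since induction).
#' @param t_nebd NEBD time in minutes (defaults to the first track frame).
#' @param belt_threshold Strict belt-membership threshold (default 0.707).
#' @param aspect_threshold Spindle elongation threshold (default 1.5).
#' @return One-row data.frame with the geometry metrics (hours post-NEBD
#'   for times) plus per-chromosome details as attributes
#'   `eq_dist_belt`, `eq_dist_late`, `ikt`.
#' @export
analyze_geometry <- function(track_set, traces = NULL, t_nebd = NULL,
                             belt_threshold = 0.707,
                             aspect_threshold = 1.5) {
  tts <- track_times(track_set)
  if (is.null(t_nebd)) t_nebd <- tts[1]
  belt <- belt_analysis(track_set, threshold = belt_threshold)
  t_belt_abs <- belt$t_belt_min
  # distances at belt formation: per-frame axis/equator estimate
  tf_belt <- tts[which.min(abs(tts - t_belt_abs))]
  cc_belt <- chromosome_centers(track_set, tf_belt)
  geom_belt <- estimate_axis_equator(cc_belt$centers)
  d_belt <- equator_distances(cc_belt$centers, geom_belt)$distance
  # later frames: axis and equator point locked after belt formation
  # (the spindle is stationary in drift-registered recordings)
  ref <- locked_geometry(track_set, t_belt_abs)
  dist_fixed_axis <- function(t_target) {
    tf <- tts[which.min(abs(tts - t_target))]
    cc <- chromosome_centers(track_set, tf)$centers
    abs(as.numeric(sweep(cc, 2, ref$equator_point) %*% ref$axis))
  }
  d_late <- dist_fixed_axis(t_belt_abs + 120)
  post <- tts[tts >= t_belt_abs]
  max_abs <- max(vapply(post, function(t) max(dist_fixed_axis(t)), 0))
  ikt <- interkinetochore_distances(track_set, t_belt_abs + 120)

  out <- data.frame(
    t_belt = (t_belt_abs - t_nebd) / 60,
    mean_eq_dist_belt = mean(d_belt),
    mean_eq_dist_late = mean(d_late),
    max_axis_excursion = max_abs,
    mean_ikt = mean(ikt),
    t_elongation = NA_real_,
    spindle_volume_6h = NA_real_)
  if (!is.null(traces) && "spindle_aspect" %in% names(traces)) {
    asp <- traces$spindle_aspect
    asp_h <- intensity_trace((asp$times - t_nebd) / 60, asp$values,
                             stream = asp$stream)
    out$t_elongation <- spindle_elongation_time(asp_h,
                                                threshold =
                                                  aspect_threshold)
  }
  if (!is.null(traces) && "spindle_volume" %in% names(traces)) {
    sv <- traces$spindle_volume
    sv_h <- intensity_trace((sv$times - t_nebd) / 60, sv$values,
                            stream = sv$stream)
    if (6 >= sv_h$times[1] && 6 <= sv_h$times[length(sv_h$times)]) {
      out$spindle_volume_6h <- spindle_volume_at(sv_h, 6)
    }
  }
  attr(out, "eq_dist_belt") <- d_belt
  attr(out, "eq_dist_late") <- d_late
  attr(out, "ikt") <- ikt
  out
}

#' Degradation-kinetics analysis of one reporter trace
#'
#' Converts the trace to hours relative to the reference time, normalizes
#' it to 1 at that reference, fits the degradation line and classifies the
#' outcome.
#'
#' @param trace Raw reporter [intensity_trace()] (minutes since
#'   induction).
#' @param t_ref_min Reference time in minutes (NEBD, drug addition or
#'   washout, depending on the experiment).
#' @param segregation_flag,pb_flag,decondense_flag Anaphase annotations
#'   (from ground truth or manual scoring).
#' @return One-row data.frame: `T_start`, `D_rate`, `I_min`, `t_min`
#'   (hours on the reference axis), `fit_valid`, `category`.
#' @export
analyze_kinetics <- function(trace, t_ref_min,
                             segregation_flag = FALSE, pb_flag = FALSE,
                             decondense_flag = FALSE) {
  tr_h <- intensity_trace((trace$times - t_ref_min) / 60, trace$values,
                          stream = trace$stream)
  i_norm <- normalize_cytoplasmic(tr_h, t_ref = max(tr_h$times[1], 0))
  fit <- fit_degradation(i_norm)
  category <- classify_outcome(fit, fit$I_min, segregation_flag, pb_flag,
                               decondense_flag)
  data.frame(T_start = fit$T_start, D_rate = fit$D_rate,
             I_min = fit$I_min, t_min = fit$t_min,
             fit_valid = fit$fit_valid, category = category)
}

#' Analyze a cohort directory
#'
#' Reads `traces.csv` / `tracks.csv` (and `truth.csv` when present, for
#' the degradation reference axis and anaphase annotations), runs the
#' three analysis stages for every oocyte and writes `events.csv`,
#' `geometry.csv` and `kinetics.csv`. Running it twice on the same inputs
#' produces byte-identical outputs.
#'
#' @param in_dir Directory with the cohort tables.
#' @param out_dir Output directory (created if needed).
#' @return Named list of the three result `data.table`s, invisibly.
#' @export
analyze_dir <- function(in_dir, out_dir) {
  traces_all <- read_traces(file.path(in_dir, "traces.csv"))
  tracks_all <- if (file.exists(file.path(in_dir, "tracks.csv"))) {
    read_tracks(file.path(in_dir, "tracks.csv"))
  } else list()
  truth <- if (file.exists(file.path(in_dir, "truth.csv"))) {
    read_truth(file.path(in_dir, "truth.csv"))
  } else NULL
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  oids <- names(traces_all)
  ev <- list(); ge <- list(); ki <- list()
  for (oid in oids) {
    trs <- traces_all[[oid]]
    e <- analyze_events(trs)
    ev[[oid]] <- data.frame(oocyte_id = oid, e)
    t_nebd <- e$t1
    if (oid %in% names(tracks_all)) {
      g <- analyze_geometry(tracks_all[[oid]], traces = trs,
                            t_nebd = if (is.na(t_nebd)) NULL else t_nebd)
      ge[[oid]] <- data.frame(oocyte_id = oid, g)
    }
    tr_row <- if (!is.null(truth)) truth[truth$oocyte_id == oid, ] else NULL
    for (stream in intersect(c("securin", "cyclin", "emi1"), names(trs))) {
      t_ref <- if (!is.null(tr_row) && nrow(tr_row) == 1 &&
                   "t_ref_min" %in% names(tr_row)) {
        tr_row$t_ref_min
      } else if (!is.na(t_nebd)) t_nebd else 0
      seg <- isTRUE(!is.null(tr_row) && nrow(tr_row) == 1 &&
                      isTRUE(tr_row$segregation))
      pb <- isTRUE(!is.null(tr_row) && nrow(tr_row) == 1 &&
                     isTRUE(tr_row$pb))
      dec <- isTRUE(!is.null(tr_row) && nrow(tr_row) == 1 &&
                      isTRUE(tr_row$decondense))
      k <- analyze_kinetics(trs[[stream]], t_ref, seg, pb, dec)
      ki[[paste(oid, stream)]] <- data.frame(oocyte_id = oid,
                                             stream = stream, k)
    }
  }
  events <- data.table::rbindlist(ev)
  geometry <- data.table::rbindlist(ge)
  kinetics <- data.table::rbindlist(ki)
  data.table::fwrite(events, file.path(out_dir, "events.csv"))
  if (nrow(geometry)) {
    data.table::fwrite(geometry, file.path(out_dir, "geometry.csv"))
  }
  data.table::fwrite(kinetics, file.path(out_dir, "kinetics.csv"))
  write_provenance(out_dir)
  invisible(list(events = events, geometry = geometry,
                 kinetics = kinetics))
}
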