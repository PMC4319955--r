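#' Simulate a cohort of oocytes for one condition
#'
#' Draws `n_oocytes` independent oocytes from the condition's preset
#' distributions. Reproducibility: the scenario seed generates one sub-seed
#' per oocyte, so cohorts are bit-identical for identical configs and the
#' per-oocyte streams do not interact.
#'
#' @param config A [scenario_config()] (or a condition name, for
#'   convenience with all defaults).
#' @param n_oocytes,seed Optional overrides of the config fields.
#' @return An `OocyteCohort`: list of `SimulatedOocyte` objects, each with
#'   `oocyte_id`, `condition`, `traces` (named list of
#'   [intensity_trace()]), `tracks` (a [kinetochore_track_set()]) and
#'   `truth` (named list of generative parameters).
#' @export
simulate_cohort <- function(config, n_oocytes = NULL, seed = NULL) {
  if (is.character(config)) config <- scenario_config(condition = config)
  stopifnot(inherits(config, "ScenarioConfig"))
  if (!is.null(n_oocytes)) config$n_oocytes <- as.integer(n_oocytes)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  params <- condition_preset(config$condition, config$parameter_overrides)
  fi <- config$frame_interval
  dur <- config$duration

  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_oocytes)

  cohort <- vector("list", config$n_oocytes)
  for (i in seq_len(config$n_oocytes)) {
    set.seed(sub_seeds[i])
    oid <- sprintf("%s_%03d", config$condition, i)

    res <- simulate_resumption_traces(params, fi$resumption, dur)
    t_nebd <- res$truth$t_nebd_onset
    deg <- simulate_degradation_trace(params, t_nebd, fi$degradation, dur)
    cyc <- simulate_degradation_trace(params, t_nebd, fi$degradation, dur,
                                      stream = "cyclin")
    spn <- simulate_spindle_trace(params, t_nebd, fi$spindle, dur)
    ppl <- simulate_pplk1_trace(params, t_nebd, fi$pplk1, dur)
    lam <- simulate_lamin_trace(params, t_nebd, fi$lamin, dur)
    trk <- simulate_kinetochore_tracks(params, t_nebd, fi$tracks, dur,
                                       oocyte_id = oid)

    truth <- c(res$truth, deg$truth, spn$truth, ppl$truth,
               lam$truth[c("lamin_duration")], trk$truth)
    cohort[[i]] <- structure(
      list(oocyte_id = oid,
           condition = config$condition,
           traces = list(dextran = res$dextran,
                         chromosome_volume = res$chromosome_volume,
                         securin = deg$trace,
                         cyclin = cyc$trace,
                         pplk1_mtoc = ppl$trace,
                         lamin = lam$trace,
                         spindle_volume = spn$spindle_volume,
                         spindle_aspect = spn$spindle_aspect),
           tracks = trk$tracks,
           truth = truth),
      class = "SimulatedOocyte")
  }
  structure(cohort, class = "OocyteCohort",
            condition = config$condition, config = config)
}

#' @export
print.OocyteCohort <- function(x, ...) {
  cat(sprintf("OocyteCohort: %d oocytes, condition '%s'\n",
              length(x), attr(x, "condition")))
  invisible(x)
}

#' Convert a simulated cohort to long-format tables
#'
#' @param cohort An `OocyteCohort`.
#' @return List of `data.table`s: `traces` (oocyte_id, stream, time_min,
#'   value), `tracks` (oocyte_id, time_min, kinetochore_id, pair_id, x_um,
#'   y_um, z_um), `truth` (one row per oocyte).
#' @export
cohort_tables <- function(cohort) {
  traces <- data.table::rbindlist(lapply(cohort, function(oo) {
    data.table::rbindlist(lapply(oo$traces, function(tr) {
      data.table::data.table(oocyte_id = oo$oocyte_id, stream = tr$stream,
                             time_min = tr$times, value = tr$values)
    }))
  }))
  tracks <- data.table::rbindlist(lapply(cohort, function(oo) {
    data.table::data.table(oocyte_id = oo$oocyte_id, oo$tracks$positions)
  }))
  truth <- data.table::rbindlist(lapply(cohort, function(oo) {
    tr <- oo$truth
    scalar <- tr[vapply(tr, function(x) length(x) == 1 &&
                          !is.list(x), logical(1))]
    data.table::data.table(oocyte_id = oo$oocyte_id,
                           condition = oo$condition,
                           as.data.frame(scalar))
  }), fill = TRUE)
  list(traces = traces, tracks = tracks, truth = truth)
}
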