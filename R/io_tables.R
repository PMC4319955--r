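## CSV I/O for cohort tables. Dialect: comma-separated, UTF-8, header row,
## '.' decimal separator. All on-disk times are minutes since induction of
## meiotic resumption; NEBD-relative times are derived, never stored.

#' Write cohort tables to a directory
#'
#' Writes `traces.csv`, `tracks.csv` and (for synthetic data) `truth.csv`,
#' plus a provenance log.
#'
#' @param tables List as produced by [cohort_tables()].
#' @param dir Output directory (created if needed).
#' @param config Optional [scenario_config()] recorded in the provenance
#'   log.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(tables, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(tables$traces, file.path(dir, "traces.csv"))
  data.table::fwrite(tables$tracks, file.path(dir, "tracks.csv"))
  if (!is.null(tables$truth)) {
    data.table::fwrite(tables$truth, file.path(dir, "truth.csv"))
  }
  write_provenance(dir, config)
  invisible(dir)
}

#' Read per-oocyte intensity traces from traces.csv
#'
#' @param path Path to a traces CSV with columns `oocyte_id`, `stream`,
#'   `time_min`, `value`.
#' @return Named list (by oocyte id) of named lists of
#'   [intensity_trace()].
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  req <- c("oocyte_id", "stream", "time_min", "value")
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) {
    stop("traces file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (oid in unique(dt$oocyte_id)) {
    sub <- dt[oocyte_id == oid]
    out[[as.character(oid)]] <- sapply(unique(sub$stream), function(s) {
      ss <- sub[stream == s][order(time_min)]
      intensity_trace(ss$time_min, ss$value, stream = s)
    }, simplify = FALSE)
  }
  out
}

#' Read kinetochore track sets from tracks.csv
#'
#' Groups rows by oocyte and validates each track set; frames in which a
#' homolog pair does not have exactly two members are flagged (in
#' `flagged_frames`), never silently dropped.
#'
#' @param path Path to a tracks CSV with columns `oocyte_id`, `time_min`,
#'   `kinetochore_id`, `pair_id`, `x_um`, `y_um`, `z_um`.
#' @return Named list of [kinetochore_track_set()] per oocyte.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  req <- c("oocyte_id", "time_min", "kinetochore_id", "pair_id",
           "x_um", "y_um", "z_um")
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) {
    stop("tracks file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (oid in unique(dt$oocyte_id)) {
    ts <- kinetochore_track_set(dt[oocyte_id == oid], oocyte_id = oid)
    if (length(ts$flagged_frames)) {
      warning(sprintf(
        "oocyte %s: %d frame(s) with incomplete homolog pairs flagged",
        oid, length(ts$flagged_frames)), call. = FALSE)
    }
    out[[as.character(oid)]] <- ts
  }
  out
}

#' Write kinetochore track sets to a CSV
#'
#' Inverse of [read_tracks()]; full numeric precision is preserved up to
#' the 15-significant-digit text representation.
#'
#' @param track_sets Named list of [kinetochore_track_set()].
#' @param path Output CSV path.
#' @export
write_tracks <- function(track_sets, path) {
  dt <- data.table::rbindlist(lapply(names(track_sets), function(oid) {
    data.table::data.table(oocyte_id = oid,
                           track_sets[[oid]]$positions)
  }))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read generator ground truth from truth.csv
#' @param path Path to a truth CSV.
#' @return A `data.table`, one row per oocyte.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data.table::fread(path)
}
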