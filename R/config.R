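#' Scenario configuration
#'
#' A `ScenarioConfig` drives the synthetic generator and the pipeline: which
#' drug condition to emulate, how many oocytes, the sampling intervals of
#' each data stream, the recording duration and the RNG seed.
#'
#' @param condition One of [meioquant_conditions()].
#' @param n_oocytes Number of oocytes in the cohort (>= 1).
#' @param frame_interval Named list of sampling intervals in minutes per
#'   data stream: `resumption` (dextran + chromosome volume), `tracks`
#'   (kinetochore positions), `degradation` (securin/cyclin), `spindle`
#'   (volume + aspect ratio), `pplk1`, `lamin`.
#' @param duration Recording duration in hours from induction of meiotic
#'   resumption.
#' @param seed Integer RNG seed.
#' @param parameter_overrides Named list forwarded to [condition_preset()].
#' @param render_images Whether `simulate`/CLI should also write voxel
#'   stacks.
#' @return A `ScenarioConfig` object (a validated list).
#' @export
scenario_config <- function(condition = "control",
                            n_oocytes = 16L,
                            frame_interval = NULL,
                            duration = 15,
                            seed = 20150206L,
                            parameter_overrides = list(),
                            render_images = FALSE) {
  default_fi <- list(resumption = 1, tracks = 10, degradation = 10,
                     spindle = 10, pplk1 = 5, lamin = 1)
  if (is.null(frame_interval)) frame_interval <- list()
  if (is.numeric(frame_interval) && is.null(names(frame_interval))) {
    frame_interval <- list(resumption = frame_interval[[1]])
  }
  bad <- setdiff(names(frame_interval), names(default_fi))
  if (length(bad)) {
    stop("unknown frame_interval stream(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fi <- utils::modifyList(default_fi, as.list(frame_interval))

  if (!is.character(condition) || length(condition) != 1 ||
      !condition %in% meioquant_conditions()) {
    stop("unknown condition: ", paste(condition, collapse = ", "),
         "; must be one of ", paste(meioquant_conditions(), collapse = ", "),
         call. = FALSE)
  }
  n_oocytes <- as.integer(n_oocytes)
  if (is.na(n_oocytes) || n_oocytes < 1) {
    stop("n_oocytes must be a positive integer", call. = FALSE)
  }
  if (!all(vapply(fi, function(x) is.numeric(x) && x > 0, logical(1)))) {
    stop("every frame_interval must be > 0", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be > 0 hours", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  # validate overrides against the preset now so bad keys fail early
  invisible(condition_preset(condition, parameter_overrides))

  structure(list(condition = condition,
                 n_oocytes = n_oocytes,
                 frame_interval = fi,
                 duration = duration,
                 seed = seed,
                 parameter_overrides = parameter_overrides,
                 render_images = isTRUE(render_images)),
            class = "ScenarioConfig")
}

#' Read a scenario configuration from a YAML file
#'
#' Absent keys are filled with documented defaults (`n_oocytes` 16, duration
#' 15 h, seed 20150206, 1-min resumption / 10-min track and degradation
#' sampling).
#'
#' @param path Path to a YAML file.
#' @return A `ScenarioConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("condition", "n_oocytes", "frame_interval", "duration", "seed",
             "parameter_overrides", "render_images")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, raw)
}

#' @export
print.ScenarioConfig <- function(x, ...) {
  cat("ScenarioConfig:", x$condition, "| n =", x$n_oocytes,
      "| duration =", x$duration, "h | seed =", x$seed, "\n")
  invisible(x)
}

# Stable hash of a config for provenance logging.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

#' Write a provenance log into an output directory
#'
#' Records the config hash, seed and package version, so that any result
#' directory identifies the exact scenario that produced it.
#'
#' @param dir Output directory.
#' @param config A `ScenarioConfig` (optional).
#' @export
write_provenance <- function(dir, config = NULL) {
  info <- list(
    package = "meioquant",
    version = as.character(utils::packageVersion("meioquant")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  if (!is.null(config)) {
    info$config_hash <- config_hash(config)
    info$seed <- config$seed
    info$condition <- config$condition
  }
  jsonlite::write_json(info, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(info)
}
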