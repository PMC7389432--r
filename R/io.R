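REPORT_SCHEMA_VERSION <- "1.0"

#' Write a subject recording (and its events) to CSV
#'
#' Produces `<subject_id>.csv` with columns `sample`, the ten EMG channels
#' and `FSW_R`, `FSW_L`, plus `<subject_id>_events.csv`
#' (`leg,type,time_ms`) when ground-truth events are attached.
#'
#' @param rec A `subject_recording`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path of the signal CSV.
#' @export
write_subject_csv <- function(rec, dir) {
  stopifnot(inherits(rec, "subject_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sid <- attr(rec, "subject_id")
  path <- file.path(dir, paste0(sid, ".csv"))
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  truth <- attr(rec, "truth_events")
  if (!is.null(truth)) {
    utils::write.csv(
      as.data.frame(truth[c("leg", "type", "time_ms")]),
      file.path(dir, paste0(sid, "_events.csv")), row.names = FALSE)
  }
  invisible(path)
}

#' Read a subject recording from CSV
#'
#' Validates column presence, binary foot-switch values and consistent
#' lengths; attaches `<id>_events.csv` as ground-truth events when present
#' (event sample indices are rebuilt from `time_ms`).
#'
#' @param path Path to the signal CSV written by [write_subject_csv()].
#' @param sampling_rate Sampling rate in Hz of the stored signals.
#' @param subject_id Identifier; defaults to the file name without
#'   extension.
#' @return A `subject_recording`.
#' @export
read_subject_csv <- function(path, sampling_rate = 2000,
                             subject_id = NULL) {
  if (!file.exists(path))
    stopf("no such file: %s", path, class = "gaitphase_io_error")
  d <- utils::read.csv(path)
  needed <- c("sample", emg_channels(), "FSW_R", "FSW_L")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0)
    stopf("%s: missing column(s) %s", path,
          paste(missing_cols, collapse = ", "),
          class = "gaitphase_parse_error")
  for (fsw in c("FSW_R", "FSW_L")) {
    bad <- which(!(d[[fsw]] %in% c(0, 1)))
    if (length(bad) > 0)
      stopf("%s: non-binary %s value %s at data row %d", path, fsw,
            format(d[[fsw]][bad[1]]), bad[1],
            class = "gaitphase_parse_error")
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.csv$", "", basename(path))
  ev_path <- file.path(dirname(path), paste0(subject_id, "_events.csv"))
  truth <- NULL
  if (file.exists(ev_path)) {
    ev <- utils::read.csv(ev_path)
    if (!all(c("leg", "type", "time_ms") %in% names(ev)))
      stopf("%s: events file must have columns leg,type,time_ms", ev_path,
            class = "gaitphase_parse_error")
    truth <- tibble(leg = ev$leg, type = ev$type,
                    sample = as.integer(round(ev$time_ms / 1000 *
                                                sampling_rate)),
                    time_ms = ev$time_ms)
  }
  new_subject_recording(as_tibble(d), subject_id = subject_id,
                        sampling_rate = sampling_rate,
                        truth_events = truth)
}

#' Write detected/matched events to CSV
#'
#' @param events Event tibble (`type`, `time_ms`, optionally `matched`,
#'   `error_ms`).
#' @param path Output path.
#' @param leg Leg identifier stored in the first column.
#' @return Invisibly, `path`.
#' @export
write_events_csv <- function(events, path, leg = "L") {
  out <- data.frame(leg = leg, type = events$type,
                    time_ms = events$time_ms)
  if (!is.null(events$matched)) out$matched <- events$matched
  if (!is.null(events$error_ms)) out$error_ms <- events$error_ms
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation or study report as JSON
#'
#' Numbers are serialized at full precision, missing metrics as `null`
#' (never 0), and every file carries a `schema_version` field.
#'
#' @param report A `gait_study`, `gait_subject_report`, or any list/tibble
#'   of results.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  payload <- if (inherits(report, "gait_study")) {
    list(protocol = report$protocol, subjects = report$subjects,
         population = glance(report))
  } else if (inherits(report, "gait_subject_report")) {
    list(protocol = report$protocol, subject_id = report$subject_id,
         folds = report$folds, event_scores = report$event_scores)
  } else report
  payload <- c(list(schema_version = REPORT_SCHEMA_VERSION), payload)
  ok <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stopf("cannot write report to %s: %s", path, conditionMessage(ok),
          class = "gaitphase_io_error")
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return Named list; tabular sections become tibbles.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stopf("no such file: %s", path, class = "gaitphase_io_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(x))
    if (is.data.frame(x[[nm]])) x[[nm]] <- as_tibble(x[[nm]])
  x
}

study_config_defaults <- function() {
  list(sampling_rate = 2000, window_len = 20, channels = emg_channels(),
       target_leg = "L", hp_cutoff = 20, lp_cutoff = 450, env_cutoff = 5,
       fir_order = 250, min_phase_ms = 175, tolerance_ms = 600,
       k_folds = 10,
       mlp = list(hidden_sizes = c(512, 256, 128), learning_rate = 0.01,
                  max_epochs = 100, patience = 10, batch_size = 32,
                  threshold = 0.5, val_fraction = 0.10),
       seed = 1L)
}

#' Assemble and validate a study configuration
#'
#' Collects every knob of the pipeline (sampling rate, filter cut-offs,
#' windowing, spike rejection, event tolerance, MLP hyper-parameters,
#' protocol options, seed) into one validated list. Unknown keys are
#' rejected with a clear message.
#'
#' @param ... Named overrides of the defaults (nested `mlp` entries may be
#'   given as a list).
#' @return A `study_config` list.
#' @export
#' @examples
#' study_config(tolerance_ms = 50, mlp = list(max_epochs = 30))
study_config <- function(...) {
  defaults <- study_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stopf("unknown study_config field(s): %s",
          paste(unknown, collapse = ", "),
          class = "gaitphase_validation_error")
  if (!is.null(over$mlp)) {
    unknown_mlp <- setdiff(names(over$mlp), names(defaults$mlp))
    if (length(unknown_mlp) > 0)
      stopf("unknown mlp field(s): %s",
            paste(unknown_mlp, collapse = ", "),
            class = "gaitphase_validation_error")
    defaults$mlp[names(over$mlp)] <- over$mlp
    over$mlp <- NULL
  }
  defaults[names(over)] <- over
  cfg <- defaults
  if (!cfg$target_leg %in% c("L", "R"))
    stopf("`target_leg` must be \"L\" or \"R\"",
          class = "gaitphase_validation_error")
  if (cfg$window_len < 1 || cfg$sampling_rate <= 0)
    stopf("window_len and sampling_rate must be positive",
          class = "gaitphase_validation_error")
  # delegate MLP-field validation
  do.call(mlp_config, c(cfg$mlp,
                        list(input_size = cfg$window_len *
                               length(cfg$channels),
                             seed = cfg$seed)))
  structure(cfg, class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' @param path YAML file with (a subset of) the [study_config()] fields.
#' @return A validated `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path))
    stopf("no such file: %s", path, class = "gaitphase_io_error")
  do.call(study_config, yaml::read_yaml(path))
}

#' The [mlp_config()] embedded in a study configuration
#'
#' @param cfg A `study_config`.
#' @return An `mlp_config` whose input size matches the study's windowing.
#' @export
as_mlp_config <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  do.call(mlp_config, c(cfg$mlp,
                        list(input_size = cfg$window_len *
                               length(cfg$channels),
                             seed = cfg$seed)))
}
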