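#' Construct a voltage trace
#'
#' A uniformly sampled current-clamp recording: membrane potential in mV and
#' injected current in pA at a fixed sampling interval.
#'
#' @param time_step sampling interval in ms (> 0)
#' @param voltage membrane potential samples, mV
#' @param current injected current samples, pA; defaults to all-zero
#'   (spontaneous recording)
#' @param label free-text label
#' @return object of class `voltage_trace`
#' @export
voltage_trace <- function(time_step, voltage, current = NULL, label = "") {
  assert_scalar_number(time_step, "time_step")
  if (time_step <= 0) abort("time_step must be > 0", "validation_error")
  if (is.null(current)) current <- numeric(length(voltage))
  if (length(voltage) < 2L)
    abort("a trace needs at least 2 samples", "validation_error")
  if (length(current) != length(voltage))
    abort("voltage and current must have the same length", "validation_error")
  if (!all(is.finite(voltage)) || !all(is.finite(current)))
    abort("trace samples must be finite", "validation_error")
  structure(list(time_step = time_step, voltage = as.numeric(voltage),
                 current = as.numeric(current), label = as.character(label)),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g kHz (%.3f s)%s\n",
              length(x$voltage), 1 / x$time_step,
              length(x$voltage) * x$time_step / 1000,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Sample times of a trace in ms
#' @param trace a [voltage_trace()]
#' @return numeric vector, first sample at t = 0
#' @export
trace_times <- function(trace) {
  (seq_along(trace$voltage) - 1) * trace$time_step
}

#' Read a voltage trace from file
#'
#' Delimited text with header `time_ms,voltage_mV` and optionally
#' `current_pA`. Time stamps must be uniform.
#'
#' @param path file path
#' @param format only `"text"` (delimited text) is supported; HDF5 input is
#'   not available in this build
#' @return a [voltage_trace()]
#' @export
read_trace <- function(path, format = c("text", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    abort("HDF5 trace input is not supported; use delimited text",
          "unsupported_format")
  if (!file.exists(path)) abort("no such file: %s", "io_error", path)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e)
                  abort("malformed trace file %s: %s", "parse_error",
                        path, conditionMessage(e)))
  if (!all(c("time_ms", "voltage_mV") %in% names(d)))
    abort("trace file %s lacks time_ms/voltage_mV columns", "parse_error", path)
  if (nrow(d) < 2L)
    abort("trace file %s has fewer than 2 samples", "validation_error", path)
  dt <- diff(d$time_ms)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    abort("trace file %s has non-uniform time stamps", "structural_error", path)
  cur <- if ("current_pA" %in% names(d)) d$current_pA else NULL
  voltage_trace(dt[1], d$voltage_mV, cur, label = basename(path))
}

#' Write a voltage trace to delimited text
#'
#' Samples are written with full double precision so that a read/write round
#' trip is bit-exact.
#'
#' @param trace a [voltage_trace()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  t_ms <- trace_times(trace)
  con <- tryCatch(file(path, "w"), error = function(e)
    abort("cannot open %s for writing", "io_error", path))
  on.exit(close(con))
  writeLines("time_ms,voltage_mV,current_pA", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", t_ms, trace$voltage, trace$current),
             con)
  invisible(path)
}

#' Bundle the recordings of one neuron
#'
#' @param neuron_id unique identifier
#' @param age_days postnatal day, 2-29 and inside a stage bin
#' @param spontaneous spontaneous [voltage_trace()] (no injected current)
#' @param passive_pulses list of `list(trace =, step_pA =)` small
#'   hyperpolarizing pulses
#' @param sag_pulse `list(trace =, step_pA =, pulse_start_ms =, pulse_end_ms =)`
#'   or `NULL`
#' @param fi_pulses list of `list(trace =, step_pA =, pulse_start_ms =,
#'   pulse_end_ms =)` depolarizing pulses
#' @param ground_truth optional named list of generator parameters
#' @return object of class `recording_set`
#' @export
recording_set <- function(neuron_id, age_days, spontaneous,
                          passive_pulses = list(), sag_pulse = NULL,
                          fi_pulses = list(), ground_truth = NULL) {
  stage <- stage_for_age(age_days)
  if (!inherits(spontaneous, "voltage_trace"))
    abort("spontaneous must be a voltage_trace", "validation_error")
  structure(list(neuron_id = as.character(neuron_id),
                 age_days = as.integer(age_days), stage = stage,
                 spontaneous = spontaneous, passive_pulses = passive_pulses,
                 sag_pulse = sag_pulse, fi_pulses = fi_pulses,
                 ground_truth = ground_truth),
            class = "recording_set")
}

#' Write a cohort feature table
#'
#' One row per neuron: `neuron_id`, `age_days`, `stage`, then the 16 feature
#' columns in canonical order. Missing features are written as empty fields,
#' never as zeros.
#'
#' @param cohort data.frame as returned by [extract_cohort()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(cohort, path) {
  if (nrow(cohort) == 0L) abort("cohort is empty", "validation_error")
  cols <- c("neuron_id", "age_days", "stage", feature_names())
  missing <- setdiff(cols, names(cohort))
  if (length(missing))
    abort("cohort lacks columns: %s", "validation_error",
          paste(missing, collapse = ", "))
  out <- cohort[, cols]
  tryCatch(
    utils::write.table(out, path, sep = ",", na = "", row.names = FALSE,
                       quote = FALSE),
    error = function(e) abort("cannot write %s", "io_error", path))
  invisible(path)
}

#' Read a cohort feature table written by [write_feature_table()]
#' @param path CSV path
#' @return data.frame with `neuron_id`, `age_days`, `stage` and the 16 features
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort("no such file: %s", "io_error", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  need <- c("neuron_id", "age_days", "stage", feature_names())
  if (!all(need %in% names(d)))
    abort("feature table %s lacks required columns", "parse_error", path)
  d$neuron_id <- as.character(d$neuron_id)
  d
}
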