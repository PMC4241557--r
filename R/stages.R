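#' Developmental stage bins
#'
#' The 15 postnatal-day bins used throughout the analysis, in developmental
#' order. Each bin covers an inclusive range of postnatal days; days 4 and
#' 24-27 fall in no bin and are rejected.
#'
#' @return data.frame with columns `stage`, `age_min`, `age_max`
#' @export
stage_bins <- function() {
  data.frame(
    stage = c("P2-P3", "P5", "P6", "P7", "P8-P9", "P10-P11", "P12-P13",
              "P14", "P15-P16", "P17", "P18", "P19", "P20", "P21-P23",
              "P28-P29"),
    age_min = c(2, 5, 6, 7, 8, 10, 12, 14, 15, 17, 18, 19, 20, 21, 28),
    age_max = c(3, 5, 6, 7, 9, 11, 13, 14, 16, 17, 18, 19, 20, 23, 29),
    stringsAsFactors = FALSE
  )
}

#' Stage labels in developmental order
#' @return character vector of the 15 stage labels
#' @export
stage_levels <- function() stage_bins()$stage

#' Map a postnatal age in days to its stage bin
#'
#' @param age_days integer postnatal day(s), between 2 and 29
#' @return character vector of stage labels
#' @export
stage_for_age <- function(age_days) {
  bins <- stage_bins()
  vapply(age_days, function(a) {
    if (!is.finite(a) || a < 2 || a > 29)
      abort("age_days %s outside the recorded range [2, 29]",
            "validation_error", format(a))
    hit <- which(bins$age_min <= a & a <= bins$age_max)
    if (length(hit) != 1L)
      abort("age_days %s falls in no stage bin", "validation_error", format(a))
    bins$stage[hit]
  }, character(1))
}

#' Canonical names of the 16 electrophysiological parameters
#'
#' Order matches the feature-table header: interspike-interval statistics,
#' passive properties, sag/rebound, action-potential waveform metrics, and
#' excitability (gain/adaptation) measures.
#'
#' @return character vector of length 16
#' @export
feature_names <- function() {
  c("isi_avg", "cv_isi", "tau_m", "r_in", "c_m", "sag", "rebound",
    "ap_threshold", "ap_amplitude", "ap_half_width", "ap_rise_slope",
    "ap_decay_slope", "ahp", "gain_start", "gain_end", "sfa_index")
}

#' The 8 spontaneous-activity parameters used by the multivariate analyses
#'
#' These are the parameters measurable from a spontaneous recording alone
#' (no current injection), in the canonical multivariate column order.
#'
#' @return character vector of length 8
#' @export
spontaneous_feature_names <- function() {
  c("isi_avg", "cv_isi", "ap_threshold", "ap_amplitude", "ap_rise_slope",
    "ap_decay_slope", "ap_half_width", "ahp")
}

#' Load a stage calibration table
#'
#' Reads a long-format calibration file (`stage,parameter,mean,sd,n`) holding
#' per-stage descriptive statistics for the 16 parameters. The default is the
#' calibration shipped with the package, transcribed from published stage-wise
#' means/SDs for rat SNc dopaminergic neurons (P2 to P29).
#'
#' @param path calibration CSV; default: shipped file
#' @return data.frame of class `ephys_calibration`
#' @export
load_calibration <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_calibration.csv",
                        package = "ephystraj", mustWork = TRUE)
  cal <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stage", "parameter", "mean", "sd", "n")
  if (!all(need %in% names(cal)))
    abort("calibration file must have columns %s", "parse_error",
          paste(need, collapse = ", "))
  if (any(cal$sd < 0)) abort("calibration sd must be >= 0", "validation_error")
  class(cal) <- c("ephys_calibration", class(cal))
  cal
}

cal_lookup <- function(calibration, stage, parameter) {
  i <- which(calibration$stage == stage & calibration$parameter == parameter)
  if (length(i) != 1L)
    abort("no calibration entry for stage '%s', parameter '%s'",
          "lookup_error", stage, parameter)
  calibration[i, c("mean", "sd", "n")]
}

#' Default per-stage cohort plan
#'
#' One entry per stage with the group size taken from the calibration table's
#' CV_ISI column Ns (271 neurons in total for the shipped calibration).
#'
#' @param calibration calibration table from [load_calibration()]
#' @param scale multiply group sizes by this factor (rounded up), e.g. `1/3`
#'   for a desk-scale cohort
#' @return data.frame with columns `stage`, `n`
#' @export
default_stage_plan <- function(calibration = load_calibration(), scale = 1) {
  cv <- calibration[calibration$parameter == "cv_isi", c("stage", "n")]
  cv <- cv[match(intersect(stage_levels(), cv$stage), cv$stage), ]
  data.frame(stage = cv$stage, n = as.integer(ceiling(cv$n * scale)),
             stringsAsFactors = FALSE)
}
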