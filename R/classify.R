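#' Classify the firing pattern from CV_ISI
#'
#' Step rule with the 20/80% thresholds: CV < 20% regular, 20-80% irregular,
#' > 80% bursting. Values exactly on a boundary are assigned to the middle
#' (irregular) class.
#'
#' @param cv_isi CV of the interspike intervals, percent (vectorized)
#' @return factor with levels `regular`, `irregular`, `bursting`
#' @export
classify_firing <- function(cv_isi) {
  if (any(!is.na(cv_isi) & cv_isi < 0))
    abort("cv_isi must be >= 0", "validation_error")
  lab <- ifelse(is.na(cv_isi), NA_character_,
                ifelse(cv_isi < 20, "regular",
                       ifelse(cv_isi <= 80, "irregular", "bursting")))
  factor(lab, levels = c("regular", "irregular", "bursting"))
}

#' Per-stage proportions of the three firing patterns
#'
#' @param cohort data.frame with `stage` and `cv_isi` columns (e.g. from
#'   [extract_cohort()])
#' @return data.frame with one row per stage (developmental order): counts
#'   and fractions of regular/irregular/bursting neurons; fractions sum to 1
#' @export
pattern_proportions <- function(cohort) {
  ok <- !is.na(cohort$cv_isi)
  if (any(!ok)) warning(sprintf("%d neurons without cv_isi dropped",
                                sum(!ok)))
  cohort <- cohort[ok, ]
  lab <- classify_firing(cohort$cv_isi)
  stages <- intersect(stage_levels(), unique(cohort$stage))
  rows <- lapply(stages, function(st) {
    l <- lab[cohort$stage == st]
    n <- length(l)
    cnt <- table(l)
    data.frame(stage = st, n = n,
               n_regular = as.integer(cnt[["regular"]]),
               n_irregular = as.integer(cnt[["irregular"]]),
               n_bursting = as.integer(cnt[["bursting"]]),
               frac_regular = cnt[["regular"]] / n,
               frac_irregular = cnt[["irregular"]] / n,
               frac_bursting = cnt[["bursting"]] / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
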