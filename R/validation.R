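#' Round-trip validation of feature extraction on noiseless cohorts
#'
#' Generates `n_per_regime` synthetic neurons of each firing regime
#' (bursting from the neonatal calibration, irregular from the first-week
#' calibration, regular from the mature calibration), renders all protocols
#' noiselessly at the given sampling rate, extracts the 16 parameters and
#' compares them with the generator ground truth. ISI statistics are
#' compared against the *realized* statistics of the generated spike train;
#' the regime-level means of ISI_avg/CV_ISI are additionally compared
#' against the generator targets.
#'
#' @param n_per_regime neurons per regime
#' @param seed RNG seed
#' @param duration_s spontaneous-trace duration, s
#' @param time_step sampling interval, ms
#' @return list: `errors` (per-neuron data.frame of relative errors, %),
#'   `summary` (named vector of worst-case errors per feature family, %),
#'   `regime_means` (data.frame of regime-level target vs extracted ISI
#'   statistics)
#' @export
roundtrip_validation <- function(n_per_regime = 50, seed = 1,
                                 duration_s = 500, time_step = 0.05) {
  regime_stage <- c(bursting = "P2-P3", irregular = "P7",
                    regular = "P21-P23")
  set.seed(seed)
  cal <- load_calibration()
  rows <- list(); k <- 0L
  for (rg in names(regime_stage)) {
    got <- 0L
    while (got < n_per_regime) {
      params <- sample_neuron_params(regime_stage[[rg]], cal)
      if (params$train$regime != rg) next          # regime by rejection
      got <- got + 1L; k <- k + 1L
      bins <- stage_bins()
      age <- bins$age_min[match(regime_stage[[rg]], bins$stage)]
      rec <- generate_recording_set(params, sprintf("%s%03d", rg, got), age,
                                    duration_s = duration_s,
                                    time_step = time_step, noise_sd = 0)
      f <- extract_features(rec)
      tr <- params$truth
      st <- rec$ground_truth$realized_spike_times
      isis <- diff(st)
      rel <- function(est, true, floor_abs = 0) {
        100 * abs(est - true) / pmax(abs(true), floor_abs / 0.02)
      }
      rows[[k]] <- data.frame(
        regime = rg,
        ap_threshold = rel(f$ap_threshold, tr["ap_threshold"], 0.5),
        ap_amplitude = rel(f$ap_amplitude, tr["ap_amplitude"], 0.5),
        ap_half_width = rel(f$ap_half_width, tr["ap_half_width"], 0.05),
        ap_rise_slope = rel(f$ap_rise_slope, tr["ap_rise_slope"], 0.5),
        ap_decay_slope = rel(f$ap_decay_slope, tr["ap_decay_slope"], 0.5),
        ahp = rel(f$ahp, tr["ahp"], 0.5),
        tau_m = rel(f$tau_m, tr["tau_m"]),
        r_in = rel(f$r_in, tr["r_in"]),
        c_m = rel(f$c_m, tr["c_m"]),
        sag = rel(f$sag, tr["sag"], 0.5),
        rebound = rel(f$rebound, tr["rebound"], 0.5),
        isi_avg = rel(f$isi_avg, mean(isis)),
        cv_isi = rel(f$cv_isi, 100 * sd(isis) / mean(isis)),
        gain_start = rel(f$gain_start, tr["gain_start"]),
        gain_end = rel(f$gain_end, tr["gain_end"]),
        sfa_index = rel(f$sfa_index, tr["sfa_index"]),
        target_isi = unname(tr["isi_avg"]), target_cv = unname(tr["cv_isi"]),
        extr_isi = f$isi_avg, extr_cv = f$cv_isi,
        stringsAsFactors = FALSE)
    }
  }
  errors <- do.call(rbind, rows)
  fam <- list(
    ap = c("ap_threshold", "ap_amplitude", "ap_half_width", "ap_rise_slope",
           "ap_decay_slope", "ahp"),
    passive = c("tau_m", "r_in", "c_m"),
    sag_rebound = c("sag", "rebound"),
    isi = c("isi_avg", "cv_isi"),
    gain = c("gain_start", "gain_end", "sfa_index"))
  summary <- vapply(fam, function(cols)
    max(as.matrix(errors[, cols]), na.rm = FALSE), numeric(1))
  names(summary) <- paste0("max_err_", names(fam), "_pct")
  regime_means <- do.call(rbind, lapply(split(errors, errors$regime),
    function(d) data.frame(
      regime = d$regime[1],
      isi_target_mean = mean(d$target_isi), isi_extracted_mean = mean(d$extr_isi),
      cv_target_mean = mean(d$target_cv), cv_extracted_mean = mean(d$extr_cv))))
  regime_means$isi_err_pct <-
    100 * abs(regime_means$isi_extracted_mean / regime_means$isi_target_mean - 1)
  regime_means$cv_err_pct <-
    100 * abs(regime_means$cv_extracted_mean / regime_means$cv_target_mean - 1)
  list(errors = errors, summary = summary, regime_means = regime_means)
}

#' Type-I-error calibration of the stacking table on null cohorts
#'
#' Each run draws `n` values per stage for `n_stages` stages from one normal
#' distribution and builds a single-parameter stacking table; the run counts
#' as calibrated when every pairwise code is non-significant. Tukey HSD
#' controls the family-wise error at 5% per parameter, so the expected
#' all-ns fraction is ~95%.
#'
#' @param n_runs number of seeded runs
#' @param n_stages,n groups and group size
#' @param seed RNG seed
#' @return fraction of runs with an all-ns table
#' @export
null_stacking_calibration <- function(n_runs = 100, n_stages = 15, n = 20,
                                      seed = 1) {
  set.seed(seed)
  stages <- stage_levels()[seq_len(n_stages)]
  all_ns <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    v <- rnorm(n_stages * n)
    g <- rep(stages, each = n)
    res <- anova_tukey(v, g)
    all_ns[r] <- all(res$p_adj >= 0.05)
  }
  mean(all_ns)
}

#' Structural validation of the multivariate stage on a calibrated cohort
#'
#' Generates a developmental cohort from the shipped calibration, extracts
#' the spontaneous features, and runs clustering and PCA. Reports the
#' automatic-cut class count, the regime purity and mean ages of the
#' three-class solution, the per-stage trajectory displacement ranking, and
#' the variability-ellipse/age association.
#'
#' @param seed RNG seed
#' @param scale stage-plan scaling (1 = calibration group sizes)
#' @param duration_s spontaneous-trace duration, s
#' @return list with `k_auto`, `purity_k3`, `class_ages_k3` (sorted young to
#'   old), `displacement` (named vector over consecutive stage pairs),
#'   `first_transition_rank`, `pc12_fraction`, `ellipse_age_spearman`,
#'   `sd_age_r`, `n`
#' @export
cohort_structure_validation <- function(seed = 1, scale = 1,
                                        duration_s = 120) {
  plan <- default_stage_plan(scale = scale)
  sim <- simulate_feature_cohort(plan, seed = seed, duration_s = duration_s,
                                 noise_sd = 0.3, protocols = "spontaneous")
  snm <- spontaneous_matrix(sim$features)
  dend <- ahc_ward(snm)
  auto <- auto_cut(dend, snm)
  k3 <- auto_cut(dend, snm, k = 3)
  tab <- table(k3$membership, sim$ground_truth$regime)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  pm <- pca_covariance(snm)
  traj <- stage_trajectory(pm)
  disp <- sqrt(diff(traj$f1_mean)^2 + diff(traj$f2_mean)^2)
  names(disp) <- paste(traj$stage[-nrow(traj)], traj$stage[-1], sep = "->")
  ell <- variability_ellipse(traj)
  list(k_auto = auto$k,
       purity_k3 = purity,
       class_ages_k3 = sort(k3$class_age[, "mean"]),
       displacement = disp,
       first_transition_rank = rank(-disp)[["P2-P3->P5"]],
       pc12_fraction = sum(pm$variance_fraction[1:2]),
       ellipse_age_spearman = suppressWarnings(
         cor(traj$age_mean, ell$area, method = "spearman")),
       sd_age_r = sd_age_correlation(traj)$r,
       n = nrow(sim$features))
}

#' Repeated-run validation of the variability-narrowing result
#'
#' Runs [cohort_structure_validation()] for several seeds and reports the
#' fraction of runs in which the ellipse area decreases with age (negative
#' Spearman correlation) and in which the largest trajectory displacement
#' straddles the first developmental transition.
#'
#' @param n_runs number of runs
#' @param seed base seed (run r uses seed + r - 1)
#' @param scale,duration_s cohort size controls
#' @return list(`frac_negative_spearman`, `frac_first_transition`, `runs`)
#' @export
trajectory_replication <- function(n_runs = 10, seed = 1, scale = 0.5,
                                   duration_s = 120) {
  runs <- lapply(seq_len(n_runs), function(r)
    cohort_structure_validation(seed = seed + r - 1L, scale = scale,
                                duration_s = duration_s))
  rho <- vapply(runs, `[[`, numeric(1), "ellipse_age_spearman")
  fr <- vapply(runs, `[[`, numeric(1), "first_transition_rank")
  list(frac_negative_spearman = mean(rho < 0),
       frac_first_transition = mean(fr == 1),
       runs = runs)
}
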