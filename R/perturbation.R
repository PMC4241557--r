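#' Leak conductance needed to reach a target input resistance
#'
#' Dynamic-clamp leak arithmetic: conductances add, so the injected leak is
#' g = 1/R_target - 1/R_in (in nS with MOhm inputs, 1/MOhm = 1000 nS).
#' Negative g (leak subtraction) when the neuron's R_in is below target.
#'
#' @param r_in measured input resistance, MOhm (> 0)
#' @param target_r_in target apparent input resistance, MOhm (default
#'   1600, the neonatal value)
#' @return signed conductance, nS
#' @export
leak_for_target <- function(r_in, target_r_in = 1600) {
  if (any(r_in <= 0)) abort("r_in must be > 0", "validation_error")
  1000 / target_r_in - 1000 / r_in
}

#' Apparent input resistance under an injected leak
#' @param r_in intrinsic input resistance, MOhm
#' @param g injected leak conductance, nS
#' @return apparent input resistance, MOhm
#' @export
apparent_r_in <- function(r_in, g) {
  1 / (1 / r_in + g / 1000)
}

#' Specification of a dynamic-clamp leak injection
#'
#' @param target_r_in target apparent input resistance, MOhm
#' @param e_rev leak reversal potential, mV (recorded for provenance; the
#'   generator-level emulation only uses the conductance arithmetic)
#' @return object of class `leak_spec`
#' @export
leak_spec <- function(target_r_in = 1600, e_rev = -65) {
  if (target_r_in <= 0) abort("target_r_in must be > 0", "validation_error")
  structure(list(target_r_in = target_r_in, e_rev = e_rev),
            class = "leak_spec")
}

#' Specification of a pharmacological manipulation
#'
#' @param ahp_block_fraction fraction of the AHP blocked (apamin), in
#'   `[0, 1]`
#' @param sodium_scale multiplicative scaling of AP amplitude and slopes
#'   (low-dose TTX), in `(0, 1]`
#' @param label free-text condition label
#' @return object of class `pharmacology_spec`
#' @export
pharmacology_spec <- function(ahp_block_fraction = 0, sodium_scale = 1,
                              label = "") {
  if (ahp_block_fraction < 0 || ahp_block_fraction > 1)
    abort("ahp_block_fraction must be in [0, 1]", "validation_error")
  if (sodium_scale <= 0 || sodium_scale > 1)
    abort("sodium_scale must be in (0, 1]", "validation_error")
  structure(list(ahp_block_fraction = ahp_block_fraction,
                 sodium_scale = sodium_scale, label = label),
            class = "pharmacology_spec")
}

#' Apply pharmacology/leak perturbations to a neuron's generator parameters
#'
#' Emulates the manipulations at the generator-parameter level: apamin
#' scales the AHP depth by (1 - block) and increases spike-train
#' irregularity through a monotone coupling CV' = CV * (1 + kappa * block);
#' low-dose TTX scales AP amplitude and both slopes; an injected leak
#' replaces R_in by its apparent value.
#'
#' @param params neuron parameters from [sample_neuron_params()]
#' @param leak a [leak_spec()] or `NULL`
#' @param pharm a [pharmacology_spec()] or `NULL`
#' @param kappa CV-AHP coupling constant (default 4: a 75% block turns a
#'   regular CV of ~10% into a bursting-range CV)
#' @return perturbed parameter list of the same structure, with the implied
#'   `truth` vector updated and `g_leak_nS` recorded
#' @export
apply_perturbation <- function(params, leak = NULL, pharm = NULL, kappa = 4) {
  out <- params
  g <- 0
  if (!is.null(leak)) {
    g <- leak_for_target(params$passive$r_in, leak$target_r_in)
    out$passive$r_in <- apparent_r_in(params$passive$r_in, g)
  }
  if (!is.null(pharm)) {
    blk <- pharm$ahp_block_fraction
    out$ap$ahp_depth <- params$ap$ahp_depth * (1 - blk)
    out$ap$amplitude <- params$ap$amplitude * pharm$sodium_scale
    out$ap$rise_slope <- params$ap$rise_slope * pharm$sodium_scale
    out$ap$decay_slope <- params$ap$decay_slope * pharm$sodium_scale
    cv <- params$train$target_cv * (1 + kappa * blk)
    out$train <- spike_train_params(as.character(classify_firing(cv)),
                                    mean_isi = params$train$mean_isi,
                                    target_cv = cv)
  }
  if (out$ap$amplitude <= 0 || out$ap$rise_slope <= 0)
    abort("perturbation produced invalid AP parameters", "validation_error")
  tr <- out$truth
  tr["r_in"] <- out$passive$r_in
  tr["tau_m"] <- out$passive$r_in * out$passive$c_m / 1000
  tr["ahp"] <- out$ap$ahp_depth
  tr["ap_amplitude"] <- out$ap$amplitude
  tr["ap_rise_slope"] <- out$ap$rise_slope
  tr["ap_decay_slope"] <- out$ap$decay_slope
  tr["cv_isi"] <- out$train$target_cv
  out$truth <- tr
  out$g_leak_nS <- g
  out
}

#' Quantify a perturbation-induced phenotype shift in PCA space
#'
#' Before and after cohorts (paired by neuron id) are projected as
#' supplementary observations into a reference PCA model; the shift is the
#' mean after-score minus the mean before-score. When anchor points are
#' given (e.g. two class centroid scores), the vector is also returned
#' translated onto the first anchor ("locked" display).
#'
#' @param model reference [pca_model][pca_covariance()] (fitted on the
#'   unperturbed cohort; never refitted)
#' @param before,after feature data.frames with `neuron_id` and the 8
#'   spontaneous columns, paired by id
#' @param anchors optional 2 x 2 matrix: rows = the two anchor points in
#'   (F1, F2)
#' @return list(`before_mean`, `after_mean`, `shift`, `locked` (or NULL),
#'   `n`)
#' @export
phenotype_shift <- function(model, before, after, anchors = NULL) {
  if (!setequal(before$neuron_id, after$neuron_id) ||
      nrow(before) != nrow(after))
    abort("before/after cohorts must be paired by neuron_id",
          "validation_error")
  after <- after[match(before$neuron_id, after$neuron_id), ]
  sb <- project_supplementary(model, before)[, 1:2, drop = FALSE]
  sa <- project_supplementary(model, after)[, 1:2, drop = FALSE]
  bm <- colMeans(sb); am <- colMeans(sa)
  shift <- am - bm
  locked <- NULL
  if (!is.null(anchors)) {
    locked <- rbind(start = anchors[1, ],
                    end = anchors[1, ] + shift)
  }
  list(before_mean = bm, after_mean = am, shift = shift, locked = locked,
       n = nrow(before))
}
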