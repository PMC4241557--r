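#' Spike-train parameters
#'
#' Describes one neuron's spontaneous firing as one of three regimes:
#' `regular` and `irregular` are gamma-renewal processes whose coefficient of
#' variation is set directly; `bursting` is an alternating burst/pause
#' renewal process.
#'
#' @param regime `"regular"`, `"irregular"` or `"bursting"`; must be
#'   consistent with `target_cv` under the 20/80% rule
#' @param mean_isi mean interspike interval, s (> 0)
#' @param target_cv target CV of the ISIs, percent (>= 0)
#' @param burst for `bursting` only: list with `intra_isi` (s),
#'   `n_per_burst`, `pause_mean` (s), `pause_sd` (s); defaults are solved
#'   from `mean_isi`/`target_cv` by [burst_structure_for()]
#' @return object of class `spike_train_params`
#' @export
spike_train_params <- function(regime = c("regular", "irregular", "bursting"),
                               mean_isi, target_cv, burst = NULL) {
  regime <- match.arg(regime)
  assert_scalar_number(mean_isi, "mean_isi")
  assert_scalar_number(target_cv, "target_cv")
  if (mean_isi <= 0) abort("mean_isi must be > 0", "validation_error")
  if (target_cv < 0) abort("target_cv must be >= 0", "validation_error")
  ok <- switch(regime,
               regular = target_cv < 20,
               irregular = target_cv >= 20 && target_cv <= 80,
               bursting = target_cv > 80)
  if (!ok)
    abort("target_cv %.1f%% inconsistent with regime '%s' (20/80%% rule)",
          "validation_error", target_cv, regime)
  if (regime == "bursting" && is.null(burst))
    burst <- burst_structure_for(mean_isi, target_cv)
  if (!is.null(burst)) {
    if (burst$pause_mean < burst$intra_isi)
      abort("burst pause shorter than intra-burst ISI", "validation_error")
  }
  structure(list(regime = regime, mean_isi = mean_isi, target_cv = target_cv,
                 burst = burst), class = "spike_train_params")
}

#' Solve a burst/pause structure for target ISI statistics
#'
#' Finds spikes-per-burst, pause mean and pause jitter such that the
#' composite ISI population (n-1 intra-burst intervals plus one pause per
#' burst) has the requested mean and CV. The preset intra-burst interval is
#' kept when possible; for CV targets too low for it, a two-spike burst with
#' a longer intra-burst interval is used instead (then the CV is matched
#' exactly with no jitter).
#'
#' @param mean_isi target mean ISI, s
#' @param target_cv target composite CV, percent
#' @param intra_isi preset intra-burst ISI, s
#' @param n_per_burst preset spikes per burst (upper bound tried first)
#' @return list(`intra_isi`, `n_per_burst`, `pause_mean`, `pause_sd`)
#' @export
burst_structure_for <- function(mean_isi, target_cv, intra_isi = 0.08,
                                n_per_burst = 4) {
  cv <- target_cv / 100
  mu <- mean_isi
  need <- (cv * mu)^2                      # required ISI variance
  for (nb in seq(n_per_burst, 2)) {
    pause <- nb * mu - (nb - 1) * intra_isi
    if (pause <= intra_isi) next
    sig2 <- nb * need - (nb - 1) * (intra_isi - mu)^2 - (pause - mu)^2
    if (sig2 >= 0)
      return(list(intra_isi = intra_isi, n_per_burst = nb,
                  pause_mean = pause, pause_sd = sqrt(sig2)))
  }
  # CV target below what the preset intra-burst ISI allows: stretch the
  # intra-burst interval so a deterministic 2-spike alternation hits it
  intra <- mu * (1 - cv)
  if (intra < intra_isi) intra <- intra_isi
  pause <- 2 * mu - intra
  sig2 <- max(0, 2 * need - 2 * (mu - intra)^2)
  list(intra_isi = intra, n_per_burst = 2L, pause_mean = pause,
       pause_sd = sqrt(sig2))
}

#' Generate spontaneous spike times
#'
#' Regular and irregular trains are gamma-renewal processes with
#' CV = 1/sqrt(shape); `target_cv = 0` gives a perfectly periodic train.
#' Bursting trains alternate `n_per_burst` spikes at the intra-burst interval
#' with pauses drawn from a truncated normal. Uses the current RNG state.
#'
#' @param params a [spike_train_params()]
#' @param duration trace duration, s (>= 60 so a 40 s analysis window fits)
#' @param t_start time of the first spike, s
#' @param refractory_floor minimum renewal ISI, s (draws below it are
#'   resampled; a biological absolute refractory period, and also the AP
#'   template support)
#' @return spike times in s, strictly increasing, within `[0, duration]`
#' @export
gen_spike_times <- function(params, duration, t_start = 0.5,
                            refractory_floor = 0.09) {
  if (duration < 60)
    abort("duration must be >= 60 s (40 s analysis window)",
          "validation_error")
  mu <- params$mean_isi
  n_exp <- ceiling((duration - t_start) / mu * 1.5) + 20L
  if (params$regime == "bursting") {
    b <- params$burst
    n_bursts <- ceiling(n_exp / b$n_per_burst) + 2L
    # pauses: shifted gamma with support above the intra-burst interval and
    # exact mean/SD (a truncated normal would bias the composite CV for
    # strongly skewed pause distributions)
    pauses <- if (b$pause_sd == 0) rep(b$pause_mean, n_bursts) else {
      m <- b$pause_mean - b$intra_isi
      b$intra_isi + rgamma(n_bursts, shape = (m / b$pause_sd)^2,
                           scale = b$pause_sd^2 / m)
    }
    isis <- as.vector(rbind(matrix(b$intra_isi, b$n_per_burst - 1L, n_bursts),
                            pauses))
  } else if (params$target_cv == 0) {
    isis <- rep(mu, n_exp)
  } else {
    k <- (100 / params$target_cv)^2        # gamma shape: CV = 1/sqrt(k)
    isis <- rgamma(n_exp, shape = k, rate = k / mu)
    low <- which(isis < refractory_floor)
    tries <- 0L
    while (length(low) && tries < 50L) {
      isis[low] <- rgamma(length(low), shape = k, rate = k / mu)
      low <- low[isis[low] < refractory_floor]
      tries <- tries + 1L
    }
  }
  t <- t_start + cumsum(c(0, isis))
  while (t[length(t)] < duration) {        # rare top-up
    extra <- if (params$regime == "bursting") mu * 2 else
      rgamma(1, shape = max((100 / max(params$target_cv, 1e-6))^2, 1e-6),
             rate = max((100 / max(params$target_cv, 1e-6))^2, 1e-6) / mu)
    t <- c(t, t[length(t)] + extra)
  }
  t[t <= duration]
}
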