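#' Fit passive membrane properties from a hyperpolarizing pulse
#'
#' Least-squares mono-exponential fit V(t) = V0 + dV*(1 - exp(-t/tau)) over
#' the pulse; R_in = |dV/step| (1 mV/pA = 1000 MOhm), C_m = tau/R_in.
#'
#' @param pulse list(`trace`, `step_pA`, `pulse_start_ms`, `pulse_end_ms`)
#'   as produced by [gen_passive_pulse()]
#' @return list(`tau_m` ms, `r_in` MOhm, `c_m` pF, `rms` mV)
#' @export
fit_passive <- function(pulse) {
  tr <- pulse$trace; step <- pulse$step_pA
  if (step >= 0) abort("passive pulse must be hyperpolarizing (step < 0)",
                       "validation_error")
  t <- trace_times(tr)
  ip <- t >= pulse$pulse_start_ms & t <= pulse$pulse_end_ms
  tt <- t[ip] - pulse$pulse_start_ms
  vv <- tr$voltage[ip]
  dv_obs <- mean(tail(vv, round(50 / tr$time_step))) - vv[1]
  if (abs(dv_obs) >= 10)
    abort("plateau deflection %.1f mV >= 10 mV", "validation_error",
          abs(dv_obs))
  if (dv_obs >= 0)
    abort("voltage deflection has the wrong sign for a negative step",
          "fit_error")
  tau0 <- {  # time to 63% of the plateau deflection
    i63 <- which(vv - vv[1] <= 0.632 * dv_obs)[1]
    if (is.na(i63)) 50 else max(tt[i63], tr$time_step)
  }
  fit <- tryCatch(
    nls(vv ~ v0 + dv * (1 - exp(-tt / tau)),
        start = list(v0 = vv[1], dv = dv_obs, tau = tau0),
        control = nls.control(maxiter = 100, scaleOffset = 1)),
    error = function(e) abort("passive fit failed: %s", "fit_error",
                              conditionMessage(e)))
  cf <- coef(fit)
  r_in <- abs(cf[["dv"]] / step) * 1000
  list(tau_m = cf[["tau"]], r_in = r_in,
       c_m = 1000 * cf[["tau"]] / r_in,
       rms = sqrt(mean(residuals(fit)^2)))
}

#' Measure sag amplitude and rebound delay
#'
#' Sag = (mean voltage over the last 50 ms of the pulse) - (minimum voltage
#' during the pulse). Rebound = time from pulse offset to the first spike
#' peak after it (NA when no rebound spike occurs).
#'
#' @param pulse list(`trace`, `pulse_start_ms`, `pulse_end_ms`) as produced
#'   by [gen_sag_pulse()]
#' @return list(`sag` mV, `rebound` ms or NA)
#' @export
measure_sag_rebound <- function(pulse) {
  tr <- pulse$trace
  t <- trace_times(tr)
  ip <- t >= pulse$pulse_start_ms & t <= pulse$pulse_end_ms
  if (!any(ip)) abort("pulse window outside trace", "validation_error")
  vv <- tr$voltage[ip]
  pre <- mean(tr$voltage[t < pulse$pulse_start_ms])
  if (min(vv) > pre - 2)
    abort("no hyperpolarizing response during the pulse", "shape_error")
  last50 <- vv[t[ip] > pulse$pulse_end_ms - 50]
  sag <- mean(last50) - min(vv)
  after <- t > pulse$pulse_end_ms
  sub <- voltage_trace(tr$time_step, tr$voltage[after],
                       tr$current[after])
  sp <- detect_spikes(sub)
  rebound <- if (length(sp)) sp[1] + t[after][1] - pulse$pulse_end_ms
             else NA_real_
  list(sag = sag, rebound = rebound)
}

inst_freq_ends <- function(spike_times_ms) {
  isis <- diff(spike_times_ms) / 1000          # s
  list(f_start = mean(1 / isis[1:2]),
       f_end = mean(1 / rev(isis)[1:2]))
}

#' Compute frequency-current gain and spike-frequency adaptation
#'
#' For each pulse, the start (end) frequency is the mean instantaneous
#' frequency of the first (last) three APs, i.e. of the two leading
#' (trailing) ISIs. Saturating pulses (depolarization block) are excluded:
#' a pulse saturates when its spike count is below the previous pulse's or
#' when spiking ceases well before the pulse end (terminal silent gap longer
#' than max(200 ms, twice the largest ISI of the pulse)). GS and GE are 100x
#' the OLS slope of frequency vs current over the maximal leading
#' non-saturating run; the SFA index is GS/GE.
#'
#' @param responses list of list(`spike_times` ms relative to pulse onset,
#'   `current_pA`, `pulse_ms`)
#' @param min_spikes minimum spikes per retained pulse. The method needs 4;
#'   the default of 6 additionally makes the first-three and last-three AP
#'   windows disjoint, so the end frequency is not contaminated by the
#'   start of the train on slow, strongly adapting responses.
#' @return list(`gain_start`, `gain_end`, `sfa_index`, `fit_range` pA,
#'   `r2_start`, `r2_end`, `n_pulses`)
#' @export
compute_gain <- function(responses, min_spikes = 6L) {
  if (min_spikes < 4L) abort("min_spikes must be >= 4", "validation_error")
  ord <- order(vapply(responses, `[[`, numeric(1), "current_pA"))
  responses <- responses[ord]
  info <- lapply(responses, function(r) {
    st <- r$spike_times
    n <- length(st)
    if (n < min_spikes) return(list(n = n, ok = FALSE))
    isis <- diff(st)
    gap <- r$pulse_ms - max(st)
    ceased <- gap > max(200, 2 * max(isis))
    c(list(n = n, ok = TRUE, ceased = ceased), inst_freq_ends(st))
  })
  ns <- vapply(info, `[[`, numeric(1), "n")
  keep <- logical(length(info))
  prev_n <- -Inf
  for (i in seq_along(info)) {
    if (!info[[i]]$ok) {
      if (any(keep)) break else next     # below rheobase before the run
    }
    if (info[[i]]$ceased || ns[i] < prev_n) break
    keep[i] <- TRUE
    prev_n <- ns[i]
  }
  if (sum(keep) < 3L)
    abort("fewer than 3 non-saturating pulses with >= 4 spikes",
          "insufficient_data_error")
  I <- vapply(responses[keep], `[[`, numeric(1), "current_pA")
  fs <- vapply(info[keep], `[[`, numeric(1), "f_start")
  fe <- vapply(info[keep], `[[`, numeric(1), "f_end")
  m1 <- lm(fs ~ I); m2 <- lm(fe ~ I)
  gs <- 100 * coef(m1)[["I"]]; ge <- 100 * coef(m2)[["I"]]
  if (ge <= 0) abort("non-positive end gain", "fit_error")
  r2 <- function(m, y) {
    tss <- sum((y - mean(y))^2)
    if (tss == 0) 1 else 1 - sum(residuals(m)^2) / tss
  }
  list(gain_start = gs, gain_end = ge, sfa_index = gs / ge,
       fit_range = range(I),
       r2_start = r2(m1, fs), r2_end = r2(m2, fe),
       n_pulses = sum(keep))
}

#' Extract the 16 electrophysiological parameters of one neuron
#'
#' Runs every measurement whose protocol is present in the recording set;
#' absent protocols leave their features `NA`. Failures in optional
#' protocols downgrade to warnings (features `NA`); a failure on the
#' spontaneous trace is fatal for the neuron.
#'
#' @param rec a [recording_set()]
#' @param min_span_s minimum spontaneous spiking span, s
#' @param dvdt_thresh,vmin spike-detector settings (see [detect_spikes()])
#' @return one-row data.frame: `neuron_id`, `age_days`, `stage`, the 16
#'   features, and `n_spikes`
#' @export
extract_features <- function(rec, min_span_s = 40, dvdt_thresh = 10,
                             vmin = -20) {
  out <- as.list(setNames(rep(NA_real_, 16L), feature_names()))
  sp <- detect_spikes(rec$spontaneous, dvdt_thresh, vmin)
  stats <- isi_statistics(sp, min_span_s)
  out$isi_avg <- stats$isi_avg
  out$cv_isi <- stats$cv_isi
  avg <- average_ap(rec$spontaneous, sp)
  thr <- measure_ap_threshold(avg)
  apf <- measure_ap_features(avg, thr)
  out$ap_threshold <- apf$threshold
  out$ap_amplitude <- apf$amplitude
  out$ap_half_width <- apf$half_width
  out$ap_rise_slope <- apf$rise_slope
  out$ap_decay_slope <- apf$decay_slope
  out$ahp <- apf$ahp
  soft <- function(expr) tryCatch(expr, error = function(e) {
    warning(sprintf("[%s] %s", rec$neuron_id, conditionMessage(e)),
            call. = FALSE)
    NULL
  })
  if (length(rec$passive_pulses)) {
    fits <- Filter(Negate(is.null),
                   lapply(rec$passive_pulses, function(p) soft(fit_passive(p))))
    if (length(fits)) {
      out$tau_m <- mean(vapply(fits, `[[`, numeric(1), "tau_m"))
      out$r_in <- mean(vapply(fits, `[[`, numeric(1), "r_in"))
      out$c_m <- 1000 * out$tau_m / out$r_in
    }
  }
  if (!is.null(rec$sag_pulse)) {
    sr <- soft(measure_sag_rebound(rec$sag_pulse))
    if (!is.null(sr)) {
      out$sag <- sr$sag
      out$rebound <- sr$rebound
    }
  }
  if (length(rec$fi_pulses)) {
    resp <- lapply(rec$fi_pulses, function(p) {
      st <- detect_spikes(p$trace, dvdt_thresh, vmin)
      st <- st[st >= p$pulse_start_ms & st <= p$pulse_end_ms]
      list(spike_times = st - p$pulse_start_ms, current_pA = p$step_pA,
           pulse_ms = p$pulse_end_ms - p$pulse_start_ms)
    })
    g <- soft(compute_gain(resp))
    if (!is.null(g)) {
      out$gain_start <- g$gain_start
      out$gain_end <- g$gain_end
      out$sfa_index <- g$sfa_index
    }
  }
  cbind(data.frame(neuron_id = rec$neuron_id, age_days = rec$age_days,
                   stage = rec$stage, stringsAsFactors = FALSE),
        as.data.frame(out), data.frame(n_spikes = length(sp)))
}

#' Extract features for a list of recordings
#' @param recordings list of [recording_set()]
#' @param ... passed to [extract_features()]
#' @return data.frame, one row per neuron
#' @export
extract_cohort <- function(recordings, ...) {
  do.call(rbind, lapply(recordings, extract_features, ...))
}
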