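#' Detect action potentials in a voltage trace
#'
#' An event is a run of samples where dV/dt exceeds `dvdt_thresh`, confirmed
#' by the voltage reaching `vmin` shortly after; the event time is the sample
#' of the voltage maximum. Events closer than the refractory period are
#' merged.
#'
#' @param trace a [voltage_trace()]
#' @param dvdt_thresh detection threshold on dV/dt, mV/ms
#' @param vmin confirmation level the voltage must exceed, mV
#' @param refractory_ms minimum event separation, ms
#' @param smooth_ms half-width of the central-difference derivative used for
#'   detection, ms; widening it low-pass filters the derivative so sampling
#'   noise cannot cross `dvdt_thresh` (at 0.3 mV noise and 20 kHz the raw
#'   successive-sample slope has an SD of ~8.5 mV/ms)
#' @return spike peak times in ms (possibly empty)
#' @export
detect_spikes <- function(trace, dvdt_thresh = 10, vmin = -20,
                          refractory_ms = 2, smooth_ms = 0.25) {
  v <- trace$voltage; dt <- trace$time_step
  w <- max(1L, round(smooth_ms / dt))
  n <- length(v)
  dv <- c(rep(0, w), (v[(1 + 2 * w):n] - v[1:(n - 2 * w)]) / (2 * w * dt),
          rep(0, w))
  hot <- which(dv > dvdt_thresh)
  if (!length(hot)) return(numeric(0))
  gap <- max(1L, round(refractory_ms / dt))
  starts <- hot[c(TRUE, diff(hot) > gap)]
  look <- round(6 / dt)                       # peak search window, 6 ms
  peaks <- integer(0)
  for (s in starts) {
    j <- min(s + look, length(v))
    p <- s + which.max(v[s:j]) - 1L
    if (v[p] > vmin &&
        (!length(peaks) || (p - peaks[length(peaks)]) * dt > refractory_ms))
      peaks <- c(peaks, p)
  }
  (peaks - 1L) * dt
}

#' Interspike-interval statistics
#'
#' Mean ISI and its coefficient of variation (sample SD / mean, percent),
#' computed from at least 40 s of spontaneous activity.
#'
#' @param spike_times spike times, ms
#' @param min_span_s minimum first-to-last spike span, s
#' @return list(`isi_avg` s, `cv_isi` percent, `n_isi`, `span_s`)
#' @export
isi_statistics <- function(spike_times, min_span_s = 40) {
  if (length(spike_times) < 3L)
    abort("need at least 3 spikes for ISI statistics",
          "insufficient_data_error")
  span <- (max(spike_times) - min(spike_times)) / 1000
  if (span < min_span_s)
    abort("only %.1f s of spiking (< %g s required)",
          "insufficient_data_error", span, min_span_s)
  isis <- diff(sort(spike_times)) / 1000
  m <- mean(isis)
  list(isi_avg = m, cv_isi = 100 * sd(isis) / m,
       n_isi = length(isis), span_s = span)
}

#' Average the spontaneous action potentials of a trace
#'
#' Windows aligned on the spike peak sample are averaged pointwise; spikes
#' whose window is truncated by the trace edges are excluded.
#'
#' @param trace a [voltage_trace()]
#' @param spike_times spike peak times, ms
#' @param window_before,window_after window extent around the peak, ms
#' @return object of class `ap_waveform` with `n_averaged`
#' @export
average_ap <- function(trace, spike_times, window_before = 10,
                       window_after = 60) {
  dt <- trace$time_step
  nb <- round(window_before / dt); na <- round(window_after / dt)
  pk <- round(spike_times / dt) + 1L
  pk <- pk[pk - nb >= 1L & pk + na <= length(trace$voltage)]
  if (!length(pk))
    abort("no spike with a complete averaging window",
          "insufficient_data_error")
  acc <- numeric(nb + na + 1L)
  for (p in pk) acc <- acc + trace$voltage[(p - nb):(p + na)]
  structure(list(voltage = acc / length(pk), time_step = dt,
                 peak_index = nb + 1L, n_averaged = length(pk)),
            class = "ap_waveform")
}

wf_parts <- function(waveform) {
  v <- waveform$voltage; dt <- waveform$time_step
  list(v = v, dt = dt, t = (seq_along(v) - 1L) * dt,
       dv = diff(v) / dt,
       tm = (seq_len(length(v) - 1L) - 0.5) * dt)   # midpoint times of dv
}

#' Measure the action-potential threshold
#'
#' The threshold is the voltage where dV/dt first reaches 5% of its peak:
#' the crossing is located by scanning backward from the dV/dt peak and
#' linearly interpolated between samples.
#'
#' @param waveform an `ap_waveform` (from [render_ap()] or [average_ap()])
#' @return threshold, mV
#' @export
measure_ap_threshold <- function(waveform) {
  w <- wf_parts(waveform)
  imax <- which.max(w$dv)
  s5 <- 0.05 * w$dv[imax]
  below <- which(w$dv[seq_len(imax)] < s5)
  if (!length(below))
    abort("dV/dt never falls below 5%% of its peak before the peak",
          "shape_error")
  i <- max(below)                       # crossing between dv[i] and dv[i+1]
  f <- (s5 - w$dv[i]) / (w$dv[i + 1L] - w$dv[i])
  t_cross <- w$tm[i] + f * (w$tm[i + 1L] - w$tm[i])
  approx(w$t, w$v, xout = t_cross)$y
}

limb_crossing <- function(w, level, idx, rising) {
  interp_crossing(w$t, w$v, level, idx, rising = rising)
}

#' Measure action-potential waveform features
#'
#' Amplitude (threshold to peak), half-width (duration at threshold +
#' amplitude/2), mean 10-90% rise and decay slopes (chord between the
#' interpolated 10% and 90% crossings, i.e. the time average of dV/dt over
#' the band), and AHP amplitude (threshold to post-peak trough).
#'
#' @param waveform an `ap_waveform`
#' @param threshold AP threshold, mV (from [measure_ap_threshold()])
#' @return list(`threshold`, `amplitude`, `half_width`, `rise_slope`,
#'   `decay_slope`, `ahp`, `n_averaged`)
#' @export
measure_ap_features <- function(waveform, threshold) {
  w <- wf_parts(waveform)
  pk <- which.max(w$v)
  peak <- w$v[pk]
  if (threshold >= peak) abort("threshold above peak", "shape_error")
  A <- peak - threshold
  lv <- function(f) threshold + f * A
  up <- seq_len(pk); down <- pk:length(w$v)
  t_half_up <- limb_crossing(w, lv(0.5), up, rising = TRUE)
  t_half_dn <- limb_crossing(w, lv(0.5), down, rising = FALSE)
  if (is.na(t_half_dn))
    abort("falling limb never reaches half height (truncated window)",
          "shape_error")
  t10u <- limb_crossing(w, lv(0.1), up, rising = TRUE)
  t90u <- limb_crossing(w, lv(0.9), up, rising = TRUE)
  t90d <- limb_crossing(w, lv(0.9), down, rising = FALSE)
  t10d <- limb_crossing(w, lv(0.1), down, rising = FALSE)
  if (anyNA(c(t_half_up, t10u, t90u, t90d, t10d)))
    abort("limb does not span the 10-90%% band", "shape_error")
  ahp <- threshold - min(w$v[down])
  list(threshold = threshold, amplitude = A,
       half_width = t_half_dn - t_half_up,
       rise_slope = 0.8 * A / (t90u - t10u),
       decay_slope = -0.8 * A / (t10d - t90d),
       ahp = ahp,
       n_averaged = waveform$n_averaged %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
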