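# Legal ranges used to truncate the stage-level parameter draws. Bounds are
# the invariant-legal ranges of each parameter, tightened where the
# downstream measurement has a hard floor (e.g. the spike detector needs the
# rising limb to exceed 10 mV/ms). Sampling is moment-matched so the
# *truncated* draws reproduce the calibration mean/SD.
param_bounds <- function() {
  list(isi_avg       = c(0.15, 10),
       cv_isi        = c(0.5, 400),
       r_in          = c(50, 4000),
       c_m           = c(20, 1000),
       sag           = c(0, 60),
       rebound       = c(30, 2500),
       ap_threshold  = c(-58, -28),
       ap_amplitude  = c(30, 110),
       ap_half_width = c(0.5, 6),
       ap_rise_slope = c(12, 150),
       ap_decay_slope = c(-120, -6),
       ahp           = c(0.5, 45),
       gain_start    = c(6, 50),
       gain_end      = c(6, 50))
}

draw_param <- function(stage, calibration, parameter) {
  cal <- cal_lookup(calibration, stage, parameter)
  b <- param_bounds()[[parameter]]
  rtnorm_matched(1L, cal$mean, cal$sd, b[1], b[2])
}

#' Sample one neuron's ground-truth parameters for a developmental stage
#'
#' Each of the 14 directly measured parameters is drawn from a truncated
#' normal moment-matched to the stage calibration (tau_m and the SFA index
#' are implied by R_in*C_m and GS/GE). The firing regime follows from the
#' drawn CV_ISI via the 20/80% rule.
#'
#' @param stage stage label present in `calibration`
#' @param calibration calibration table from [load_calibration()]
#' @return list with components `ap` ([ap_shape_params()]), `train`
#'   ([spike_train_params()]), `passive`, `gain`, `stage`, and `truth` (named
#'   vector of the 16 implied feature values)
#' @export
sample_neuron_params <- function(stage, calibration = load_calibration()) {
  if (!stage %in% calibration$stage)
    abort("unknown stage '%s'", "lookup_error", stage)
  p <- sapply(names(param_bounds()), draw_param,
              stage = stage, calibration = calibration)
  # keep the AP peak comfortably above the -20 mV detector confirmation level
  p["ap_amplitude"] <- max(p["ap_amplitude"], -12 - p["ap_threshold"])
  regime <- as.character(classify_firing(p["cv_isi"]))
  # keep the template support below the shortest interspike interval the
  # train can produce (intra-burst ISI of bursting neurons); extreme joint
  # draws (wide slow AP) are redrawn
  intra <- 0.12
  for (try in 1:20) {
    ap <- ap_shape_params(threshold = p[["ap_threshold"]],
                          amplitude = p[["ap_amplitude"]],
                          half_width = p[["ap_half_width"]],
                          rise_slope = p[["ap_rise_slope"]],
                          decay_slope = p[["ap_decay_slope"]],
                          ahp_depth = p[["ahp"]], ahp_duration = 30)
    total <- tryCatch(ap_geometry(ap)$total, error = function(e) Inf)
    if (total <= intra * 1000 - 10) break
    for (nm in c("ap_half_width", "ap_rise_slope", "ap_decay_slope"))
      p[nm] <- draw_param(stage, calibration, nm)
    if (try == 20L)
      abort("cannot draw an AP shape compatible with burst rendering",
            "validation_error")
  }
  train <- spike_train_params(regime, mean_isi = p[["isi_avg"]],
                              target_cv = p[["cv_isi"]],
                              burst = if (regime == "bursting")
                                burst_structure_for(p[["isi_avg"]],
                                                    p[["cv_isi"]],
                                                    intra_isi = intra))
  passive <- list(r_in = p[["r_in"]], c_m = p[["c_m"]],
                  sag_amp = p[["sag"]], sag_tau = 120,
                  rebound_delay = p[["rebound"]], resting = -60)
  gain <- list(gain_start = p[["gain_start"]], gain_end = p[["gain_end"]],
               rheobase = 30, saturation = 400)
  truth <- c(isi_avg = p[["isi_avg"]], cv_isi = p[["cv_isi"]],
             tau_m = p[["r_in"]] * p[["c_m"]] / 1000, r_in = p[["r_in"]],
             c_m = p[["c_m"]], sag = p[["sag"]], rebound = p[["rebound"]],
             ap_threshold = p[["ap_threshold"]],
             ap_amplitude = p[["ap_amplitude"]],
             ap_half_width = p[["ap_half_width"]],
             ap_rise_slope = p[["ap_rise_slope"]],
             ap_decay_slope = p[["ap_decay_slope"]], ahp = p[["ahp"]],
             gain_start = p[["gain_start"]], gain_end = p[["gain_end"]],
             sfa_index = p[["gain_start"]] / p[["gain_end"]])
  list(ap = ap, train = train, passive = passive, gain = gain,
       stage = stage, truth = truth)
}

#' Render a spontaneous recording from spike times and an AP shape
#'
#' AP templates are pasted at the given spike times (snapped to the sample
#' grid, template peak on the spike time) over a flat inter-spike baseline,
#' with optional additive Gaussian noise.
#'
#' @param spike_times spike times, s
#' @param shape an [ap_shape_params()]
#' @param duration trace duration, s
#' @param time_step sampling interval, ms
#' @param noise_sd Gaussian noise SD, mV (0 = noiseless)
#' @return a [voltage_trace()]
#' @export
render_spontaneous <- function(spike_times, shape, duration,
                               time_step = 0.05, noise_sd = 0.3) {
  tmpl <- render_ap(shape, time_step)
  n <- round(duration * 1000 / time_step)
  v <- rep(tmpl$baseline, n)
  if (length(spike_times)) {
    pk <- round(spike_times * 1000 / time_step) + 1L
    pk <- pk[pk - tmpl$n_pre >= 1L & pk + tmpl$n_post <= n]
    if (length(pk) > 1L && any(diff(pk) <= tmpl$n_pre + tmpl$n_post))
      abort("spikes closer than the AP template support", "validation_error")
    for (p in pk) {
      v[(p - tmpl$n_pre):(p + tmpl$n_post)] <- tmpl$voltage
    }
  }
  if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
  voltage_trace(time_step, v, label = "spontaneous")
}

#' Generate an ideal passive (RC) current-pulse response
#'
#' Mono-exponential response to a small hyperpolarizing step:
#' V(t) = resting + step*R_in*(1 - exp(-t/tau)), tau = R_in*C_m. The plateau
#' must stay within 10 mV of rest.
#'
#' @param truth list with `r_in` (MOhm), `c_m` (pF), `resting` (mV)
#' @param step_pA step amplitude, pA (< 0)
#' @param duration_s pulse duration, s
#' @param time_step sampling interval, ms
#' @param noise_sd Gaussian noise SD, mV
#' @return list(`trace`, `step_pA`, `pulse_start_ms`, `pulse_end_ms`)
#' @export
gen_passive_pulse <- function(truth, step_pA, duration_s = 0.8,
                              time_step = 0.05, noise_sd = 0) {
  dv_inf <- step_pA * truth$r_in / 1000        # mV
  if (abs(dv_inf) >= 10)
    abort("pulse would hyperpolarize by %.1f mV (>= 10 mV)",
          "validation_error", abs(dv_inf))
  tau <- truth$r_in * truth$c_m / 1000         # ms
  pre <- 100; post <- 200
  pulse_ms <- duration_s * 1000
  t <- seq(0, pre + pulse_ms + post, by = time_step)
  v <- rep(truth$resting, length(t))
  ip <- t >= pre & t <= pre + pulse_ms
  v[ip] <- truth$resting + dv_inf * (1 - exp(-(t[ip] - pre) / tau))
  io <- t > pre + pulse_ms
  v_end <- truth$resting + dv_inf * (1 - exp(-pulse_ms / tau))
  v[io] <- truth$resting + (v_end - truth$resting) *
    exp(-(t[io] - pre - pulse_ms) / tau)
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  cur <- ifelse(ip, step_pA, 0)
  list(trace = voltage_trace(time_step, v, cur, label = "passive"),
       step_pA = step_pA, pulse_start_ms = pre, pulse_end_ms = pre + pulse_ms)
}

#' Generate a sag/rebound protocol response
#'
#' A large hyperpolarizing step producing a voltage trough followed by a
#' depolarizing sag relaxation (time constant `sag_tau`) so the response ends
#' at `v_end` (default -85 mV; the step amplitude is auto-scaled to reach
#' it). A rebound AP is pasted with its peak `rebound_delay` ms after pulse
#' offset.
#'
#' @param truth list with `r_in`, `sag_amp` (mV), `sag_tau` (ms),
#'   `rebound_delay` (ms), `resting` (mV)
#' @param shape [ap_shape_params()] for the rebound AP (or `NULL` for none)
#' @param pulse_ms pulse duration, ms
#' @param time_step sampling interval, ms
#' @param v_end target voltage at the end of the pulse, mV
#' @param noise_sd Gaussian noise SD, mV
#' @return list(`trace`, `step_pA`, `pulse_start_ms`, `pulse_end_ms`)
#' @export
gen_sag_pulse <- function(truth, shape = NULL, pulse_ms = 1000,
                          time_step = 0.05, v_end = -85, noise_sd = 0) {
  if (v_end >= truth$resting)
    abort("sag protocol must hyperpolarize below rest", "validation_error")
  if (v_end - truth$sag_amp >= truth$resting)
    abort("sag amplitude exceeds the total hyperpolarization",
          "validation_error")
  trough <- v_end - truth$sag_amp
  pre <- 200; t_min <- 120
  post <- max(truth$rebound_delay + 150, 400)
  t <- seq(0, pre + pulse_ms + post, by = time_step)
  v <- rep(truth$resting, length(t))
  # descent to the trough (half-cosine, zero slope at the trough)
  i1 <- t >= pre & t < pre + t_min
  s <- (t[i1] - pre) / t_min
  v[i1] <- trough + (truth$resting - trough) * (1 + cos(pi * s)) / 2
  # sag relaxation towards v_end
  i2 <- t >= pre + t_min & t <= pre + pulse_ms
  v[i2] <- v_end - truth$sag_amp * exp(-(t[i2] - pre - t_min) / truth$sag_tau)
  # recovery to rest after offset
  i3 <- t > pre + pulse_ms
  v_off <- v_end - truth$sag_amp * exp(-(pulse_ms - t_min) / truth$sag_tau)
  rec <- 150
  s3 <- pmin((t[i3] - pre - pulse_ms) / rec, 1)
  v[i3] <- truth$resting + (v_off - truth$resting) * (1 + cos(pi * s3)) / 2
  if (!is.null(shape)) {
    # the rebound AP replaces the recovering baseline: a spike implies the
    # membrane has recovered to its firing trajectory, and an additive
    # paste on a still-hyperpolarized baseline could keep the peak below
    # the detector's confirmation level
    tmpl <- render_ap(shape, time_step)
    pk <- round((pre + pulse_ms + truth$rebound_delay) / time_step) + 1L
    idx <- (pk - tmpl$n_pre):(pk + tmpl$n_post)
    keep <- idx >= 1L & idx <= length(v)
    v[idx[keep]] <- tmpl$voltage[keep]
  }
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  step_pA <- 1000 * (v_end - truth$resting) / truth$r_in
  cur <- ifelse(t >= pre & t <= pre + pulse_ms, step_pA, 0)
  list(trace = voltage_trace(time_step, v, cur, label = "sag"),
       step_pA = step_pA, pulse_start_ms = pre, pulse_end_ms = pre + pulse_ms)
}

# spike times (s, relative to pulse onset) for one depolarizing pulse:
# the first three spikes fire at the start-gain frequency, then the
# instantaneous frequency relaxes exponentially to the end-gain frequency.
# The adaptation time constant is short (SK-type adaptation) so that the
# trailing interspike intervals express the end frequency essentially
# exactly even on slow trains.
fi_spike_times <- function(f_start, f_end, pulse_s = 1, tau_adapt = 0.02) {
  t1 <- 1 / (2 * f_start)
  times <- t1 + (0:2) / f_start
  t_hold <- times[3]
  t <- t_hold
  repeat {
    f <- f_end + (f_start - f_end) * exp(-(t - t_hold) / tau_adapt)
    t <- t + 1 / f
    if (t > pulse_s) break
    times <- c(times, t)
  }
  times[times <= pulse_s]
}

# compact AP variant used to render driven (f-I) trains: same core waveform
# but a short AHP recovery, since during sustained depolarization the
# inter-spike trajectory never returns to the spontaneous baseline
fi_render_shape <- function(shape) {
  ap_shape_params(shape$threshold, shape$amplitude, shape$half_width,
                  shape$rise_slope, shape$decay_slope, shape$ahp_depth,
                  ahp_duration = 2,
                  baseline = shape$threshold - min(1.5, 0.8 * shape$ahp_depth))
}

#' Maximum sustainable firing rate of the f-I rendering, Hz
#'
#' The reciprocal of the compact AP template support: above this rate APs
#' would overlap, which the generator treats as depolarization block.
#'
#' @param shape an [ap_shape_params()]
#' @param time_step sampling interval, ms
#' @return rate ceiling, Hz
#' @export
fi_rate_ceiling <- function(shape, time_step = 0.05) {
  geo <- ap_geometry(fi_render_shape(shape))
  1000 / (geo$total + 1 + 4 * time_step)
}

#' Generate a frequency-current protocol
#'
#' For each injected current in the non-saturating range the instantaneous
#' firing frequency decays from `gain_start*I/100` to `gain_end*I/100` Hz
#' during a 1 s pulse. Below rheobase no spikes are fired; at or above the
#' saturation current -- or when the requested start frequency exceeds the
#' neuron's rate ceiling ([fi_rate_ceiling()]) -- spiking ceases mid-pulse
#' (depolarization-block emulation).
#'
#' @param truth list with `gain_start`, `gain_end` (Hz/100 pA), `rheobase`,
#'   `saturation` (pA)
#' @param shape [ap_shape_params()] used for the rendered APs
#' @param currents injected current amplitudes, pA
#' @param pulse_ms pulse duration, ms
#' @param time_step sampling interval, ms
#' @param noise_sd Gaussian noise SD, mV
#' @return list of list(`trace`, `step_pA`, `pulse_start_ms`, `pulse_end_ms`)
#' @export
gen_fi_set <- function(truth, shape, currents = seq(50, 300, by = 50),
                       pulse_ms = 1000, time_step = 0.05, noise_sd = 0) {
  if (!length(currents)) abort("empty current list", "validation_error")
  tmpl <- render_ap(fi_render_shape(shape), time_step, pad = 0.5)
  f_max <- fi_rate_ceiling(shape, time_step)
  pre <- 100; post <- 200
  n <- round((pre + pulse_ms + post) / time_step) + 1L
  lapply(currents, function(I) {
    v <- rep(tmpl$baseline, n)
    if (I > truth$rheobase) {
      fs <- truth$gain_start * I / 100
      fe <- truth$gain_end * I / 100
      st <- if (I >= truth$saturation || fs > f_max)
        fi_spike_times(min(fs, 0.8 * f_max), min(fs, 0.8 * f_max),
                       pulse_s = 0.4)           # block: spiking stops early
      else fi_spike_times(fs, fe, pulse_s = pulse_ms / 1000)
      pk <- round((pre + st * 1000) / time_step) + 1L
      pk <- pk[pk - tmpl$n_pre >= 1L & pk + tmpl$n_post <= n]
      if (length(pk) > 1L)                      # safety: never overlap APs
        pk <- pk[c(TRUE, diff(pk) > tmpl$n_pre + tmpl$n_post)]
      for (p in pk) v[(p - tmpl$n_pre):(p + tmpl$n_post)] <- tmpl$voltage
    }
    if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
    t <- (seq_len(n) - 1L) * time_step
    cur <- ifelse(t >= pre & t <= pre + pulse_ms, I, 0)
    list(trace = voltage_trace(time_step, v, cur, label = sprintf("fi_%g", I)),
         step_pA = I, pulse_start_ms = pre, pulse_end_ms = pre + pulse_ms)
  })
}

#' Generate the full recording set of one synthetic neuron
#'
#' @param params output of [sample_neuron_params()] (or a hand-built list of
#'   the same structure)
#' @param neuron_id identifier
#' @param age_days postnatal day (consistent with the stage in `params`)
#' @param duration_s spontaneous-trace duration, s
#' @param time_step sampling interval, ms
#' @param noise_sd Gaussian noise SD, mV
#' @param protocols subset of `c("spontaneous", "passive", "sag", "fi")`
#' @return a [recording_set()] with `ground_truth = params$truth`
#' @export
generate_recording_set <- function(params, neuron_id, age_days,
                                   duration_s = 120, time_step = 0.05,
                                   noise_sd = 0.3,
                                   protocols = c("spontaneous", "passive",
                                                 "sag", "fi")) {
  st <- gen_spike_times(params$train, duration_s)
  spont <- render_spontaneous(st, params$ap, duration_s, time_step, noise_sd)
  passive <- list(); sagp <- NULL; fip <- list()
  if ("passive" %in% protocols) {
    step <- -0.8 * 10 * 1000 / params$passive$r_in   # ~8 mV plateau
    passive <- list(gen_passive_pulse(params$passive, step,
                                      time_step = time_step,
                                      noise_sd = noise_sd))
  }
  if ("sag" %in% protocols)
    sagp <- gen_sag_pulse(params$passive, params$ap, time_step = time_step,
                          noise_sd = noise_sd)
  if ("fi" %in% protocols) {
    # adapt the current range to the neuron: stay below the current at
    # which the start frequency would hit the rate ceiling (block)
    f_max <- fi_rate_ceiling(params$ap, time_step)
    imax <- min(300, floor(0.95 * 100 * f_max / params$gain$gain_start))
    currents <- if (imax >= 290) seq(50, 300, by = 50) else {
      lo <- max(40, params$gain$rheobase + 10)
      unique(5 * round(seq(lo, max(imax, lo + 50), length.out = 6) / 5))
    }
    fip <- gen_fi_set(params$gain, params$ap, currents = currents,
                      time_step = time_step, noise_sd = noise_sd)
  }
  recording_set(neuron_id, age_days, spont, passive, sagp, fip,
                ground_truth = c(list(stage = params$stage),
                                 as.list(params$truth),
                                 list(regime = params$train$regime,
                                      realized_spike_times = st)))
}

sample_age_in_stage <- function(stage) {
  bins <- stage_bins()
  i <- match(stage, bins$stage)
  if (is.na(i)) abort("unknown stage '%s'", "lookup_error", stage)
  if (bins$age_min[i] == bins$age_max[i]) bins$age_min[i]
  else sample(seq(bins$age_min[i], bins$age_max[i]), 1L)
}

#' Generate a seeded synthetic cohort
#'
#' @param plan data.frame with columns `stage`, `n` (e.g.
#'   [default_stage_plan()]); all `n` must be > 0
#' @param calibration calibration table
#' @param seed RNG seed (reproducible: identical plan/calibration/seed give
#'   identical cohorts)
#' @param ... passed to [generate_recording_set()]
#' @return list(`recordings` = list of [recording_set()], `ground_truth` =
#'   data.frame of the per-neuron true feature values)
#' @export
generate_cohort <- function(plan, calibration = load_calibration(),
                            seed = 1L, ...) {
  if (any(plan$n <= 0)) abort("plan group sizes must be > 0",
                              "validation_error")
  set.seed(seed)
  recs <- list(); gt <- list(); k <- 0L
  for (i in seq_len(nrow(plan))) {
    for (j in seq_len(plan$n[i])) {
      k <- k + 1L
      id <- sprintf("n%04d", k)
      age <- sample_age_in_stage(plan$stage[i])
      params <- sample_neuron_params(plan$stage[i], calibration)
      recs[[k]] <- generate_recording_set(params, id, age, ...)
      st <- recs[[k]]$ground_truth$realized_spike_times
      isis <- diff(st)
      gt[[k]] <- data.frame(neuron_id = id, age_days = age,
                            stage = plan$stage[i],
                            regime = params$train$regime,
                            t(params$truth),
                            realized_isi_avg = mean(isis),
                            realized_cv_isi = 100 * sd(isis) / mean(isis),
                            stringsAsFactors = FALSE)
    }
  }
  list(recordings = recs, ground_truth = do.call(rbind, gt))
}

#' Generate a cohort and extract its features, one neuron at a time
#'
#' Streaming variant of [generate_cohort()] + [extract_cohort()]: each
#' neuron's traces are generated, measured and discarded, so long recordings
#' do not accumulate in memory.
#'
#' @inheritParams generate_cohort
#' @param ... passed to [generate_recording_set()]
#' @return list(`features`, `ground_truth`): data.frames, one row per neuron
#' @export
simulate_feature_cohort <- function(plan, calibration = load_calibration(),
                                    seed = 1L, ...) {
  if (any(plan$n <= 0)) abort("plan group sizes must be > 0",
                              "validation_error")
  set.seed(seed)
  feats <- list(); gt <- list(); k <- 0L
  for (i in seq_len(nrow(plan))) {
    for (j in seq_len(plan$n[i])) {
      k <- k + 1L
      id <- sprintf("n%04d", k)
      age <- sample_age_in_stage(plan$stage[i])
      params <- sample_neuron_params(plan$stage[i], calibration)
      rec <- generate_recording_set(params, id, age, ...)
      feats[[k]] <- extract_features(rec)
      st <- rec$ground_truth$realized_spike_times
      isis <- diff(st)
      gt[[k]] <- data.frame(neuron_id = id, age_days = age,
                            stage = plan$stage[i],
                            regime = params$train$regime,
                            t(params$truth),
                            realized_isi_avg = mean(isis),
                            realized_cv_isi = 100 * sd(isis) / mean(isis),
                            stringsAsFactors = FALSE)
    }
  }
  list(features = do.call(rbind, feats), ground_truth = do.call(rbind, gt))
}
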