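#' Action-potential shape parameters
#'
#' Parameter set of the analytic AP template: threshold, amplitude
#' (threshold to peak), half-width, 10-90% mean rise and decay slopes,
#' afterhyperpolarization depth (threshold to trough) and duration, and the
#' inter-spike baseline the waveform starts from and relaxes back to.
#'
#' @param threshold AP threshold, mV (voltage where dV/dt reaches 5% of its
#'   peak)
#' @param amplitude threshold-to-peak amplitude, mV (> 0)
#' @param half_width duration at threshold + amplitude/2, ms (> 0)
#' @param rise_slope mean dV/dt between 10 and 90% of amplitude on the rising
#'   limb, mV/ms (> 0)
#' @param decay_slope likewise on the falling limb, mV/ms (< 0)
#' @param ahp_depth threshold-to-trough AHP amplitude, mV (>= 0)
#' @param ahp_duration trough-to-baseline relaxation time, ms
#' @param baseline inter-spike baseline, mV; `NULL` places it just below
#'   threshold (a shallow depolarizing foot), never below the AHP trough
#' @return object of class `ap_shape_params`
#' @export
ap_shape_params <- function(threshold, amplitude, half_width, rise_slope,
                            decay_slope, ahp_depth, ahp_duration = 40,
                            baseline = NULL) {
  for (nm in c("threshold", "amplitude", "half_width", "rise_slope",
               "decay_slope", "ahp_depth", "ahp_duration"))
    assert_scalar_number(get(nm), nm)
  if (amplitude <= 0) abort("amplitude must be > 0", "validation_error")
  if (half_width <= 0) abort("half_width must be > 0", "validation_error")
  if (rise_slope <= 0) abort("rise_slope must be > 0", "validation_error")
  if (decay_slope >= 0) abort("decay_slope must be < 0", "validation_error")
  if (ahp_depth < 0) abort("ahp_depth must be >= 0", "validation_error")
  structure(list(threshold = threshold, amplitude = amplitude,
                 half_width = half_width, rise_slope = rise_slope,
                 decay_slope = decay_slope, ahp_depth = ahp_depth,
                 ahp_duration = ahp_duration, baseline = baseline),
            class = "ap_shape_params")
}

# Solve one limb of the template. Given the half-to-peak (or peak-to-half)
# time h, the target 10-90% mean slope S and the amplitude A, returns the
# slopes of the lower [0.1A, 0.3A] and upper [0.3A, 0.9A] band segments and
# the duration u of the parabolic cap above 0.9A.
#
# The mean dV/dt over the 10-90% band is the chord 0.8A / t_band, so the band
# need only have total duration 0.8A/S; its *shape* is free, which is what
# lets half-width be controlled independently of the slopes. When the limb is
# slow enough the band is a single line of slope S; otherwise the part above
# 0.3A is steepened, with the lower slope set so the 10-90% chord stays
# exactly S. The segment split sits at 0.3A deliberately: the measured
# levels (10%, 50%, 90% of amplitude) must all fall on smooth stretches,
# because a slope corner at a measured level biases its interpolated
# crossing time.
solve_limb <- function(h, S, A) {
  if (h >= 0.6 * A / S) {
    u <- h - 0.4 * A / S            # cap absorbs the slack time
    list(s_lo = S, s_hi = S, u = u)
  } else {
    s_hi <- 0.6 * A / h             # minimal C1 cap: u = 0.2A/s_hi
    s_lo <- 0.2 / (0.8 / S - 0.6 / s_hi)
    list(s_lo = s_lo, s_hi = s_hi, u = 0.2 * A / s_hi)
  }
}

# Piecewise-analytic template geometry. Returns segment durations and value
# functions; t = 0 at template onset, peak at t = t_peak.
ap_geometry <- function(shape) {
  T0 <- shape$threshold; A <- shape$amplitude; HW <- shape$half_width
  RS <- shape$rise_slope; aDS <- -shape$decay_slope; D <- shape$ahp_depth
  P <- T0 + A

  # split the half-width between the two limbs in proportion to their
  # characteristic times (1/RS vs 1/|DS|)
  h_r <- HW * (1 / RS) / (1 / RS + 1 / aDS)
  h_f <- HW - h_r
  rise <- solve_limb(h_r, RS, A)
  fall <- solve_limb(h_f, aDS, A)

  s_max <- rise$s_hi                # global peak of dV/dt sits in the rise
  s5 <- 0.05 * s_max                # the threshold-detection level
  # the rising limb must stay clearly above the 5%-of-peak-dV/dt level
  # everywhere past the foot, or the threshold criterion would fire inside
  # the limb instead of at `threshold`; extremely concave rises (slow
  # 10-90% chord combined with a very short half-width) violate this
  if (rise$s_lo <= 1.3 * s5)
    abort("rise too concave: sub-band slope %.2f mV/ms falls below the 5%%-of-peak dV/dt level",
          "validation_error", rise$s_lo)

  # depolarizing foot: quadratic, dV/dt ramps 0 -> s5, ending exactly at
  # threshold so the 5%-of-peak-dV/dt criterion lands on `threshold`.
  # Its depth is kept below the AHP so the trough stays the global minimum,
  # and its duration is capped at 15 ms so slow APs keep a compact support.
  fd <- if (is.null(shape$baseline)) min(8, 0.8 * D, 7.5 * s5)
        else T0 - shape$baseline
  if (fd < 0) abort("baseline above threshold", "validation_error")
  if (fd > D && D > 0 && !is.null(shape$baseline))
    abort("baseline below AHP trough", "validation_error")
  B <- T0 - fd
  t_foot <- if (fd > 0) 2 * fd / s5 else 0

  d1 <- 0.2 * A / (s5 + rise$s_lo)  # slope ramp s5 -> s_lo over [T, T+0.1A]
  d3 <- 2 * (0.1 * A + D) / fall$s_lo # ramp -s_lo -> 0 over [T+0.1A, T-D]

  # peak cap of one limb, covering the top 0.1A over duration u with the
  # band slope S at its outer end. When u is the minimal C1 value the cap is
  # a single parabola; longer caps are split into a steep parabola covering
  # 0.09A and a smoothstep dome for the last 0.01A, keeping dV/dt continuous
  # at the 90%-amplitude level (a slope corner there would bias the
  # interpolated 10-90% chord).
  cap_segs <- function(u, S, rising) {
    sgn <- if (rising) 1 else -1
    u_min <- 0.2 * A / S
    if (u <= u_min * (1 + 1e-9)) {
      f <- if (rising) function(tau) P - (0.1 * A / u^2) * (u - tau)^2
           else function(tau) P - (0.1 * A / u^2) * tau^2
      return(list(list(dur = u, f = f)))
    }
    uA <- 0.18 * A / S                 # parabola: slope S -> 0 over 0.09A
    uB <- u - uA
    dome <- function(tau, dur) 0.01 * A * (3 * (tau / dur)^2 -
                                           2 * (tau / dur)^3)
    if (rising) list(
      list(dur = uA, f = function(tau)
        (T0 + 0.9 * A) + S * tau - S * tau^2 / (2 * uA)),
      list(dur = uB, f = function(tau) (P - 0.01 * A) + dome(tau, uB)))
    else list(
      list(dur = uB, f = function(tau) (P - 0.01 * A) + dome(uB - tau, uB)),
      list(dur = uA, f = function(tau)
        (T0 + 0.9 * A) + S * (uA - tau) - S * (uA - tau)^2 / (2 * uA)))
  }

  segs <- c(
    if (t_foot > 0) list(list(dur = t_foot, f = function(tau)
      B + s5 * tau^2 / (2 * t_foot))),
    list(
      list(dur = d1, f = function(tau)
        T0 + s5 * tau + (rise$s_lo - s5) * tau^2 / (2 * d1)),
      list(dur = 0.2 * A / rise$s_lo, f = function(tau)
        T0 + 0.1 * A + rise$s_lo * tau),
      list(dur = 0.6 * A / rise$s_hi, f = function(tau)
        T0 + 0.3 * A + rise$s_hi * tau)),
    cap_segs(rise$u, rise$s_hi, rising = TRUE),
    cap_segs(fall$u, fall$s_hi, rising = FALSE),
    list(
      list(dur = 0.6 * A / fall$s_hi, f = function(tau)
        T0 + 0.9 * A - fall$s_hi * tau),
      list(dur = 0.2 * A / fall$s_lo, f = function(tau)
        T0 + 0.3 * A - fall$s_lo * tau),
      list(dur = d3, f = function(tau)
        T0 + 0.1 * A - fall$s_lo * tau + fall$s_lo * tau^2 / (2 * d3)),
      list(dur = shape$ahp_duration, f = function(tau) {
        s <- tau / shape$ahp_duration
        (T0 - D) + (B - (T0 - D)) * (3 * s^2 - 2 * s^3)
      })))
  durs <- vapply(segs, `[[`, numeric(1), "dur")
  if (any(!is.finite(durs)) || any(durs < 0))
    abort("shape parameters imply a non-monotone limb", "validation_error")
  n_rise <- (if (t_foot > 0) 1L else 0L) + 3L +
    length(cap_segs(rise$u, rise$s_hi, TRUE))
  t_peak <- sum(durs[seq_len(n_rise)])
  list(segs = segs, durs = durs, t_peak = t_peak, total = sum(durs),
       baseline = B, s5 = s5, s_max = s_max)
}

#' Render an analytic action-potential waveform
#'
#' Builds a piecewise-smooth AP from [ap_shape_params()]: a shallow quadratic
#' depolarizing foot (so the 5%-of-peak-dV/dt threshold criterion lands at
#' `threshold`), a rising limb whose 10-90% chord slope equals `rise_slope`,
#' a parabolic peak, a falling limb with chord slope `decay_slope`, descent
#' to the AHP trough at `threshold - ahp_depth`, and a smooth relaxation back
#' to baseline. Every extracted metric therefore has a closed-form target.
#'
#' @param shape an [ap_shape_params()]
#' @param time_step sampling interval, ms (<= 0.1)
#' @param pad flat baseline added on both sides of the analytic support, ms
#' @return object of class `ap_waveform`: list with `voltage`, `time_step`,
#'   `peak_index`, `baseline`, and the support before/after the peak in
#'   samples (`n_pre`, `n_post`)
#' @export
render_ap <- function(shape, time_step = 0.05, pad = 2) {
  if (time_step > 0.1)
    abort("time_step must be <= 0.1 ms for AP rendering", "validation_error")
  geo <- ap_geometry(shape)
  n_pre <- ceiling((geo$t_peak + pad) / time_step)
  n_post <- ceiling((geo$total - geo$t_peak + pad) / time_step)
  t <- (seq_len(n_pre + n_post + 1L) - 1L - n_pre) * time_step + geo$t_peak
  v <- eval_ap_geometry(geo, t)
  structure(list(voltage = v, time_step = time_step, peak_index = n_pre + 1L,
                 baseline = geo$baseline, n_pre = n_pre, n_post = n_post),
            class = "ap_waveform")
}

eval_ap_geometry <- function(geo, t) {
  breaks <- cumsum(c(0, geo$durs))
  seg <- findInterval(t, breaks, rightmost.closed = TRUE)
  v <- rep(geo$baseline, length(t))
  inside <- seg >= 1L & seg <= length(geo$segs) & t >= 0 & t <= geo$total
  for (k in unique(seg[inside])) {
    i <- which(seg == k & inside)
    v[i] <- geo$segs[[k]]$f(t[i] - breaks[k])
  }
  v
}
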