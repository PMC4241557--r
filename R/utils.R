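#' @keywords internal
"_PACKAGE"

# unit conventions used throughout: voltage mV, current pA, time ms for
# traces, s for interspike intervals, resistance MOhm, capacitance pF,
# CV_ISI in percent.  1 mV / 1 pA = 1000 MOhm; tau[ms] = R[MOhm]*C[pF]/1000.

abort <- function(msg, class, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "ephystraj_error")))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort("`%s` must be a single finite number", "validation_error", name)
  invisible(x)
}

#' Linearly interpolated crossing time of a level
#'
#' Returns the time at which a sampled signal first crosses `level`, scanning
#' the index range `idx` in order, with linear interpolation between samples.
#'
#' @param t time of each sample
#' @param y sampled signal
#' @param level level to cross
#' @param idx index range to scan (in scan order)
#' @param rising if `TRUE`, look for an upward crossing, else downward
#' @return interpolated crossing time, or `NA_real_` if no crossing
#' @keywords internal
interp_crossing <- function(t, y, level, idx, rising = TRUE) {
  for (k in seq_len(length(idx) - 1L)) {
    i <- idx[k]; j <- idx[k + 1L]
    if (rising && y[i] <= level && y[j] > level ||
        !rising && y[i] >= level && y[j] < level) {
      f <- (level - y[i]) / (y[j] - y[i])
      return(t[i] + f * (t[j] - t[i]))
    }
  }
  NA_real_
}

# Moment-matched truncated normal: find (mu, sigma) of the parent normal such
# that the truncation of N(mu, sigma) to [a, b] has the requested mean and sd.
# Needed so that cohorts reproduce published stage means/SDs even for
# parameters whose legal range clips an appreciable normal tail.
tnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  if (z < 1e-12) return(c(mean = NA_real_, sd = NA_real_))
  d1 <- (dnorm(al) - dnorm(be)) / z
  m <- mu + sigma * d1
  t2 <- 1 + (ifelse(is.finite(al), al * dnorm(al), 0) -
             ifelse(is.finite(be), be * dnorm(be), 0)) / z - d1^2
  c(mean = m, sd = sigma * sqrt(max(t2, 0)))
}

match_tnorm <- function(target_mean, target_sd, a, b) {
  if (target_sd <= 0) return(c(mu = target_mean, sigma = 0))
  # quick exit when truncation is negligible
  mm <- tnorm_moments(target_mean, target_sd, a, b)
  if (abs(mm["mean"] - target_mean) < 1e-3 * target_sd &&
      abs(mm["sd"] - target_sd) < 1e-3 * target_sd)
    return(c(mu = target_mean, sigma = target_sd))
  obj <- function(p) {
    mm <- tnorm_moments(p[1], exp(p[2]), a, b)
    if (any(!is.finite(mm))) return(1e6)
    (mm[1] - target_mean)^2 / target_sd^2 + (mm[2] - target_sd)^2 / target_sd^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# inverse-CDF sampler for the truncated normal (one uniform per draw, so the
# RNG stream is consumed predictably)
rtnorm <- function(n, mu, sigma, a, b) {
  if (sigma == 0) return(rep(mu, n))
  pa <- pnorm(a, mu, sigma); pb <- pnorm(b, mu, sigma)
  qnorm(pa + runif(n) * (pb - pa), mu, sigma)
}

#' Sample one value from a moment-matched truncated normal
#'
#' Draws from a normal distribution truncated to `[a, b]` whose *truncated*
#' mean and sd equal `mean` and `sd` (the parent parameters are adjusted by
#' moment matching).
#'
#' @param n number of draws
#' @param mean,sd target mean and sd of the truncated distribution
#' @param a,b truncation bounds
#' @return numeric vector of draws
#' @export
rtnorm_matched <- function(n, mean, sd, a = -Inf, b = Inf) {
  p <- match_tnorm(mean, sd, a, b)
  pmin(pmax(rtnorm(n, p[["mu"]], p[["sigma"]], a, b), a), b)
}
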