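# Pulsatile-circadian TSH time-series generator and a simple trough-to-peak
# pulse detector.
#
# TSH is secreted in bursts (5-20 per day, mean amplitude about 0.6 mU/L)
# riding on a circadian rhythm that peaks shortly after midnight; the
# nocturnal rise affects not only the baseline but also the amplitude of the
# fast pulses, which is modelled here as multiplicative coupling of the
# pulse-amplitude mean to the circadian cosine.

#' Parameters of the pulsatile TSH secretion model
#'
#' @param pulses_per_day mean number of secretory bursts per 24 h. Values
#'   outside the physiological 5–20 range are accepted with a warning.
#' @param mean_amplitude mean pulse amplitude, mU/L.
#' @param amplitude_cv coefficient of variation of the log-normal pulse
#'   amplitudes (0 = all pulses identical).
#' @param pulse_halflife exponential decay half-life of a secreted pulse,
#'   minutes (plasma TSH half-life).
#' @param baseline tonic (non-pulsatile) TSH level, mU/L.
#' @param circadian_amplitude amplitude of the circadian cosine added to the
#'   baseline, mU/L.
#' @param acrophase clock time of the circadian maximum, hours after
#'   midnight.
#' @param amplitude_circadian_coupling multiplicative coupling of the pulse
#'   amplitude mean to the circadian cosine (0 = none; 0.5 means nocturnal
#'   pulses are on average 50% larger at the acrophase than the 24-h mean).
#' @param interval_shape gamma shape of the inter-pulse intervals; larger
#'   values give a more regular pulse train (interval CV is
#'   `1/sqrt(shape)`).
#' @return A list of class `pulse_model`.
#' @examples
#' pulse_model()                      # euthyroid defaults
#' pulse_model(pulses_per_day = 8)
#' @export
pulse_model <- function(pulses_per_day = 12, mean_amplitude = 0.6,
                        amplitude_cv = 0.15, pulse_halflife = 50,
                        baseline = 1.5, circadian_amplitude = 1.2,
                        acrophase = 0.8, amplitude_circadian_coupling = 0.5,
                        interval_shape = 12) {
  m <- list(pulses_per_day = pulses_per_day, mean_amplitude = mean_amplitude,
            amplitude_cv = amplitude_cv, pulse_halflife = pulse_halflife,
            baseline = baseline, circadian_amplitude = circadian_amplitude,
            acrophase = acrophase,
            amplitude_circadian_coupling = amplitude_circadian_coupling,
            interval_shape = interval_shape)
  stopifnot(all(vapply(m, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))))
  if (pulses_per_day <= 0 || mean_amplitude <= 0 || pulse_halflife <= 0 ||
      amplitude_cv < 0 || baseline < 0 || circadian_amplitude < 0 ||
      interval_shape <= 0) {
    stop("pulse_model: invalid parameter values")
  }
  if (pulses_per_day < 5 || pulses_per_day > 20) {
    warning("pulse_model: pulses_per_day outside the physiological 5-20/day")
  }
  if (baseline - circadian_amplitude < 0) {
    stop("pulse_model: circadian trough would be negative")
  }
  structure(m, class = "pulse_model")
}

.circadian <- function(t_s, acrophase_h) {
  cos(2 * pi * (t_s / 86400 - acrophase_h / 24))
}

#' Generate a pulsatile-circadian TSH time series
#'
#' Pulse onsets are drawn from a gamma renewal process (shape
#' `interval_shape`, giving inter-pulse intervals far more regular than
#' Poisson) with mean interval `24 h / pulses_per_day`; the process is
#' started one day before the observation window so that the series is
#' stationary from its first sample. Each pulse is an instantaneous rise,
#' snapped to the sampling grid, with log-normal amplitude whose mean is
#' `mean_amplitude * (1 + coupling * circadian(t))`, decaying exponentially
#' with `pulse_halflife`. The deterministic floor is
#' `baseline + circadian_amplitude * circadian(t)` with the circadian cosine
#' peaking at `acrophase` (default: 00:48, shortly after midnight).
#'
#' @param model a [pulse_model()].
#' @param duration_hours length of the observed series.
#' @param dt sampling interval in seconds (>= 1).
#' @param seed integer seed; identical `(model, seed)` give identical series.
#' @return A tibble of class `tsh_series` with `t_s` (seconds from midnight)
#'   and `tsh` (mU/L), carrying the truth record of observed-window pulses
#'   as `attr(, "truth")`: a tibble of `time_s` and `amplitude`.
#' @examples
#' ser <- generate_series(pulse_model(), duration_hours = 24, seed = 42)
#' head(attr(ser, "truth"))
#' @export
generate_series <- function(model = pulse_model(), duration_hours = 24,
                            dt = 60, seed = NULL) {
  stopifnot(inherits(model, "pulse_model"), duration_hours > 0, dt >= 1)
  if (!is.null(seed)) set.seed(seed)
  end_s <- duration_hours * 3600
  t_grid <- seq(0, end_s, by = dt)

  # renewal process with one-day burn-in so decay tails and phase coverage
  # are stationary at t = 0
  mean_interval <- 86400 / model$pulses_per_day
  shape <- model$interval_shape
  onsets <- numeric(0)
  t_cur <- -86400
  repeat {
    gap <- stats::rgamma(1L, shape = shape, scale = mean_interval / shape)
    t_cur <- t_cur + gap
    if (t_cur > end_s) break
    onsets <- c(onsets, t_cur)
  }
  onsets <- round(onsets / dt) * dt  # snap to the sampling grid

  amp_mean <- model$mean_amplitude *
    pmax(0, 1 + model$amplitude_circadian_coupling *
           .circadian(onsets, model$acrophase))
  if (model$amplitude_cv > 0) {
    sdlog <- sqrt(log(1 + model$amplitude_cv^2))
    amps <- stats::rlnorm(length(onsets), log(amp_mean) - sdlog^2 / 2, sdlog)
  } else {
    amps <- amp_mean
  }

  tsh <- model$baseline + model$circadian_amplitude *
    .circadian(t_grid, model$acrophase)
  lambda <- log(2) / (model$pulse_halflife * 60)
  for (i in seq_along(onsets)) {
    idx <- which(t_grid >= onsets[i])
    if (length(idx)) {
      tsh[idx] <- tsh[idx] + amps[i] * exp(-lambda * (t_grid[idx] - onsets[i]))
    }
  }

  keep <- onsets >= 0 & onsets <= end_s
  truth <- tibble::tibble(time_s = onsets[keep], amplitude = amps[keep])
  ser <- tibble::tibble(t_s = t_grid, tsh = tsh)
  attr(ser, "truth") <- truth
  class(ser) <- c("tsh_series", class(ser))
  ser
}

# centred rolling SD; width forced odd
.running_sd <- function(x, width) {
  width <- max(3L, width + (1L - width %% 2L))
  half <- width %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  m <- hi - lo
  mu <- (cs[hi + 1L] - cs[lo + 1L]) / m
  v <- (cs2[hi + 1L] - cs2[lo + 1L]) / m - mu^2
  sqrt(pmax(0, v) * m / pmax(1, m - 1))
}

#' Detect TSH pulses by trough-to-peak excursion
#'
#' A deliberately simple detector that closes the recovery loop on the
#' generator: the series is detrended with a running median (window
#' `detrend_hours`), and local maxima whose detrended height exceeds
#' `threshold_sd` running standard deviations are reported as pulses. The
#' amplitude estimate is the peak value minus the preceding trough (the
#' minimum since the previous detection or the series start). Deconvolution
#' methods are intentionally out of scope.
#'
#' @param series a [generate_series()] result, or any data frame with
#'   columns `t_s` and `tsh` (at least 20 samples).
#' @param threshold_sd detection threshold in running-SD units.
#' @param detrend_hours running-median window, hours.
#' @return A tibble with `time_s` and `amplitude` of detected pulses; zero
#'   rows for a flat series.
#' @examples
#' ser <- generate_series(pulse_model(), seed = 1)
#' nrow(detect_pulses(ser))
#' @export
detect_pulses <- function(series, threshold_sd = 1, detrend_hours = 2) {
  stopifnot(all(c("t_s", "tsh") %in% names(series)))
  t_s <- series$t_s; v <- series$tsh
  n <- length(v)
  if (n < 20L) stop("detect_pulses: need at least 20 samples")
  dt <- stats::median(diff(t_s))
  w <- max(3L, round(detrend_hours * 3600 / dt))
  w <- w + (1L - w %% 2L)
  trend <- stats::runmed(v, min(w, n - (1 - n %% 2)))
  resid <- v - trend
  rsd <- .running_sd(resid, w)

  is_max <- c(FALSE, diff(v) > 0) & c(v[-n] >= v[-1], FALSE)
  cand <- which(is_max & resid > threshold_sd * rsd)
  if (!length(cand)) {
    return(tibble::tibble(time_s = numeric(0), amplitude = numeric(0)))
  }
  amp <- numeric(length(cand))
  prev <- 1L
  for (i in seq_along(cand)) {
    seg <- v[prev:cand[i]]
    amp[i] <- v[cand[i]] - min(seg)
    prev <- cand[i]
  }
  tibble::tibble(time_s = t_s[cand], amplitude = amp)
}
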