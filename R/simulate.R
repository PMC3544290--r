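# Dynamic simulation of the feedback loop: first-order plasma-pool lags
# toward the instantaneous transfer outputs, integrated with fixed-step RK4
# under a time-varying parameter schedule.

.schedulable <- c("g_t", "g_d", "g_h", "g_d2", "trh_drive")

#' Time-indexed parameter schedule
#'
#' A scenario is a table of `(parameter, time_days, value)` breakpoints;
#' between breakpoints the parameter is linearly interpolated, and it is
#' held constant beyond the first/last breakpoint. Schedulable parameters:
#' `g_t`, `g_d`, `g_h`, `g_d2`, `trh_drive`.
#'
#' @param parameter character vector of parameter names.
#' @param time_days breakpoint times in days.
#' @param value parameter values at the breakpoints.
#' @return A tibble of class `scenario`.
#' @seealso [scenario_thyrotropic_adaptation()] for the shipped critical-
#'   illness scenario; [read_scenario()] to load one from CSV.
#' @export
scenario <- function(parameter, time_days, value) {
  bad <- setdiff(unique(parameter), .schedulable)
  if (length(bad)) {
    stop("scenario: not schedulable: ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.schedulable, collapse = ", "))
  }
  stopifnot(is.numeric(time_days), is.numeric(value),
            all(is.finite(time_days)), all(is.finite(value)), all(value > 0))
  s <- tibble::tibble(parameter = as.character(parameter),
                      time_days = time_days, value = value)
  s <- s[order(s$parameter, s$time_days), ]
  class(s) <- c("scenario", class(s))
  s
}

#' Read a scenario from CSV
#'
#' Expects columns `parameter`, `time_days`, `value`.
#' @param path CSV file path.
#' @return A [scenario()] tibble.
#' @export
read_scenario <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scenario(df$parameter, df$time_days, df$value)
}

#' Central hyperdeiodination scenario (thyrotropic adaptation)
#'
#' The shipped critical-illness scenario: central type 2 deiodinase activity
#' ramps linearly from its euthyroid value 1 up to `peak` between
#' `ramp_start` and `ramp_end` days, plateaus, and is restored linearly to 1
#' between `restore_start` and `restore_end` days. During the ramp TSH is
#' suppressed and FT4 drifts down (the laboratory picture of thyrotropic
#' adaptation); after restoration TSH transiently overshoots its baseline
#' while the slow T4 pool refills.
#'
#' @param peak maximal central D2 scaling.
#' @param ramp_start,ramp_end,restore_start,restore_end breakpoints in days.
#' @return A [scenario()] tibble scheduling `g_d2`.
#' @export
scenario_thyrotropic_adaptation <- function(peak = 3, ramp_start = 3,
                                            ramp_end = 10, restore_start = 14,
                                            restore_end = 17) {
  scenario(rep("g_d2", 5),
           c(0, ramp_start, ramp_end, restore_start, restore_end),
           c(1, 1, peak, peak, 1))
}

# piecewise-linear schedule values for one parameter at times t (days)
.schedule_values <- function(scn, parameter, t_days, default) {
  if (is.null(scn)) return(rep(default, length(t_days)))
  rows <- scn$parameter == parameter
  if (!any(rows)) return(rep(default, length(t_days)))
  x <- scn$time_days[rows]; y <- scn$value[rows]
  if (length(x) == 1L) return(rep(y, length(t_days)))
  stats::approx(x, y, xout = t_days, rule = 2)$y
}

#' Simulate the feedback loop through time
#'
#' Integrates first-order lag dynamics
#' \deqn{dX/dt = (X_{target}(t) - X)/\tau_X, \quad X \in \{TSH, FT4, FT3\}}
#' where each target is the instantaneous transfer output given the current
#' upstream state and the (possibly scheduled) parameters, using fixed-step
#' classical Runge-Kutta. Central T3 follows FT4 algebraically
#' (`ft3_central = g_d2(t) * c2 * ft4`). The integration starts at the
#' equilibrium of the schedule's initial parameter values unless `init` is
#' given, so a constant schedule yields constant trajectories.
#'
#' @param params a [feedback_parameters()] object (baseline values for any
#'   parameter the scenario does not schedule).
#' @param scenario a [scenario()] tibble, or `NULL` for constant parameters.
#' @param duration_days length of the simulation in days.
#' @param dt integration step in seconds (default 60 s; states move on
#'   time scales of hours to days, so this is far inside the stability
#'   region).
#' @param seed integer seed; only consumed when `noise_cv > 0`.
#' @param init optional named numeric `c(tsh=, ft4=, ft3=)` initial state.
#' @param sample_dt output sampling interval in seconds.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   observation noise applied to the sampled hormone columns (0 = off).
#' @return A tibble with `time_days`, `tsh`, `ft4`, `ft3`, `ft3_central`
#'   and the scheduled parameter trajectories `g_t`, `g_d`, `g_h`, `g_d2`,
#'   `trh_drive`.
#' @examples
#' sim <- simulate_dynamics(feedback_parameters(),
#'                          scenario_thyrotropic_adaptation(),
#'                          duration_days = 30)
#' range(sim$tsh)
#' @export
simulate_dynamics <- function(params = feedback_parameters(), scenario = NULL,
                              duration_days = 30, dt = 60, seed = NULL,
                              init = NULL, sample_dt = 3600, noise_cv = 0) {
  stopifnot(inherits(params, "feedback_parameters"),
            duration_days > 0, dt >= 1)
  if (!is.null(scenario) && max(scenario$time_days) > duration_days) {
    stop("simulate_dynamics: duration_days must cover the schedule span")
  }
  k <- params$constants
  n_steps <- ceiling(duration_days * 86400 / dt)
  # schedule values on the half-step grid RK4 touches: t, t+dt/2, t+dt
  t_half <- seq(0, n_steps * dt, by = dt / 2) / 86400
  sched <- lapply(.schedulable, function(nm) {
    .schedule_values(scenario, nm, t_half, params[[nm]])
  })
  names(sched) <- .schedulable

  B4 <- 1 + k$K41 * params$tbg + k$K42 * params$tbpa
  B3 <- 1 + k$K30 * params$tbg
  pit_fac <- function(g_h, trh, d_h) g_h * trh / (d_h + trh)

  deriv <- function(st, i_half) {
    g_t <- sched$g_t[i_half]; g_d <- sched$g_d[i_half]
    g_h <- sched$g_h[i_half]; g_d2 <- sched$g_d2[i_half]
    trh <- sched$trh_drive[i_half]
    tsh_t <- pit_fac(g_h, trh, params$d_h) /
      (1 + params$l_s * g_d2 * params$c2 * st[2])
    ft4_t <- k$alpha_T * g_t * st[1] / (k$beta_T * (k$D_T + st[1]) * B4)
    ft4_si <- st[2] * 1e-12
    ft3_t <- k$alpha_31 * (g_d * 1e-9) * ft4_si /
      (k$beta_31 * (k$K_M1 + ft4_si) * B3) * 1e12
    c((tsh_t - st[1]) / params$tau_tsh,
      (ft4_t - st[2]) / params$tau_t4,
      (ft3_t - st[3]) / params$tau_t3)
  }

  if (is.null(init)) {
    p0 <- params
    for (nm in .schedulable) p0[[nm]] <- sched[[nm]][1]
    class(p0) <- "feedback_parameters"
    eq <- solve_equilibrium(p0)
    if (!isTRUE(eq$converged)) stop("simulate_dynamics: no initial equilibrium")
    st <- c(eq$tsh, eq$ft4, eq$ft3)
  } else {
    st <- unname(init[c("tsh", "ft4", "ft3")])
    if (any(!is.finite(st)) || any(st <= 0)) {
      stop("simulate_dynamics: init must give positive tsh, ft4, ft3")
    }
  }

  every <- max(1L, round(sample_dt / dt))
  n_out <- floor(n_steps / every) + 1L
  out <- matrix(NA_real_, n_out, 4L)
  out_t <- numeric(n_out)
  out[1L, ] <- c(st, sched$g_d2[1] * params$c2 * st[2])
  j <- 1L
  for (i in seq_len(n_steps)) {
    i0 <- 2L * i - 1L            # index of t in the half-step grid
    k1 <- deriv(st, i0)
    k2 <- deriv(st + dt / 2 * k1, i0 + 1L)
    k3 <- deriv(st + dt / 2 * k2, i0 + 1L)
    k4 <- deriv(st + dt * k3, i0 + 2L)
    st <- st + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(st)) || any(st < 0)) {
      stop(sprintf("simulate_dynamics: unstable step at t = %.4f days",
                   i * dt / 86400))
    }
    if (i %% every == 0L) {
      j <- j + 1L
      out[j, ] <- c(st, sched$g_d2[i0 + 2L] * params$c2 * st[2])
      out_t[j] <- i * dt / 86400
    }
  }
  out <- out[seq_len(j), , drop = FALSE]
  res <- tibble::tibble(
    time_days = out_t[seq_len(j)],
    tsh = out[, 1], ft4 = out[, 2], ft3 = out[, 3], ft3_central = out[, 4]
  )
  for (nm in .schedulable) {
    res[[nm]] <- .schedule_values(scenario, nm, res$time_days, params[[nm]])
  }
  if (noise_cv > 0) {
    if (is.null(seed)) stop("simulate_dynamics: observation noise needs a seed")
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    for (nm in c("tsh", "ft4", "ft3")) {
      res[[nm]] <- res[[nm]] *
        stats::rlnorm(nrow(res), -sdlog^2 / 2, sdlog)
    }
  }
  res
}
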