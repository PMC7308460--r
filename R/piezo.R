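# critically damped second-order plant natural frequency (rad/s), set from
# the steady-state velocity-lag bound: tracking at v the plant lags by
# 2*v/omega, which must not exceed the following-error bound
piezo_omega <- function(cfg) {
  2 * (cfg$piezo$v_max * 1e6) / cfg$piezo$following_error_um
}

# time for the critically damped step response to come within `frac` of a
# unit step: solve (1 + x) exp(-x) = frac, t = x / omega
piezo_settle_time <- function(cfg, frac) {
  x <- uniroot(function(x) (1 + x) * exp(-x) - frac, c(1e-6, 60),
               tol = 1e-12)$root
  x / piezo_omega(cfg)
}

#' Simulate the piezo actuator following a commanded trajectory
#'
#' The plant is a critically damped second-order system (two cascaded
#' first-order stages with a common pole at `omega`), with `omega` chosen so
#' the steady-state lag while tracking at the maximum velocity equals the
#' configured following-error bound. The capacitive position sensor is
#' modelled as the true plant position plus Gaussian noise. Commands that
#' violate the acceleration or velocity limit are rejected.
#'
#' @param traj A [plan_z_trajectory()] result.
#' @param cfg A [hardware_config()].
#' @param seed Seed for the sensor noise (deterministic per seed).
#' @param rate Simulation rate (Hz); defaults to the configured feedback
#'   rate.
#' @param noise_sd_um Sensor noise SD (um); defaults to the configured
#'   value.
#' @return A `piezo_trace` tibble covering one cycle: `t` (s), `z_cmd`,
#'   `z_true`, `z_fb` (um), with attributes `omega`, `rate`, `period`.
#' @export
simulate_piezo <- function(traj, cfg, seed = 1, rate = NULL,
                           noise_sd_um = NULL) {
  stopifnot(inherits(traj, "z_trajectory"), inherits(cfg, "hardware_config"))
  if (is.null(rate)) rate <- cfg$piezo$feedback_rate
  if (is.null(noise_sd_um)) noise_sd_um <- cfg$piezo$feedback_noise_um
  v_um <- cfg$piezo$v_max * 1e6
  a_um <- cfg$piezo$a_max * 1e6
  bad_v <- traj$v_pk > v_um * (1 + 1e-9)
  if (any(bad_v)) {
    abort(sprintf("simulate_piezo: trajectory violates V_max in %d segment(s)",
                  sum(bad_v)))
  }
  acc <- trajectory_accelerations(traj)
  if (any(acc > a_um * (1 + 1e-9))) {
    abort(sprintf("simulate_piezo: trajectory violates A_max (max %.3g m/s^2 > %.3g)",
                  max(acc) * 1e-6, cfg$piezo$a_max))
  }
  cmd <- sample_trajectory(traj, rate)
  z_true <- piezo_filter(cmd$z_cmd, piezo_omega(cfg), 1 / rate)
  z_fb <- if (noise_sd_um > 0) {
    withr_seed(seed, function() z_true + rnorm(length(z_true), 0, noise_sd_um))
  } else {
    z_true
  }
  new_tibble(
    tibble(t = cmd$t, z_cmd = cmd$z_cmd, z_true = z_true, z_fb = z_fb),
    class = "piezo_trace",
    omega = piezo_omega(cfg), rate = rate, period = attr(traj, "period"),
    noise_sd_um = noise_sd_um
  )
}

# peak commanded acceleration per segment (um/s^2)
trajectory_accelerations <- function(traj) {
  dur <- traj$t1 - traj$t0
  d <- abs(traj$z1 - traj$z0)
  t_a <- ifelse(traj$v_pk > 0, dur - d / pmax(traj$v_pk, 1e-300), Inf)
  ifelse(d < 1e-12, 0, traj$v_pk / t_a)
}

# cascade of two exact first-order discretisations = critically damped
# second-order response (exact for piecewise-constant input)
piezo_filter <- function(x, omega, dt) {
  a <- exp(-omega * dt)
  y1 <- stats::filter(x * (1 - a), a, method = "recursive", init = x[1])
  y2 <- stats::filter(as.numeric(y1) * (1 - a), a, method = "recursive",
                      init = x[1])
  as.numeric(y2)
}

#' Step response of the simulated piezo plant
#'
#' Convenience probe of the plant model used by [simulate_piezo()]: applies
#' a position step and returns the response, for checking settling
#' behaviour against the configured limits.
#'
#' @param cfg A [hardware_config()].
#' @param step_um Step size (um).
#' @param duration Observation window (s).
#' @param rate Simulation rate (Hz).
#' @return A tibble with `t` (s) and `z` (um); the command steps from 0 to
#'   `step_um` at t = 0.
#' @export
piezo_step_response <- function(cfg, step_um = 100, duration = 5e-3,
                                rate = NULL) {
  if (is.null(rate)) rate <- cfg$piezo$feedback_rate
  t <- seq(0, duration, by = 1 / rate)
  cmd <- c(0, rep(step_um, length(t) - 1))
  tibble(t = t, z = piezo_filter(cmd, piezo_omega(cfg), 1 / rate))
}

#' Interpolate a piezo trace at arbitrary times
#'
#' Times are wrapped modulo the cycle period, matching the repeating
#' template trajectory of a rapid scan.
#'
#' @param piezo A `piezo_trace`.
#' @param t Times (s).
#' @param what Column to interpolate (`"z_true"` or `"z_fb"`).
#' @return Positions (um).
#' @export
piezo_position_at <- function(piezo, t, what = "z_true") {
  period <- attr(piezo, "period")
  tm <- t %% period
  approx(piezo$t, piezo[[what]], xout = tm, rule = 2)$y
}
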