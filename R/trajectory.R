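# trapezoidal point-to-point move under velocity/acceleration limits
# (um, um/s, um/s^2); returns duration and peak velocity
trapezoid_move <- function(d_um, v_um, a_um) {
  d <- abs(d_um)
  if (d < 1e-12) return(list(t = 0, v_pk = 0))
  d_crit <- v_um^2 / a_um
  if (d <= d_crit) {
    list(t = 2 * sqrt(d / a_um), v_pk = sqrt(d * a_um))
  } else {
    list(t = d / v_um + v_um / a_um, v_pk = v_um)
  }
}

#' Plan the monotone piezo Z-trajectory for a POI rapid scan
#'
#' Clusters the POIs, sorted by Z, into dwell windows no wider than
#' `2 * (d_TOL - dwell_margin)` so that every POI in a window lies within
#' the axial tolerance of the window centre, then builds a single monotone
#' sweep from the lowest window to the highest: the stage pauses at each
#' window centre long enough to scan all its POIs (plus a short transient
#' allowance `t_pad`) and moves between windows along trapezoidal profiles
#' bounded by the piezo's maximum velocity and acceleration. One flyback
#' move plus a full settling time returns the stage to the start, closing
#' the cycle. An optional `rate_target` stretches the cycle with an idle
#' hold so the scan repeats at a prescribed (slower) rate, as used when
#' locking acquisition to a stimulus protocol.
#'
#' @param pois A `poi_set` (or any data frame with a `z` column, um).
#' @param cfg A [hardware_config()].
#' @param timing A [compute_timing()] model; defaults to `compute_timing(cfg)`.
#' @param rate_target Optional cycle rate to pad down to (Hz).
#' @return A `z_trajectory`: a tibble of timed segments (`type`, `t0`, `t1`,
#'   `z0`, `z1`, `v_pk`) with attributes `windows` (dwell-window table),
#'   `period` (s), `z_min`, `z_max` (um), `timing` and `cfg`.
#' @examples
#' tree <- generate_synthetic_neuron(seed = 1)
#' traj <- plan_z_trajectory(interpolate_pois(tree), hardware_config())
#' attr(traj, "period")
#' @export
plan_z_trajectory <- function(pois, cfg, timing = NULL, rate_target = NULL) {
  stopifnot(inherits(cfg, "hardware_config"))
  if (nrow(pois) == 0) abort("plan_z_trajectory: empty POI set")
  if (is.null(timing)) timing <- compute_timing(cfg)
  z <- pois$z
  if (diff(range(z)) > cfg$piezo$travel_um) {
    abort("plan_z_trajectory: POI Z extent exceeds piezo travel range")
  }
  d_eff <- cfg$piezo$d_tol_um - cfg$piezo$dwell_margin_um
  ord <- order(z)
  zs <- z[ord]
  # greedy clustering in sorted order
  win_id <- integer(length(zs))
  w <- 0L
  anchor <- -Inf
  for (i in seq_along(zs)) {
    if (zs[i] > anchor + 2 * d_eff) {
      w <- w + 1L
      anchor <- zs[i]
    }
    win_id[i] <- w
  }
  windows <- tibble(
    window_id = seq_len(w),
    z_lo = vapply(seq_len(w), function(k) min(zs[win_id == k]), numeric(1)),
    z_hi = vapply(seq_len(w), function(k) max(zs[win_id == k]), numeric(1)),
    n_poi = as.integer(tabulate(win_id, w))
  )
  windows$z_center <- (windows$z_lo + windows$z_hi) / 2
  poi_rows <- split(ord, win_id)

  v_um <- cfg$piezo$v_max * 1e6
  a_um <- cfg$piezo$a_max * 1e6
  t_pad <- cfg$piezo$t_pad
  t_g <- timing$t_g

  seg <- list()
  t <- 0
  t_dwell0 <- numeric(w)
  for (k in seq_len(w)) {
    dwell <- t_pad + windows$n_poi[k] * t_g
    t_dwell0[k] <- t
    seg[[length(seg) + 1]] <- tibble(
      type = "dwell", t0 = t, t1 = t + dwell,
      z0 = windows$z_center[k], z1 = windows$z_center[k], v_pk = 0
    )
    t <- t + dwell
    if (k < w) {
      mv <- trapezoid_move(windows$z_center[k + 1] - windows$z_center[k], v_um, a_um)
      seg[[length(seg) + 1]] <- tibble(
        type = "transit", t0 = t, t1 = t + mv$t,
        z0 = windows$z_center[k], z1 = windows$z_center[k + 1], v_pk = mv$v_pk
      )
      t <- t + mv$t
    }
  }
  extent <- windows$z_center[w] - windows$z_center[1]
  fly <- trapezoid_move(extent, v_um, a_um)
  t_close <- fly$t + if (extent > 1e-12) cfg$piezo$t_settle else 0
  if (!is.null(rate_target)) {
    idle <- max(0, 1 / rate_target - (t + t_close))
    if (idle > 0) {
      seg[[length(seg) + 1]] <- tibble(
        type = "idle", t0 = t, t1 = t + idle,
        z0 = windows$z_center[w], z1 = windows$z_center[w], v_pk = 0
      )
      t <- t + idle
    }
  }
  if (extent > 1e-12) {
    seg[[length(seg) + 1]] <- tibble(
      type = "flyback", t0 = t, t1 = t + fly$t,
      z0 = windows$z_center[w], z1 = windows$z_center[1], v_pk = fly$v_pk
    )
    t <- t + fly$t
    seg[[length(seg) + 1]] <- tibble(
      type = "settle", t0 = t, t1 = t + cfg$piezo$t_settle,
      z0 = windows$z_center[1], z1 = windows$z_center[1], v_pk = 0
    )
    t <- t + cfg$piezo$t_settle
  }
  windows$t_dwell0 <- t_dwell0
  windows$t_event0 <- t_dwell0 + t_pad
  windows$poi_rows <- unname(poi_rows)
  new_tibble(
    bind_rows(seg),
    class = "z_trajectory",
    windows = windows, period = t,
    z_min = windows$z_center[1], z_max = windows$z_center[w],
    d_eff_um = d_eff, timing = timing, cfg = cfg
  )
}

#' @export
print.z_trajectory <- function(x, ...) {
  w <- attr(x, "windows")
  cat(sprintf("<z_trajectory> %d dwell windows over [%.1f, %.1f] um, period %.3f ms\n",
              nrow(w), attr(x, "z_min"), attr(x, "z_max"),
              attr(x, "period") * 1e3))
  NextMethod()
}

#' Evaluate the commanded Z position of a trajectory
#'
#' Closed-form evaluation of the piecewise trajectory (dwells, trapezoidal
#' transits/flyback, idle and settling holds) at arbitrary times. Times are
#' wrapped modulo the cycle period, matching a repeating scan.
#'
#' @param traj A `z_trajectory`.
#' @param t Times (s), vectorised.
#' @return Commanded position (um).
#' @export
trajectory_position <- function(traj, t) {
  period <- attr(traj, "period")
  tm <- t %% period
  tm[t == period] <- period
  idx <- findInterval(tm, traj$t0, rightmost.closed = FALSE)
  idx <- pmin(pmax(idx, 1L), nrow(traj))
  type <- traj$type; t0 <- traj$t0; t1 <- traj$t1
  z0 <- traj$z0; z1 <- traj$z1; v_pk <- traj$v_pk
  out <- z0[idx]
  moving <- which(type[idx] %in% c("transit", "flyback"))
  for (i in moving) {
    j <- idx[i]
    out[i] <- trapezoid_position(tm[i] - t0[j], t1[j] - t0[j], z0[j], z1[j], v_pk[j])
  }
  out
}

trapezoid_position <- function(tau, dur, z0, z1, v_pk) {
  d <- abs(z1 - z0)
  if (d < 1e-12 || dur <= 0) return(z0)
  sgn <- sign(z1 - z0)
  t_a <- dur - d / v_pk # acceleration phase length (= dur/2 for triangles)
  a <- v_pk / t_a
  tau <- min(max(tau, 0), dur)
  disp <- if (tau <= t_a) {
    0.5 * a * tau^2
  } else if (tau <= dur - t_a) {
    0.5 * v_pk * t_a + v_pk * (tau - t_a)
  } else {
    d - 0.5 * a * (dur - tau)^2
  }
  z0 + sgn * disp
}

#' Sample a trajectory on a regular clock
#'
#' @param traj A `z_trajectory`.
#' @param rate Sampling rate (Hz); defaults to the piezo feedback rate.
#' @return A tibble with `t` (s) and `z_cmd` (um) covering one cycle.
#' @export
sample_trajectory <- function(traj, rate = NULL) {
  cfg <- attr(traj, "cfg")
  if (is.null(rate)) rate <- cfg$piezo$feedback_rate
  t <- seq(0, attr(traj, "period"), by = 1 / rate)
  tibble(t = t, z_cmd = trajectory_position(traj, t))
}
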