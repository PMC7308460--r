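#' POI timing model
#'
#' Derives the per-POI service time from the hardware configuration. One POI
#' visit is a short diagonal line scan: the AODs need the access time `T_ACC`
#' to load the new frequency pair, the sweep itself takes
#' `T_SCAN = pixels_per_poi * samples_per_pixel / f_clk`, and an
#' inter-instruction buffer `T_Buffer` separates visits, giving
#' `T_POI = T_Buffer + T_ACC + T_SCAN`. The maximum piezo velocity at which a
#' POI can still be scanned inside the axial tolerance is
#' `V_Z_MAX = 2 * d_TOL / T_POI`.
#'
#' @param cfg A [hardware_config()].
#' @param t_g Inter-POI period (s); must be at least `T_POI`. Defaults to
#'   `T_POI` (back-to-back scanning).
#' @return A `timing_model` list with `t_scan`, `t_poi`, `t_g` (s) and
#'   `v_z_max` (m/s).
#' @examples
#' compute_timing(hardware_config(t_buffer = 0))$t_poi # 35 us
#' @export
compute_timing <- function(cfg, t_g = NULL) {
  stopifnot(inherits(cfg, "hardware_config"))
  if (cfg$daq$f_clk <= 0) abort("compute_timing: sample clock rate must be positive")
  t_scan <- cfg$daq$pixels_per_poi * cfg$daq$samples_per_pixel / cfg$daq$f_clk
  t_poi <- cfg$daq$t_buffer + cfg$aod$t_acc + t_scan
  if (is.null(t_g)) t_g <- t_poi
  if (t_g < t_poi) abort("compute_timing: t_g must be >= T_POI")
  # start pulses live on the sample clock grid, so the inter-POI period is
  # rounded up to a whole number of clock ticks
  t_g <- ceiling(t_g * cfg$daq$f_clk - 1e-9) / cfg$daq$f_clk
  structure(
    list(
      t_scan = t_scan,
      t_poi = t_poi,
      t_g = t_g,
      v_z_max = 2 * (cfg$piezo$d_tol_um * 1e-6) / t_poi
    ),
    class = "timing_model"
  )
}

#' @export
print.timing_model <- function(x, ...) {
  cat(sprintf("<timing_model> T_SCAN %.2f us, T_POI %.2f us, T_G %.2f us, V_Z_MAX %.4f m/s\n",
              x$t_scan * 1e6, x$t_poi * 1e6, x$t_g * 1e6, x$v_z_max))
  invisible(x)
}

#' @method glance timing_model
#' @export
glance.timing_model <- function(x, ...) {
  tibble(
    t_scan_s = x$t_scan, t_poi_s = x$t_poi, t_g_s = x$t_g,
    v_z_max_m_s = x$v_z_max
  )
}

#' AOD deflection angle and access time
#'
#' The deflection angle of an acousto-optic deflector is
#' `theta = lambda * f_mod / v` for modulation frequency `f_mod`, laser
#' wavelength `lambda` and acoustic velocity `v`; the access time — the
#' minimum repositioning latency — is `T_ACC = beam_diameter / v`.
#'
#' @param f_mod Modulation frequency (Hz), vectorised.
#' @param cfg A [hardware_config()].
#' @return `deflection_angle()`: angle in radians; `aod_access_time()`:
#'   seconds.
#' @examples
#' deflection_angle(100e6, hardware_config()) # ~0.14 rad
#' @export
deflection_angle <- function(f_mod, cfg) {
  stopifnot(inherits(cfg, "hardware_config"))
  if (cfg$aod$acoustic_velocity <= 0) {
    abort("deflection_angle: acoustic velocity must be positive")
  }
  if (any(f_mod < 0)) abort("deflection_angle: f_mod must be >= 0")
  cfg$aod$wavelength * f_mod / cfg$aod$acoustic_velocity
}

#' @rdname deflection_angle
#' @export
aod_access_time <- function(cfg) {
  stopifnot(inherits(cfg, "hardware_config"))
  cfg$aod$beam_diameter / cfg$aod$acoustic_velocity
}

#' AOD frequency sweep for a POI line scan
#'
#' Maps image-space POI centre coordinates to the AOD frequency-pair
#' instruction `<f0, f1>` that sweeps an `L_POI`-pixel line through the POI.
#' With `s = (f_max - f_min) / S_px` Hz per pixel,
#' `f0 = s * (u - L_POI/2 - 0.5) + f_min` and
#' `f1 = s * (u + L_POI/2 + 0.5) + f_min`, so the sweep spans the outer edges
#' of the `L_POI` pixels centred on `u`. Identical pairs are issued to both
#' orthogonal deflectors, offset to the POI's own X and Y pixel coordinates,
#' which realises a diagonal sweep through the POI.
#'
#' Pixel convention: 0-based indices, pixel centres at integer coordinates,
#' `fov_um / s_px` micrometres per pixel.
#'
#' @param u_x,u_y POI centre pixel coordinates (vectorised).
#' @param cfg A [hardware_config()].
#' @param clamp If `TRUE`, sweeps that would leave `[f_min, f_max]` are
#'   clamped to the range and flagged; if `FALSE` (default) they raise a
#'   boundary error (the POI is too close to the FOV edge).
#' @return A tibble with one row per POI: `f0_x, f1_x, f0_y, f1_y` (Hz) and
#'   `clamped` (logical).
#' @examples
#' cfg <- hardware_config()
#' aod_sweep(256, 256, cfg)
#' @export
aod_sweep <- function(u_x, u_y, cfg, clamp = FALSE) {
  stopifnot(inherits(cfg, "hardware_config"), length(u_x) == length(u_y))
  half <- cfg$daq$pixels_per_poi / 2 + 0.5
  s <- (cfg$aod$f_max - cfg$aod$f_min) / cfg$aod$s_px
  pair <- function(u) {
    list(f0 = s * (u - half) + cfg$aod$f_min,
         f1 = s * (u + half) + cfg$aod$f_min)
  }
  px <- pair(u_x)
  py <- pair(u_y)
  lo <- cfg$aod$f_min - 1e-6
  hi <- cfg$aod$f_max + 1e-6
  out_of_band <- px$f0 < lo | px$f1 > hi | py$f0 < lo | py$f1 > hi
  if (any(out_of_band) && !clamp) {
    abort(sprintf(
      "aod_sweep: %d POI(s) too close to the FOV edge for an %d-pixel sweep (first at u = (%.1f, %.1f))",
      sum(out_of_band), cfg$daq$pixels_per_poi,
      u_x[which(out_of_band)[1]], u_y[which(out_of_band)[1]]
    ))
  }
  clip <- function(f) pmin(pmax(f, cfg$aod$f_min), cfg$aod$f_max)
  tibble(
    f0_x = clip(px$f0), f1_x = clip(px$f1),
    f0_y = clip(py$f0), f1_y = clip(py$f1),
    clamped = out_of_band
  )
}

#' Invert a frequency sweep back to the POI centre pixel
#'
#' @param f0,f1 Sweep endpoint frequencies (Hz).
#' @param cfg A [hardware_config()].
#' @return Centre pixel coordinate (0-based, fractional).
#' @export
sweep_to_pixel <- function(f0, f1, cfg) {
  s <- (cfg$aod$f_max - cfg$aod$f_min) / cfg$aod$s_px
  ((f0 + f1) / 2 - cfg$aod$f_min) / s
}

#' Micrometre <-> pixel conversion for image space
#'
#' @param x_um Specimen-space lateral coordinate (um).
#' @param cfg A [hardware_config()].
#' @return Pixel coordinate (0-based).
#' @export
um_to_pixel <- function(x_um, cfg) {
  x_um / (cfg$aod$fov_um / cfg$aod$s_px)
}

#' Temporal sampling budget for comprehensive POI imaging
#'
#' The achievable cycle rate of an AOD-limited comprehensive scan of `N_POI`
#' points is `f_s = 1 / (N_POI * T_POI_SCAN)`, with
#' `N_POI ~= L_T / d_L` for an arbor of total length `L_T` interpolated at
#' spacing `d_L`. Saturation imaging is feasible when `f_s` is at least twice
#' the signal bandwidth; the largest POI count that still meets that Nyquist
#' requirement is `N_max = floor(1 / (2 * bandwidth * T_POI_SCAN))`.
#'
#' @param pois A [interpolate_pois()] POI set, or a plain POI count.
#' @param timing A [compute_timing()] model (or a number, T_POI in s).
#' @param signal_bandwidth Signal bandwidth to sample against (Hz).
#' @return A `sampling_budget` list: `n_poi`, `l_t_um`, `d_l_um`,
#'   `t_poi_scan`, `f_s`, `f_nyq_required`, `n_max`, `feasible`.
#' @examples
#' sampling_budget(600, hardware_config(t_buffer = 0), signal_bandwidth = 3)
#' @export
sampling_budget <- function(pois, timing, signal_bandwidth) {
  if (inherits(timing, "hardware_config")) timing <- compute_timing(timing)
  t_poi <- if (inherits(timing, "timing_model")) timing$t_poi else as.numeric(timing)
  if (signal_bandwidth <= 0) abort("sampling_budget: signal bandwidth must be positive")
  if (t_poi <= 0) abort("sampling_budget: T_POI must be positive")
  if (inherits(pois, "poi_set")) {
    n_poi <- nrow(pois)
    l_t <- attr(pois, "l_t_um")
    d_l <- attr(pois, "d_l_um")
  } else {
    n_poi <- as.integer(pois)
    l_t <- NA_real_
    d_l <- NA_real_
  }
  if (n_poi < 1) abort("sampling_budget: need at least one POI")
  f_s <- 1 / (n_poi * t_poi)
  structure(
    list(
      n_poi = n_poi, l_t_um = l_t, d_l_um = d_l, t_poi_scan = t_poi,
      f_s = f_s,
      f_nyq_required = 2 * signal_bandwidth,
      n_max = floor(1 / (2 * signal_bandwidth * t_poi)),
      feasible = f_s >= 2 * signal_bandwidth
    ),
    class = "sampling_budget"
  )
}

#' @export
print.sampling_budget <- function(x, ...) {
  cat(sprintf(
    "<sampling_budget> N_POI %d, f_s %.2f Hz, required %.2f Hz, N_max %d -> %s\n",
    x$n_poi, x$f_s, x$f_nyq_required, x$n_max,
    if (x$feasible) "feasible" else "INFEASIBLE"
  ))
  invisible(x)
}

#' @method glance sampling_budget
#' @export
glance.sampling_budget <- function(x, ...) {
  as_tibble(x[c("n_poi", "l_t_um", "d_l_um", "t_poi_scan", "f_s",
                "f_nyq_required", "n_max", "feasible")])
}
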