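#' Instrument configuration for an AOD random-access two-photon microscope
#'
#' Collects every hardware symbol used by the planner and the digital twin:
#' the acousto-optic deflectors (AODs) that steer the beam in X/Y, the DAQ
#' sample clock that times acquisition, the piezo Z-actuator that moves the
#' objective, and the excitation/detection optics. Defaults are the values of
#' the instrument the package models: wide-angle TeO2 AODs with a 13 us
#' access time, 40 MHz bandwidth and 9 mm apertures; an 11-pixel line scan
#' with 5 samples per pixel on a 2.5 MHz sample clock; and a piezo actuator
#' reaching 0.043 m/s with stable accelerations below 60,000 m/s^2 and a
#' step-settling time under 2.1 ms.
#'
#' All times are seconds, frequencies Hz, optical path lengths metres;
#' specimen-space positions and PSF widths are micrometres (fields suffixed
#' `_um`).
#'
#' @param t_acc AOD access time (s): time for the acoustic wave to cross the
#'   beam waist, the minimum repositioning latency.
#' @param beam_diameter Laser beam diameter at the AOD aperture (m).
#' @param acoustic_velocity Acoustic velocity of the AOD crystal (m/s).
#' @param wavelength Laser wavelength (m).
#' @param f_min,f_max AOD drive frequency range (Hz); `f_max - f_min` is the
#'   modulation bandwidth.
#' @param scan_angle_deg Full optical scan angle (degrees).
#' @param fov_um Side of the square field of view (um).
#' @param s_px Image width in pixels.
#' @param f_clk DAQ sample clock rate (Hz).
#' @param samples_per_pixel PMT samples summed per pixel.
#' @param pixels_per_poi Length of the short line scan through each POI
#'   (pixels, odd so a centre pixel exists).
#' @param t_buffer Inter-instruction buffer time (s).
#' @param v_max Piezo maximum velocity (m/s).
#' @param a_max Piezo maximum stable acceleration (m/s^2).
#' @param t_settle Piezo step-response settling time (s).
#' @param travel_um Piezo travel range (um).
#' @param d_tol_um Axial tolerance for a POI scan to count (um).
#' @param following_error_um Bound on |plant - command| while tracking a
#'   smooth trajectory within `a_max` (um).
#' @param dwell_margin_um Portion of `d_tol_um` reserved for dynamic
#'   following error when clustering POIs into dwell windows (um).
#' @param t_pad Per-window transient allowance before the first start pulse
#'   (s).
#' @param feedback_rate Capacitive-sensor feedback sampling rate (Hz).
#' @param feedback_noise_um Feedback sensor noise SD (um).
#' @param psf_lateral_major_um,psf_lateral_minor_um Lateral excitation PSF
#'   FWHM along the image axes (um).
#' @param psf_axial_um Axial excitation PSF FWHM (um).
#' @param gain Mean detected counts per unit fluorescence per sample.
#' @param read_noise_sd Gaussian read noise SD (counts).
#'
#' @return A `hardware_config` object (a validated named list with sections
#'   `aod`, `daq`, `piezo`, `optics`, `detector`).
#' @examples
#' cfg <- hardware_config()
#' compute_timing(cfg)
#' @export
hardware_config <- function(t_acc = 13e-6,
                            beam_diameter = 9e-3,
                            acoustic_velocity = 650,
                            wavelength = 910e-9,
                            f_min = 60e6,
                            f_max = 100e6,
                            scan_angle_deg = 5.4,
                            fov_um = 112,
                            s_px = 512,
                            f_clk = 2.5e6,
                            samples_per_pixel = 5,
                            pixels_per_poi = 11,
                            t_buffer = 3e-6,
                            v_max = 0.043,
                            a_max = 60000,
                            t_settle = 2.1e-3,
                            travel_um = 250,
                            d_tol_um = 0.5,
                            following_error_um = 0.5,
                            dwell_margin_um = 0.05,
                            t_pad = 50e-6,
                            feedback_rate = 2.5e5,
                            feedback_noise_um = 0,
                            psf_lateral_major_um = 1.24,
                            psf_lateral_minor_um = 0.34,
                            psf_axial_um = 2.5,
                            gain = 1,
                            read_noise_sd = 0) {
  cfg <- list(
    aod = list(
      t_acc = t_acc, beam_diameter = beam_diameter,
      acoustic_velocity = acoustic_velocity, wavelength = wavelength,
      f_min = f_min, f_max = f_max, scan_angle_deg = scan_angle_deg,
      fov_um = fov_um, s_px = s_px
    ),
    daq = list(
      f_clk = f_clk, samples_per_pixel = samples_per_pixel,
      pixels_per_poi = pixels_per_poi, t_buffer = t_buffer
    ),
    piezo = list(
      v_max = v_max, a_max = a_max, t_settle = t_settle,
      travel_um = travel_um, d_tol_um = d_tol_um,
      following_error_um = following_error_um,
      dwell_margin_um = dwell_margin_um, t_pad = t_pad,
      feedback_rate = feedback_rate, feedback_noise_um = feedback_noise_um
    ),
    optics = list(
      psf_lateral_major_um = psf_lateral_major_um,
      psf_lateral_minor_um = psf_lateral_minor_um,
      psf_axial_um = psf_axial_um
    ),
    detector = list(gain = gain, read_noise_sd = read_noise_sd)
  )
  validate_hardware_config(structure(cfg, class = "hardware_config"))
}

validate_hardware_config <- function(cfg) {
  num <- unlist(cfg[c("aod", "daq", "piezo", "optics", "detector")])
  must_pos <- setdiff(
    names(num),
    c("daq.t_buffer", "piezo.feedback_noise_um", "detector.read_noise_sd",
      "piezo.dwell_margin_um", "piezo.t_pad")
  )
  if (any(!is.finite(num))) {
    abort("hardware_config: all parameters must be finite numbers")
  }
  if (any(num[must_pos] <= 0)) {
    bad <- names(which(num[must_pos] <= 0))
    abort(paste0("hardware_config: parameters must be positive: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(num[setdiff(names(num), must_pos)] < 0)) {
    abort("hardware_config: buffer, pad and noise terms must be >= 0")
  }
  if (cfg$aod$f_min >= cfg$aod$f_max) {
    abort("hardware_config: f_min must be < f_max")
  }
  if (cfg$daq$pixels_per_poi %% 2 != 1) {
    abort("hardware_config: pixels_per_poi must be odd (a centre pixel must exist)")
  }
  if (cfg$piezo$dwell_margin_um >= cfg$piezo$d_tol_um) {
    abort("hardware_config: dwell_margin_um must be < d_tol_um")
  }
  cfg
}

#' @export
print.hardware_config <- function(x, ...) {
  cat("<hardware_config>\n")
  cat(sprintf("  AOD:   T_ACC %.1f us, bandwidth %.0f MHz, FOV %g um / %d px\n",
              x$aod$t_acc * 1e6, (x$aod$f_max - x$aod$f_min) / 1e6,
              x$aod$fov_um, x$aod$s_px))
  cat(sprintf("  DAQ:   %.2f MHz clock, %d px x %d samples per POI, buffer %.1f us\n",
              x$daq$f_clk / 1e6, x$daq$pixels_per_poi,
              x$daq$samples_per_pixel, x$daq$t_buffer * 1e6))
  cat(sprintf("  Piezo: V_max %g m/s, A_max %g m/s^2, T_S %.2f ms, d_TOL %g um\n",
              x$piezo$v_max, x$piezo$a_max, x$piezo$t_settle * 1e3,
              x$piezo$d_tol_um))
  invisible(x)
}

#' Write or read a hardware configuration as a key/value text file
#'
#' The file format is one `section.key = value` pair per line with `#`
#' comments; values are plain numbers in the units documented in
#' [hardware_config()].
#'
#' @param cfg A `hardware_config`.
#' @param path File path.
#' @return `write_hardware_config()` returns `path` invisibly;
#'   `read_hardware_config()` returns a `hardware_config`.
#' @export
write_hardware_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "hardware_config"))
  flat <- unlist(cfg)
  lines <- c(
    "# poiscan hardware configuration",
    "# times s, frequencies Hz, optical lengths m, *_um fields um",
    sprintf("%s = %.15g", names(flat), flat)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hardware_config
#' @export
read_hardware_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  flat <- setNames(as.list(vals), keys)
  args <- setNames(flat, sub("^[a-z]+\\.", "", keys))
  do.call(hardware_config, args)
}
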