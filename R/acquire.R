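#' Execute a scan schedule against the digital twin
#'
#' Replays the schedule cycle after cycle: at every start pulse the AODs
#' sweep the 11-pixel diagonal line through the POI while the objective sits
#' wherever the simulated piezo actually is. The expected signal of each
#' pixel is the POI's ground-truth fluorescence attenuated by the axial
#' Gaussian excitation profile of the focus offset (`actual Z - POI Z`) and
#' by the lateral profile along the diagonal sweep; each pixel is sampled
#' `samples_per_pixel` times, with optional Poisson shot noise and Gaussian
#' read noise. Everything is deterministic for a fixed seed.
#'
#' @param sched A [schedule_scan()] result.
#' @param phys A [build_physiology()] map for the same POI set.
#' @param cfg A [hardware_config()].
#' @param piezo A [simulate_piezo()] trace of the schedule's trajectory;
#'   `NULL` (planar schedules or ideal-stage runs) holds Z exactly at each
#'   event's expected position.
#' @param n_cycles Number of scan cycles; defaults to covering the
#'   physiology's stimulus protocol.
#' @param duration Alternative to `n_cycles`: cover at least this time (s).
#' @param noise `"poisson"` (shot + read noise) or `"none"` (exact expected
#'   values).
#' @param seed Noise seed.
#' @return An `acquisition_records` tibble: `poi_id`, `cycle`, `t` (s),
#'   `z_true`, `z_expected` (um), `f_true`, and a 55-column `samples`
#'   matrix column (counts); attributes `schedule`, `physiology`, `cfg`.
#' @export
acquire <- function(sched, phys, cfg, piezo = NULL, n_cycles = NULL,
                    duration = NULL, noise = c("poisson", "none"), seed = 1) {
  stopifnot(inherits(sched, "scan_schedule"), inherits(phys, "physiology_map"))
  noise <- match.arg(noise)
  period <- attr(sched, "period")
  if (is.null(n_cycles)) {
    if (is.null(duration)) {
      duration <- attr(phys$protocol, "total_duration")
      if (is.null(duration)) duration <- period
    }
    n_cycles <- max(1L, ceiling(duration / period))
  }
  if (!is.null(piezo) && abs(attr(piezo, "period") - period) > 1e-9) {
    abort("acquire: piezo trace and schedule do not share a time base")
  }
  n_ev <- nrow(sched)
  n_px <- cfg$daq$pixels_per_poi
  n_sp <- cfg$daq$samples_per_pixel

  cyc <- rep(seq_len(n_cycles), each = n_ev)
  poi_id <- rep(sched$poi_id, n_cycles)
  z_exp <- rep(sched$z_um, n_cycles)
  t_abs <- rep(sched$t_start, n_cycles) + (cyc - 1) * period
  row_of <- match(poi_id, phys$pois$poi_id)
  if (anyNA(row_of)) abort("acquire: schedule references POIs absent from the physiology map")

  z_true <- if (is.null(piezo)) z_exp else piezo_position_at(piezo, t_abs, "z_true")
  f_true <- physiology_fluorescence(phys, row_of, t_abs)

  # axial Gaussian attenuation (FWHM definition)
  dz <- z_true - z_exp
  w_ax <- exp(-4 * log(2) * dz^2 / cfg$optics$psf_axial_um^2)
  # lateral attenuation along the 45-degree diagonal sweep
  px_um <- cfg$aod$fov_um / cfg$aod$s_px
  off <- (seq_len(n_px) - 1) - (n_px - 1) / 2
  w_lat <- exp(-4 * log(2) * (off * px_um)^2 *
                 (1 / cfg$optics$psf_lateral_major_um^2 +
                    1 / cfg$optics$psf_lateral_minor_um^2))
  expected_px <- (cfg$detector$gain * f_true * w_ax) %o% w_lat
  expected <- expected_px[, rep(seq_len(n_px), each = n_sp), drop = FALSE]

  samples <- if (noise == "none") {
    expected
  } else {
    withr_seed(seed, function() {
      s <- matrix(rpois(length(expected), lambda = as.vector(expected)),
                  nrow = nrow(expected))
      if (cfg$detector$read_noise_sd > 0) {
        s <- s + matrix(rnorm(length(s), 0, cfg$detector$read_noise_sd),
                        nrow = nrow(s))
      }
      s
    })
  }
  out <- tibble(
    poi_id = poi_id, cycle = cyc, t = t_abs,
    z_true = z_true, z_expected = z_exp, f_true = f_true
  )
  out$samples <- samples
  new_tibble(out, class = "acquisition_records",
             schedule = sched, physiology = phys, cfg = cfg,
             n_cycles = n_cycles, seed = seed, noise = noise)
}

#' @export
print.acquisition_records <- function(x, ...) {
  cat(sprintf("<acquisition_records> %d records (%d cycles x %d POIs), noise: %s\n",
              nrow(x), attr(x, "n_cycles"),
              nrow(x) / max(attr(x, "n_cycles"), 1), attr(x, "noise")))
  NextMethod()
}
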