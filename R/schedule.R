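#' Schedule a synchronized random-access POI scan
#'
#' Turns a POI set into an executable scan: for every POI an AOD start pulse
#' (quantized to the DAQ sample clock, flooring), the frequency pair driving
#' each deflector, and the Z position the focal plane is expected to hold
#' while the 11-pixel line scan runs. In `"volume"` mode events are placed
#' inside the dwell windows of the monotone Z-trajectory (POIs within a
#' window ordered by branch id, then arc offset); in `"planar"` mode the
#' stage is parked at a fixed plane and the cycle period is exactly
#' `N_POI * T_G`.
#'
#' @param pois A `poi_set`.
#' @param cfg A [hardware_config()].
#' @param mode `"volume"` or `"planar"`.
#' @param traj A [plan_z_trajectory()] result for `"volume"` mode (planned
#'   automatically when `NULL`). When supplied it must cover every POI's Z
#'   within the axial tolerance.
#' @param timing Optional [compute_timing()] model.
#' @param z_plane Plane for `"planar"` mode (um); defaults to the median POI
#'   Z. Every POI must lie within `d_TOL` of it.
#' @param rate_target Optional cycle rate (Hz) to pad the cycle down to.
#' @param fov_origin_um Length-2 specimen-space coordinate (um) mapped to
#'   pixel 0 on X and Y; defaults to centring the POI bounding box in the
#'   field of view.
#' @return A `scan_schedule`: a tibble of events (`poi_id`, `window`,
#'   `t_start`, `z_um`, `f0_x`, `f1_x`, `f0_y`, `f1_y`) with attributes
#'   `mode`, `period` (s), `rate` (Hz), `trajectory`, `timing`, `cfg`.
#' @examples
#' tree <- generate_synthetic_neuron(seed = 1)
#' sched <- schedule_scan(interpolate_pois(tree), hardware_config())
#' glance(sched)
#' @export
schedule_scan <- function(pois, cfg, mode = c("volume", "planar"),
                          traj = NULL, timing = NULL, z_plane = NULL,
                          rate_target = NULL, fov_origin_um = NULL) {
  stopifnot(inherits(cfg, "hardware_config"))
  mode <- match.arg(mode)
  if (nrow(pois) == 0) abort("schedule_scan: empty POI set")
  if (is.null(timing)) timing <- compute_timing(cfg)
  t_g <- timing$t_g
  f_clk <- cfg$daq$f_clk
  quantize <- function(t) floor(t * f_clk) / f_clk

  if (is.null(fov_origin_um)) {
    fov_origin_um <- c(
      mean(range(pois$x)) - cfg$aod$fov_um / 2,
      mean(range(pois$y)) - cfg$aod$fov_um / 2
    )
  }
  px_um <- cfg$aod$fov_um / cfg$aod$s_px
  u_x <- (pois$x - fov_origin_um[1]) / px_um
  u_y <- (pois$y - fov_origin_um[2]) / px_um
  sweeps <- aod_sweep(u_x, u_y, cfg)

  if (mode == "planar") {
    if (is.null(z_plane)) z_plane <- median(pois$z)
    off <- abs(pois$z - z_plane)
    if (any(off > cfg$piezo$d_tol_um + 1e-9)) {
      bad <- pois$poi_id[off > cfg$piezo$d_tol_um + 1e-9]
      abort(sprintf(
        "schedule_scan: %d POI(s) outside d_TOL of the scan plane (ids %s%s)",
        length(bad), paste(head(bad, 5), collapse = ", "),
        if (length(bad) > 5) ", ..." else ""
      ))
    }
    ord <- order(pois$branch_id, pois$arc_offset)
    period <- nrow(pois) * t_g
    if (!is.null(rate_target)) period <- max(period, 1 / rate_target)
    events <- tibble(
      poi_id = pois$poi_id[ord],
      window = 1L,
      t_start = quantize((seq_along(ord) - 1) * t_g),
      z_um = pois$z[ord]
    )
    events <- dplyr::bind_cols(events, sweeps[ord, ])
    return(new_scan_schedule(events, mode = "planar", period = period,
                             traj = NULL, timing = timing, cfg = cfg,
                             fov_origin_um = fov_origin_um,
                             z_plane = z_plane))
  }

  if (is.null(traj)) {
    traj <- plan_z_trajectory(pois, cfg, timing = timing,
                              rate_target = rate_target)
    windows <- attr(traj, "windows")
    assignment <- windows$poi_rows
  } else {
    windows <- attr(traj, "windows")
    d_eff <- attr(traj, "d_eff_um")
    # greedy capacity-aware assignment in sorted Z order, matching the
    # planner's own clustering
    ord <- order(pois$z)
    wid <- integer(nrow(pois))
    w <- 1L
    used <- 0L
    for (i in ord) {
      while (w <= nrow(windows) &&
             (used >= windows$n_poi[w] ||
                pois$z[i] > windows$z_center[w] + d_eff + 1e-9)) {
        w <- w + 1L
        used <- 0L
      }
      if (w > nrow(windows) ||
          abs(pois$z[i] - windows$z_center[w]) > d_eff + 1e-9) {
        abort(sprintf(
          "schedule_scan: POI %d (z = %.2f um) unreachable within tolerance on the trajectory",
          pois$poi_id[i], pois$z[i]))
      }
      wid[i] <- w
      used <- used + 1L
    }
    assignment <- split(seq_len(nrow(pois)), wid)
  }

  win_of <- if (is.null(names(assignment))) {
    seq_along(assignment)
  } else {
    as.integer(names(assignment))
  }
  ev <- list()
  for (k in seq_along(assignment)) {
    rows <- assignment[[k]]
    rows <- rows[order(pois$branch_id[rows], pois$arc_offset[rows])]
    w <- win_of[k]
    ev[[k]] <- tibble(
      row = rows,
      window = w,
      t_start = quantize(windows$t_event0[w] + (seq_along(rows) - 1) * t_g)
    )
  }
  ev <- bind_rows(ev)
  events <- tibble(
    poi_id = pois$poi_id[ev$row],
    window = as.integer(ev$window),
    t_start = ev$t_start,
    z_um = pois$z[ev$row]
  )
  events <- dplyr::bind_cols(events, sweeps[ev$row, ])
  events <- events[order(events$t_start), ]
  new_scan_schedule(events, mode = "volume", period = attr(traj, "period"),
                    traj = traj, timing = timing, cfg = cfg,
                    fov_origin_um = fov_origin_um, z_plane = NULL)
}

new_scan_schedule <- function(events, mode, period, traj, timing, cfg,
                              fov_origin_um, z_plane) {
  new_tibble(events, class = "scan_schedule",
             mode = mode, period = period, rate = 1 / period,
             trajectory = traj, timing = timing, cfg = cfg,
             fov_origin_um = fov_origin_um, z_plane = z_plane)
}

#' @export
print.scan_schedule <- function(x, ...) {
  cat(sprintf("<scan_schedule> mode %s: %d POIs/cycle, period %.3f ms (%.2f Hz)\n",
              attr(x, "mode"), nrow(x), attr(x, "period") * 1e3, attr(x, "rate")))
  NextMethod()
}

#' @method glance scan_schedule
#' @export
glance.scan_schedule <- function(x, ...) {
  traj <- attr(x, "trajectory")
  tibble(
    mode = attr(x, "mode"),
    n_poi = nrow(x),
    n_windows = if (is.null(traj)) 1L else nrow(attr(traj, "windows")),
    period_s = attr(x, "period"),
    rate_hz = attr(x, "rate"),
    t_poi_s = attr(x, "timing")$t_poi
  )
}

#' @method tidy scan_schedule
#' @export
tidy.scan_schedule <- function(x, ...) as_tibble(x)

#' Plan a segmented scan
#'
#' Partitions a POI set into `k` compartments ([segment_pois()]) and plans
#' one volume rapid scan per compartment. In segmented operation the
#' compartments are scanned serially, one acquisition epoch each, trading
#' per-cycle coverage for a higher per-compartment cycle rate.
#'
#' @inheritParams schedule_scan
#' @param k Number of compartments.
#' @return A `segmented_scan` list with `schedules` (one `scan_schedule` per
#'   compartment), `rates` (Hz) and `min_rate` (Hz).
#' @export
plan_segmented_scan <- function(pois, k, cfg, timing = NULL,
                                rate_target = NULL, fov_origin_um = NULL) {
  if (!"compartment" %in% names(pois)) pois <- segment_pois(pois, k)
  scheds <- lapply(seq_len(k), function(g) {
    sub <- pois[pois$compartment == g, , drop = FALSE]
    sub <- new_tibble(sub, class = "poi_set",
                      d_l_um = attr(pois, "d_l_um"),
                      l_t_um = attr(pois, "l_t_um"),
                      bounds = attr(pois, "bounds"))
    schedule_scan(sub, cfg, mode = "volume", timing = timing,
                  rate_target = rate_target, fov_origin_um = fov_origin_um)
  })
  rates <- vapply(scheds, function(s) attr(s, "rate"), numeric(1))
  structure(
    list(schedules = scheds, rates = rates, min_rate = min(rates), k = k),
    class = "segmented_scan"
  )
}

#' @export
print.segmented_scan <- function(x, ...) {
  cat(sprintf("<segmented_scan> %d compartments, per-compartment rates %s Hz (min %.2f)\n",
              x$k, paste(sprintf("%.2f", x$rates), collapse = "/"), x$min_rate))
  invisible(x)
}

#' @method glance segmented_scan
#' @export
glance.segmented_scan <- function(x, ...) {
  out <- lapply(x$schedules, glance)
  out <- bind_rows(out)
  out$compartment <- seq_len(x$k)
  out[, c("compartment", setdiff(names(out), "compartment"))]
}

#' Plan a full 3D raster stack (F3DS)
#'
#' The conventional raster mode used to capture morphology and correct
#' drift: `N_IMG = floor((Z_max - Z_min) / Z_INT) + 1` X-Y raster planes at
#' `Z_INT` um separation, each of `S_px x S_px` pixels at the POI pixel
#' dwell (`samples_per_pixel / f_clk`). When `Z_INT` exceeds the axial
#' extent a single plane is produced.
#'
#' @param bounds A [volume_bounds()].
#' @param z_int Plane separation (um), > 0.
#' @param cfg A [hardware_config()].
#' @return An `f3ds_plan` list: `planes` (tibble of plane index and Z),
#'   `n_img`, `frame_time_s`, `period_s`, `s_px`.
#' @export
plan_f3ds <- function(bounds, z_int, cfg) {
  stopifnot(inherits(cfg, "hardware_config"))
  if (z_int <= 0) abort("plan_f3ds: Z_INT must be positive")
  extent <- bounds$z_max - bounds$z_min
  n_img <- floor(extent / z_int + 1e-9) + 1
  planes <- tibble(
    plane = seq_len(n_img),
    z_um = bounds$z_min + (seq_len(n_img) - 1) * z_int
  )
  frame <- cfg$aod$s_px^2 * cfg$daq$samples_per_pixel / cfg$daq$f_clk
  v_um <- cfg$piezo$v_max * 1e6
  a_um <- cfg$piezo$a_max * 1e6
  step_t <- trapezoid_move(z_int, v_um, a_um)$t + cfg$piezo$t_settle
  fly_t <- if (n_img > 1) {
    trapezoid_move(extent, v_um, a_um)$t + cfg$piezo$t_settle
  } else 0
  structure(
    list(
      planes = planes, n_img = n_img, z_int_um = z_int,
      frame_time_s = frame,
      period_s = n_img * frame + (n_img - 1) * step_t + fly_t,
      s_px = cfg$aod$s_px, mode = "F3DS"
    ),
    class = "f3ds_plan"
  )
}

#' @export
print.f3ds_plan <- function(x, ...) {
  cat(sprintf("<f3ds_plan> %d planes at %.2f um, frame %.1f ms, stack %.2f s\n",
              x$n_img, x$z_int_um, x$frame_time_s * 1e3, x$period_s))
  invisible(x)
}

#' Shift a POI set to compensate measured drift (focus-and-shift step)
#'
#' @param pois A `poi_set`.
#' @param shift_um Length-3 X/Y/Z displacement to apply (um).
#' @return The shifted `poi_set`.
#' @export
apply_drift_shift <- function(pois, shift_um) {
  stopifnot(inherits(pois, "poi_set"), length(shift_um) == 3)
  out <- pois
  out$x <- out$x + shift_um[1]
  out$y <- out$y + shift_um[2]
  out$z <- out$z + shift_um[3]
  new_tibble(out, class = "poi_set",
             d_l_um = attr(pois, "d_l_um"), l_t_um = attr(pois, "l_t_um"),
             bounds = attr(pois, "bounds"))
}

#' Export a scan schedule as JSON metadata plus a CSV event table
#'
#' Writes `<stem>.json` (cycle metadata) and `<stem>_events.csv`
#' (`poi_id, t_start_s, f0_x_hz, f1_x_hz, f0_y_hz, f1_y_hz, z_um`), and for
#' volume scans `<stem>_trajectory.csv` (sampled command positions).
#'
#' @param sched A `scan_schedule`.
#' @param stem Output path stem (no extension).
#' @param traj_rate Sampling rate for the exported trajectory (Hz).
#' @return Invisibly, the vector of files written.
#' @export
write_schedule <- function(sched, stem, traj_rate = 1e5) {
  stopifnot(inherits(sched, "scan_schedule"))
  meta <- as.list(glance(sched))
  json_path <- paste0(stem, ".json")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  ev <- data.frame(
    poi_id = sched$poi_id, t_start_s = sched$t_start,
    f0_x_hz = sched$f0_x, f1_x_hz = sched$f1_x,
    f0_y_hz = sched$f0_y, f1_y_hz = sched$f1_y, z_um = sched$z_um
  )
  ev_path <- paste0(stem, "_events.csv")
  write.csv(ev, ev_path, row.names = FALSE, quote = FALSE)
  files <- c(json_path, ev_path)
  traj <- attr(sched, "trajectory")
  if (!is.null(traj)) {
    tr_path <- paste0(stem, "_trajectory.csv")
    write.csv(as.data.frame(sample_trajectory(traj, traj_rate)), tr_path,
              row.names = FALSE, quote = FALSE)
    files <- c(files, tr_path)
  }
  invisible(files)
}
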