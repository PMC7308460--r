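#' Reproducible run configuration for a plan / simulate / analyze pipeline
#'
#' Bundles everything that determines a simulated experiment: the hardware,
#' the neuron source (an SWC file or generator parameters), the scan mode
#' and its parameters, the stimulus protocol, indicator kinetics and a
#' single master seed from which every stochastic stage derives its own
#' sub-seed, so stages can be rerun independently yet reproducibly.
#'
#' @param hardware A [hardware_config()].
#' @param neuron Either a path to an SWC file or a list of
#'   [generate_synthetic_neuron()] arguments (must contain `seed` unless
#'   the master seed should be used).
#' @param mode Scan mode: `"volume"`, `"planar"` or `"segmented"`.
#' @param d_l POI spacing (um).
#' @param k Compartments for segmented mode.
#' @param labelled_only In segmented mode, scan only labelled POIs (soma,
#'   branch points, filopodium bases/tips).
#' @param z_plane Plane for planar mode (um; default median POI Z).
#' @param rate_target Optional cycle rate to lock to (Hz).
#' @param protocol A [stimulus_protocol()].
#' @param kinetics A [transient_kinetics()].
#' @param responsiveness Passed to [build_physiology()].
#' @param noise Acquisition noise model: `"poisson"` or `"none"`.
#' @param seed Master seed.
#' @param out_dir Output directory (`NULL`: no files written).
#' @return A `run_config` list with a stable `config_hash`.
#' @export
run_config <- function(hardware = hardware_config(),
                       neuron = list(seed = 7, target_length_um = 400,
                                     n_major = 10, n_filopodia = 40),
                       mode = c("volume", "planar", "segmented"),
                       d_l = 2, k = 3, labelled_only = TRUE,
                       z_plane = NULL, rate_target = NULL,
                       protocol = stimulus_protocol(t_p = 4),
                       kinetics = transient_kinetics(),
                       responsiveness = list(),
                       noise = c("poisson", "none"),
                       seed = 1, out_dir = NULL) {
  noise <- match.arg(noise)
  mode <- match.arg(mode)
  cfg <- list(
    hardware = hardware, neuron = neuron, mode = mode, d_l = d_l, k = k,
    labelled_only = labelled_only, z_plane = z_plane,
    rate_target = rate_target, protocol = protocol, kinetics = kinetics,
    responsiveness = responsiveness, noise = noise, seed = seed,
    out_dir = out_dir
  )
  cfg$config_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

# per-stage sub-seeds derived from the master seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  offsets <- c(neuron = 101L, piezo = 211L, physiology = 307L,
               acquisition = 401L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

load_or_generate_neuron <- function(config) {
  if (is.character(config$neuron)) {
    read_swc(config$neuron)
  } else {
    args <- config$neuron
    if (is.null(args$seed)) args$seed <- derive_seed(config$seed, "neuron")
    do.call(generate_synthetic_neuron, args)
  }
}

#' Plan stage: neuron to executable schedule plus feasibility report
#'
#' Loads or generates the neuron, interpolates POIs, plans the scan for the
#' configured mode and computes the sampling budget. With an output
#' directory set, writes the schedule (JSON + CSV event table), the sampled
#' Z-trajectory, the POI table and a feasibility report, each stamped with
#' the config hash and seed.
#'
#' @param config A [run_config()].
#' @return A `scan_plan` list: `tree`, `pois`, `schedule` (or
#'   `segmented_scan`), `budget`, `config`.
#' @export
plan_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tree <- classify_nodes(load_or_generate_neuron(config))
  pois <- interpolate_pois(tree, d_l = config$d_l)
  if (nrow(pois) == 0) abort("plan_run: neuron yields no POIs")
  hw <- config$hardware
  timing <- compute_timing(hw)
  if (config$mode == "segmented") {
    scan_pois <- if (config$labelled_only) poi_subset_labelled(pois) else pois
    sched <- plan_segmented_scan(scan_pois, config$k, hw,
                                 rate_target = config$rate_target)
    rate <- sched$min_rate
    n_scan <- nrow(scan_pois)
  } else if (config$mode == "planar") {
    scan_pois <- pois
    sched <- schedule_scan(pois, hw, mode = "planar",
                           z_plane = config$z_plane,
                           rate_target = config$rate_target)
    rate <- attr(sched, "rate")
    n_scan <- nrow(pois)
  } else {
    scan_pois <- pois
    sched <- schedule_scan(pois, hw, mode = "volume",
                           rate_target = config$rate_target)
    rate <- attr(sched, "rate")
    n_scan <- nrow(pois)
  }
  budget <- sampling_budget(pois, timing, signal_bandwidth = 3)
  plan <- structure(
    list(tree = tree, pois = pois, scan_pois = scan_pois, schedule = sched,
         budget = budget, rate = rate, config = config),
    class = "scan_plan"
  )
  if (!is.null(config$out_dir)) write_plan_files(plan)
  plan
}

write_plan_files <- function(plan) {
  dir.create(plan$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- function(x) file.path(plan$config$out_dir, x)
  write_pois(plan$pois, stem("pois.csv"))
  scheds <- if (inherits(plan$schedule, "segmented_scan")) {
    plan$schedule$schedules
  } else {
    list(plan$schedule)
  }
  for (i in seq_along(scheds)) {
    write_schedule(scheds[[i]], stem(sprintf("schedule_%02d", i)))
  }
  report <- c(
    list(config_hash = plan$config$config_hash, seed = plan$config$seed,
         mode = plan$config$mode, cycle_rate_hz = plan$rate),
    as.list(glance(plan$budget))
  )
  jsonlite::write_json(report, stem("feasibility.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(plan)
}

#' Simulate stage: execute the plan on the digital twin
#'
#' Simulates the piezo following each planned trajectory, builds the
#' ground-truth physiology and acquires raw records for the full stimulus
#' protocol. All randomness derives from the master seed.
#'
#' @param config A [run_config()].
#' @param plan A [plan_run()] result (planned in-line when `NULL`).
#' @return A `scan_sim` list: `records` (one `acquisition_records` per
#'   schedule), `physiology`, `piezo` traces, `plan`.
#' @export
simulate_run <- function(config, plan = NULL) {
  if (is.null(plan)) plan <- plan_run(config)
  hw <- config$hardware
  phys <- build_physiology(
    plan$scan_pois, config$protocol, kinetics = config$kinetics,
    responsiveness = config$responsiveness,
    seed = derive_seed(config$seed, "physiology")
  )
  scheds <- if (inherits(plan$schedule, "segmented_scan")) {
    plan$schedule$schedules
  } else {
    list(plan$schedule)
  }
  piezo <- vector("list", length(scheds))
  records <- vector("list", length(scheds))
  for (i in seq_along(scheds)) {
    traj <- attr(scheds[[i]], "trajectory")
    piezo[[i]] <- if (is.null(traj)) NULL else {
      simulate_piezo(traj, hw, seed = derive_seed(config$seed, "piezo") + i)
    }
    records[[i]] <- acquire(
      scheds[[i]], phys, hw, piezo = piezo[[i]], noise = config$noise,
      seed = derive_seed(config$seed, "acquisition") + i
    )
  }
  sim <- structure(
    list(records = records, physiology = phys, piezo = piezo, plan = plan,
         config = config),
    class = "scan_sim"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    gt <- phys$events
    gt$config_hash <- config$config_hash
    gt$seed <- config$seed
    write.csv(as.data.frame(gt),
              file.path(config$out_dir, "ground_truth.csv"),
              row.names = FALSE, quote = FALSE)
  }
  sim
}

#' Analyze stage: traces, kinetics, events, evoked map
#'
#' Reduces the raw records to dF/F0 traces, extracts somatic transient
#' kinetics around each stimulus, estimates the FFT bandwidth of the
#' somatic trace, runs matched-filter event detection on every POI and
#' computes the evoked-response map. Writes CSV tables and a JSON summary
#' when an output directory is configured.
#'
#' @param config A [run_config()].
#' @param sim A [simulate_run()] result (simulated in-line when `NULL`).
#' @return A `scan_analysis` list: `traces`, `kinetics`, `bandwidth`,
#'   `events`, `evoked_map`, `summary`.
#' @export
analyze_run <- function(config, sim = NULL) {
  if (is.null(sim)) sim <- simulate_run(config)
  traces <- lapply(sim$records, function(r) compute_dff(records_to_traces(r)))
  all_traces <- bind_rows(lapply(traces, as_tibble))
  proto <- config$protocol

  soma_id <- sim$plan$scan_pois$poi_id[sim$plan$scan_pois$label == "soma"][1]
  soma_tr <- traces[[1]][traces[[1]]$poi_id == soma_id, c("t", "dff")]
  kin_rows <- list()
  for (s in seq_len(nrow(proto))) {
    seg <- soma_tr[soma_tr$t >= proto$onset[s] - 0.5 &
                     soma_tr$t <= proto$onset[s] + attr(proto, "t_p"), ]
    if (nrow(seg) > 4) {
      est <- extract_kinetics(seg, stim_time = proto$onset[s],
                              noise_floor = 0.2)
      est$stim_idx <- proto$stim_idx[s]
      kin_rows[[length(kin_rows) + 1]] <- as_tibble(est)
    }
  }
  kinetics <- if (length(kin_rows)) bind_rows(kin_rows) else tibble()
  bw <- if (nrow(soma_tr) >= 4) {
    fft_bandwidth(soma_tr, rate = attr(traces[[1]], "rate"))
  } else {
    list(f_max = NA_real_, required_rate = NA_real_)
  }
  events <- bind_rows(lapply(traces, function(tr) {
    detect_events(tr, config$kinetics, protocol = proto)
  }))
  maps <- lapply(traces, evoked_response_map, protocol = proto)
  evoked_map <- bind_rows(maps)

  summary <- list(
    config_hash = config$config_hash,
    seed = config$seed,
    mode = config$mode,
    n_poi = nrow(sim$plan$scan_pois),
    cycle_rate_hz = sim$plan$rate,
    budget = as.list(glance(sim$plan$budget)),
    median_kinetics = if (nrow(kinetics)) {
      lapply(kinetics[, c("tau_delay", "tau_r", "tau_f")],
             median, na.rm = TRUE)
    } else NULL,
    bandwidth_hz = bw$f_max,
    required_rate_hz = bw$required_rate,
    n_events = nrow(events),
    n_ground_truth_events = nrow(sim$physiology$events),
    top_evoked_pois = evoked_map$poi_id[order(-evoked_map$evoked_dff)][
      seq_len(min(5, nrow(evoked_map)))]
  )
  out <- structure(
    list(traces = traces, kinetics = kinetics, bandwidth = bw,
         events = events, evoked_map = evoked_map, summary = summary,
         config = config, sim = sim),
    class = "scan_analysis"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- function(x) file.path(config$out_dir, x)
    write.csv(as.data.frame(all_traces), stem("traces.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(as.data.frame(events), stem("events.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(as.data.frame(evoked_map), stem("evoked_map.csv"),
              row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, stem("summary.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}

#' Run the bundled demonstration pipeline
#'
#' Plans, simulates and analyzes a small synthetic tectal-like neuron end
#' to end: a full-arbor volume rapid scan locked to a shortened stimulus
#' protocol, with evoked somatic transients and synaptic input at seeded
#' filopodium tips.
#'
#' @param seed Master seed.
#' @param out_dir Optional output directory for all artefacts.
#' @return The [analyze_run()] result, invisibly; its `summary` element is
#'   printed.
#' @export
run_demo <- function(seed = 1, out_dir = NULL) {
  config <- run_config(
    neuron = list(seed = 7, target_length_um = 300, n_major = 8,
                  n_filopodia = 30),
    mode = "volume",
    rate_target = 8,
    protocol = stimulus_protocol(t_p = 4, t_b = 1),
    responsiveness = list(p_off = 0.5, p_on = 0.1, p_transition = 1,
                          n_sites = 3),
    seed = seed, out_dir = out_dir
  )
  res <- analyze_run(config)
  utils::str(res$summary, give.attr = FALSE)
  invisible(res)
}
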