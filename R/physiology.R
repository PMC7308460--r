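#' Canonical fluorescence transient kinetics
#'
#' Parameterises the stereotyped evoked indicator transient by the three
#' quantities read off experimental traces: the delay from stimulus onset to
#' peak (`tau_delay`), the rise-time parameter `tau_r` (time post-stimulus
#' at which the trace first reaches `1 - 1/e` of peak) and the decay-time
#' parameter `tau_f` (time post-peak at which it falls to `1/e` of peak).
#' The waveform is a saturating-exponential rise normalised to peak at
#' `tau_delay`, followed by a single-exponential decay with time constant
#' `tau_f`. The rise constant is solved numerically so the `(1 - 1/e)`
#' crossing lands exactly at `tau_r`; a solution exists only when
#' `tau_r / tau_delay < 1 - 1/e`.
#'
#' Defaults are the fitted GCaMP6m somatic values (0.404, 0.237, 2.907 s);
#' `iglusnfr_kinetics()` returns the fast glutamate-sensor dynamics
#' (tau_r 5 ms, tau_f 150 ms).
#'
#' @param tau_delay Stimulus-to-peak delay (s).
#' @param tau_r Rise-time parameter (s), < `tau_delay`.
#' @param tau_f Decay-time parameter (s).
#' @param amplitude Peak amplitude (dF/F0 units).
#' @return A `transient_kinetics` list with the parameters and the solved
#'   `rise_const` (s).
#' @examples
#' kin <- transient_kinetics()
#' transient_waveform(kin, kin$tau_delay) # 1 (the peak)
#' @export
transient_kinetics <- function(tau_delay = 0.404, tau_r = 0.237,
                               tau_f = 2.907, amplitude = 1) {
  if (tau_f <= 0) abort("transient_kinetics: tau_f must be positive")
  if (tau_r <= 0 || tau_r >= tau_delay) {
    abort("transient_kinetics: need 0 < tau_r < tau_delay")
  }
  if (tau_r / tau_delay >= 1 - exp(-1)) {
    abort("transient_kinetics: no valid rise constant; tau_r / tau_delay must be < 1 - 1/e")
  }
  gap <- function(tc) {
    (1 - exp(-tau_r / tc)) - (1 - exp(-1)) * (1 - exp(-tau_delay / tc))
  }
  rise_const <- uniroot(gap, c(1e-7, 1e3), tol = 1e-9)$root
  structure(
    list(tau_delay = tau_delay, tau_r = tau_r, tau_f = tau_f,
         amplitude = amplitude, rise_const = rise_const),
    class = "transient_kinetics"
  )
}

#' @rdname transient_kinetics
#' @export
iglusnfr_kinetics <- function(tau_r = 0.005, tau_f = 0.150,
                              tau_delay = 2.5 * tau_r, amplitude = 1) {
  transient_kinetics(tau_delay = tau_delay, tau_r = tau_r, tau_f = tau_f,
                     amplitude = amplitude)
}

#' @export
print.transient_kinetics <- function(x, ...) {
  cat(sprintf(
    "<transient_kinetics> tau_delay %.3f s, tau_r %.3f s, tau_f %.3f s (rise const %.4f s), peak %.2f\n",
    x$tau_delay, x$tau_r, x$tau_f, x$rise_const, x$amplitude))
  invisible(x)
}

#' Evaluate the canonical transient waveform
#'
#' Unit-peak waveform: 0 before the event, saturating-exponential rise to 1
#' at `tau_delay`, then `exp(-(t - tau_delay) / tau_f)`.
#'
#' @param kinetics A [transient_kinetics()].
#' @param t Time since stimulus onset (s), vectorised.
#' @return Waveform values in [0, 1].
#' @export
transient_waveform <- function(kinetics, t) {
  tc <- kinetics$rise_const
  peak_rise <- 1 - exp(-kinetics$tau_delay / tc)
  out <- numeric(length(t))
  up <- t >= 0 & t <= kinetics$tau_delay
  dn <- t > kinetics$tau_delay
  out[up] <- (1 - exp(-t[up] / tc)) / peak_rise
  out[dn] <- exp(-(t[dn] - kinetics$tau_delay) / kinetics$tau_f)
  out
}

#' Simulate a noiseless evoked transient trace
#'
#' @param kinetics A [transient_kinetics()].
#' @param rate Sampling rate (Hz).
#' @param duration Trace duration (s).
#' @param onset Stimulus onset time (s).
#' @return A tibble with `t` (s) and `dff` (dF/F0), plus attributes `rate`
#'   and `onset`.
#' @export
simulate_transient <- function(kinetics, rate = 1000, duration = 10,
                               onset = 0.5) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  new_tibble(
    tibble(t = t,
           dff = kinetics$amplitude * transient_waveform(kinetics, t - onset)),
    rate = rate, onset = onset
  )
}

#' Visual stimulation protocol
#'
#' The validation stimulus sequence: `n_off` OFF pulses on a bright
#' background, one background transition shift, and `n_on` ON pulses, each
#' presented in a `t_p`-second interval with a buffer `t_b` before the
#' stimulus, repeated `n_rs` times. Within its slot each stimulus onset can
#' be jittered pseudorandomly.
#'
#' @param n_off,n_on Numbers of OFF and ON pulses.
#' @param transition Include the transition-shift stimulus.
#' @param t_p Presentation interval per stimulus (s).
#' @param t_b Buffer before each stimulus (s).
#' @param stim_duration Pulse duration (s).
#' @param n_rs Number of repetitions of the whole sequence.
#' @param jitter Maximal pseudorandom onset jitter within the slot (s).
#' @param seed Seed for the jitter.
#' @return A `stimulus_protocol` tibble: `stim_idx`, `type`
#'   (`off`/`transition`/`on`), `onset` (s), `duration` (s); attributes
#'   `t_p`, `t_b`, `total_duration`.
#' @export
stimulus_protocol <- function(n_off = 4, n_on = 4, transition = TRUE,
                              t_p = 8, t_b = 1, stim_duration = 0.05,
                              n_rs = 1, jitter = 0, seed = 1) {
  types <- c(rep("off", n_off), if (transition) "transition", rep("on", n_on))
  n_seq <- length(types)
  types <- rep(types, n_rs)
  slot <- seq_along(types) - 1
  jit <- if (jitter > 0) {
    withr_seed(seed, function() runif(length(types), 0, jitter))
  } else {
    rep(0, length(types))
  }
  onset <- slot * t_p + t_b + jit
  new_tibble(
    tibble(stim_idx = seq_along(types), type = types, onset = onset,
           duration = ifelse(types == "transition", 2, stim_duration)),
    class = "stimulus_protocol",
    t_p = t_p, t_b = t_b, n_rs = n_rs,
    total_duration = n_seq * n_rs * t_p
  )
}

#' Build the ground-truth physiology of a simulated experiment
#'
#' Assigns fluorescence dynamics to every POI: a baseline `F0`, global
#' somatic (action-potential-like) transients that appear simultaneously at
#' the soma and throughout the arbor, and spatially restricted synaptic
#' transients confined to POIs within `local_radius_um` of a seeded subset
#' of filopodium tips. Each stimulus evokes a global event with a
#' type-dependent probability and, independently per synaptic site, a local
#' event. All ground-truth event times and sites are recorded for scoring
#' detections.
#'
#' @param pois A `poi_set` (labels are used to find filopodium tips).
#' @param protocol A [stimulus_protocol()].
#' @param kinetics A [transient_kinetics()] for global events.
#' @param kinetics_local Kinetics for local synaptic events (defaults to
#'   `kinetics`).
#' @param responsiveness List of response probabilities and amplitudes:
#'   `p_off`, `p_on`, `p_transition` (global, per stimulus type),
#'   `amp_global`, `n_sites` (filopodium tips carrying synaptic input),
#'   `p_local`, `amp_local`, `local_radius_um`, `f0` (baseline counts
#'   scale).
#' @param seed Seed; the same seed reproduces the same physiology.
#' @return A `physiology_map` list: `events` (ground-truth event table),
#'   `sites` (seeded synaptic site POI ids), `f0`, `affected` (per-event
#'   POI-row index list), `pois`.
#' @export
build_physiology <- function(pois, protocol, kinetics = transient_kinetics(),
                             kinetics_local = NULL,
                             responsiveness = list(), seed = 1) {
  stopifnot(inherits(pois, "poi_set"))
  resp <- utils::modifyList(
    list(p_off = 0.5, p_on = 0.1, p_transition = 1, amp_global = 1.5,
         n_sites = 4, p_local = 0.6, amp_local = 1.0, local_radius_um = 2,
         f0 = 100),
    responsiveness
  )
  probs <- unlist(resp[c("p_off", "p_on", "p_transition", "p_local")])
  if (any(probs < 0 | probs > 1)) {
    abort("build_physiology: response probabilities must be in [0, 1]")
  }
  if (is.null(kinetics_local)) kinetics_local <- kinetics
  tips <- which(pois$label == "filopodium_tip")
  drawn <- withr_seed(seed, function() {
    sites <- if (length(tips) && resp$n_sites > 0) {
      tips[sample.int(length(tips), min(resp$n_sites, length(tips)))]
    } else {
      integer()
    }
    p_glob <- c(off = resp$p_off, on = resp$p_on,
                transition = resp$p_transition)[protocol$type]
    glob <- runif(nrow(protocol)) < p_glob
    loc <- if (length(sites)) {
      matrix(runif(length(sites) * nrow(protocol)) < resp$p_local,
             nrow = length(sites))
    } else {
      matrix(logical(), nrow = 0, ncol = nrow(protocol))
    }
    list(sites = sites, glob = glob, loc = loc)
  })
  ev <- list()
  for (s in which(drawn$glob)) {
    ev[[length(ev) + 1]] <- tibble(
      scope = "global", site_poi = NA_integer_, stim_idx = s,
      t_onset = protocol$onset[s], amplitude = resp$amp_global
    )
  }
  if (length(drawn$sites)) {
    for (i in seq_along(drawn$sites)) {
      for (s in which(drawn$loc[i, ])) {
        ev[[length(ev) + 1]] <- tibble(
          scope = "local", site_poi = pois$poi_id[drawn$sites[i]],
          stim_idx = s, t_onset = protocol$onset[s],
          amplitude = resp$amp_local
        )
      }
    }
  }
  events <- if (length(ev)) bind_rows(ev) else {
    tibble(scope = character(), site_poi = integer(), stim_idx = integer(),
           t_onset = numeric(), amplitude = numeric())
  }
  events$event_id <- seq_len(nrow(events))
  affected <- lapply(seq_len(nrow(events)), function(i) {
    if (events$scope[i] == "global") {
      seq_len(nrow(pois))
    } else {
      site <- which(pois$poi_id == events$site_poi[i])
      d <- sqrt((pois$x - pois$x[site])^2 + (pois$y - pois$y[site])^2 +
                  (pois$z - pois$z[site])^2)
      which(d <= resp$local_radius_um)
    }
  })
  structure(
    list(events = events, sites = pois$poi_id[drawn$sites], f0 = resp$f0,
         affected = affected, pois = pois, protocol = protocol,
         kinetics = kinetics, kinetics_local = kinetics_local,
         responsiveness = resp, seed = seed),
    class = "physiology_map"
  )
}

#' @export
print.physiology_map <- function(x, ...) {
  cat(sprintf(
    "<physiology_map> %d POIs, %d global + %d local events, %d synaptic sites\n",
    nrow(x$pois), sum(x$events$scope == "global"),
    sum(x$events$scope == "local"), length(x$sites)))
  invisible(x)
}

#' @method tidy physiology_map
#' @export
tidy.physiology_map <- function(x, ...) x$events

#' Ground-truth fluorescence of selected POIs at given times
#'
#' @param phys A [build_physiology()] map.
#' @param poi_rows Row indices into `phys$pois`.
#' @param t Times (s), one per row index (vectorised pairwise).
#' @return Fluorescence values (arbitrary units, baseline `f0`).
#' @export
physiology_fluorescence <- function(phys, poi_rows, t) {
  stopifnot(length(poi_rows) == length(t))
  f <- rep(1, length(t))
  ev <- phys$events
  for (i in seq_len(nrow(ev))) {
    kin <- if (ev$scope[i] == "global") phys$kinetics else phys$kinetics_local
    hit <- poi_rows %in% phys$affected[[i]]
    if (any(hit)) {
      f[hit] <- f[hit] +
        ev$amplitude[i] * transient_waveform(kin, t[hit] - ev$t_onset[i])
    }
  }
  phys$f0 * f
}
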