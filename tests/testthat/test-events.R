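kin_ca <- transient_kinetics()

test_that("a flat trace yields no detections", {
  ev <- matched_filter_detect(numeric(500), kin_ca, rate = 20, window = 16)
  expect_equal(nrow(ev), 0)
  ev2 <- matched_filter_detect(rep(2.5, 500), kin_ca, rate = 20, window = 16)
  expect_equal(nrow(ev2), 0)
})

test_that("a single noiseless embedded template is found once, at its onset", {
  rate <- 20
  w <- 16
  y <- numeric(600)
  at <- 301
  y[at + 0:(4 * rate)] <- transient_waveform(kin_ca, (0:(4 * rate)) / rate)
  ev <- matched_filter_detect(y, kin_ca, rate = rate, window = w)
  expect_equal(nrow(ev), 1)
  # the projection statistic may peak within a couple of samples of the onset
  expect_lte(abs(ev$onset_idx - at), 2)
  expect_equal(ev$peak_dff, max(y), tolerance = 1e-9)
})

test_that("the score of the exact normalized template is 1", {
  rate <- 20
  w <- 16
  tmpl <- transient_waveform(kin_ca, (0:(w - 1)) / rate)
  tmpl <- (tmpl - mean(tmpl)) / sqrt(sum((tmpl - mean(tmpl))^2))
  ev <- matched_filter_detect(c(numeric(50), tmpl, numeric(50)), kin_ca,
                              rate = rate, window = w)
  expect_equal(max(attr(ev, "scores")), 1, tolerance = 1e-9)
})

test_that("seeded events at peak SNR 5 are recovered with recall and precision >= 0.9", {
  rate <- 20
  w <- 24
  n <- 6000
  truth <- round(seq(100, n - 200, length.out = 20))
  y <- withr::with_seed(42, rnorm(n, 0, max(transient_waveform(kin_ca,
                                                               (0:(w - 1)) / rate)) / 5))
  for (i in truth) {
    y[i + 0:(3 * rate)] <- y[i + 0:(3 * rate)] +
      transient_waveform(kin_ca, (0:(3 * rate)) / rate)
  }
  ev <- matched_filter_detect(y, kin_ca, rate = rate, window = w)
  tp <- sum(vapply(ev$onset_idx,
                   function(i) any(abs(truth - i) <= w), logical(1)))
  recall <- sum(vapply(truth,
                       function(i) any(abs(ev$onset_idx - i) <= w),
                       logical(1))) / length(truth)
  expect_gte(recall, 0.9)
  expect_gte(tp / nrow(ev), 0.9)
})

test_that("short traces and degenerate windows are rejected", {
  expect_error(matched_filter_detect(numeric(5), kin_ca, rate = 20,
                                     window = 16), "shorter")
  expect_error(matched_filter_detect(numeric(50), kin_ca, rate = 20,
                                     window = 1), ">= 2")
})

test_that("evoked-response maps isolate responding POIs", {
  proto <- stimulus_protocol(t_p = 4)
  t <- seq(0, attr(proto, "total_duration"), by = 0.25)
  mk_traces <- function(f) {
    tibble::new_tibble(
      dplyr::bind_rows(lapply(1:3, function(p) {
        tibble::tibble(poi_id = p, cycle = seq_along(t), t = t,
                       intensity = 100, f0 = 100, dff = f(p))
      })),
      class = "trace_set", rate = 4, protocol = proto)
  }
  # all-zero traces -> all-zero map
  m0 <- evoked_response_map(mk_traces(function(p) 0), proto)
  expect_equal(m0$evoked_dff, rep(0, 3))

  # POI 2 steps up by 1 for 2 s after each onset (clear of the next buffer)
  step_f <- function(p) {
    if (p != 2) return(rep(0, length(t)))
    y <- numeric(length(t))
    for (on in proto$onset) y[t >= on & t <= on + 2] <- 1
    y
  }
  m1 <- evoked_response_map(mk_traces(step_f), proto, window = 2)
  expect_equal(m1$evoked_dff[m1$poi_id == 2], 1, tolerance = 1e-9)
  expect_equal(m1$evoked_dff[m1$poi_id != 2], c(0, 0))

  expect_error(evoked_response_map(mk_traces(function(p) 0), proto,
                                   window = 10), "presentation interval")
})

test_that("end-to-end: seeded synaptic sites top the evoked map and somatic events are detected", {
  cfg <- hardware_config()
  pois <- interpolate_pois(small_neuron(9, n_filopodia = 25))
  proto <- stimulus_protocol(t_p = 8, n_on = 0, transition = FALSE, n_off = 6)
  phys <- build_physiology(
    pois, proto, kinetics = kin_ca, seed = 6,
    responsiveness = list(p_off = 1, p_on = 0, p_transition = 0,
                          n_sites = 3, p_local = 1, amp_local = 2,
                          amp_global = 0.6)
  )
  sched <- schedule_scan(pois, cfg, rate_target = 10)
  rec <- acquire(sched, phys, cfg, seed = 3)
  traces <- compute_dff(records_to_traces(rec))
  emap <- evoked_response_map(traces, proto)
  top <- emap$poi_id[order(-emap$evoked_dff)]
  # the synaptic site POIs (plus their <= 2 um neighbours) dominate the map;
  # every seeded site must rank within the plausible neighbourhood count
  n_neigh <- sum(vapply(phys$sites, function(s) {
    i <- match(s, pois$poi_id)
    sum((pois$x - pois$x[i])^2 + (pois$y - pois$y[i])^2 +
          (pois$z - pois$z[i])^2 <= 4)
  }, numeric(1)))
  expect_true(all(phys$sites %in% top[seq_len(n_neigh)]))

  # somatic events: detected at the soma POI in >= 90% of stimuli
  soma_id <- pois$poi_id[pois$label == "soma"]
  soma_tr <- traces[traces$poi_id == soma_id, c("t", "dff")]
  ev <- matched_filter_detect(soma_tr, kin_ca,
                              rate = attr(traces, "rate"), window = 24)
  hits <- vapply(proto$onset, function(on) {
    any(ev$t_onset >= on - 0.3 & ev$t_onset <= on + 2 * kin_ca$tau_delay)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
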