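cfg <- hardware_config()

flat_setup <- function(seed = 4, n_filopodia = 15) {
  pois <- interpolate_pois(small_neuron(seed, n_filopodia = n_filopodia))
  proto <- stimulus_protocol(t_p = 4)
  phys <- build_physiology(pois, proto, seed = 1,
                           responsiveness = list(p_off = 0, p_on = 0,
                                                 p_transition = 0,
                                                 n_sites = 0))
  sched <- schedule_scan(pois, cfg)
  list(pois = pois, phys = phys, sched = sched)
}

test_that("noiseless flat physiology yields one identical record per POI per cycle", {
  s <- flat_setup()
  rec <- acquire(s$sched, s$phys, cfg, n_cycles = 3, noise = "none")
  expect_equal(nrow(rec), 3 * nrow(s$pois))
  sums <- rowSums(rec$samples)
  expect_equal(ncol(rec$samples), 55)
  expect_equal(max(sums) - min(sums), 0, tolerance = 1e-9)
})

test_that("an axial offset of FWHM/2 halves the central-pixel expectation", {
  pois <- interpolate_pois(chain_tree(len = 20, n = 3)) # co-planar at z = 0
  proto <- stimulus_protocol(t_p = 4)
  phys <- build_physiology(pois, proto, seed = 1,
                           responsiveness = list(p_off = 0, p_on = 0,
                                                 p_transition = 0,
                                                 n_sites = 0))
  sched <- schedule_scan(pois, cfg)
  centre <- cfg$daq$pixels_per_poi %/% 2 * cfg$daq$samples_per_pixel + 1
  rec0 <- acquire(sched, phys, cfg, n_cycles = 1, noise = "none")
  # a synthetic stage trace parked half an axial FWHM off focus
  dz <- cfg$optics$psf_axial_um / 2
  period <- attr(sched, "period")
  off_stage <- tibble::new_tibble(
    tibble::tibble(t = c(0, period), z_cmd = dz, z_true = dz, z_fb = dz),
    class = "piezo_trace", period = period, rate = 2 / period, omega = NA
  )
  rec_off <- acquire(sched, phys, cfg, piezo = off_stage, n_cycles = 1,
                     noise = "none")
  expect_equal(rec_off$samples[1, centre] / rec0$samples[1, centre], 0.5,
               tolerance = 1e-9)
})

test_that("acquisition is bit-identical for a fixed seed", {
  s <- flat_setup()
  a <- acquire(s$sched, s$phys, cfg, n_cycles = 2, seed = 7)
  b <- acquire(s$sched, s$phys, cfg, n_cycles = 2, seed = 7)
  c <- acquire(s$sched, s$phys, cfg, n_cycles = 2, seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("mean summed intensity is linear in fluorescence (shot-noise statistics)", {
  pois <- interpolate_pois(chain_tree(len = 20, n = 3))
  proto <- stimulus_protocol(t_p = 4)
  mk <- function(f0) {
    build_physiology(pois, proto, seed = 1,
                     responsiveness = list(p_off = 0, p_on = 0,
                                           p_transition = 0, n_sites = 0,
                                           f0 = f0))
  }
  sched <- schedule_scan(pois, cfg)
  m1 <- mean(rowSums(acquire(sched, mk(50), cfg, n_cycles = 100,
                             seed = 1)$samples))
  m2 <- mean(rowSums(acquire(sched, mk(100), cfg, n_cycles = 100,
                             seed = 2)$samples))
  expect_equal(m2 / m1, 2, tolerance = 0.02)
})

test_that("global somatic events hit the soma and all dendritic POIs in the same cycle", {
  pois <- interpolate_pois(small_neuron(5))
  proto <- stimulus_protocol(t_p = 4, n_on = 0, transition = FALSE)
  phys <- build_physiology(pois, proto, seed = 2,
                           responsiveness = list(p_off = 1, n_sites = 0,
                                                 amp_global = 2))
  sched <- schedule_scan(pois, cfg, rate_target = 8)
  rec <- acquire(sched, phys, cfg, noise = "none")
  traces <- compute_dff(records_to_traces(rec))
  # in the cycle just after each onset every POI is elevated
  onset <- proto$onset[1]
  cyc <- unique(traces$cycle[traces$t > onset + 0.3 & traces$t < onset + 0.6])
  hit <- traces[traces$cycle == cyc[1], ]
  expect_true(all(hit$dff > 0.5))
})

test_that("simulated scans land within the axial tolerance at every event", {
  pois <- interpolate_pois(small_neuron(6))
  traj <- plan_z_trajectory(pois, cfg)
  sched <- schedule_scan(pois, cfg, traj = traj)
  proto <- stimulus_protocol(t_p = 4)
  phys <- build_physiology(pois, proto, seed = 3)
  # sigma = 0: all records within d_TOL
  pz0 <- simulate_piezo(traj, cfg, seed = 1, noise_sd_um = 0)
  rec0 <- acquire(sched, phys, cfg, piezo = pz0, n_cycles = 2)
  expect_true(all(abs(rec0$z_true - rec0$z_expected) <=
                    cfg$piezo$d_tol_um + 1e-9))
  # sensor noise sigma = 0.1 um does not perturb the plant itself
  pz1 <- simulate_piezo(traj, cfg, seed = 1, noise_sd_um = 0.1)
  rec1 <- acquire(sched, phys, cfg, piezo = pz1, n_cycles = 2)
  frac <- mean(abs(rec1$z_true - rec1$z_expected) <= cfg$piezo$d_tol_um + 1e-9)
  expect_gte(frac, 0.99)
})
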