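cfg <- hardware_config()
tm <- compute_timing(cfg)

test_that("a single POI yields one event and a pure-dwell cycle", {
  pois <- interpolate_pois(chain_tree(len = 1, n = 2), d_l = 2)
  one <- pois[1, ]
  one <- tibble::new_tibble(one, class = "poi_set", d_l_um = 2, l_t_um = 1)
  sched <- schedule_scan(one, cfg)
  expect_equal(nrow(sched), 1)
  expect_equal(attr(sched, "period"), cfg$piezo$t_pad + tm$t_g)
})

test_that("every cycle period is bounded below by N_POI x T_POI", {
  for (seed in 1:4) {
    pois <- interpolate_pois(small_neuron(seed))
    sched <- schedule_scan(pois, cfg)
    expect_gte(attr(sched, "period"), nrow(pois) * tm$t_poi)
    expect_equal(nrow(sched), nrow(pois))
    expect_false(any(duplicated(sched$poi_id)))
  }
})

test_that("replaying schedules confirms tolerance and AOD exclusivity", {
  for (seed in 1:12) {
    n_f <- 5 + (seed %% 4) * 8
    pois <- interpolate_pois(small_neuron(seed, n_filopodia = n_f))
    sched <- schedule_scan(pois, cfg)
    rep <- replay_schedule(sched, cfg)
    expect_true(rep$within_tol)
    expect_false(rep$overlap)
  }
})

test_that("start pulses are quantized to the DAQ sample clock", {
  pois <- interpolate_pois(small_neuron(2))
  sched <- schedule_scan(pois, cfg)
  ticks <- sched$t_start * cfg$daq$f_clk
  expect_lt(max(abs(ticks - round(ticks))), 1e-6)
})

test_that("POIs within a dwell window are ordered by branch then arc offset", {
  pois <- interpolate_pois(small_neuron(1))
  sched <- schedule_scan(pois, cfg)
  key <- match(sched$poi_id, pois$poi_id)
  by_win <- split(seq_len(nrow(sched)), sched$window)
  for (rows in by_win) {
    o <- order(sched$t_start[rows])
    b <- pois$branch_id[key[rows]][o]
    a <- pois$arc_offset[key[rows]][o]
    expect_true(all(diff(b) >= 0))
    same <- which(diff(b) == 0)
    expect_true(all(diff(a)[same] > 0))
  }
})

test_that("planar schedules have exact period N_POI x T_G and reject off-plane POIs", {
  z <- rep(30, 130)
  pois <- tibble::new_tibble(
    tibble::tibble(poi_id = 1:130, x = seq(20, 90, length.out = 130),
                   y = 56, z = z, branch_id = 1L, arc_offset = 1:130,
                   label = "interstitial"),
    class = "poi_set", d_l_um = 2, l_t_um = 260
  )
  sched <- schedule_scan(pois, cfg, mode = "planar")
  expect_equal(attr(sched, "period"), 130 * tm$t_g, tolerance = 1e-15)
  expect_gte(attr(sched, "rate"), 200)

  pois$z[5] <- 35
  expect_error(schedule_scan(pois, cfg, mode = "planar"), "ids 5")
})

test_that("a trajectory planned for one POI set rejects unreachable POIs of another", {
  pois <- interpolate_pois(small_neuron(6))
  traj <- plan_z_trajectory(pois, cfg)
  other <- pois
  other$z <- other$z + 30
  other <- tibble::new_tibble(other, class = "poi_set", d_l_um = 2,
                              l_t_um = attr(pois, "l_t_um"))
  expect_error(schedule_scan(other, cfg, traj = traj), "unreachable")
})

test_that("cycle rate does not increase with POI count or Z extent", {
  base <- interpolate_pois(small_neuron(5))
  r_base <- attr(schedule_scan(base, cfg), "rate")
  bigger <- interpolate_pois(small_neuron(5, target_length_um = 500,
                                          n_filopodia = 40))
  r_big <- attr(schedule_scan(bigger, cfg), "rate")
  expect_lte(r_big, r_base)

  stretched <- base
  stretched$z <- (stretched$z - min(stretched$z)) * 2 + min(stretched$z)
  stretched <- tibble::new_tibble(stretched, class = "poi_set", d_l_um = 2,
                                  l_t_um = attr(base, "l_t_um"))
  r_str <- attr(schedule_scan(stretched, cfg), "rate")
  expect_lte(r_str, r_base)
})

test_that("segmented plans scan each compartment faster than the whole", {
  pois <- poi_subset_labelled(interpolate_pois(small_neuron(8, n_filopodia = 30)))
  seg <- plan_segmented_scan(pois, 3, cfg)
  whole <- attr(schedule_scan(pois, cfg), "rate")
  expect_length(seg$rates, 3)
  expect_true(all(seg$rates > whole))
  got <- unlist(lapply(seg$schedules, function(s) s$poi_id))
  expect_setequal(got, pois$poi_id)
})

test_that("raster stack geometry follows the floor rule", {
  b <- volume_bounds(100, 100, 0, 125)
  expect_equal(plan_f3ds(b, 1, cfg)$n_img, 126)
  expect_equal(plan_f3ds(b, 125, cfg)$n_img, 2)
  expect_equal(plan_f3ds(b, 200, cfg)$n_img, 1)
  planes <- plan_f3ds(b, 5, cfg)$planes
  expect_true(all(diff(planes$z_um) > 0))
  expect_equal(plan_f3ds(b, 1, cfg)$frame_time_s,
               512^2 * 5 / 2.5e6)
  expect_error(plan_f3ds(b, 0, cfg), "positive")
})

test_that("schedule export writes JSON metadata and a CSV event table", {
  pois <- interpolate_pois(small_neuron(1))
  sched <- schedule_scan(pois, cfg)
  stem <- file.path(withr::local_tempdir(), "sched")
  files <- write_schedule(sched, stem)
  expect_true(all(file.exists(files)))
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(meta$n_poi, nrow(pois))
  ev <- utils::read.csv(paste0(stem, "_events.csv"))
  expect_named(ev, c("poi_id", "t_start_s", "f0_x_hz", "f1_x_hz",
                     "f0_y_hz", "f1_y_hz", "z_um"))
})
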