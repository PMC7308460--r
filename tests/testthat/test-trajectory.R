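cfg <- hardware_config()
tm <- compute_timing(cfg)

fake_pois <- function(z) {
  tibble::new_tibble(
    tibble::tibble(poi_id = seq_along(z), x = 56, y = 56, z = z,
                   branch_id = 1L, arc_offset = seq_along(z),
                   label = "interstitial"),
    class = "poi_set", d_l_um = 2, l_t_um = 2 * length(z)
  )
}

test_that("co-planar POIs give a constant trajectory with pure dwell", {
  traj <- plan_z_trajectory(fake_pois(rep(40, 12)), cfg)
  expect_equal(nrow(attr(traj, "windows")), 1)
  expect_equal(unique(traj$type), "dwell")
  expect_equal(attr(traj, "period"), cfg$piezo$t_pad + 12 * tm$t_g)
  expect_equal(trajectory_position(traj, c(0, 1e-4, 2e-4)), rep(40, 3))
})

test_that("a two-cluster scan is dwell + trapezoidal transit + flyback + settle", {
  z <- c(rep(0, 10), rep(50, 10))
  traj <- plan_z_trajectory(fake_pois(z), cfg)
  v <- cfg$piezo$v_max * 1e6
  a <- cfg$piezo$a_max * 1e6
  transit <- 50 / v + v / a # trapezoid with cruise phase
  dwell <- cfg$piezo$t_pad + 10 * tm$t_g
  expect_equal(attr(traj, "period"),
               2 * dwell + 2 * transit + cfg$piezo$t_settle,
               tolerance = 1e-12)
  expect_equal(traj$type, c("dwell", "transit", "dwell", "flyback", "settle"))
})

test_that("trapezoid transit profiles match numerical integration of the velocity", {
  for (d in c(1.5, 5, 50, 120)) {
    traj <- plan_z_trajectory(fake_pois(c(0, d)), cfg)
    seg <- traj[traj$type == "transit", ]
    tt <- seq(seg$t0, seg$t1, length.out = 2001)
    z <- trajectory_position(traj, tt)
    # velocity and acceleration limits
    vel <- diff(z) / diff(tt)
    acc <- diff(vel) / diff(tt)[-1]
    expect_lte(max(abs(vel)), cfg$piezo$v_max * 1e6 * (1 + 1e-6))
    expect_lte(max(abs(acc)), cfg$piezo$a_max * 1e6 * 1.02) # finite differencing
    # displacement equals the integral of the velocity profile
    expect_equal(z[length(z)] - z[1], d, tolerance = 1e-6)
    # endpoints at rest (within one finite-difference step of acceleration)
    expect_lt(abs(vel[1]), cfg$piezo$a_max * 1e6 * diff(tt)[1] * 1.01)
    expect_lt(abs(vel[length(vel)]), cfg$piezo$a_max * 1e6 * diff(tt)[1] * 1.01)
  }
})

test_that("the active sweep is monotone non-decreasing from Z_min to Z_max", {
  for (seed in 1:5) {
    pois <- interpolate_pois(small_neuron(seed))
    traj <- plan_z_trajectory(pois, cfg)
    active <- traj[traj$type %in% c("dwell", "transit"), ]
    tt <- seq(0, max(active$t1), length.out = 1500)
    z <- trajectory_position(traj, tt)
    expect_true(all(diff(z) >= -1e-9))
    expect_equal(min(z), attr(traj, "z_min"), tolerance = 1e-9)
    expect_equal(max(z), attr(traj, "z_max"), tolerance = 1e-9)
    # dwell windows never exceed the tolerance width
    w <- attr(traj, "windows")
    expect_true(all(w$z_hi - w$z_lo <=
                      2 * (cfg$piezo$d_tol_um - cfg$piezo$dwell_margin_um) + 1e-9))
  }
})

test_that("cycle duration is monotone in the POI service time", {
  pois <- interpolate_pois(small_neuron(3))
  p1 <- attr(plan_z_trajectory(pois, cfg, timing = compute_timing(cfg)), "period")
  slow <- compute_timing(cfg, t_g = 2 * tm$t_poi)
  p2 <- attr(plan_z_trajectory(pois, cfg, timing = slow), "period")
  expect_gte(p2, p1)
})

test_that("degenerate and oversized inputs are rejected", {
  expect_error(plan_z_trajectory(fake_pois(numeric()), cfg), "empty")
  expect_error(plan_z_trajectory(fake_pois(c(0, 400)), cfg), "travel")
})

test_that("a rate target stretches the cycle with an idle hold", {
  pois <- fake_pois(c(rep(10, 4), rep(20, 4)))
  traj <- plan_z_trajectory(pois, cfg, rate_target = 10)
  expect_equal(attr(traj, "period"), 0.1, tolerance = 1e-12)
  expect_true("idle" %in% traj$type)
})
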