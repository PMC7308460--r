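# shared fixtures built in code

# soma at the origin, stem along +x, two arms forking at the junction
y_tree <- function(l_stem = 10, l_arm1 = 6, l_arm2 = 4) {
  neuron_tree(tibble::tibble(
    id = 1:4,
    parent_id = c(NA, 1L, 2L, 2L),
    x = c(0, l_stem, l_stem, l_stem),
    y = c(0, 0, l_arm1, -l_arm2),
    z = 0,
    radius = c(5, 0.5, 0.5, 0.5),
    kind = c("soma", rep("dendrite", 3))
  ))
}

chain_tree <- function(len = 30, n = 4) {
  xs <- seq(0, len, length.out = n)
  neuron_tree(tibble::tibble(
    id = seq_len(n),
    parent_id = c(NA, seq_len(n - 1)),
    x = xs, y = 0, z = 0,
    radius = c(5, rep(0.5, n - 1)),
    kind = c("soma", rep("dendrite", n - 1))
  ))
}

write_swc_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".swc",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

small_neuron <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, target_length_um = 250, n_major = 6, n_filopodia = 15),
    list(...)
  )
  do.call(generate_synthetic_neuron, args)
}

# independent replay: walk every scheduled event against the commanded
# trajectory and check tolerance and AOD interval exclusivity
replay_schedule <- function(sched, cfg) {
  traj <- attr(sched, "trajectory")
  tm <- attr(sched, "timing")
  busy <- cfg$aod$t_acc + tm$t_scan
  probes <- c(0, 0.5, 1) * busy
  dz_max <- 0
  for (p in probes) {
    z <- trajectory_position(traj, sched$t_start + p)
    dz_max <- max(dz_max, max(abs(z - sched$z_um)))
  }
  ts <- sort(sched$t_start)
  list(
    max_dz = dz_max,
    overlap = any(diff(ts) < busy - 1e-12),
    within_tol = dz_max <= cfg$piezo$d_tol_um + 1e-9
  )
}
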