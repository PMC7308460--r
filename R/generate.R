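#' Generate a synthetic tectal-like neuron morphology
#'
#' Builds a reproducible stand-in for a developing tadpole tectal neuron: a
#' soma near the bottom of the imaging volume, a set of tortuous major
#' dendritic branches grown by a persistent random walk, and many short
#' terminal filopodia attached at interior points of the major branches.
#' The arbor fits inside the stated volume bounds (walk steps reflect off
#' the volume walls) and its total branch length equals the target exactly:
#' major-branch lengths are scaled so that majors plus filopodia sum to
#' `target_length_um`.
#'
#' Topology is deterministic for a fixed seed, and by construction the
#' structurally labelled locations number
#' `1 soma + (n_major - 1 + n_filopodia) junctions + n_filopodia tips`,
#' i.e. `n_major + 2 * n_filopodia` in total, provided every major terminal
#' branch exceeds the filopodium length threshold.
#'
#' @param seed Integer seed; the same seed always yields the same tree.
#' @param target_length_um Total arbor length (um).
#' @param n_major Number of major dendritic branches (>= 1).
#' @param n_filopodia Number of filopodia.
#' @param filopodium_len_range Filopodium length range (um).
#' @param major_min_len_um Minimum major-branch length (um); kept above the
#'   filopodium threshold so major branches never classify as filopodia.
#' @param persistence Direction persistence of the branch walk in [0, 1).
#' @param z_drift Upward bias of the branch walk (0 = isotropic); gives the
#'   arbor the apical climb of tectal neurons through the neuropil.
#' @param bounds A [volume_bounds()] the tree must fit in.
#' @param inset_um Margin kept from the volume walls (um).
#' @param n_steps Polyline segments per major branch.
#' @return A [neuron_tree()].
#' @examples
#' tree <- generate_synthetic_neuron(seed = 7)
#' total_arbor_length(tree)
#' @export
generate_synthetic_neuron <- function(seed,
                                      target_length_um = 1200,
                                      n_major = 24,
                                      n_filopodia = 150,
                                      filopodium_len_range = c(1, 4),
                                      major_min_len_um = 12,
                                      persistence = 0.65,
                                      z_drift = 0.35,
                                      bounds = volume_bounds(),
                                      inset_um = 1.5,
                                      n_steps = 24) {
  if (n_major < 1) abort("generate_synthetic_neuron: need at least one major branch")
  if (target_length_um <= 0) {
    abort("generate_synthetic_neuron: target length must be positive")
  }
  draws <- withr_seed(seed, function() {
    list(
      rel_major = c(3, 0.5 + rgamma(n_major - 1, shape = 2, rate = 1))[seq_len(n_major)],
      host_major = if (n_major > 1) {
        vapply(2:n_major, function(j) sample.int(j - 1, 1), integer(1))
      } else integer(),
      frac_major = runif(max(n_major - 1, 0), 0.15, 0.9),
      dirs_major = lapply(seq_len(n_major), function(i) {
        matrix(rnorm(n_steps * 3), ncol = 3)
      }),
      host_filo = if (n_filopodia > 0) {
        sample.int(n_major, n_filopodia, replace = TRUE)
      } else integer(),
      frac_filo = runif(n_filopodia, 0.05, 0.95),
      len_filo = runif(n_filopodia, filopodium_len_range[1], filopodium_len_range[2]),
      dirs_filo = matrix(rnorm(max(n_filopodia, 1) * 3), ncol = 3)
    )
  })
  sum_filo <- sum(draws$len_filo)
  base_len <- sum_filo + n_major * major_min_len_um
  if (target_length_um <= base_len * 1.02) {
    abort(sprintf(
      "generate_synthetic_neuron: target length %.0f um infeasible; filopodia plus minimum-length major branches already total %.0f um",
      target_length_um, base_len
    ))
  }
  # every major branch gets the minimum length (keeping majors clear of the
  # filopodium class) plus a share of the remaining length; linear in the
  # target so POI counts are monotone for calibration
  scale <- (target_length_um - base_len) / sum(draws$rel_major)
  len_major <- major_min_len_um + scale * draws$rel_major

  lo <- c(inset_um, inset_um, bounds$z_min + inset_um)
  hi <- c(bounds$s_x - inset_um, bounds$s_y - inset_um, bounds$z_max - inset_um)
  # steer a step of exact length `len` from p along dir, flipping direction
  # components that would leave the volume (steps are far shorter than the
  # volume sides, so a flip always lands inside and segment lengths stay exact)
  steer <- function(p, dir, len) {
    for (tries in 1:4) {
      p_new <- p + len * dir
      bad <- p_new < lo | p_new > hi
      if (!any(bad)) break
      dir[bad] <- -dir[bad]
    }
    list(p = p_new, dir = dir)
  }

  # growing node store
  nid <- 1L
  nodes <- list(list(id = 1L, parent = NA_integer_,
                     p = c(bounds$s_x / 2, bounds$s_y / 2,
                           bounds$z_min + 0.18 * bounds$s_z),
                     radius = 5, kind = "soma"))
  new_node <- function(parent, p, radius = 0.5) {
    nid <<- nid + 1L
    nodes[[nid]] <<- list(id = nid, parent = parent, p = p,
                          radius = radius, kind = "dendrite")
    nid
  }
  # per-major-branch polyline bookkeeping: node ids and cumulative arc
  poly <- vector("list", n_major)

  attach_at <- function(b, s) {
    ids <- poly[[b]]$ids
    cum <- poly[[b]]$cum
    j <- findInterval(s, cum, rightmost.closed = TRUE)
    j <- min(max(j, 1), length(ids) - 1)
    if (abs(s - cum[j]) < 1e-9) return(ids[j])
    if (abs(s - cum[j + 1]) < 1e-9) return(ids[j + 1])
    f <- (s - cum[j]) / (cum[j + 1] - cum[j])
    pa <- nodes[[ids[j]]]$p
    pb <- nodes[[ids[j + 1]]]$p
    m <- new_node(ids[j], pa + f * (pb - pa))
    nodes[[ids[j + 1]]]$parent <<- m
    poly[[b]]$ids <<- append(ids, m, after = j)
    poly[[b]]$cum <<- append(cum, s, after = j)
    m
  }

  grow_branch <- function(start_id, length_um, raw_dirs, dir0) {
    step <- length_um / n_steps
    p <- nodes[[start_id]]$p
    dir <- dir0 / sqrt(sum(dir0^2))
    ids <- start_id
    parent <- start_id
    for (s in seq_len(n_steps)) {
      dir <- persistence * dir + (1 - persistence) * raw_dirs[s, ] +
        c(0, 0, z_drift)
      dir <- dir / sqrt(sum(dir^2))
      stepped <- steer(p, dir, step)
      p <- stepped$p
      dir <- stepped$dir
      parent <- new_node(parent, p)
      ids <- c(ids, parent)
    }
    ids
  }

  for (b in seq_len(n_major)) {
    if (b == 1) {
      start <- 1L
      dir0 <- c(0.15, 0.15, 1) + 0.3 * draws$dirs_major[[1]][1, ]
    } else {
      host <- draws$host_major[b - 1]
      # keep attachments clear of the host's distal end so the terminal
      # remainder of a major branch never falls under the filopodium length
      s <- draws$frac_major[b - 1] * max(len_major[host] - 11, 1)
      start <- attach_at(host, s)
      dir0 <- draws$dirs_major[[b]][1, ]
    }
    ids <- grow_branch(start, len_major[b], draws$dirs_major[[b]], dir0)
    poly[[b]] <- list(ids = ids,
                      cum = seq(0, len_major[b], length.out = n_steps + 1))
  }

  for (f in seq_len(n_filopodia)) {
    host <- draws$host_filo[f]
    base <- attach_at(host, draws$frac_filo[f] * max(len_major[host] - 11, 1))
    raw <- draws$dirs_filo[f, ]
    dir <- raw / sqrt(sum(raw^2))
    p0 <- nodes[[base]]$p
    tip <- steer(p0, dir, draws$len_filo[f])$p
    new_node(base, tip, radius = 0.3)
  }

  tab <- tibble(
    id = map_int(nodes, "id"),
    parent_id = map_int(nodes, "parent"),
    x = map_dbl(nodes, function(n) n$p[1]),
    y = map_dbl(nodes, function(n) n$p[2]),
    z = map_dbl(nodes, function(n) n$p[3]),
    radius = map_dbl(nodes, "radius"),
    kind = vapply(nodes, function(n) n$kind, character(1))
  )
  neuron_tree(tab, bounds = bounds)
}

# run fn with a temporary RNG state seeded by `seed`
withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Calibrate a synthetic neuron to an exact POI count
#'
#' Adjusts `target_length_um` of [generate_synthetic_neuron()] by bisection
#' until interpolation at `d_l` yields exactly `n_poi` points. With the
#' topology fixed by the seed, every branch length scales linearly with the
#' target length, so the POI count is a monotone step function of it and the
#' bisection converges to an exact hit whenever the count steps by single
#' POIs.
#'
#' @param n_poi Desired POI count.
#' @param seed Generator seed.
#' @param d_l POI spacing (um).
#' @param lo,hi Search bracket for the total length (um).
#' @param ... Further arguments for [generate_synthetic_neuron()].
#' @return A list with `tree`, `pois` and the calibrated `target_length_um`.
#' @export
calibrate_neuron_pois <- function(n_poi, seed, d_l = 2,
                                  lo = 0.4 * n_poi * d_l,
                                  hi = 2.5 * n_poi * d_l, ...) {
  count_at <- function(len) {
    tree <- tryCatch(
      generate_synthetic_neuron(seed, target_length_um = len, ...),
      error = function(e) NULL
    )
    if (is.null(tree)) return(list(n = -Inf, tree = NULL, pois = NULL))
    pois <- interpolate_pois(tree, d_l = d_l)
    list(n = nrow(pois), tree = tree, pois = pois)
  }
  f_lo <- count_at(lo)
  f_hi <- count_at(hi)
  if (f_lo$n > n_poi || f_hi$n < n_poi) {
    abort(sprintf("calibrate_neuron_pois: count range [%s, %s] does not bracket %d",
                  f_lo$n, f_hi$n, n_poi))
  }
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    f_mid <- count_at(mid)
    if (f_mid$n < n_poi) {
      lo <- mid
    } else {
      hi <- mid
      f_hi <- f_mid
    }
  }
  if (f_hi$n != n_poi) {
    abort(sprintf("calibrate_neuron_pois: nearest achievable count is %d, not %d",
                  f_hi$n, n_poi))
  }
  list(tree = f_hi$tree, pois = f_hi$pois, target_length_um = hi)
}
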