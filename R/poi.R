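#' Interpolate points of interest along a dendritic arbor
#'
#' Resamples every branch of a traced neuron at (at most) `d_l` micrometre
#' arc-length spacing, the operator-selected POI resolution of a
#' random-access scan. Each branch of length `l` is divided into
#' `ceiling(l / d_l)` equal intervals of `l / ceiling(l / d_l)` um, so branch
#' endpoints (soma attachment, junctions, tips) are always POIs and no
#' spacing exceeds `d_l`. A junction shared between a parent branch and its
#' children is emitted once, owned by the parent branch; the soma root is
#' emitted once as the first POI.
#'
#' @param tree A [neuron_tree()]; classified with [classify_nodes()] first if
#'   you want non-default filopodium thresholds.
#' @param d_l POI spacing (um), > 0.
#' @param filopodium_max_len Passed to [classify_nodes()] when `tree` has no
#'   `label` column.
#' @return A `poi_set`: a tibble with `poi_id`, `x`, `y`, `z` (um),
#'   `branch_id`, `arc_offset` (um along the owning branch) and `label`,
#'   with attributes `d_l_um`, `l_t_um` and the volume bounds of the tree.
#' @examples
#' tree <- generate_synthetic_neuron(seed = 1)
#' pois <- interpolate_pois(tree, d_l = 2)
#' @export
interpolate_pois <- function(tree, d_l = 2, filopodium_max_len = 10) {
  stopifnot(inherits(tree, "neuron_tree"))
  if (!is.numeric(d_l) || length(d_l) != 1 || d_l <= 0) {
    abort("interpolate_pois: d_l must be a positive number")
  }
  if (!"label" %in% names(tree)) tree <- classify_nodes(tree, filopodium_max_len)
  br <- tree_branches(tree)
  root_row <- which(is.na(tree$parent_id))

  rows <- list()
  # soma root first
  rows[[1]] <- tibble(
    x = tree$x[root_row], y = tree$y[root_row], z = tree$z[root_row],
    branch_id = if (nrow(br)) br$branch_id[1] else 0L,
    arc_offset = 0, label = "soma"
  )
  for (i in seq_len(nrow(br))) {
    path <- br$node_rows[[i]]
    px <- tree$x[path]; py <- tree$y[path]; pz <- tree$z[path]
    seg <- sqrt(diff(px)^2 + diff(py)^2 + diff(pz)^2)
    cum <- c(0, cumsum(seg))
    len <- cum[length(cum)]
    if (len <= 0) next
    n_int <- ceiling(len / d_l - 1e-9)
    s <- len * seq_len(n_int) / n_int # start point owned by parent branch
    xi <- approx(cum, px, xout = s, rule = 2)$y
    yi <- approx(cum, py, xout = s, rule = 2)$y
    zi <- approx(cum, pz, xout = s, rule = 2)$y
    lab <- rep("interstitial", n_int)
    lab[n_int] <- tree$label[path[length(path)]]
    rows[[i + 1]] <- tibble(x = xi, y = yi, z = zi,
                            branch_id = br$branch_id[i], arc_offset = s,
                            label = lab)
  }
  out <- bind_rows(rows)
  out <- tibble(poi_id = seq_len(nrow(out)), out)
  new_tibble(out, class = "poi_set",
             d_l_um = d_l, l_t_um = sum(br$length_um),
             bounds = attr(tree, "bounds"))
}

#' @export
print.poi_set <- function(x, ...) {
  cat(sprintf("<poi_set> %d POIs at d_L = %g um over %.1f um of arbor\n",
              nrow(x), attr(x, "d_l_um"), attr(x, "l_t_um")))
  NextMethod()
}

#' Keep only structurally labelled POIs
#'
#' Restricts a POI set to the soma, branch points and filopodium bases/tips —
#' the synapse-enriched locations sampled by the segmented scan mode.
#'
#' @param pois A `poi_set`.
#' @return A `poi_set` containing only labelled (non-interstitial) POIs.
#' @export
poi_subset_labelled <- function(pois) {
  stopifnot(inherits(pois, "poi_set"))
  keep <- pois$label != "interstitial"
  new_tibble(pois[keep, , drop = FALSE], class = "poi_set",
             d_l_um = attr(pois, "d_l_um"), l_t_um = attr(pois, "l_t_um"),
             bounds = attr(pois, "bounds"))
}

#' Partition a POI set into k scan compartments
#'
#' Splits the depth-first-ordered POI list into `k` consecutive compartments
#' for segmented scanning. Whole branches are kept together whenever the
#' branch granularity supports `k` parts: compartments are consecutive runs
#' of branches chosen by exact dynamic programming to minimise the largest
#' compartment and, among such partitions, maximise the smallest. When there
#' are fewer branches than `k` (or a single branch), the partition falls
#' back to POI granularity, giving sizes that differ by at most one.
#'
#' @param pois A `poi_set`.
#' @param k Number of compartments (>= 1, <= number of POIs).
#' @return The `poi_set` with a `compartment` column (integer 1..k).
#' @examples
#' tree <- generate_synthetic_neuron(seed = 1)
#' pois <- interpolate_pois(tree)
#' table(segment_pois(pois, 3)$compartment)
#' @export
segment_pois <- function(pois, k) {
  stopifnot(inherits(pois, "poi_set"))
  n <- nrow(pois)
  if (k < 1 || k != round(k)) abort("segment_pois: k must be a positive integer")
  if (k > n) abort(sprintf("segment_pois: k = %d exceeds the %d available POIs", k, n))
  runs <- rle(pois$branch_id)
  sizes <- if (length(runs$lengths) >= k) runs$lengths else rep(1L, n)
  grp_sizes <- partition_consecutive(sizes, k)
  comp <- rep.int(seq_len(k), vapply(seq_len(k), function(g) {
    sum(sizes[grp_sizes$start[g]:grp_sizes$end[g]])
  }, numeric(1)))
  out <- pois
  out$compartment <- as.integer(comp)
  new_tibble(out, class = "poi_set",
             d_l_um = attr(pois, "d_l_um"), l_t_um = attr(pois, "l_t_um"),
             bounds = attr(pois, "bounds"))
}

# Partition `sizes` into k consecutive groups minimising the maximum group
# sum, tie-broken to maximise the minimum group sum (so sizes are as
# balanced as the unit granularity allows). Returns start/end unit indices
# per group.
partition_consecutive <- function(sizes, k) {
  n <- length(sizes)
  cs <- c(0, cumsum(sizes))
  gsum <- function(a, b) cs[b + 1] - cs[a]
  # pass 1 - dp_max[g, i]: minimal max-sum splitting sizes[1..i] into g groups
  dp_max <- matrix(Inf, k, n)
  dp_max[1, ] <- cs[-1]
  if (k > 1) {
    for (g in 2:k) {
      for (i in g:n) {
        t <- (g - 1):(i - 1)
        dp_max[g, i] <- min(pmax(dp_max[g - 1, t], gsum(t + 1, i)))
      }
    }
  }
  m_star <- dp_max[k, n]
  # pass 2 - dp_min[g, i]: maximal min-sum subject to every group sum <= m_star
  dp_min <- matrix(-Inf, k, n)
  cut <- matrix(NA_integer_, k, n)
  dp_min[1, ] <- ifelse(cs[-1] <= m_star + 1e-9, cs[-1], -Inf)
  if (k > 1) {
    for (g in 2:k) {
      for (i in g:n) {
        t <- (g - 1):(i - 1)
        v <- pmin(dp_min[g - 1, t], gsum(t + 1, i))
        v[gsum(t + 1, i) > m_star + 1e-9] <- -Inf
        best <- max(v)
        dp_min[g, i] <- best
        if (is.finite(best)) {
          # among ties keep the latest cut: later groups stay small
          cut[g, i] <- t[max(which(v >= best - 1e-9))]
        }
      }
    }
  }
  end <- integer(k)
  i <- n
  for (g in rev(seq_len(k))) {
    end[g] <- i
    i <- if (g > 1) cut[g, i] else 0L
  }
  start <- c(1L, head(end, -1) + 1L)
  list(start = start, end = end)
}

#' Export a POI set as CSV
#'
#' Columns `id, x, y, z, branch_id, arc_offset, label` (um), plus
#' `compartment` when present.
#'
#' @param pois A `poi_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pois <- function(pois, path) {
  stopifnot(inherits(pois, "poi_set"))
  df <- as.data.frame(pois)
  names(df)[names(df) == "poi_id"] <- "id"
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
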