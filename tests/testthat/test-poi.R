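test_that("interpolation uses ceil-division equal spacing with endpoints included", {
  # 10 um branch at d_L = 2: exact division, POIs at 0, 2, ..., 10
  tree <- chain_tree(len = 10, n = 3)
  pois <- interpolate_pois(tree, d_l = 2)
  expect_equal(nrow(pois), 6)
  expect_equal(sort(pois$x), seq(0, 10, by = 2))

  # 5 um branch at d_L = 2: ceil(5/2) = 3 intervals of 5/3 um
  tree5 <- chain_tree(len = 5, n = 3)
  pois5 <- interpolate_pois(tree5, d_l = 2)
  expect_equal(nrow(pois5), 4)
  expect_equal(diff(sort(pois5$x)), rep(5 / 3, 3), tolerance = 1e-9)

  expect_error(interpolate_pois(tree, d_l = 0), "positive")
  expect_error(interpolate_pois(tree, d_l = -1), "positive")
})

test_that("junctions are emitted once and counts match a brute-force enumeration", {
  tree <- y_tree(10, 6, 4)
  pois <- interpolate_pois(tree, d_l = 2)
  # brute-force oracle: sample every branch with the ceil rule, then
  # deduplicate identical positions
  br <- tree_branches(tree)
  pts <- list(matrix(c(0, 0, 0), ncol = 3)) # soma
  for (i in seq_len(nrow(br))) {
    path <- br$node_rows[[i]]
    a <- c(tree$x[path[1]], tree$y[path[1]], tree$z[path[1]])
    b <- c(tree$x[path[length(path)]], tree$y[path[length(path)]],
           tree$z[path[length(path)]])
    len <- sqrt(sum((b - a)^2))
    n_int <- ceiling(len / 2)
    fr <- (0:n_int) / n_int
    pts[[i + 1]] <- t(vapply(fr, function(f) a + f * (b - a), numeric(3)))
  }
  all_pts <- unique(round(do.call(rbind, pts), 9))
  expect_equal(nrow(pois), nrow(all_pts))
  # the junction appears exactly once
  junc <- sum(abs(pois$x - 10) < 1e-9 & abs(pois$y) < 1e-9)
  expect_equal(junc, 1)
  expect_equal(sum(pois$label == "branch_point"), 1)
})

test_that("POI spacing never exceeds d_L on random trees, and endpoints are POIs", {
  for (seed in 1:8) {
    d_l <- withr::with_seed(seed, runif(1, 1, 4))
    tree <- small_neuron(seed)
    pois <- interpolate_pois(tree, d_l = d_l)
    sp <- dplyr::group_by(tibble::as_tibble(pois), branch_id)
    gaps <- dplyr::summarise(sp, g = max(c(0, diff(sort(arc_offset)))))
    expect_true(all(gaps$g <= d_l + 1e-9))
    # every branch end is a POI at arc length == branch length
    br <- tree_branches(tree)
    ends <- dplyr::summarise(sp, last = max(arc_offset))
    m <- match(ends$branch_id, br$branch_id)
    expect_equal(ends$last, br$length_um[m], tolerance = 1e-9)
    # count bracket: one POI per d_L of arbor plus at most one per branch
    n <- nrow(pois)
    l_t <- attr(pois, "l_t_um")
    expect_gte(n - 1, floor(l_t / d_l))
    expect_lte(n - 1, ceiling(l_t / d_l) + nrow(br))
  }
})

test_that("segmentation balances sizes and respects branch contiguity", {
  # one 20 um branch -> 11 POIs incl. soma; k = 3 falls back to POI units
  tree <- chain_tree(len = 20, n = 3)
  pois <- interpolate_pois(tree, d_l = 2)
  seg <- segment_pois(pois, 3)
  sizes <- as.integer(table(seg$compartment))
  expect_equal(max(sizes) - min(sizes) <= 1, TRUE)
  expect_equal(sum(sizes), nrow(pois))

  # 10 POIs on one branch, k = 3 -> sizes {4, 3, 3}
  sub <- pois[pois$label != "soma", ][1:10, ]
  sub <- tibble::new_tibble(sub, class = "poi_set", d_l_um = 2, l_t_um = 20)
  seg10 <- segment_pois(sub, 3)
  expect_equal(as.integer(table(seg10$compartment)), c(4, 3, 3))

  # identity partition
  seg1 <- segment_pois(pois, 1)
  expect_equal(unique(seg1$compartment), 1L)

  expect_error(segment_pois(sub, 11), "exceeds")
})

test_that("segmentation partitions exactly (disjoint, exhaustive, contiguous)", {
  tree <- small_neuron(4)
  pois <- interpolate_pois(tree)
  for (k in c(2, 3, 5)) {
    seg <- segment_pois(pois, k)
    expect_equal(sort(unique(seg$compartment)), 1:k)
    expect_equal(nrow(seg), nrow(pois))
    expect_identical(seg$poi_id, pois$poi_id)
    # compartments are consecutive runs in depth-first POI order
    expect_true(all(diff(seg$compartment) >= 0))
    # whole branches stay together when there are >= k branches
    split_br <- tapply(seg$compartment, seg$branch_id,
                       function(x) length(unique(x)))
    expect_true(all(split_br == 1))
  }
})

test_that("a 324-POI labelled set splits into three equal compartments", {
  tree <- generate_synthetic_neuron(seed = 7)
  lab <- poi_subset_labelled(interpolate_pois(tree))
  expect_equal(nrow(lab), 324)
  seg <- segment_pois(lab, 3)
  expect_equal(as.integer(table(seg$compartment)), c(108, 108, 108))
})

test_that("POI CSV export has the documented columns", {
  pois <- interpolate_pois(y_tree())
  path <- withr::local_tempfile(fileext = ".csv")
  write_pois(pois, path)
  got <- utils::read.csv(path)
  expect_named(got, c("id", "x", "y", "z", "branch_id", "arc_offset", "label"))
  expect_equal(nrow(got), nrow(pois))
})
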