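test_that("SWC round trip preserves a morphology, including a soma-only file", {
  one <- write_swc_lines("1 1 50 50 20 5 -1")
  tree <- read_swc(one)
  expect_equal(nrow(tree), 1)
  expect_equal(nrow(tree_branches(tree)), 0)
  expect_equal(total_arbor_length(tree), 0)

  fork <- write_swc_lines(c(
    "# soma, 2-node stem, fork with 2-node and 1-node arms",
    "1 1 0 0 0 5 -1",
    "2 3 5 0 0 0.5 1",
    "3 3 10 0 0 0.5 2",
    "4 3 10 4 0 0.5 3",
    "5 3 10 8 0 0.5 4",
    "6 3 10 -3 0 0.5 3",
    "7 3 10 -6 0 0.5 6"
  ))
  tree <- read_swc(fork)
  expect_equal(nrow(tree), 7)
  br <- tree_branches(tree)
  expect_equal(nrow(br), 3)
  lab <- classify_nodes(tree)
  expect_equal(sum(lab$label == "branch_point"), 1)

  out <- withr::local_tempfile(fileext = ".swc")
  write_swc(tree, out)
  tree2 <- read_swc(out)
  expect_equal(tree2$x, tree$x, tolerance = 1e-4)
  expect_equal(tree2$parent_id, tree$parent_id)
})

test_that("malformed SWC files raise structural errors", {
  missing_parent <- write_swc_lines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 0.5 99"))
  expect_error(read_swc(missing_parent), "missing parent")

  two_roots <- write_swc_lines(c("1 1 0 0 0 5 -1", "2 1 9 0 0 5 -1"))
  expect_error(read_swc(two_roots), "exactly one root")

  # 2 <-> 3 parent cycle, disconnected from the root
  cyclic <- write_swc_lines(c("1 1 0 0 0 5 -1", "2 3 1 0 0 0.5 3",
                              "3 3 2 0 0 0.5 2"))
  expect_error(read_swc(cyclic), "unreachable")

  expect_error(read_swc(file.path(tempdir(), "nope.swc")), "no such file")
})

test_that("total arbor length matches a per-segment Euclidean oracle", {
  for (seed in 1:5) {
    tree <- small_neuron(seed)
    p <- match(tree$parent_id, tree$id)
    keep <- !is.na(p)
    oracle <- sum(sqrt((tree$x[keep] - tree$x[p[keep]])^2 +
                         (tree$y[keep] - tree$y[p[keep]])^2 +
                         (tree$z[keep] - tree$z[p[keep]])^2))
    expect_equal(total_arbor_length(tree), oracle, tolerance = 1e-9)
    br <- tree_branches(tree)
    expect_equal(sum(br$length_um), oracle, tolerance = 1e-6)
  }
})

test_that("node classification follows degree and terminal-length rules", {
  chain <- classify_nodes(chain_tree(len = 30), filopodium_max_len = 10)
  expect_equal(sum(chain$label == "branch_point"), 0)
  expect_equal(sum(grepl("filopodium", chain$label)), 0)
  expect_equal(chain$label[1], "soma")

  # two short terminal arms: both are filopodia; their shared origin is a
  # junction, and branch_point takes precedence over filopodium_base
  y <- classify_nodes(y_tree(10, 4, 4), filopodium_max_len = 10)
  expect_equal(sum(y$label == "branch_point"), 1)
  expect_equal(sum(y$label == "filopodium_tip"), 2)
  expect_equal(sum(y$label == "filopodium_base"), 0)

  # long arms are plain tips
  y2 <- classify_nodes(y_tree(10, 20, 15), filopodium_max_len = 10)
  expect_equal(sum(grepl("filopodium", y2$label)), 0)
})

test_that("classification label counts match an independent recount", {
  tree <- classify_nodes(small_neuron(1))
  p <- match(tree$parent_id, tree$id)
  n_children <- tabulate(p[!is.na(p)], nbins = nrow(tree))
  # independent recount by degree rule
  expect_equal(sum(tree$label == "branch_point"),
               sum(n_children >= 2 & !is.na(p)))
  # every filopodium tip is a terminal node of a short terminal branch
  br <- tree_branches(tree)
  short_term <- br$terminal & br$length_um <= 10
  tips <- vapply(br$node_rows[short_term], function(r) r[length(r)], 0L)
  expect_setequal(which(tree$label == "filopodium_tip"), tips)
})

test_that("label counts are invariant under node re-indexing", {
  tree <- small_neuron(2)
  perm <- withr::with_seed(9, sample(nrow(tree)))
  remap <- integer(nrow(tree))
  remap[perm] <- seq_len(nrow(tree))
  shuffled <- tree[perm, ]
  shuffled$id <- remap[shuffled$id]
  shuffled$parent_id <- ifelse(is.na(shuffled$parent_id), NA_integer_,
                               remap[shuffled$parent_id])
  t1 <- table(classify_nodes(tree)$label)
  t2 <- table(classify_nodes(neuron_tree(shuffled))$label)
  expect_equal(as.list(t1), as.list(t2))
})

test_that("tree validation rejects out-of-bounds coordinates", {
  nodes <- tibble::tibble(
    id = 1:2, parent_id = c(NA, 1L), x = c(50, 130), y = 50, z = 10,
    radius = c(5, 0.5), kind = c("soma", "dendrite")
  )
  expect_error(neuron_tree(nodes, bounds = volume_bounds(100, 100, 0, 125)),
               "outside the imaging volume")
  expect_silent(neuron_tree(nodes))
})
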