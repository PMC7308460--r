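#' Imaging volume bounds
#'
#' Lateral extents `s_x`, `s_y` and axial window `[z_min, z_max]` (all um)
#' that every scanned structure must fit inside. The axial extent must not
#' exceed the piezo travel range.
#'
#' @param s_x,s_y Lateral extents (um).
#' @param z_min,z_max Axial window (um).
#' @param travel_um Optional piezo travel range (um) to validate against.
#' @return A `volume_bounds` list with `s_x`, `s_y`, `s_z`, `z_min`, `z_max`.
#' @export
volume_bounds <- function(s_x = 100, s_y = 100, z_min = 0, z_max = 125,
                          travel_um = NULL) {
  if (z_min >= z_max) abort("volume_bounds: z_min must be < z_max")
  if (s_x <= 0 || s_y <= 0) abort("volume_bounds: lateral extents must be positive")
  if (!is.null(travel_um) && z_max - z_min > travel_um) {
    abort("volume_bounds: axial extent exceeds piezo travel range")
  }
  structure(
    list(s_x = s_x, s_y = s_y, s_z = z_max - z_min, z_min = z_min, z_max = z_max),
    class = "volume_bounds"
  )
}

#' Construct a neuron morphology tree
#'
#' A `neuron_tree` is a node table describing a traced dendritic arbor:
#' exactly one root of kind `soma`, every other node with exactly one parent,
#' connected and acyclic, coordinates in micrometres. It is the unit from
#' which branches are decomposed and POIs interpolated.
#'
#' @param nodes A data frame with columns `id`, `parent_id` (`NA` for the
#'   root), `x`, `y`, `z` (um), `radius` (um) and `kind`
#'   (`"soma"`/`"dendrite"`).
#' @param bounds Optional [volume_bounds()]; when given, all coordinates must
#'   fall inside.
#' @return A `neuron_tree` (a tibble with class and metadata attributes).
#' @export
neuron_tree <- function(nodes, bounds = NULL) {
  nodes <- as_tibble(nodes)
  required <- c("id", "parent_id", "x", "y", "z", "radius", "kind")
  if (!all(required %in% names(nodes))) {
    abort(paste("neuron_tree: nodes must have columns",
                paste(required, collapse = ", ")))
  }
  nodes$id <- as.integer(nodes$id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyDuplicated(nodes$id)) abort("neuron_tree: duplicate node ids")
  root <- which(is.na(nodes$parent_id))
  if (length(root) != 1) {
    abort(sprintf("neuron_tree: expected exactly one root, found %d", length(root)))
  }
  if (nodes$kind[root] != "soma") abort("neuron_tree: the root node must be the soma")
  parent_row <- match(nodes$parent_id, nodes$id)
  missing_parent <- !is.na(nodes$parent_id) & is.na(parent_row)
  if (any(missing_parent)) {
    abort(sprintf("neuron_tree: node %d references missing parent %d",
                  nodes$id[which(missing_parent)[1]],
                  nodes$parent_id[which(missing_parent)[1]]))
  }
  # reachability from the root proves connectedness and rules out cycles
  children <- split(seq_len(nrow(nodes)), parent_row)
  visited <- logical(nrow(nodes))
  queue <- root
  while (length(queue)) {
    visited[queue] <- TRUE
    queue <- unlist(children[as.character(queue)], use.names = FALSE)
  }
  if (!all(visited)) {
    abort(sprintf("neuron_tree: %d node(s) unreachable from the root (cycle or disconnection)",
                  sum(!visited)))
  }
  if (!is.null(bounds)) {
    inside <- nodes$x >= 0 & nodes$x <= bounds$s_x &
      nodes$y >= 0 & nodes$y <= bounds$s_y &
      nodes$z >= bounds$z_min & nodes$z <= bounds$z_max
    if (!all(inside)) {
      abort(sprintf("neuron_tree: %d node(s) outside the imaging volume bounds",
                    sum(!inside)))
    }
  }
  new_tibble(nodes, class = "neuron_tree", bounds = bounds)
}

#' @export
print.neuron_tree <- function(x, ...) {
  br <- tree_branches(x)
  cat(sprintf("<neuron_tree> %d nodes, %d branches, total length %.1f um\n",
              nrow(x), nrow(br), total_arbor_length(x)))
  NextMethod()
}

#' Total arbor length
#'
#' Sum of Euclidean parent-child segment lengths over the whole tree (um).
#'
#' @param tree A [neuron_tree()].
#' @return Length in um.
#' @export
total_arbor_length <- function(tree) {
  p <- match(tree$parent_id, tree$id)
  keep <- !is.na(p)
  sum(sqrt((tree$x[keep] - tree$x[p[keep]])^2 +
             (tree$y[keep] - tree$y[p[keep]])^2 +
             (tree$z[keep] - tree$z[p[keep]])^2))
}

#' Decompose a neuron tree into branches
#'
#' A branch is a maximal unbranched path between topological nodes (the soma
#' root, junctions with two or more children, and terminal tips). Branches
#' are numbered in depth-first order from the soma with children visited in
#' node-id order, which also defines the canonical POI ordering.
#'
#' @param tree A [neuron_tree()].
#' @return A tibble with one row per branch: `branch_id`, `parent_branch`,
#'   `start_node`, `end_node`, `length_um`, `terminal`, and `node_rows`
#'   (list column of row indices into `tree` along the branch, start first).
#' @export
tree_branches <- function(tree) {
  n <- nrow(tree)
  parent_row <- match(tree$parent_id, tree$id)
  kids <- vector("list", n)
  for (i in seq_len(n)) kids[[i]] <- integer()
  ord <- order(tree$id)
  for (i in ord) {
    p <- parent_row[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  root <- which(is.na(parent_row))
  seglen <- function(a, b) {
    sqrt((tree$x[a] - tree$x[b])^2 + (tree$y[a] - tree$y[b])^2 +
           (tree$z[a] - tree$z[b])^2)
  }
  out <- list()
  # stack of (start_row, first_child_row, parent_branch)
  stack <- lapply(rev(kids[[root]]), function(ch) c(root, ch, 0L))
  bid <- 0L
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    path <- c(top[1], top[2])
    cur <- top[2]
    while (length(kids[[cur]]) == 1) {
      cur <- kids[[cur]][1]
      path <- c(path, cur)
    }
    bid <- bid + 1L
    len <- sum(vapply(seq_len(length(path) - 1),
                      function(j) seglen(path[j], path[j + 1]), numeric(1)))
    out[[bid]] <- list(
      branch_id = bid, parent_branch = top[3],
      start_node = tree$id[path[1]], end_node = tree$id[cur],
      length_um = len, terminal = length(kids[[cur]]) == 0,
      node_rows = list(path)
    )
    for (ch in rev(kids[[cur]])) stack[[length(stack) + 1]] <- c(cur, ch, bid)
  }
  if (bid == 0L) {
    return(tibble(branch_id = integer(), parent_branch = integer(),
                  start_node = integer(), end_node = integer(),
                  length_um = numeric(), terminal = logical(),
                  node_rows = list()))
  }
  bind_rows(lapply(out, as_tibble))
}

#' Classify nodes of a neuron tree
#'
#' Labels every node by its structural role with precedence
#' `soma > branch_point > filopodium_base > filopodium_tip > interstitial`:
#' the root is the soma; any non-root node with two or more children is a
#' branch point; a terminal branch no longer than `filopodium_max_len` is a
#' filopodium, its end node the filopodium tip and its origin node the
#' filopodium base. In developing tectal neurons these short protrusions are
#' the principal sites of synaptic input, which is why the segmented scan
#' mode samples exactly these labelled locations.
#'
#' @param tree A [neuron_tree()].
#' @param filopodium_max_len Maximum filopodium length (um, default 10).
#' @return The tree with a `label` column added.
#' @export
classify_nodes <- function(tree, filopodium_max_len = 10) {
  br <- tree_branches(tree)
  n <- nrow(tree)
  parent_row <- match(tree$parent_id, tree$id)
  n_children <- tabulate(parent_row[!is.na(parent_row)], nbins = n)
  rank <- c(interstitial = 0, filopodium_tip = 1, filopodium_base = 2,
            branch_point = 3, soma = 4)
  lab <- rep("interstitial", n)
  bump <- function(lab, rows, value) {
    up <- rank[value] > rank[lab[rows]]
    lab[rows[up]] <- value
    lab
  }
  filo <- br$terminal & br$length_um <= filopodium_max_len
  for (i in which(filo)) {
    path <- br$node_rows[[i]]
    lab <- bump(lab, path[length(path)], "filopodium_tip")
    lab <- bump(lab, path[1], "filopodium_base")
  }
  lab <- bump(lab, which(n_children >= 2 & !is.na(parent_row)), "branch_point")
  lab[is.na(parent_row)] <- "soma"
  out <- tree
  out$label <- lab
  new_tibble(out, class = "neuron_tree", bounds = attr(tree, "bounds"))
}

#' Read / write SWC morphology files
#'
#' Standard 7-column SWC (`id type x y z radius parent`), 1-based ids,
#' coordinates in micrometres, `#` comments, parent `-1` for the root. SWC
#' type 1 maps to `soma`; every other type is treated as `dendrite`. The
#' soma may be a single sphere record.
#'
#' @param path File path.
#' @param bounds Optional [volume_bounds()] passed to [neuron_tree()].
#' @return `read_swc()`: a [neuron_tree()]; `write_swc()`: `path`,
#'   invisibly.
#' @export
read_swc <- function(path, bounds = NULL) {
  if (!file.exists(path)) abort(paste("read_swc: no such file:", path))
  raw <- tryCatch(
    read.table(path, comment.char = "#",
               col.names = c("id", "type", "x", "y", "z", "radius", "parent"),
               colClasses = "numeric"),
    error = function(e) abort(paste("read_swc: cannot parse", path, "-", conditionMessage(e)))
  )
  if (nrow(raw) == 0) abort("read_swc: file contains no records")
  neuron_tree(
    tibble(
      id = as.integer(raw$id),
      parent_id = ifelse(raw$parent < 0, NA_integer_, as.integer(raw$parent)),
      x = raw$x, y = raw$y, z = raw$z, radius = raw$radius,
      kind = ifelse(raw$type == 1, "soma", "dendrite")
    ),
    bounds = bounds
  )
}

#' @rdname read_swc
#' @param tree A [neuron_tree()].
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  df <- data.frame(
    id = tree$id,
    type = ifelse(tree$kind == "soma", 1L, 3L),
    x = tree$x, y = tree$y, z = tree$z, radius = tree$radius,
    parent = ifelse(is.na(tree$parent_id), -1L, tree$parent_id)
  )
  lines <- c("# SWC exported by poiscan (um)",
             sprintf("%d %d %.4f %.4f %.4f %.3f %d",
                     df$id, df$type, df$x, df$y, df$z, df$radius, df$parent))
  writeLines(lines, path)
  invisible(path)
}
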