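#' @importFrom ggplot2 ggplot aes geom_segment geom_point geom_line
#'   geom_rect geom_tile facet_wrap labs scale_color_viridis_c
#'   scale_fill_viridis_c theme_minimal coord_equal autoplot
NULL

#' @export
ggplot2::autoplot

# edge table (parent -> child segments) of a neuron tree
tree_edges <- function(tree) {
  p <- match(tree$parent_id, tree$id)
  keep <- !is.na(p)
  tibble(
    x = tree$x[p[keep]], y = tree$y[p[keep]], z = tree$z[p[keep]],
    xend = tree$x[keep], yend = tree$y[keep], zend = tree$z[keep]
  )
}

#' Plot a neuron arbor in the imaging plane
#'
#' X-Y projection of the arbor with segments coloured by depth.
#'
#' @param object A [neuron_tree()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot neuron_tree
#' @export
autoplot.neuron_tree <- function(object, ...) {
  ed <- tree_edges(object)
  ggplot(ed, aes(x = .data$x, y = .data$y, xend = .data$xend,
                 yend = .data$yend, color = .data$z)) +
    geom_segment(linewidth = 0.4) +
    scale_color_viridis_c(name = "z (um)") +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)", title = "Dendritic arbor (XY projection)") +
    theme_minimal()
}

#' Plot a POI set coloured by structural label
#'
#' @param object A `poi_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot poi_set
#' @export
autoplot.poi_set <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$x, y = .data$y, color = .data$label)) +
    geom_point(size = 0.8) +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)",
         title = sprintf("%d POIs at d_L = %g um", nrow(object),
                         attr(object, "d_l_um"))) +
    theme_minimal()
}

#' Plot a planned Z-trajectory
#'
#' Commanded Z against time with dwell windows shaded.
#'
#' @param object A `z_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot z_trajectory
#' @export
autoplot.z_trajectory <- function(object, ...) {
  tr <- sample_trajectory(object, rate = 2e4)
  w <- attr(object, "windows")
  ggplot(tr, aes(x = .data$t * 1e3, y = .data$z_cmd)) +
    geom_rect(data = w, inherit.aes = FALSE,
              aes(xmin = .data$t_dwell0 * 1e3,
                  xmax = (.data$t_dwell0 + 1e-9 +
                            (.data$t_event0 - .data$t_dwell0)) * 1e3,
                  ymin = .data$z_lo, ymax = .data$z_hi),
              alpha = 0.2, fill = "steelblue") +
    geom_line(linewidth = 0.4) +
    labs(x = "time (ms)", y = "commanded z (um)",
         title = sprintf("Monotone Z sweep, %d dwell windows, period %.2f ms",
                         nrow(w), attr(object, "period") * 1e3)) +
    theme_minimal()
}

#' Plot dF/F0 traces for a subset of POIs
#'
#' @param object A `trace_set` (after [compute_dff()]).
#' @param poi_ids POIs to show (default: first 12).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trace_set
#' @export
autoplot.trace_set <- function(object, poi_ids = NULL, ...) {
  yvar <- if ("dff" %in% names(object)) "dff" else "intensity"
  if (is.null(poi_ids)) poi_ids <- head(unique(object$poi_id), 12)
  df <- as_tibble(object[object$poi_id %in% poi_ids, ])
  ggplot(df, aes(x = .data$t, y = .data[[yvar]])) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~poi_id, scales = "free_y") +
    labs(x = "time (s)",
         y = if (yvar == "dff") "dF/F0" else "intensity (a.u.)") +
    theme_minimal()
}

#' Arbor overlay of an evoked-response map
#'
#' @param map An [evoked_response_map()] result with positions.
#' @param tree Optional [neuron_tree()] drawn underneath.
#' @return A ggplot.
#' @export
plot_evoked_map <- function(map, tree = NULL) {
  if (!all(c("x", "y") %in% names(map))) {
    abort("plot_evoked_map: map lacks POI positions")
  }
  p <- ggplot()
  if (!is.null(tree)) {
    p <- p + geom_segment(data = tree_edges(tree),
                          aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend),
                          color = "grey70", linewidth = 0.3)
  }
  p +
    geom_point(data = map,
               aes(x = .data$x, y = .data$y, color = .data$evoked_dff),
               size = 1.2) +
    scale_color_viridis_c(name = "evoked dF/F0") +
    coord_equal() +
    labs(x = "x (um)", y = "y (um)", title = "Stimulus-evoked response map") +
    theme_minimal()
}
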