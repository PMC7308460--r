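#' Bin the raw samples of one POI line scan
#'
#' The short line scan delivers `pixels_per_poi * samples_per_pixel` raw PMT
#' samples per POI visit. The samples of each pixel site are summed to a
#' pixel intensity, and the POI intensity is the mean of the brightest
#' `top_k` pixels — a reduction tolerant of the small lateral drift the line
#' scan exists to absorb.
#'
#' @param samples Numeric vector of raw samples, pixel-major (the first
#'   `samples_per_pixel` entries belong to pixel 1, and so on).
#' @param samples_per_pixel Samples per pixel site.
#' @param top_k Number of brightest pixels averaged into the POI intensity.
#' @return A list with `pixels` (summed pixel intensities) and `intensity`
#'   (the POI intensity).
#' @examples
#' bin_record(0:54)$intensity # 235
#' @export
bin_record <- function(samples, samples_per_pixel = 5, top_k = 3) {
  if (length(samples) %% samples_per_pixel != 0) {
    abort(sprintf("bin_record: %d samples is not a multiple of %d per pixel",
                  length(samples), samples_per_pixel))
  }
  px <- colSums(matrix(samples, nrow = samples_per_pixel))
  list(pixels = px,
       intensity = mean(sort(px, decreasing = TRUE)[seq_len(min(top_k, length(px)))]))
}

#' Reduce acquisition records to per-POI fluorescence traces
#'
#' Applies [bin_record()] to every record and assembles the per-POI time
#' series sampled once per scan cycle.
#'
#' @param records An [acquire()] result.
#' @param top_k Brightest pixels averaged per POI (see [bin_record()]).
#' @return A `trace_set` tibble: `poi_id`, `cycle`, `t` (s), `intensity`;
#'   attributes `rate` (cycle rate, Hz), `labels` (POI label lookup),
#'   `protocol`, `schedule`.
#' @export
records_to_traces <- function(records, top_k = 3) {
  stopifnot(inherits(records, "acquisition_records"))
  cfg <- attr(records, "cfg")
  n_sp <- cfg$daq$samples_per_pixel
  n_px <- cfg$daq$pixels_per_poi
  S <- records$samples
  # pixel sums: fold the sample axis
  agg <- matrix(0, nrow(S), n_px)
  for (p in seq_len(n_px)) {
    agg[, p] <- rowSums(S[, ((p - 1) * n_sp + 1):(p * n_sp), drop = FALSE])
  }
  ord <- t(apply(agg, 1, sort, decreasing = TRUE))
  intensity <- rowMeans(ord[, seq_len(min(top_k, n_px)), drop = FALSE])
  phys <- attr(records, "physiology")
  out <- tibble(
    poi_id = records$poi_id, cycle = records$cycle, t = records$t,
    intensity = intensity
  )
  new_tibble(out, class = "trace_set",
             rate = attr(attr(records, "schedule"), "rate"),
             labels = phys$pois[, c("poi_id", "label")],
             positions = phys$pois[, c("poi_id", "x", "y", "z")],
             protocol = phys$protocol,
             f0_true = phys$f0)
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d POIs x %d cycles at %.2f Hz\n",
              length(unique(x$poi_id)), max(x$cycle), attr(x, "rate")))
  NextMethod()
}

#' @method glance trace_set
#' @export
glance.trace_set <- function(x, ...) {
  tibble(
    n_poi = length(unique(x$poi_id)),
    n_cycles = max(x$cycle),
    rate_hz = attr(x, "rate"),
    duration_s = diff(range(x$t))
  )
}

#' Compute dF/F0 for every POI trace
#'
#' The baseline `F0` is either a low quantile of the whole trace (default
#' the 20th percentile, robust to sparse transients) or the mean of a
#' stated pre-stimulus window; `dF/F0 = (F - F0) / F0`.
#'
#' @param traces A `trace_set` (or tibble with `poi_id`, `t`, `intensity`).
#' @param baseline `"quantile"` or `"window"`.
#' @param q Baseline quantile for `baseline = "quantile"`.
#' @param window Length-2 time window (s) for `baseline = "window"`.
#' @return The input with `f0` and `dff` columns added.
#' @export
compute_dff <- function(traces, baseline = c("quantile", "window"),
                        q = 0.2, window = NULL) {
  baseline <- match.arg(baseline)
  at <- attributes(traces)
  grp <- split(seq_len(nrow(traces)), traces$poi_id)
  f0 <- numeric(nrow(traces))
  for (rows in grp) {
    f0[rows] <- if (baseline == "quantile") {
      quantile(traces$intensity[rows], q, names = FALSE)
    } else {
      if (is.null(window)) abort("compute_dff: baseline window required")
      inwin <- traces$t[rows] >= window[1] & traces$t[rows] <= window[2]
      if (!any(inwin)) abort("compute_dff: no samples in the baseline window")
      mean(traces$intensity[rows][inwin])
    }
  }
  if (any(f0 <= 0)) {
    abort(sprintf("compute_dff: degenerate baseline (F0 <= 0) for %d POI(s)",
                  length(unique(traces$poi_id[f0 <= 0]))))
  }
  out <- traces
  out$f0 <- f0
  out$dff <- (out$intensity - f0) / f0
  keep <- at[setdiff(names(at), c("names", "row.names", "class"))]
  for (nm in names(keep)) attr(out, nm) <- keep[[nm]]
  class(out) <- class(traces)
  out
}

#' Export a trace set as CSV
#'
#' Columns `poi_id, t, F` plus `dFF` when present.
#'
#' @param traces A `trace_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- data.frame(poi_id = traces$poi_id, t = traces$t,
                   F = traces$intensity)
  if ("dff" %in% names(traces)) df$dFF <- traces$dff
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
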