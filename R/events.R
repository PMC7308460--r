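#' Matched-filter transient detection
#'
#' Slides a kinetics-shaped template over a dF/F0 trace and scores each
#' window by its projection onto the zero-mean, unit-norm template (the
#' matched-filter statistic: the score of the exact normalized template is
#' 1, white noise of SD `s` gives scores of SD `s`). Windows scoring above
#' the threshold — by default `3.5 x` the robust (MAD-based) SD of the
#' score series — and locally maximal within one window length are
#' reported as events, so a transient spanning several windows is counted once.
#'
#' @param trace A tibble with `t` and `dff` for one POI, or a numeric dF/F0
#'   vector.
#' @param kinetics A [transient_kinetics()] describing the expected
#'   dynamics (e.g. [iglusnfr_kinetics()] for glutamate imaging).
#' @param rate Sampling rate (Hz); taken from `t` when omitted.
#' @param window Template length (samples, >= 2).
#' @param threshold Absolute score threshold; overrides `threshold_k`.
#' @param threshold_k Threshold in robust SDs of the score series.
#' @return A `detected_events` tibble: `onset_idx`, `t_onset` (s), `score`,
#'   `peak_dff`; attribute `scores` holds the full score series.
#' @examples
#' kin <- iglusnfr_kinetics()
#' y <- c(numeric(40), transient_waveform(kin, (0:7) / 6), numeric(40))
#' matched_filter_detect(y, kin, rate = 6, window = 8)
#' @export
matched_filter_detect <- function(trace, kinetics, rate = NULL, window = 8,
                                  threshold = NULL, threshold_k = 3.5) {
  if (is.data.frame(trace)) {
    if (is.null(rate)) rate <- 1 / median(diff(trace$t))
    y <- trace$dff
    t0 <- trace$t[1]
  } else {
    if (is.null(rate)) abort("matched_filter_detect: rate required for a bare vector")
    y <- as.numeric(trace)
    t0 <- 0
  }
  if (window < 2) abort("matched_filter_detect: window must be >= 2 samples")
  n <- length(y)
  if (n < window) abort("matched_filter_detect: trace shorter than the template window")
  tmpl <- transient_waveform(kinetics, (seq_len(window) - 1) / rate)
  tmpl <- tmpl - mean(tmpl)
  tn <- sqrt(sum(tmpl^2))
  if (tn == 0) abort("matched_filter_detect: degenerate template")
  tmpl <- tmpl / tn
  # running projection onto the template
  scores <- as.numeric(stats::filter(y, rev(tmpl), sides = 1))[window:n]
  thr <- if (!is.null(threshold)) threshold else threshold_k * mad(scores)
  thr <- max(thr, 1e-9) # guard against floating-point residue on flat traces
  cand <- which(scores > thr)
  # deduplicate: keep local maxima within one window length
  keep <- logical(length(scores))
  for (i in cand) {
    lo <- max(1, i - window + 1)
    hi <- min(length(scores), i + window - 1)
    if (scores[i] >= max(scores[lo:hi])) keep[i] <- TRUE
  }
  idx <- which(keep)
  peak <- vapply(idx, function(i) max(y[i:min(n, i + window - 1)]), numeric(1))
  new_tibble(
    tibble(
      onset_idx = idx,
      t_onset = t0 + (idx - 1) / rate,
      score = scores[idx],
      peak_dff = peak
    ),
    class = "detected_events", scores = scores, threshold = thr, rate = rate
  )
}

#' Detect events across all POIs of a trace set
#'
#' Runs [matched_filter_detect()] on each POI's dF/F0 trace and associates
#' every detection with the stimulus whose response window
#' `[onset, onset + 2 * tau_delay]` contains it (or `NA` for spontaneous
#' detections).
#'
#' @param traces [compute_dff()] output.
#' @param kinetics A [transient_kinetics()].
#' @param protocol Optional [stimulus_protocol()]; defaults to the one
#'   attached to the traces.
#' @param ... Passed to [matched_filter_detect()].
#' @return A tibble of events with `poi_id` and `stimulus_idx` columns.
#' @export
detect_events <- function(traces, kinetics, protocol = NULL, ...) {
  if (is.null(protocol)) protocol <- attr(traces, "protocol")
  rate <- attr(traces, "rate")
  out <- list()
  for (pid in unique(traces$poi_id)) {
    tr <- traces[traces$poi_id == pid, c("t", "dff")]
    ev <- matched_filter_detect(tr, kinetics, rate = rate, ...)
    if (nrow(ev)) {
      ev$poi_id <- pid
      out[[length(out) + 1]] <- as_tibble(ev)
    }
  }
  ev <- if (length(out)) bind_rows(out) else {
    tibble(onset_idx = integer(), t_onset = numeric(), score = numeric(),
           peak_dff = numeric(), poi_id = integer())
  }
  ev$stimulus_idx <- NA_integer_
  if (!is.null(protocol) && nrow(ev)) {
    for (s in seq_len(nrow(protocol))) {
      hit <- ev$t_onset >= protocol$onset[s] &
        ev$t_onset <= protocol$onset[s] + 2 * kinetics$tau_delay
      ev$stimulus_idx[hit] <- protocol$stim_idx[s]
    }
  }
  ev
}

#' Per-POI evoked-response map
#'
#' For every POI, averages over stimuli the difference between the mean
#' dF/F0 in the post-stimulus window `[onset, onset + window]` and the mean
#' in the pre-stimulus buffer `[onset - t_b, onset]`, yielding the
#' stimulus-locked response strength that can be painted back onto the
#' arbor.
#'
#' @param traces [compute_dff()] output.
#' @param protocol A [stimulus_protocol()]; defaults to the traces'
#'   protocol.
#' @param window Post-stimulus averaging window (s).
#' @param t_b Pre-stimulus baseline window (s); defaults to the protocol
#'   buffer.
#' @return A tibble `poi_id`, `evoked_dff`, `n_stim`, joined with POI
#'   positions when available; attribute `n_truncated` counts stimulus
#'   windows clipped by the end of the recording.
#' @export
evoked_response_map <- function(traces, protocol = NULL, window = 3,
                                t_b = NULL) {
  if (is.null(protocol)) protocol <- attr(traces, "protocol")
  if (is.null(protocol)) abort("evoked_response_map: no stimulus protocol available")
  if (is.null(t_b)) t_b <- attr(protocol, "t_b")
  if (is.null(t_b)) t_b <- 1
  t_p <- attr(protocol, "t_p")
  if (!is.null(t_p) && window > t_p) {
    abort("evoked_response_map: window exceeds the presentation interval")
  }
  t_end <- max(traces$t)
  truncated <- sum(protocol$onset + window > t_end)
  if (truncated > 0) {
    warn(sprintf("evoked_response_map: %d stimulus window(s) truncated by the end of the recording",
                 truncated))
  }
  pids <- unique(traces$poi_id)
  res <- numeric(length(pids))
  nst <- integer(length(pids))
  for (i in seq_along(pids)) {
    tr <- traces[traces$poi_id == pids[i], ]
    vals <- c()
    for (s in seq_len(nrow(protocol))) {
      on <- protocol$onset[s]
      post <- tr$dff[tr$t >= on & tr$t <= on + window]
      pre <- tr$dff[tr$t >= on - t_b & tr$t < on]
      if (length(post) == 0) next
      base <- if (length(pre)) mean(pre) else 0
      vals <- c(vals, mean(post) - base)
    }
    res[i] <- if (length(vals)) mean(vals) else 0
    nst[i] <- length(vals)
  }
  out <- tibble(poi_id = pids, evoked_dff = res, n_stim = nst)
  pos <- attr(traces, "positions")
  if (!is.null(pos)) out <- left_join(out, pos, by = "poi_id")
  attr(out, "n_truncated") <- truncated
  out
}
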