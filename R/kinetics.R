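#' Extract transient kinetics parameters from an evoked trace
#'
#' Measures the three stereotyped transient parameters from a single evoked
#' trace, following the conventions used for experimental line scans:
#' delay-to-peak is the time from stimulus onset to the trace maximum; the
#' rise parameter is the first post-stimulus crossing of `(1 - 1/e)` of the
#' peak (linearly interpolated between samples); the decay parameter is the
#' first post-peak crossing of `peak / e` (interpolated likewise). When the
#' peak does not clear the noise floor the result is a no-transient row of
#' `NA`s rather than an error.
#'
#' @param trace A tibble with `t` (s) and `dff`, e.g. from
#'   [simulate_transient()] or one POI of [compute_dff()] output.
#' @param stim_time Stimulus onset (s).
#' @param noise_floor Minimum peak dF/F0 to count as a transient.
#' @return A `kinetics_estimate` tibble (one row): `tau_delay`, `tau_r`,
#'   `tau_f` (s), `peak_dff`, `t_peak` (s).
#' @examples
#' kin <- transient_kinetics()
#' tr <- simulate_transient(kin, rate = 1000, duration = 10, onset = 0.5)
#' extract_kinetics(tr, stim_time = 0.5)
#' @export
extract_kinetics <- function(trace, stim_time, noise_floor = 0) {
  t <- trace$t
  y <- trace$dff
  post <- which(t >= stim_time)
  if (length(post) < 3) abort("extract_kinetics: trace does not cover the stimulus")
  pk <- post[which.max(y[post])]
  peak <- y[pk]
  if (!is.finite(peak) || peak <= noise_floor) {
    return(new_tibble(
      tibble(tau_delay = NA_real_, tau_r = NA_real_, tau_f = NA_real_,
             peak_dff = peak, t_peak = NA_real_),
      class = "kinetics_estimate"))
  }
  cross_up <- function(idx, level) {
    above <- y[idx] >= level
    j <- which(above)[1]
    if (is.na(j)) return(NA_real_)
    if (j == 1) return(t[idx[1]])
    i0 <- idx[j - 1]; i1 <- idx[j]
    t[i0] + (level - y[i0]) / (y[i1] - y[i0]) * (t[i1] - t[i0])
  }
  cross_dn <- function(idx, level) {
    below <- y[idx] <= level
    j <- which(below)[1]
    if (is.na(j)) return(NA_real_)
    if (j == 1) return(t[idx[1]])
    i0 <- idx[j - 1]; i1 <- idx[j]
    t[i0] + (level - y[i0]) / (y[i1] - y[i0]) * (t[i1] - t[i0])
  }
  rise_t <- cross_up(post[post <= pk], (1 - exp(-1)) * peak)
  decay_idx <- which(t > t[pk])
  decay_t <- if (length(decay_idx)) cross_dn(decay_idx, peak * exp(-1)) else NA_real_
  new_tibble(
    tibble(
      tau_delay = t[pk] - stim_time,
      tau_r = rise_t - stim_time,
      tau_f = decay_t - t[pk],
      peak_dff = peak,
      t_peak = t[pk]
    ),
    class = "kinetics_estimate"
  )
}

#' @method glance kinetics_estimate
#' @export
glance.kinetics_estimate <- function(x, ...) as_tibble(x)

#' Signal bandwidth and required Nyquist sampling rate by FFT
#'
#' Computes the one-sided power spectrum of a trace and reports the
#' smallest frequency below which at least `coverage` (default 95%) of the
#' cumulative non-DC power lies, together with the sampling rate required
#' to capture the signal without aliasing (twice that bandwidth). A
#' constant trace has zero bandwidth.
#'
#' @param trace Numeric vector, or tibble with a `dff` (or `intensity`)
#'   column.
#' @param rate Sampling rate (Hz).
#' @param coverage Cumulative power fraction defining the bandwidth.
#' @return A list with `f_max` (Hz), `required_rate` (Hz) and `spectrum`
#'   (tibble of `freq`, `power`).
#' @examples
#' fft_bandwidth(sin(2 * pi * 1 * seq(0, 10, by = 1e-3)), rate = 1000)$f_max
#' @export
fft_bandwidth <- function(trace, rate, coverage = 0.95) {
  y <- if (is.data.frame(trace)) {
    if ("dff" %in% names(trace)) trace$dff else trace$intensity
  } else {
    as.numeric(trace)
  }
  n <- length(y)
  if (n < 4) abort("fft_bandwidth: trace too short")
  sp <- fft(y)
  half <- floor(n / 2)
  power <- Mod(sp[seq_len(half + 1)])^2
  freq <- (0:half) * rate / n
  power[1] <- 0 # exclude DC
  tot <- sum(power)
  if (tot <= .Machine$double.eps * n) {
    return(list(f_max = 0, required_rate = 0,
                spectrum = tibble(freq = freq, power = power)))
  }
  cum <- cumsum(power) / tot
  f_max <- freq[which(cum >= coverage)[1]]
  list(f_max = f_max, required_rate = 2 * f_max,
       spectrum = tibble(freq = freq, power = power))
}
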