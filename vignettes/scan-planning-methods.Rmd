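---
title: "Planning and simulating random-access POI scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning and simulating random-access POI scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poiscan)
```

`poiscan` models a random-access two-photon microscope built around two
acousto-optic deflectors (AODs) for lateral beam steering and a piezo
actuator for depth. This vignette explains the models behind the planner,
the digital twin and the analysis layer, the parameters that matter, and
the design choices made where the instrument physics left the design open.

## The timing model

A POI visit is a short diagonal line scan of `pixels_per_poi` (default 11)
pixels, each integrated over `samples_per_pixel` (default 5) samples of the
DAQ clock (default 2.5 MHz), so the sweep takes
`T_SCAN = 11 × 5 / 2.5 MHz = 22 µs`. Before each sweep the AODs need their
access time `T_ACC = Ø_L / v` — the time the acoustic wave takes to cross
the beam waist, 13 µs for a 9 mm aperture at 650 m/s — plus an
inter-instruction buffer `T_Buffer` (default 3 µs; the electronics impose
some such gap but its exact value is configuration, not physics). The
per-POI service time is their sum:

```{r}
glance(compute_timing(hardware_config()))
```

`V_Z_MAX = 2·d_TOL/T_POI` is the fastest the focal plane may move while a
POI is being scanned and still stay inside the axial tolerance
`d_TOL` (default 0.5 µm) for the whole visit.

## Image space and AOD frequencies

Image space uses 0-based pixel indices with pixel centres at integer
coordinates and `fov_um / s_px` µm per pixel (112 µm / 512 px by default).
A POI at pixel `u` is excited by sweeping each deflector from
`f0 = s(u − L_POI/2 − 0.5) + f_min` to `f1 = s(u + L_POI/2 + 0.5) + f_min`,
`s = (f_max − f_min)/S_px`, so the 40 MHz modulation bandwidth spans the
field of view and the sweep covers the outer pixel edges of the
11-pixel line. Identical pairs go to both (orthogonally mounted)
deflectors, offset to the POI's own X and Y pixels — a 45° diagonal sweep
through the POI. The map is affine and inverts exactly, which the tests
exercise to 1e-9 px. The scale factor is read as *per-pixel* bandwidth:
only that reading makes the matrix equation dimensionally consistent and
lets the hardware bandwidth span the image; the planner records sweeps
that would leave `[f_min, f_max]` as boundary errors (POIs too close to
the field edge).

## The Z-trajectory

POIs are distributed non-uniformly in depth, so the planner sorts them by
Z and clusters them greedily into dwell windows no wider than
`2(d_TOL − dwell_margin)`; every POI in a window is then within tolerance
of the window centre. The cycle is a single monotone sweep: the stage
pauses at each window centre for `t_pad + n·T_G` (the transient allowance
`t_pad`, default 50 µs, lets the plant's residual error decay before the
first start pulse), moves between windows along trapezoidal profiles
bounded by `V_max = 0.043 m/s` and `A_max = 60 000 m/s²`, and closes with
one flyback plus a full settling time `T_S = 2.1 ms`.

Two choices deserve justification:

* **No per-window settling.** The settling time characterises the response
  to a *step* command. The planned sweep is smooth (bounded velocity and
  acceleration everywhere), and under the stated acceleration limit the
  plant's following error stays below 0.5 µm, so inserting `T_S` after
  every inter-window move would be physically unmotivated — and with
  hundreds of occupied windows it would also cap segmented scans near
  4 Hz, well below what the instrument class demonstrably achieves. The
  one genuine step in the cycle is the flyback, which is followed by a
  full `T_S`.
* **`dwell_margin`** (default 0.05 µm) reserves a slice of `d_TOL` for
  dynamic following error, so command-space clustering plus plant lag
  still lands every visit inside the tolerance; the twin's replay tests
  confirm 100% of visits within `d_TOL` at zero sensor noise.

Start pulses are quantized to the DAQ clock grid (flooring) and POIs
within a window are ordered by branch id then arc offset, the tie-break
that makes schedules deterministic. An optional `rate_target` pads the
cycle with an idle hold, used to lock acquisition to a stimulus protocol
(the instrument scans no faster than the experiment needs).

Scan modes: `volume` (full-arbor rapid scan), `planar` (AOD-only, fixed
plane; the cycle period is exactly `N_POI·T_G`), `segmented`
(`segment_pois()` + one volume scan per compartment), and `plan_f3ds()`
for conventional raster stacks (`N_IMG = floor(extent/Z_INT) + 1` planes).
`apply_drift_shift()` covers the post-scan re-registration step.

## Segmentation

Compartments are consecutive runs of the depth-first POI order. When there
are at least `k` branches, whole branches are kept together and an exact
dynamic program minimises the largest compartment (tie-broken to maximise
the smallest); with fewer branches than `k` the split falls back to POI
granularity, where sizes differ by at most one. Scanning only the
structurally labelled POIs — soma, branch points, filopodium bases and
tips, the synapse-enriched locations of developing tectal neurons — is
what buys the higher per-compartment rate.

## The synthetic neuron generator

`generate_synthetic_neuron()` emulates a developing tadpole tectal
neuron: a soma low in a 100 × 100 × 125 µm volume, `n_major` (24) tortuous
major branches grown by a persistent random walk with an upward drift
(the apical climb through the neuropil), and `n_filopodia` (150) short
terminal protrusions of 1–4 µm attached at interior points. Total branch
length is exact by construction (major-branch lengths are a minimum of
12 µm plus a scaled share of the remainder), steps reflect off the volume
walls without changing segment lengths, and the whole tree is a
deterministic function of the seed. Because every attachment creates one
junction and attachments stay clear of branch ends, the labelled-location
count is exactly `n_major + 2·n_filopodia` — convenient for constructing
study-sized problems (324 labelled POIs with the defaults).
`calibrate_neuron_pois()` bisects the target length until interpolation
yields an exact POI count; the count is a monotone step function of the
target because all branch lengths scale linearly with it.

What the generator does *not* emulate: real arbors' reconstruction noise,
branch-diameter tapering, growth and drift during the experiment, and the
spatial correlation of filopodia with synaptic partners. Planner tests
passing on synthetic trees therefore validate geometry handling and
scheduling, not biological realism of any particular arbor.

## The digital twin

The piezo plant is a critically damped second-order system (two cascaded
first-order stages). Its natural frequency is set from the steady-state
velocity lag: tracking at `V_max` the plant trails the command by
`2·V_max/ω`, and this is pinned to the configured following-error bound
(0.5 µm), giving `ω ≈ 1.7×10⁵ rad/s`. The implied 100 µm step response
settles to 0.5 µm in ~43 µs, comfortably inside the configured `T_S`; both
the step behaviour and dwell-window tracking are asserted in tests. The
capacitive sensor adds Gaussian noise to the *measurement only* — sensor
noise does not shake the objective.

Excitation is a separable Gaussian: axial weight
`exp(−4 ln 2 · Δz²/FWHM_ax²)` (FWHM 2.5 µm) and a lateral weight along the
diagonal sweep from the elliptical lateral PSF (FWHM 1.24 × 0.34 µm).
Counts are Poisson around `gain × fluorescence × weight`, plus optional
Gaussian read noise; `noise = "none"` gives exact expectations for
deterministic tests.

Physiology is the canonical evoked transient: a saturating-exponential
rise whose `(1 − 1/e)`-of-peak crossing is exactly at `τ_R` and whose
maximum is at `τ_Delay` (the rise constant is solved numerically to below
1e-6 s; a solution exists iff `τ_R/τ_Delay < 1 − 1/e`), then exponential
decay with `τ_F`. Defaults are the fitted GCaMP6m somatic values
(0.404, 0.237, 2.907 s); `iglusnfr_kinetics()` provides the fast
glutamate-sensor variant (τ_R 5 ms, τ_F 150 ms; its delay-to-peak is not
separately characterised and defaults to 2.5·τ_R). Somatic events are
global — one action potential elevates every POI in the same cycle —
while synaptic events are confined to POIs within 2 µm of seeded
filopodium tips. Dendritic kinetics are assumed identical to somatic ones
(configurable via `kinetics_local`). The stimulus protocol is the
standard 4 OFF / transition / 4 ON sequence in 8 s slots, and all ground
truth is logged for scoring.

## Analysis choices

* **Pixel reduction**: each pixel is the sum of its 5 samples; the POI
  intensity is the mean of the 3 brightest pixels — the line scan exists
  to absorb small lateral drift, and a top-k reduction is insensitive to
  which pixels the structure lands on.
* **Baseline**: `F0` defaults to the 20th percentile of the trace (robust
  when transients are sparse); a pre-stimulus window mean is available
  when the protocol warrants it.
* **Kinetics extraction** mirrors the transient conventions (argmax,
  `(1−1/e)`-of-peak and `peak/e` crossings with linear interpolation); a
  peak under the noise floor returns a no-transient row rather than an
  error. Noiseless round trips recover parameters to within one sample
  period, which the tests assert over 50 random kinetics draws at 1 kHz.
* **Bandwidth**: the smallest frequency containing 95% of cumulative
  one-sided FFT power, DC excluded; the required sampling rate is twice
  that. On the noiseless canonical transient this criterion yields
  ~0.6 Hz (required rate ~1.2 Hz): the 2.9 s decay concentrates nearly
  all power below 1 Hz. Experimental spectra of the same transients read
  higher because broadband shot noise and trial averaging flatten the
  spectrum; a noiseless synthetic trace is the clean lower bound, and the
  package reports it as computed.
* **Matched filter**: each window is projected onto the zero-mean,
  unit-norm kinetics template (so the exact normalized template scores 1
  and white noise of SD σ produces scores of SD σ); detections exceed
  `3.5 ×` the MAD-based robust SD of the score series and are
  deduplicated to local maxima within one window length. A Pearson-style
  normalization was rejected: its noise SD at short windows (~0.4 at
  window 8) puts a 3.5-robust-SD threshold above the statistic's upper
  bound of 1.
* **Evoked maps**: per POI, the mean over stimuli of (post-window mean −
  pre-buffer mean) of ΔF/F₀, attachable to POI positions for arbor
  overlays (`plot_evoked_map()`). Detections are associated with a
  stimulus when they fall within `[onset, onset + 2·τ_Delay]`.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script run at desk scale: synthetic
neurons of 150–1200 µm total length (up to ~800 POIs), 100-neuron replay
sweeps, and simulated recordings of a few hundred cycles across ~200 POIs
— a few seconds to about a minute end to end. Degenerate inputs are
contracts, not crashes: a soma-only SWC yields one POI and a pure-dwell
schedule; a constant trace has zero bandwidth and no detections; `Z_INT`
larger than the axial extent gives a single raster plane; empty POI sets,
non-positive spacings, off-plane planar POIs and POIs unreachable on a
supplied trajectory raise errors naming the offender.

## Known limitations

The twin omits AOD dispersion and wavefront effects, photobleaching,
laser-power dynamics, and motion artifacts (the modelled preparation is
drift-minimal); the piezo model is linear and ignores hysteresis and
load resonances beyond the single dominant pole pair; trace analysis
performs no image registration or spike deconvolution. Cycle rates
reported by the planner are upper bounds for an instrument whose
electronics insert no delays beyond `T_Buffer`, `T_ACC`, the sweep time,
and the piezo dynamics modelled here.
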