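---
title: "Quantifying modular spontaneous activity in developing cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying modular spontaneous activity in developing cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In the developing cortex, before sensory experience, neural activity is
dominated by spontaneous events: transient episodes in which activity
organizes into patchy, quasi-periodic *modules* spanning millimeters of
cortex. Widefield calcium imaging captures these events at mesoscale;
two-photon imaging resolves whether nearby neurons inside one "module"
really co-activate or are intermixed salt-and-pepper style. `modcortex`
implements the full measurement chain for such recordings:

1. **Preprocessing** — rigid registration by phase correlation, a
   running-median baseline \(F_0\), and \(\Delta F/F_0 = (F - F_0)/F_0\).
2. **Event detection** — per-pixel activity thresholds (mean + 3 SD over
   all frames), a minimum contiguous active area (0.01 mm²), and a
   frame-level criterion (>40% of ROI pixels active); runs of active
   frames become events, split at interior local minima of the ROI-mean
   trace; each event is summarized by its maximally active "event frame".
3. **Modular structure** — from each band-pass-filtered event frame, the
   radially averaged, mask-corrected spatial autocorrelation; the
   wavelength \(\Lambda\) (twice the radius of the first minimum), the
   modularity (first-minimum-to-next-maximum excursion), and the module
   amplitude (peak \(\Delta F/F\) over the median on the annulus at
   \(\Lambda/2\), computed on unfiltered frames).
4. **Correlation networks** — seed-point correlation fields
   \(C(\mathbf{x}, \mathbf{s})\): the Pearson correlation across event
   patterns between activity at location \(\mathbf{x}\) and seed
   \(\mathbf{s}\); local maxima (800 µm minimum separation) pooled over
   seeds and binned by distance; significance of the 1.8–2.2 mm band
   against ensembles of randomly rotated/reflected surrogate patterns.
5. **Dimensionality** — the cross-validated participation ratio
   \(d_\mathrm{eff} = (\sum_i \lambda_i)^2 / \sum_i \lambda_i^2\), where
   \(\lambda_i\) is the variance of a held-out half of the ensemble
   projected on the \(i\)-th principal axis of the training half.
6. **Cellular coherence** — neuropil correction
   \(F_\mathrm{cell} = F_\mathrm{raw} - 0.4\,F_\mathrm{neuropil}\),
   cellular event detection (2 SD, >5% of cells), pairwise correlations
   of per-frame z-scored event activity, a within-cell shuffle null, and
   the local coherence index
   \(\mathrm{LCI} = (N_+ - N_-)/(N_+ + N_-)\) over distance annuli.

Every stage is validated on synthetic data with known ground truth,
generated by the package itself.

## The synthetic-data generator

`synth_params()` + `synth_widefield_movie()` emulate the statistical
structure the analysis assumes:

- **Modular patterns.** Basis patterns are Gaussian random fields whose
  power spectrum is an annulus at spatial frequency \(1/\Lambda_F\)
  (relative width `spectral_bandwidth`, default 0.1). This choice is
  deliberate: a ring spectrum gives an isotropic autocorrelation whose
  expectation is \(J_0(2\pi r/\Lambda_F)\), so the wavelength estimator
  has a closed-form target — the first minimum of \(J_0\) is at
  \(0.6098\,\Lambda_F\), hence an unbiased estimator reports
  \(1.2196\,\Lambda_F\). The default \(\Lambda_F = 0.9\) mm places the
  estimated wavelength near 1.1 mm, the scale seen in developing cortex.
- **Low-dimensional event ensembles.** Each event pattern is
  \(\max(\sum_j c_{ij} B_j + \mu_i + \sigma_i \varepsilon_i, 0)\) with
  *half-normal* weights \(c_{ij} \sim |N(0,1)|\), a pedestal
  \(\mu_i\) of `pattern_offset_sd` (default 1) mixture SDs, and fresh
  ring-spectrum noise at `pattern_noise_sd` (relative to the mixture
  SD). Nonnegative weights model events as graded activations of a
  repertoire, and the pedestal models the broad depolarization real
  events ride on (a finite peak-to-background module amplitude means
  the inter-module background is a substantial fraction of the peak,
  not zero). Both choices serve the generator's contract —
  *controllable* dimensionality. Rectification is a nonlinearity, and
  the participation-ratio target for `n_basis` planted components is
  derived from the linear covariance: with signed weights the
  rectified ensemble splits each basis into two components
  (\(d_\mathrm{eff}\sim 13\text{--}16\) for 8 bases), and even with
  nonnegative weights, rectifying at zero clips half of every field
  and the clipping harmonics add \(\sim\!1.5\) effective dimensions
  (\(d_\mathrm{eff}\approx 9.6\text{--}10.3\)). The one-SD pedestal
  leaves only \(\sim\!16\%\) of pixels clipped, keeping the ensemble
  near-linear: \(d_\mathrm{eff} \approx 8.8\) for 8 bases, and exactly
  1 in the noiseless single-basis limit (for one basis the pattern is
  exactly \(c_i\) times a fixed field). `pattern_offset_sd = 0`
  recovers the pure rectified variant. The recorded `premix` ground
  truth excludes the pedestal, so the noiseless mixtures have exactly
  `n_basis` nonzero singular values.
- **Movies.** Events are planted at spacing `1/event_rate_hz` (default
  30 s, a typical inter-event interval in this preparation) with small
  jitter, convolved with a difference-of-exponentials calcium kernel,
  on a slowly drifting multiplicative baseline with per-pixel sensor
  noise (`pixel_noise_sd`, default 0.05 against a default event peak of
  0.5 \(\Delta F/F\), i.e. 10:1). The kernel defaults (rise 0.1 s,
  decay 0.5 s, GCaMP6f-like) are chosen so that the event duty cycle
  stays low: the detection rule computes per-pixel statistics over *all*
  frames, so a slow indicator at a realistic event rate would inflate
  every pixel's SD with event variance until no pixel could ever sit
  3 SD above its mean — the detector's implicit assumption is
  quiet-dominated statistics, and the generator must honor it to be a
  valid recovery target.
- **Event shape.** The planted \(\Delta F/F\) frame is a monotone
  transform of the mixed pattern: shift by one SD, rectify,
  peak-normalize, and compress (`shape_offset_sd = 1`,
  `shape_compress = 0.4`). This gives events the broad active pedestal
  with modular peaks that real event frames show (a pure rectified
  Gaussian field puts well under half its pixels above 30% of peak, so
  the >40%-active criterion could never fire); the module-amplitude
  statistic, a peak-to-background *ratio*, is only meaningful with a
  nonzero pedestal. Module geometry is unchanged by the transform.
- **Cellular traces.** Cells are placed uniformly in a central 1 mm
  region and sample the event shapes by bilinear interpolation; the raw
  trace adds a local neuropil signal (disk average, 20 µm) weighted by
  `neuropil_weight` and white cell noise (`cell_noise_sd`, relative to
  the event amplitude; default 0.1, calibrated so nearby pairwise
  correlations land in the 0.5–0.8 range reported for developing
  cortex). A `salt_and_pepper` flag permutes the cell *positions* while
  leaving every trace untouched — the exact control for locally
  coherent organization.

What the generator does **not** emulate: hemodynamic signals, motion
beyond rigid translation, spiking statistics, multi-area geometry, or
history-dependent event amplitudes. Passing tests on this generator
therefore demonstrate that the estimators recover known structure under
the model's assumptions — not that real recordings satisfy those
assumptions.

## Numerical choices

- **Mask-aware filtering.** The Gaussian band-pass is implemented as
  two FFT low-passes with mask normalization (blur of masked data
  divided by blur of the mask), so irregular ROI edges neither leak
  zeros in nor darken the boundary. The spatial autocorrelation divides
  the lag-domain correlation sum by the overlap pair count before
  normalizing to 1 at zero lag.
- **Radial profiles** use one-pixel annuli with parabolic (three-point)
  refinement of extrema, which removes most of the grid quantization of
  \(\Lambda\). The "subsequent maximum" entering modularity is the
  *global* maximum beyond the first minimum: sparse annuli produce
  one-bin ripples of order 0.01 around the trough, and taking the first
  strict local maximum would measure ripple amplitude instead of the
  rebound peak.
- **Module-amplitude peaks** are local maxima of a lightly smoothed
  copy (SD \(\Lambda/8\)) above the frame median + 1 MAD. The reference
  peak finder used in this literature is an external routine with
  unspecified parameters; our criterion is explicit, and the 1-MAD
  default matters — broad event frames have a frame-wide MAD so large
  that stricter thresholds reject every module peak.
- **Surrogates** rotate band-pass-filtered patterns about the ROI
  centroid (multiples of 10°, reflections with probability 1/2 per
  axis) with bilinear interpolation; target pixels whose source support
  leaves the ROI are undefined and excluded, never filled. Transform
  maps are cached (at most 144 distinct transforms).
- **Registration** is integer-pixel only; at ~19 µm pixels, sub-pixel
  residuals are negligible for every downstream statistic.
- **p-values** from \(n\) surrogates are counting fractions
  (\(\geq\)-tie convention); the raw fraction can be 0 and is reported
  alongside a value floored at \(1/n\), the resolution of the null
  sample.
- **Cross-validated spectra** clip negative projected variances at zero
  before the participation ratio (they arise from finite-sample
  cross-validation noise and would make the ratio ill-defined);
  ensembles are mean-centered per pixel before splitting. Widefield
  dimensionality averages over 20 seeded splits.
- **Determinism.** Every stochastic step derives its seed from the
  global seed and a stage label, so a run is a pure function of its
  configuration; generators save and restore the global RNG state.
- **Degenerate inputs** are first-class: zero-variance pixels are
  undefined (not errors) in correlation fields but a zero-variance
  *seed* is an error; constant patterns cannot enter the
  autocorrelation; events with no first minimum inside the profile are
  flagged and excluded from medians with a QC count.

## Problem sizes and defaults

The shipped tests exercise the full 160×135 analysis grid (18.75 µm
pixels, ~3.0 × 2.5 mm): wavelength recovery on 100 single-basis fields;
modularity significance on a 100-event movie against 100
event-count-matched control sets drawn from the bottom activity decile
(that movie uses the generator's planted event times and a 6.7 s event
spacing, keeping the movie near 10,000 frames; detection itself is
validated separately on 20 events at the default 30 s spacing, where it
recovers every event exactly); the long-range band against 100
rotation/reflection surrogates with a 6-pixel seed stride; and
dimensionality recovery from 400 events. Seed-grid stride and all null
ensemble sizes are configuration, not constants.

## Known limitations

- The baseline window (10–23 s) is exposed as configuration; the
  original selection rule is visual and per-session, and no automatic
  selection is attempted.
- Only rigid translation is corrected; non-rigid motion must be handled
  upstream.
- Post hoc pairwise tests after Kruskal–Wallis are not implemented;
  `compare_groups()` reports the omnibus test only.
- Cell segmentation and 2-photon-to-widefield alignment are inputs, not
  computations.

## A minimal end-to-end run

```{r, eval = FALSE}
library(modcortex)

cfg <- run_config(synth = synth_params(n_events = 20, seed = 1),
                  n_surrogates = 100, seed = 1)
report <- run_widefield(cfg, out_dir = "wf_run")
report

p <- cfg$synth
truth <- synth_event_truth(p)
cells <- synth_cell_recording(p, truth)
run_cellular(cfg, cells$recording)
```
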