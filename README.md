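# modcortex

Analysis of modular spontaneous activity in calcium-imaging recordings
of developing cortex.

Before sensory experience, cortical activity is dominated by spontaneous
events in which activity organizes into patchy, quasi-periodic modules
spanning millimeters. `modcortex` is for researchers who record such
activity with widefield or two-photon calcium imaging and want to
quantify it with a tested, reproducible pipeline:

- **Preprocessing**: phase-correlation registration, running-median
  baseline, ΔF/F₀ = (F − F₀)/F₀.
- **Event detection**: per-pixel thresholds (mean + 3 SD), 0.01 mm²
  minimum contiguous area, >40% of ROI pixels active per event frame;
  runs split at local minima; each event summarized by its maximally
  active frame.
- **Modular structure**: wavelength Λ (twice the radius of the first
  minimum of the radially averaged spatial autocorrelation), modularity
  (first-minimum-to-rebound excursion of that profile) with a
  control-frame bootstrap null, and module amplitude (peak ΔF/F over
  the median on the annulus at Λ/2).
- **Correlation networks**: seed-point Pearson correlation fields
  C(**x**, **s**) across band-pass-filtered event patterns; local
  maxima (800 µm minimum separation) pooled over seeds and binned by
  distance; significance of long-range (1.8–2.2 mm) correlations
  against random rotation/reflection surrogate ensembles, plus a
  surrogate-subtracted variance-ring alternative.
- **Dimensionality**: cross-validated participation ratio
  d_eff = (Σλ)² / Σλ², with λ the variances of held-out patterns
  projected on training-half principal axes.
- **Cellular coherence**: neuropil correction
  F_cell = F_raw − 0.4·F_neuropil, cellular event detection (2 SD, >5%
  of cells), pairwise correlations of per-frame z-scored event
  activity, a within-cell shuffle null, distance-binned correlations,
  and the local coherence index LCI = (N₊ − N₋)/(N₊ + N₋).
- **Synthetic data**: a generator of modular movies and cellular
  recordings with full ground truth (ring-spectrum Gaussian random
  fields, controllable wavelength and dimensionality, calcium kinetics,
  neuropil contamination, salt-and-pepper controls), so every stage is
  verifiable without experimental data.

## Worked example

Generate a synthetic session with 12 planted events on the standard
160×135 analysis grid and run the widefield pipeline end to end:

```r
library(modcortex)

cfg <- run_config(synth = synth_params(n_events = 12, seed = 7),
                  n_surrogates = 50, n_control_sets = 50, seed = 7)
report <- run_widefield(cfg)
report
#> <run_report>
#>   n_events                 12
#>   wavelength_mm_median     1.044
#>   modularity_median        0.5356
#>   modularity_p             0
#>   module_amplitude_mean    3.203
#>   longrange_median_r       0.763
#>   longrange_p              0
#>   d_eff                    4.538
#>   n_variance_75            3.7
#>   n_flagged_no_minimum     0
```

Reading the numbers: all 12 planted events were detected; the median
estimated wavelength (1.04 mm) is close to what an unbiased estimator
should report for the planted 0.9 mm ring spectrum (the first
autocorrelation minimum of such a field sits at 0.61·Λ_F, so the
target is 1.22·Λ_F ≈ 1.10 mm); the events are strongly modular while
none of the 50 low-activity control sets comes close (p = 0, i.e.
< 1/50); module peaks run ~3.2× the inter-module background; the
median correlation at maxima 1.8–2.2 mm from the seed (0.76) exceeds
every rotation/reflection surrogate (p = 0); and the cross-validated
participation ratio (~4.5) reflects the handful of basis patterns that
dominate a 12-event ensemble drawn from 8.

The cellular branch runs from the same ground truth without
materializing a movie (with only 13 detected cell events, the
dimensionality subsample shrinks to the data, with a warning):

```r
truth <- synth_event_truth(cfg$synth)
cells <- synth_cell_recording(cfg$synth, truth)
run_cellular(cfg, cells$recording)
#> <run_report>
#>   n_events                 13
#>   nearby_r_mean            0.766
#>   nearby_r_median          0.7826
#>   shuffle_p                0
#>   lci_nearby               1
#>   lci_zero_crossing_um     342.9
#>   cellular_d_eff           3.881
```

Nearby cells (30–100 µm) co-fluctuate strongly (mean r = 0.77, every
within-cell shuffle falls below the real statistic), the local
coherence index is 1 in the nearest annulus, and its sign flip at
~343 µm matches the first zero of J0(2πr/0.9 mm) at 344 µm.

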