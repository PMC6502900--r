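---
title: "Ridge tracing and relative quantification for CIVM-NMR time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ridge tracing and relative quantification for CIVM-NMR time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(civmtrace)
```

## The measurement and the analysis problem

Continuous in vivo metabolism NMR (CIVM-NMR) records a 1D ^1^H spectrum every
few minutes on a living sample — cells or a piece of tissue — spinning in an
HR-MAS rotor, for hours. The result is a dense spectral time series: a
T × P matrix of intensities over a shared chemical-shift axis, with one row
roughly every 4 minutes over an 11-hour run. Two features make these data
different from ordinary 1D metabolomics spectra:

* **Peaks drift.** Chemical shifts of organic acids and other ionisable
  metabolites respond to pH and ion content, and the culture acidifies as it
  ferments. A peak is therefore not a fixed position but a *ridge* through
  (ppm, time, intensity) space. Because acquisition is continuous, peak
  identity across adjacent timepoints is unambiguous, so ridges can be
  *traced* instead of aligning spectra — alignment artefacts never arise.
* **Heights are relative.** With a constant 1 mM DSS reference in the medium,
  normalising every spectrum to its own DSS peak height makes heights
  comparable across time and samples without absolute calibration.

`civmtrace` implements the downstream analysis of such series: the
post-acquisition processing chain, semi-automated ridge tracing, compositing
of several ridges of one compound into a single relative-concentration
trajectory, and pH estimation from the drift of a titrated reference peak.
Upstream FID processing (apodisation, Fourier transform, phasing, baseline
correction) is deliberately out of scope: the package consumes
frequency-domain spectra, and rejects time-domain input.

## The processing chain

`preprocess_pipeline()` applies six stages in a fixed order:

1. **DSS referencing** (`reference_to_dss`): per spectrum, the maximum within
   ±0.25 ppm of 0 is shifted by *whole axis indices* onto the axis point
   nearest 0 ppm. Index shifting (rather than sub-index re-interpolation)
   preserves raw intensities exactly, which matters because all downstream
   quantification is maximum-based. A per-spectrum override table supplies
   the manual half of "semi-automatic" referencing.
2. **End trimming** (`trim_ppm`): only [−0.5, 10] ppm is kept. All intervals
   in the package are closed on both ends.
3. **Water zeroing** (`zero_region`): [4.7, 5.0] ppm is replaced by exact
   zeros; residual water suppression signal is meaningless.
4. **Time truncation** (`truncate_time`): timepoints after 11 h are dropped,
   keeping runs comparable.
5. **DSS normalisation** (`normalize_to_reference`): each spectrum is divided
   by its own DSS window maximum, which becomes exactly 1.0.
6. **Block summation** (`block_sum`): every 3 consecutive spectra are summed
   (≈ 4.23 min → ≈ 12.7 min effective resolution) to improve S/N. The
   trailing incomplete block is dropped — a partial block would have
   different noise characteristics from its neighbours — and a summed
   spectrum carries the mean of its constituent times.

The order matters and is tested by counterexample: normalisation does not
commute with summation whenever the reference height varies within a block,
while trimming, zeroing and truncation commute freely with each other.

A reference peak is "detectable" when the window maximum exceeds 5× the
median absolute intensity in the window; below that floor, referencing and
normalisation raise an error naming the offending timepoint rather than
silently normalising to noise.

## Ridge tracing

`trace_region()` operates on one user-chosen region of roughly 0.5–1 ppm at
a time, because clustering weights and cluster counts are region-specific
choices. The stages:

1. **Smoothing** (`gaussian_smooth_2d`): separable Gaussian convolution
   along ppm then time, with user sigmas in physical units (ppm, hours).
   Kernels are sampled on the grid spacing, truncated at 4σ, normalised to
   unit sum; boundaries replicate the edge value, so constants are
   preserved. The smoothed surface only guides picking and clustering —
   reported intensities always come from the raw data.
2. **Peak picking** (`pick_local_maxima`): per timepoint, interior strict
   local maxima along ppm at or above `peak_floor`. The default floor of 0
   is deliberately permissive: stray noise picks land in their own clusters
   or are rejected at visual QC, whereas a high floor silently truncates
   ridges of depleting metabolites.
3. **Clustering** (`cluster_peak_points`): each dimension (ppm, time,
   smoothed intensity) is min–max scaled to [0, 1] over the picked point
   set, multiplied by its weight, and points are merged by single-linkage
   agglomeration on Euclidean distances. Min–max scaling makes the weights
   dimensionless and portable across regions of different widths and
   intensity scales; weights of `(1, 1, 0.3)` are a sensible starting point
   — intensity helps separate crossing ridges but should not dominate.
   The number of clusters is normally chosen by the analyst per region
   (`n_clusters`); a linkage-distance cut (`linkage_cut`) is offered as an
   automated alternative. Smoothed (not raw) intensities enter the
   clustering space, consistent with picking being performed on the
   smoothed surface.
4. **Ridge building** (`ridges_from_clusters`): within a cluster, at most
   one point per timepoint is kept — the highest smoothed intensity, ties
   broken toward higher ppm (an arbitrary but deterministic rule). Interior
   temporal gaps are filled by points whose *position* is linear in time
   between the flanking retained points; gaps before the first or after the
   last retained point are never extrapolated.
5. **Mapping** (`map_ridge_to_raw`): every point, interpolated ones
   included, is re-localised on the raw data as the maximum within a
   window of `map_window_indices` total width (±⌊w/2⌋ indices, default 10
   ≈ 2.9 × 10⁻³ ppm at typical resolution, validated to [1, 60]) around
   the smoothed position. Interpolated positions therefore acquire *raw*
   intensities — interpolation estimates where the peak is, the data say
   how high it is. Mapping can only increase the reported intensity
   relative to the unrefined position, a tested monotonicity.

Visual inspection of ridges is represented programmatically: `qc_ridges()`
flags rejected ridge ids rather than deleting them, keeping decisions
auditable.

The algorithm assumes low peak overlap. The `crowded_region` fixture — two
peaks closer than their linewidth — documents the failure mode: maxima
merge, and the method has no deconvolution to fall back on.

## Compositing multiple ridges of one compound

Most metabolites have several resonances. For ridges annotated to the same
compound, `shared_timepoints()` finds the timepoints attained by the
largest number of ridges, `scale_factors()` rescales each ridge by
(highest support mean)/(its own support mean) — so all support means become
equal, with the strongest ridge untouched — and `composite_trajectory()`
takes the per-timepoint mean of the scaled ridges. At timepoints covered by
only some ridges the mean is over those present; `n_contributing` exposes
that count so users can mask thinly supported times. Ridges that share no
timepoints at all cannot be scaled onto a common footing, and the package
raises an error rather than guessing a factor. Interpolated points
participate by default and can be excluded with a flag.

## pH from chemical shift

A cubic `ppm = f(pH)` is fit by least squares to a titration table of a
standard (`fit_titration`); the fit must be strictly monotone over the
calibrated range or it is rejected as a calibration error, because
monotonicity is what makes inversion well defined. `ppm_to_ph()` inverts
the cubic by bisection on the calibrated range to 10⁻⁶ pH. Positions
outside the calibrated ppm span are an error: titration behaviour beyond
the measured range is not safe to assume, so the package never
extrapolates. The shipped citrate titration table
(`fixture_citrate_titration()`, also under `inst/extdata/`) is *synthetic*
— generated from a fixed monotone cubic — and is labelled as such; it
stands in for an instrument-specific in-house titration.

## The synthetic generator and what passing tests mean

`simulate_series()` produces series with known ground truth: Lorentzian /
Gaussian / pseudo-Voigt peaks parameterised by *height* (matching the
maximum-based quantification), centres following constant, linear,
sigmoidal, or pH-schedule-through-a-cubic drifts, heights following
constant, logistic growth/depletion, or exponential-decay trajectories,
plus a constant DSS anchor at 0 ppm, an optional polynomial baseline, and
seeded i.i.d. Gaussian noise. Defaults mirror the acquisition geometry the
package targets: 4.23-min spacing over 11 h, ~2.9 × 10⁻⁴ ppm/point, so
tests exercise realistic index arithmetic. Several peaks may share one
concentration trajectory with different response factors, which is exactly
the situation compositing must undo.

The standard fixtures are: `two_drifting_peaks` (drift ≤ 0.03 ppm over
11 h, smooth height trajectories; tracing recovery), `glucose_ethanol`
(logistic depletion reaching ≈ 0 near 6 h and an inverse rise; compositing
and end-to-end), `ph_drift_citrate` (sigmoidal pH schedule 6.3 → 5.3,
midpoint 3 h, mapped through the fixture cubic), and `crowded_region`
(the documented overlap failure). Amplitude trajectories in
`two_drifting_peaks` were given non-constant shapes so that a Pearson
correlation against ground truth is well defined.

What the generator does *not* emulate bounds what green tests prove:
no J-coupling multiplets, ¹³C satellites, spinning sidebands, field
inhomogeneity, baseline roll from imperfect phasing, or amplitude-dependent
lineshape changes. Recovery results on fixtures demonstrate the algorithm's
correctness on isolated-to-moderately-drifting peaks with realistic noise,
not its behaviour on heavily overlapped real spectra — the visual-QC hooks
exist precisely because real data need them.

## Numerical choices

* Canonical ppm orientation is **descending** everywhere (NMR display
  convention); readers and constructors canonicalise, eliminating axis-sign
  branches in windowed searches.
* Times are hours, relative to a user-supplied origin; per-sample offsets
  (e.g. between inoculation and first acquisition) are folded into the
  origin.
* The delimited series interchange format writes 17 significant digits so
  round trips are bitwise; the NMRPipe 1D reader/writer is exact to the
  format's float32 storage.
* Smoothing kernel truncation at 4σ loses < 10⁻⁶ of unit mass; edge
  replication was chosen over zero padding so smoothing never depresses
  intensities at region borders.
* Equal-intensity ties in deduplication break toward higher ppm;
  `which.max`-style ties elsewhere take the first (downfield) candidate —
  deterministic by construction, and determinism is tested end to end
  (identical seed + configuration → hash-identical tabular outputs).
* g₀ = 9.81 m s⁻² and M(D-glucose) = 180.16 g mol⁻¹ in the experiment
  arithmetic; these reproduce the conventional rounded planning figures.

## Problem sizes used in the shipped checks

Unit tests run on reduced axes (600–4500 points) for speed; the tracing
recovery, compositing and pH checks run the full-geometry fixtures
(≈ 15 500 points × 157 timepoints before block summation, 52 after). The
clustering implementation is verified against an exhaustive single-linkage
oracle on 1000 seeded random instances of up to 200 points in the test
suite (200 instances in the standalone acceptance script). On one CPU the
whole suite completes in well under a minute.

## Limitations

* No deconvolution: overlapping peaks closer than their linewidth merge.
* No automatic annotation of ridges to compounds; annotation maps are user
  input.
* No absolute concentrations — everything is relative to DSS height.
* The pH module reproduces the *mechanism* (calibrate, trace, invert), not
  any particular culture's pH values, which depend on instrument-specific
  titrations and raw spectra.
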