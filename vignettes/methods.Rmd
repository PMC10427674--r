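---
title: "Models and design choices in hypoxamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in hypoxamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxamap)
```

# What the package computes

`hypoxamap` analyzes dual-modality widefield acquisitions of the mouse
dorsal cortex: a blue-excited GCaMP fluorescence channel reporting neuronal
activity, interlaced with green (535 nm), amber (590 nm) and red (620 nm)
reflectance channels reporting hemodynamics. The camera runs at 80 Hz and
cycles through the four LEDs, so each color is sampled at 20 Hz. The
experimental protocol alternates normoxia and a 10-minute hypoxia epoch
(12, 10 or 8 % inspired oxygen) inside a 40-minute acquisition.

Two families of outputs are produced:

* **Hemodynamics** — per-pixel changes in oxy-, deoxy- and total hemoglobin
  (∆HbO, ∆HbR, ∆HbT, µM) and oxygen saturation sO2 = HbO/HbT, via the
  modified Beer–Lambert law, summarized as whole-brain traces with plateau /
  dip / overshoot statistics.
* **Connectivity** — band-passed ∆F/F seed time courses for 8 pooled
  cortical regions (left/right Motor, Somatosensory, Retrosplenial, Visual),
  seed-pixel correlation maps, seed-pair correlation matrices in matched
  normoxia (min 2.5–7.5) and hypoxia (min 12.5–17.5) windows, and their
  Fisher-z contrasts with exact nonparametric statistics.

Because the in-vivo recordings behind the original study are not public,
the package ships a forward simulator (`simulate_acquisition()`) that
generates the full acquisition with known ground truth; every analysis
stage is validated against it.

# The optical model

The modified Beer–Lambert law relates reflectance changes to chromophore
concentration changes:

$$-\log\frac{R_\lambda(t)}{R_\lambda(0)} = D_\lambda\,\big(\varepsilon_{HbO,\lambda}\,\Delta HbO + \varepsilon_{HbR,\lambda}\,\Delta HbR\big)$$

with wavelength-specific molar extinction coefficients
$\varepsilon$ (cm⁻¹ M⁻¹) and differential pathlength factors $D_\lambda$
(cm). The inverse problem has three equations (green/amber/red) and two
unknowns per pixel and frame; `beer_lambert_invert()` solves it by ordinary
least squares, which uses all channels and degrades gracefully when one is
noisy. Baselines are the assumed resting concentrations HbO₀ = 60 µM and
HbR₀ = 40 µM, so baseline saturation is exactly 60 %.

Numerical choices:

* $R_\lambda(0)$ is the per-pixel temporal **mean over the first normoxia
  epoch** (trimmed by the transition margin). A mean is robust to frame
  noise and matches the "∆ relative to baseline" semantics of the summary
  statistics.
* The extinction table (`default_extinction_table()`) uses the standard
  compiled hemoglobin spectra evaluated at the LED center wavelengths; LEDs
  are treated as monochromatic (their spectral bandwidth is not modeled).
  Pathlength factors default to 0.05/0.07/0.30 cm for 535/590/620 nm —
  weakly absorbed red light travels much deeper — and are configurable.
  Since the simulator's forward model and the inversion share the same
  table, validation results do not depend on the specific values, only on
  the conditioning of the 3×2 system (reported as `condition_number`).
* Pixels with non-positive counts (possible after sensor-noise clipping)
  are removed from the brain mask rather than patched.

# Hemodynamic correction of fluorescence

Hemoglobin absorbs at both the GCaMP excitation (475 nm) and emission
(~515 nm) bands, multiplicatively contaminating the fluorescence signal.
`hemodynamic_correction()` regresses each pixel's fluorescence trace on its
three reflectance traces plus an intercept and keeps the residual (plus
intercept, preserving the intensity scale for ∆F/F). This "blind" approach
needs no baseline-concentration or pathlength assumptions. The regression
is fitted on the whole acquisition by default; `fit_frames` can restrict
the fit to normoxia epochs to avoid absorbing hypoxia-driven neural
covariance, but the default follows the simpler whole-acquisition
description. On a simulated zero-signal analog (a GFP-like indicator with
hemodynamic contamination but no neural fluctuations, rendered without
sensor noise so the measured quantity is the contamination itself) the
correction removes > 95 % of the temporal standard deviation per pixel;
any additive sensor noise would be — correctly — retained.

∆F/F (`compute_dff()`) follows the band-pass convention: the baseline F₀ is
the < 0.3 Hz low-pass of each pixel's trace and the signal of interest the
0.3–3 Hz band-pass; ∆F/F = band(F)/F₀. Filters are 4th-order Butterworth
applied forward-backward (zero phase). Traces are mean-centered and
odd-reflection padded before `signal::filtfilt`, so a constant input maps
to exactly zero and filter edge transients stay negligible.

# Registration

Every frame is co-registered to the first frame of the acquisition with a
2-D affine transform minimizing the mean squared error (Nelder–Mead over
the 6 parameters, initialized by an exhaustive integer-translation search
and a continuous translation refinement). Both images are Gaussian
pre-smoothed (σ = 1 px) during optimization: bilinear interpolation
attenuates high frequencies in a way that depends on the fractional shift,
and without pre-smoothing this biases the MSE optimum toward integer
offsets. An optional second stage estimates a coarse, smoothness-
regularized displacement field (local block matching on a 5×5 grid,
Gaussian-smoothed and bilinearly upsampled) standing in for a full
diffeomorphic refinement; frames are resampled once through the composed
transform. Any frame whose registration would *increase* the MSE keeps the
identity transform, so registration can never degrade a stack. Sessions of
the same subject are aligned to the subject's first acquisition with the
same machinery (`register_between_days()`), and atlas labels are carried
across with nearest-neighbor resampling (`map_atlas()`).

# Connectivity and statistics

Seeds are 3-pixel-radius lattice disks (29 pixels unmasked) around the
integer-rounded centroid of each atlas region; the seed time course is the
unweighted mean over the disk ∩ brain mask. Correlation matrices use
Pearson correlation of the band-passed ∆F/F (or ∆HbO) time courses over
minute windows, without further detrending; Fisher z = atanh(r) with |r|
clipped at 1 − 10⁻¹² so degenerate perfect correlations stay finite.
Global signal regression (per-pixel OLS on the mask-mean trace) is applied
**only** to seed-pixel correlation maps; all quantitative statistics run on
non-GSR data.

Epoch contrasts subtract the Fisher-z matrices of matched hypoxia and
normoxia windows per subject. Across subjects each of the 28 unique pairs
is tested with the **exact** Wilcoxon signed-rank test and
Benjamini–Hochberg adjusted. The exact test matters: at the study's n = 8,
the smallest attainable two-sided p is 2/2⁸ = 0.0078125, which is also the
q floor when all pairs move in the same direction; a normal approximation
misstates exactly this regime. The implementation enumerates the signed-
rank distribution by dynamic programming over doubled (tie-averaged) ranks,
so ties are handled exactly; above n = 25 it switches to the tie-corrected
normal approximation. Within- vs between-macrocluster changes
(anterior = Mot + Sen, posterior = Ret + Vis; 12 and 16 pairs) are compared
per condition with a two-sample t-test on per-subject means, gated by a
Kolmogorov–Smirnov normality check (computed with estimated parameters —
the Lilliefors caveat applies and is accepted for fidelity to the original
procedure) and an F-test of variance homogeneity (Welch otherwise). All
tests are two-sided. Longitudinal stability of normoxia connectivity is
screened with a Friedman test per pair across weeks (BH over the 28
pairs), followed for significant pairs by Kruskal–Wallis tests of each week
against week 1.

Whole-brain hemodynamic summaries exclude values more than 3 standard
deviations from the trace mean (single pass), use minutes 14.5–19.5
(plateau) vs 4.5–9.5 (baseline), the minimum in a one-minute window after
hypoxia onset (dip) and the maximum in minutes 20–21 (overshoot); the
dip/peak window width is not prescribed anywhere and defaults to 60 s.
Outlier exclusion operates on the whole-brain mean trace, where the
statistic is consumed; a per-pixel variant would also be defensible but is
not what the summary statistics need.

# The forward simulator

The simulator is organized so each downstream stage has a recoverable
target:

* **Calcium** (`simulate_calcium()`): per-region ∆F/F traces are
  band-limited (0.3–3 Hz) Gaussian processes mixed by the Cholesky factor
  of a block target correlation matrix — `within_cluster_r` inside a
  macrocluster, `between_cluster_r` across, dropping to
  `between_cluster_r_hypoxia` during hypoxia. The band-limited noise is
  *empirically whitened per epoch segment* before mixing, so the epoch-wise
  empirical correlation equals the target almost exactly while sub-windows
  retain natural sampling variability. An infeasible (non-PSD) target fails
  naming the most implicated region pair. Default trace amplitude is 2 %
  ∆F/F.
* **Hemodynamics** (`simulate_hemodynamics()`): a global epoch-driven ramp
  plus a local neurovascular component. The ramp is piecewise-exponential:
  ∆HbR rises with τ = 20 s to its plateau (10.9/13.4/21.2 µM for 12/10/8 %
  oxygen — the reported group means); ∆HbO dips briefly (gamma-shaped,
  τ = 15 s) then rises slowly (τ = 60–200 s, slower at lower oxygen) toward
  7.8/20.0/28.0 µM; on return to normoxia the plateau decays (τ = 25 s)
  with an HbO overshoot and an HbR undershoot scaled by severity. At 21 %
  oxygen every amplitude is zero. The local component convolves each
  region's calcium trace with a gamma kernel (peak delay 1.5 s, FWHM ≈ 2 s)
  at 0.5 µM ∆HbO per calcium standard deviation and an HbR:HbO ratio of
  −0.4 — conventional rodent widefield values, since the source protocol
  prescribes none.
* **Optics** (`render_optics()`): the Beer–Lambert forward model generates
  the three reflectance channels; fluorescence is F₀(1 + ∆F/F) attenuated
  by the mean excitation/emission extinction. A shared smooth random
  texture (15 %) gives frames the spatial structure registration needs;
  Gaussian sensor noise, optional smooth rigid motion and interleaving in
  the fixed order blue→green→amber→red at 80 Hz complete the stack.
  Negative post-noise intensities are clipped at zero with a logged count.

What the simulator does **not** emulate: vascular anatomy (the "sinus" is a
simple midline stripe), spatially heterogeneous hemodynamics, pathlength
dispersion, photon noise statistics (noise is additive Gaussian, not
Poisson), behavioral artifacts, and slow photobleaching. Passing tests
therefore demonstrate correctness of the computational chain under the
stated physics, not robustness to every property of in-vivo data; the
reported in-vivo group values depend on the original recordings and are
used here only as simulator parameters.

# Problem sizes and determinism

Unit tests run the full chain at reduced scale (12–96 px images, tens of
seconds to a few simulated minutes, region-trace cohorts at full 40-minute
length where the protocol windows matter); these sizes were chosen so the
suite exercises every stage in a couple of minutes while estimates stay
well inside their tolerances. All randomness flows through
`rng_seed` (simulations are bit-reproducible), and `run_pipeline()` writes
a manifest with config hash and per-artifact checksums so identical
configurations yield identical outputs.

# Known limitations

* The diffeomorphic refinement is a coarse block-matching field, adequate
  for the small smooth deformations it is asked to absorb, not a general
  deformable registration.
* The Beer–Lambert inversion assumes the baseline concentrations and
  pathlengths globally; absolute (non-∆) concentrations are out of scope.
* Blood-flow (speckle) measurements, spike inference, graph-theoretic
  connectivity metrics and ICA-based network discovery are out of scope.
* With fewer than 5 subjects the contrast functions report estimates but
  skip inferential tests.
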