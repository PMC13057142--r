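---
title: "Quality control of mid-infrared spectra: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of mid-infrared spectra: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirqc)
```

## The problem

Spectral libraries of organic matter (peat in particular) collect
mid-infrared (MIR) spectra measured over decades on different FTIR
instruments, under different purge conditions, and at different stages of
preprocessing. Before such spectra can be compared or used to train
prediction models, four questions must be answered per spectrum:

1. Was it already baseline corrected before archiving?
2. How much residual atmospheric **water vapor** does it carry?
3. How much residual atmospheric **CO₂** does it carry?
4. How noisy is it?

`mirqc` computes one quantitative indicator for each question, on a common
footing provided by two primitives: rubberband baseline correction and a
total-area normalizer.

## Primitives

**Rubberband baseline.** The baseline of a spectrum is the piecewise-linear
interpolation between the vertices of the lower convex hull of its
`(wavenumber, intensity)` points (computed by a monotone-chain scan, which
is deterministic and exact). The corrected spectrum is the input minus this
baseline: nonnegative everywhere, zero at the hull touch points, and zero at
both ends. Because a convex hull commutes with the addition of any affine
function, every indicator built on it is invariant under affine baseline
shifts — a property the test suite checks directly.

**Total area A.** All artifact indicators are expressed *relative to the
spectrum's total signal*, defined as the sum of intensities after
(1) clipping to [699, 3999] cm⁻¹, (2) replacing the CO₂ doublet region
[2250, 2450] cm⁻¹ by a straight line (negative CO₂ peaks would otherwise
drag the hull down and corrupt the baseline), and (3) rubberband
correction.

## The four indicators

**Baseline-correction detector.** Organic-matter spectra that were *not*
baseline corrected have large baseline absorbances toward low wavenumbers.
The detector computes the rubberband baseline of the CO₂-interpolated,
clipped spectrum, clips that baseline to [1400, 3400] cm⁻¹ (a range covered
by essentially all archived spectra, giving a uniform reference range),
divides by A, and reads the value at 1400 cm⁻¹ (`i1400`). Spectra with
`i1400 ≤ t_bc = 9e-5` are classified as already corrected. Note the
orientation: corrected spectra sit *below* the threshold. Both `i1400` and
the flag are reported, so the opposite convention can be re-derived.

**Artifact contributions.** For each gas the spectrum is clipped to a
diagnostic region where organic matter is transparent — [3780, 3920] cm⁻¹
for water vapor (diagnostic peak 3853 cm⁻¹), [2250, 2450] cm⁻¹ for CO₂
(peak 2362 cm⁻¹) — and baseline corrected *with sign awareness*: if the
intensity at the diagnostic peak lies below the chord joining the region
endpoints, the artifact is negative (the background scan contained more gas
than the sample scan), and the region is negated, hull-corrected, and
negated back. The extracted region, divided by A, is regressed by ordinary
least squares (with intercept) on the reference spectrum's region processed
through the *identical* path. The slope `c` is the relative contribution;
its classical standard error is reported alongside. By construction the
reference itself yields `c = 1` exactly with `se = 0` — the package
computes the slope by the closed-form centered-sum formula precisely so
this identity is float-exact.

**Noise.** After clipping, CO₂ interpolation and rubberband correction, a
Savitzky–Golay smooth (window 21 points, order 3) estimates the local
average intensity; the smoothing residual, divided by the sum of the
corrected intensities, is the relative noise component. Its variance over
[2700, 2750] cm⁻¹ — a range free of sharp organic-matter and water-vapor
peaks — is `c_noise`. The window/order default passes broad organic bands
(widths ≳ 25 cm⁻¹) into the smooth part while leaving grid-scale noise in
the residual; both are exposed in `qc_config()`. The division by the
corrected-intensity sum (rather than the residual's own sum, which is ~0 by
construction) makes `c_noise` scale-free.

## Reference spectra from background scans

Pure-gas spectra measured on every instrument are rarely available, so the
references are derived from pairs of single-beam background scans recorded
on the same device under different gas concentrations:

- **CO₂**: ratio the scans, convert to absorbance, interpolate to a
  1 cm⁻¹ grid, replace [728, 2230] and > 3800 cm⁻¹ (regions without CO₂
  bands) by straight lines, rubberband correct.
- **Water vapor**: same start, but no straight-line replacement; instead an
  atmospheric correction with the CO₂ reference (OLS scale over
  [2250, 2450] cm⁻¹) removes residual CO₂. Negative values are then removed
  by dividing so the broadband level at 2000 cm⁻¹ — a wavenumber free of
  gas lines — equals 1, subtracting 1, and clamping at 0; finally
  [600, 1200] and [2200, 3300] cm⁻¹ are replaced by straight lines. The
  result is nonnegative with value exactly 0 at 2000 cm⁻¹.

The anchor normalization is applied at the absorbance stage *after* the
atmospheric correction but *before* any baseline correction: the anchor
reads the broadband throughput offset between the two scans, which a
baseline correction would have removed, making the division ill-posed. This
also fixes the scan order convention: the first scan of a pair is the one
with the higher gas concentration, so the absorbance of the ratio carries
positive gas lines and a positive offset.

A device→reference YAML lookup assigns references to instruments, with a
declared default (and a warning) for devices lacking their own background
scans, mirroring how archived libraries reuse references across devices.

## The synthetic generator

Every indicator is validated on synthetic spectra with known ground truth;
no real database is needed. The generator emulates:

- **Organic bands**: eight Gaussians (3400, 2920, 2850, 1720, 1630, 1510,
  1420, 1090 cm⁻¹) with the O–H stretch comparable in height to the
  polysaccharide band, as in real peat spectra; default overall scale gives
  A ≈ 100.
- **Artifacts**: a water-vapor comb of narrow (sd 2 cm⁻¹) lines spanning
  1300–1900 and 3500–3920 cm⁻¹ with its maximum at 3853 cm⁻¹, and a CO₂
  doublet at 2340/2362 cm⁻¹ plus the 668 cm⁻¹ bending band.
- **Background pairs**: a smooth source-emission envelope in transmission,
  attenuated in one scan by the gas combs plus a broadband drift
  (absorbance offset 0.012), with transmission noise 1e-4.
- **Noise**: iid Gaussian intensity noise, default sd 1e-3 — a typical
  noise floor for a transmission FTIR scan at this intensity scale.

All randomness flows through an explicitly seeded generator per call; the
global RNG state is saved and restored.

`inject_artifact()` adds a gas artifact of *known relative contribution*:
the injected scale is solved by a fixed-point iteration on the actual total
area, because the injected intensity itself enlarges A for regions outside
the CO₂ interpolation range. This makes the linearity of the estimator
testable: recovered `c` tracks injected α one-to-one.

What the generator does **not** emulate: instrument line-shape functions and
resolution effects, HITRAN-accurate line positions/strengths, ATR
penetration-depth distortions, scattering baselines, and detector
nonlinearity. Passing tests therefore demonstrate the correctness and
calibration of the *algorithms*, not robustness to every instrumental
artifact of real archives.

## Numerical choices and degenerate inputs

- Wavenumber intervals are closed; grids ascend; interpolation is linear
  with no extrapolation; lookups use the nearest grid point with ties
  toward the lower wavenumber.
- Transmission values below 1e-8 are clamped before the logarithm.
- Interior missing values are bridged linearly during grid interpolation;
  leading/trailing missing values are dropped.
- The extraction sign test compares the single grid point nearest the
  diagnostic peak with the endpoint chord; ties count as positive.
- Background pairs that are near-identical (max absorbance < 1e-6) or that
  carry no gas structure after baseline correction raise a
  degenerate-reference error rather than returning an all-zero reference.
- Indicators whose spectral region is not covered (e.g. ATR spectra ending
  near 3750 cm⁻¹) are reported as missing with a flag, not as errors.
- Artifact scales that cannot be realized (see below) raise an informative
  error in `inject_artifact()`.

## Known limitations

**Negative water-vapor contributions saturate.** A large negative
water-vapor artifact pulls the convex-hull baseline down across the
low-absorbance 2500–3800 cm⁻¹ region, inflating the total-area normalizer
faster than the regression signal grows; for realistic organic spectra
`c_wv` cannot fall much below about −0.07. This is intrinsic to normalizing
by the rubberband-corrected area of the *observed* spectrum — the same
corruption the CO₂-region interpolation guards against, but no such guard
exists for the water-vapor region (and CO₂ recovery is indeed exact for
negative artifacts). Strongly negative `c_wv` values should therefore be
read qualitatively.

**Standard errors understate uncertainty for near-null regions.** The
hull correction of a pure-noise region leaves autocorrelated residuals, so
the classical OLS standard error underestimates the across-replicate
scatter of `c` by a factor of ~2–3 when no artifact is present (the
estimates themselves remain centered on zero). When a real artifact
dominates the region, the reported `se` is well calibrated — on the
simulated validation panel, >95% of estimates fall within 3 `se` of truth.

**Problem sizes.** The validation suite uses 100-spectrum classification
suites, 50-seed Monte-Carlo grids, and a 500-spectrum end-to-end panel —
sizes chosen to make sampling statements (95% coverage, strict
monotonicity) stable across seeds while keeping the suite quick to run.
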