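---
title: "Wing deformation modes and mechanosensory encoding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wing deformation modes and mechanosensory encoding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeronerve)
```

# The model

A flexible wing in airflow settles into a small set of structural
oscillation modes. `aeronerve` represents the dorsoventral displacement of
the wing surface as a frames × bins matrix `U` on a regular wing-plane grid
(`WingGrid`: spanwise `x`, chordwise `y`, planform mask), and models it as

    U(t, b) = Σ_m s_m(t) φ_m(b) + ε(t, b)

with spatial mode shapes `φ_m` (bend, twist, camber), score series `s_m`
in mm, and i.i.d. Gaussian measurement noise `ε`. All displacement is
dorsoventral with **positive = dorsal**; the other displacement components
are treated as negligible and are not modelled. Strain is the spanwise
normal strain `∂u/∂x` (unitless, tensile positive). Units are mm, s, Hz and
bits throughout.

The analysis chain answers three questions:

1. **What deforms?** PCA of `U` (per-bin temporal mean removed) yields
   orthonormal shapes, mm-scaled scores, and variance fractions
   (`fitModes()`).
2. **When do sensors fire?** Spike phases relative to score-oscillation
   cycles; vector strength `VS = |Σ e^{2πiθ}| / N`; classes strong
   (VS > 0.6), weak (0.5 < VS ≤ 0.6), none; spike-triggered averages of the
   scores; phase shift as a function of cycle amplitude
   (`cyclePhases()`, `vectorStrength()`, `spikeTriggeredAverage()`,
   `phaseAmplitudeProfile()`).
3. **Where are the sensors?** Welch magnitude-squared coherence between the
   binary spike vector and each bin's displacement or strain, the
   lower-bound information rate `I = −∫ log₂(1 − C_xy) df` over 0–500 Hz,
   spike-rate normalization to bits/spike, top-percentile high-information
   regions, and nearest-bin sensor matching (`coherenceMap()`,
   `informationRate()`, `highInformationRegions()`,
   `matchCandidateSensors()`).

The lower-bound information rate assumes linearity and stationarity of the
stimulus–response relation; it is conservative for unrepeatable stimuli
such as turbulent airflow, which is why it is used here rather than
direct or upper-bound estimators (out of scope by design).

# The synthetic generator

Because real recordings cannot ship with a package, every stage is
validated against a generator whose ground truth is known exactly and
emitted alongside the data (`groundTruth()` sidecars).

* **Fields** (`synthDisplacementField()`): analytic bend (`s²`), twist
  (`s·(c − ½)`), and camber (`s·c²`) profiles are Gram–Schmidt
  orthonormalized on the masked bins and scaled to unit RMS, so score RMS
  amplitudes are in mm and PCA can be scored shape-for-shape. Scores are
  sinusoids at the configured frequencies (optional 2nd harmonic), with
  modes sharing a frequency driven in quadrature so their scores stay
  uncorrelated. A slow (≤ 5 Hz) random envelope modulates amplitude; with
  the default RMS 1.8 mm and depth 0.6, cycle peak amplitudes span roughly
  1–4 mm, the displacement range over which phase shifts are characterized.
  Noise is i.i.d. Gaussian per bin, specified absolutely (mm) or relative
  to the clean-field RMS.
* **Working natural frequency.** 170 Hz is the default flutter mode
  frequency — a configuration choice representative of dragonfly-wing
  flutter, not a measured constant — and is exposed on `modalModel()`.
  Flapping surrogates use 35 Hz with a 70 Hz second harmonic.
* **Spikes** (`synthSpikeTrain()`): per oscillation cycle, with probability
  `p`, one spike at phase `θ ~ vonMises(μ₀ + β·A, κ)` where `A` is the
  cycle's starting peak amplitude; an absolute refractory period then
  prunes. The per-cycle Bernoulli × von Mises construction is chosen over
  an inhomogeneous Poisson process because it has the closed-form expected
  vector strength `I₁(κ)/I₀(κ)`, giving the statistical tests an analytic
  target (with delta-method SE `((1 + I₂/I₀)/2 − (I₁/I₀)²)/N`).
* **Video** (`synthSpeckleVideo()`): a smoothed-noise speckle texture
  warped per frame by the interpolated displacement (out-of-plane mm
  mapped to image px through a gain and a unit image direction), then
  optionally through a plane→camera homography; 8-bit grayscale.
* **Edges and sensors** (`synthEdgeTraces()`, `synthSensorMap()`): edge
  traces are sampled at grid columns within span fractions 0.10–0.90 so
  analytic profiles evaluate exactly; sensors sit on straight spanwise
  "vein" rays with a configurable proximal fraction — real venation
  geometry is out of scope.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: aerodynamic feedback (no fluid–structure
coupling), wing corrugation and vein-level stiffness heterogeneity,
DIC-specific artifacts such as motion blur or decorrelation, non-Gaussian
and spatially correlated measurement noise, multi-unit interactions, and
sensor transduction dynamics beyond a phase preference with an
amplitude-dependent shift.

# Numerical choices

* **PCA** uses the eigendecomposition of the smaller of the two covariance
  matrices (bins × bins or frames × frames), so both long recordings and
  large grids are handled; no scaling or whitening is applied (all bins
  are in mm). Bins invalid in *any* frame are dropped (mask intersection)
  rather than imputed, keeping the decomposition a fixed linear map. Each
  shape's largest-magnitude bin is made positive (dorsal), fixing the
  otherwise arbitrary PC sign deterministically.
* **Cycle detection**: local maxima with minimum prominence 10% of the
  score SD and minimum separation half the dominant period (periodogram
  argmax); peak positions are refined by a three-point quadratic fit so
  phases are not quantized to the frame clock.
* **Vector strength** is computed with phase angles in radians
  (`cos 2πθ`), the standard circular-statistics definition, normalized by
  the number of spikes. Class boundaries are strict inequalities at 0.5
  and 0.6. STA is reported only for units classed strong or weak; an
  unlocked unit's STA under cyclic stimulation is uninterpretable and is
  excluded at the pipeline level.
* **Welch coherence**: 100 ms Hann-tapered segments with 50% overlap
  (10 Hz resolution at 1,000 fps). The spike vector and each bin series
  are mean-subtracted; segments containing invalid (`NA`) samples are
  dropped *per bin* rather than discarding whole frames, and bins with
  fewer than 2 valid segments are excluded. No analytic subtraction of the
  `1/n_segments` coherence bias floor is applied — the floor is instead
  kept interpretable (independent signals sit near `1/n_segments`, and
  shorter segments lower it). Coherence is clipped to `1 − 10⁻⁹` before
  the information-rate logarithm; the integral is trapezoidal on the
  frequency grid; the band must not exceed Nyquist.
* **High-information regions**: normalized rate = bits/s divided by the
  unit's mean firing rate (bits/spike); the mask keeps the top `p`% of
  normalized rates (default 5, valid 0.5–10) with ties at the cutoff all
  included and flagged. Peak frequency is reported at the grid point of
  maximum averaged coherence, without interpolation.
* **DIC**: subsets are odd-sided, by default sized so the subset area is
  ~1% of the wing's pixel area; matching is an integer-pixel
  zero-normalized cross-correlation search followed by a per-axis
  three-point Gaussian (log-parabolic) peak fit. The Gaussian estimator is
  exact for the Gaussian-shaped correlation peaks that smoothed speckle
  produces, where a least-squares quadratic vertex over the 3 × 3
  neighbourhood is biased by peak asymmetry; a perfect correlation
  (identical frames) short-circuits to zero offset. Peaks on the search
  border, subsets leaving the frame, textureless subsets, and peak
  correlations below `minCorrelation` (default 0.6, exposed) are invalid.
  Every frame is correlated against the rest frame (displacement is
  defined relative to rest), and strain uses the small-strain measure from
  a local least-squares plane fit over each bin's 3 × 3 valid
  neighbourhood (≥ 6 points required) — appropriate because per-bin
  displacements are small.
* **Kinematics**: 5th-order per-axis edge polynomials over span fractions
  0.10–0.90; the surface is 80 spanwise × 50 chordwise points with linear
  chordwise interpolation. The mean stroke plane is the total-least-squares
  plane through the wingtip track; the stroke angle is the signed in-plane
  angle to the mean tip direction. Bend amplitude is reported at a single
  configurable station (default 70% span, midchord) — a scalar-per-frame
  interpretation; twist pivots about midchord (configurable).
* **Seeds**: one run seed expands into per-stage child seeds through a
  fixed congruential map (`childSeed()`); identical config + seed gives
  byte-identical artifacts and report.

# Localization scenario

`synthLocalizationScenario()` builds the end-to-end ground-truth test for
sensor localization: bend + twist flutter at 170 Hz with 5% relative noise
on a 12 × 20 grid, 60 s at 1,000 fps; the spiking unit (κ = 4, p = 0.9) is
driven by the strain series at the maximum-strain-RMS bin — where a strain
sensor would sit — and a sensor map contains one sensor planted at that bin
among 30 background sensors. Strain, not displacement, is used as the
coherence field here because local strain is what campaniform sensilla
transduce; both field kinds share one code path distinguished only by the
field's `kind`. The test suite requires the information-map argmax to fall
within 2 bin widths of the true bin, and the planted sensor to rank first,
in ≥ 90% of 20 seeded runs.

# Problem sizes

The test suite exercises: flutter surrogates up to 20,000 frames × 1,000
bins and flapping surrogates of 10,000 frames × 4,000 bins for the
variance-fraction checks; 2,000-spike samples for the vector-strength
statistics; 60 s × 1,000 fps recordings (240 bins) × 20 seeds for
localization; and ~100 px images with 11 px subsets for DIC. These sizes
were chosen so the full suite runs in a few minutes while keeping the
statistical checks well-powered.

# Known limitations

* Single dorsoventral displacement component; no 3D (stereo) DIC, lens
  distortion, or contrast enhancement (a pass-through hook only).
* The DIC engine uses cumulative referencing and a correlation-peak fit —
  not an iterative shape-function solver — so severely deformed subsets
  (large rotations/stretches within a subset) will lose correlation before
  a production DIC code would.
* Per-recording PCA: no pooling across trials or animals is provided.
* The information estimate is a lower bound under linear-stationary
  assumptions; nonlinear encoding (e.g. strong rectification) will be
  under-counted.
* The generator's vein rays, planform taper and mode shapes are idealized;
  conclusions about where real sensors sit require real strain fields.
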