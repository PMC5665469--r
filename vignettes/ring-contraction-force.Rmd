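---
title: "Measuring actomyosin-ring contractile pressure by impulsive-force counter-balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring actomyosin-ring contractile pressure by impulsive-force counter-balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringforce)
```

## The measurement problem

Cell extrusion removes a dying cell from an epithelial sheet: the
neighbouring cells assemble a circumferential actomyosin ring whose
contraction pushes the cell out. Classical in vitro force assays (traction
force microscopy, micropillars, single-cell force spectroscopy) require the
cells to be removed from the organism, so they cannot report the force of
extrusion where it actually happens. The counter-balance strategy this
package implements works in the intact epithelium: a femtosecond-laser pulse
focused at the centre of the contracting ring launches a stress wave that
acts as a brief, calibrated, outward impulsive force. Under repeated loading
the ring stops contracting and stalls at a *counter-balanced radius* $R$
where the inward contractile pressure and the outward load pressure are
equal. Varying the load and reading off the stall radius traces out the
ring's pressure.

## Model and inference chain

Three relations carry the whole analysis.

1. **Calibration.** The total impulsive force at the focal point is
   proportional to the pulse energy $L$ (nJ/pulse):
   $F_0 = k\,L$, with $k$ fitted by ordinary least squares from an
   AFM-cantilever calibration table. The through-origin constraint encodes
   that zero energy delivers zero force; an affine fit is available
   (`through_origin = FALSE`) as a diagnostic, and its intercept is reported
   but never used by the pressure conversion.

2. **Spherical volume-wave propagation.** The impulse is assumed to spread
   uniformly over a sphere centred at the focal point, so at distance $R$
   the pressure is
   $$P = \frac{F_0}{4\pi R^2}.$$
   The factor $4\pi$ is isolated as a single `geometry_factor` argument: it
   is the one place where the propagation geometry enters, and a user who
   believes the impulse is hemispherical (e.g. near a strongly reflecting
   interface) can substitute $2\pi$ without touching anything else. Units
   are fixed internally — µm, µN, s — and 1 µN/µm² = 10⁶ Pa, so pressures
   come out in kPa with a single constant; no unit inference is attempted on
   input files.

3. **Counter-balance line.** At stall, $P_{\text{ring}} = P_{\text{load}}$,
   hence $R^2 = a F_0$ with $a = 1/(4\pi P_{\text{ring}})$. The slope of the
   through-origin regression of $R^2$ (µm²) on $F_0$ (µN) therefore converts
   directly to the contractile pressure $P = 1/(4\pi a)$. On exact data this
   is algebraically identical to applying the pointwise law to any datum on
   the line, and the test suite holds the two routes together at relative
   error $10^{-10}$. The regression runs on $F_0$, not on $L$: the
   calibration is applied first, so a nonzero calibration intercept would
   propagate correctly.

The regression is deliberately fitted through the origin: the physical
boundary condition ($R \to 0$ as $F_0 \to 0$) and the fact that the
conversion uses only the slope both argue for it. Whether the original
experiments constrained their fits this way is not something the data we
generate can decide; the affine mode exists so a user can check both on
their own data. Under 10% multiplicative radius noise the through-origin
estimator carries a small known bias — $E[(1+\varepsilon)^2] = 1 + cv^2$
inflates $R^2$ by about 1% — which is why the recovery tests demand 5%
accuracy of the *mean* estimate rather than exactness.

Uncertainty is attached by case-resampling bootstrap over observations
(percentile 95% CI, default 2000 resamples, seeded). Resamples that collapse
to a single distinct pulse energy leave the slope unidentifiable and are
redrawn (at most 100 times before an error). Inside the resampling loop the
through-origin slope is computed by its closed normal-equations formula —
the same estimator as the full fit, just without the model-frame overhead —
and the oracle tests pin both routes to the same sums.

## Ring measurement

Ring size over time is measured from multi-page TIFF stacks. Per frame the
operator chain is: Gaussian smoothing (σ = 1 px), Otsu threshold,
morphological closing (3×3), largest connected component, then three gates —
minimum size (50 px), circularity of the filled component
($4\pi A/P^2 \ge 0.6$), and foreground contrast (≥ 3 background MADs above
the background median). Frames failing the gates are flagged `no_ring` or
`low_contrast` and carry no area; a uniform frame is `no_ring` by
construction.

The radius readout deserves a note. Thresholding a bright band yields an
annulus of pixels; the area *enclosed by* the filled band over-estimates the
ring radius by half the band thickness, which at realistic band widths
(2–3 px) exceeds the half-pixel accuracy we want. The package therefore
estimates the band's **centreline radius** directly: with band pixels at
distances $d_i$ from the band centroid and intensities $I_i$, the estimate
is the weighted mean of $d_i$ with weights $(I_i - t)/d_i$ (threshold $t$).
The $1/d$ factor cancels the geometric growth of pixel count with radius, so
for any radially symmetric band profile the estimator is unbiased; on
rendered annuli it is accurate to ~0.01 px both noiseless and at SNR 10.
Ring area is then reported as the enclosed disk $\pi r^2$, which keeps the
`area = π·radius²` invariant exact and matches the convention that the ring
"size" shrinks to zero at closure.

Event detection on the resulting trace:

* **Formation** — first time a ring is found in 3 consecutive frames
  (`k_formation`); guards against single-frame false positives.
* **Completion** — first time the area falls below 5% of its peak
  (`closure_fraction`), or the ring vanishes for good after contracting
  below half its peak.
* **Counter-balanced plateau** — only looked for inside a user-supplied
  loading schedule. Each in-schedule frame gets a local area-change rate
  $|dA/dt|$ from a windowed linear fit (15 s window); the plateau is the
  longest run of frames whose rate stays below `stall_fraction` (default
  0.2) of the pre-loading contraction rate, and the counter-balanced radius
  is the **mean** effective radius over that run, not a single extreme
  frame, to suppress frame noise.

The stall threshold default is worth justifying. A much stricter criterion
(a few percent of the contraction rate) sounds attractive but is
statistically unattainable on realistic traces: with per-frame area noise of
order 0.5 µm² and pre-loading rates of order 0.26 µm²/s, the standard error
of even a 15-frame local slope (~0.035 µm²/s) exceeds a 2% threshold
(~0.005 µm²/s) several-fold, so no frame would ever qualify. At 20% the
genuine plateau (true slope 0) passes with high probability while
contraction (slope ≈ 7 standard errors above threshold) is reliably
excluded; the relaxation transient at the start of loading decays below
threshold within ~4 time constants, contributing < 0.02 µm to the plateau
mean. Both the fraction and the window are arguments.

## What the synthetic data emulates — and what it does not

The generators reproduce the statistical structure the analysis assumes, with
the experiment's stated conditions as defaults:

* **Calibration tables** (`gen_calibration_table`): linear $L$–$F_0$ with
  additive Gaussian noise. Default slope 0.02 µN/nJ with zero intercept —
  an order-of-magnitude-plausible choice (µN-scale forces at tens of nJ),
  configurable everywhere and never asserted as a measured value. Energies
  span 10–60 nJ/pulse, the range used for loading.
* **Ring movies** (`gen_ring_movie`): an annulus with a radial Gaussian
  intensity profile, no ring before the 120 s formation onset, piecewise
  linear area decay to closure (the measured-area traces motivate a simple
  monotone law; an exponential option exists since the true functional form
  of ring closure is not established), and under loading an exponential
  relaxation (τ = 5 s) to the balance radius implied by the spec's
  ground-truth pressure, a plateau, then resumed contraction at the
  pre-loading area rate. Noise is Poisson shot noise plus Gaussian read
  noise, default SNR 10 (peak amplitude 1000 counts, read noise 100);
  field 512×512 at 0.124 µm/px, plausible Nyquist-ish sampling for a
  100×/1.25 objective. The unloaded closure default (420 s, i.e. 300 s of
  contraction from a 5 µm ring) sits in the several-minute range typical of
  these events.
* **Counter-balance sets** (`gen_counterbalance_set`): radii from the exact
  propagation law with multiplicative Gaussian noise. The default CV of 10%
  reproduces balance-line correlation coefficients around 0.6–0.9 at
  n = 30, the range reported for in vivo counter-balance data.
* **Cohorts** (`gen_extrusion_cohort`): Gaussian completion times, control
  mean 300 s, sd 20 s, inhibitor delay 100 s. The sd is a declared choice;
  the dispersion of real extrusion times is not published.

Every generator is bit-reproducible under a fixed seed and returns or
implies its ground truth, so recovery is always checkable. What the
synthetic movies do **not** emulate: photobleaching, drift, neighbouring
structures and autofluorescence, z-projection artifacts (real stacks are
3D), partial or elliptical rings, and multiple simultaneous extrusions.
Passing the round-trip tests therefore demonstrates correctness of the
measurement chain on data satisfying the model's assumptions — not
segmentation robustness on arbitrary microscopy.

## Statistics

Group comparisons use the classical pooled-variance Student's $t$ with a
one-tailed alternative and significance at $P < 0.01$; Welch's correction is
available behind `welch = TRUE`. Two conventions: a zero pooled variance
with equal means returns $p = 0.5$ (the boundary of the one-tailed null),
and tests are only applied where replicate-level samples exist on both sides
— single point estimates are compared by difference with the test column
marked not applicable. With at most two planned comparisons no
multiple-testing correction is applied; this is documented rather than
corrected. A 5000-replicate null simulation in the test suite confirms the
type-I error at α = 0.01 stays inside its binomial 99% band.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use 100 replicate datasets of 30
observations for pressure recovery, 10 cells per group for cohorts, one
300-frame 512×512 movie for onset detection, and smaller (160 px, ~70
frame) movies wherever the full field is not the point; the whole suite runs
in about a minute on one core. Bootstrap defaults (2000 resamples) are kept
for user-facing calls and reduced in tests where only determinism or
coverage is being checked.

## Known limitations

* The spherical-propagation factor is an assumption, not a measurement;
  attenuation between focal point and ring is neglected, so pressures are
  best read comparatively across conditions.
* The contractile ring is treated as the sole force generator;
  contributions from the extruding cell itself or from cells beneath are
  outside the model.
* Segmentation assumes one approximately circular ring per field.
* The calibration table is taken as ground truth; cantilever mechanics and
  distance dependence of the impulse are out of scope.
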