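---
title: "Methods: normal-database construction and pixel-wise permutation inference for perfusion polar maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normal-database construction and pixel-wise permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsnorm)
```

## The model

A stress polar map projects relative myocardial perfusion onto a disc:
apex at the centre, base at the rim, anterior wall up, inferior down,
septum left, lateral wall right. `mpsnorm` works on square count grids
(default 65×65) whose valid region is the inscribed disc — 3313 pixels
whose centres lie within 32.5 pixel units of the centre pixel. A pixel
belongs to the disc (or to a segment) when its centre satisfies the
radius/angle condition, boundary ties included inward; this makes every
partition deterministic.

Analysis proceeds in four stages.

**1. Count normalization.** Counts are relative, so each map is scaled
so that the median over its `ceiling(0.10 × n_valid)` brightest valid
pixels (332 on the default disc) equals 100. The brightest decile is
the region most likely to show normal perfusion; anchoring it to 100
puts all maps, and any difference between group means, on a −100..100
scale. The operation is exactly scale-invariant and idempotent, and the
top set is chosen by full ordering with index-order tie-breaking, so it
is reproducible bit for bit. Maps are normalized independently — the NC
and AC reconstructions of one subject each get their own scale.

**2. Normal databases.** A database is the pixel-wise sample mean and
sample SD (denominator n−1; the estimator is chosen to match the
t-statistics downstream) over a group selected by gender, BMI class and
correction type.

**3. Pixel-wise inference.** Group differences are tested per pixel:
pooled-variance (Student) two-sample t for independent groups — pooled
rather than Welch because the permutation argument rests on
exchangeability, under which the pooled statistic is the natural pivot
— and the one-sample t of per-subject NC−AC differences for paired
designs. Testing 3313 (or, on the full grid, 65² = 4225) pixels at
α = 0.001 needs a multiplicity correction; the package uses the max-|t|
permutation procedure: recompute the t-map under B random relabellings
(two-sample: label reshuffles preserving group sizes; paired:
independent per-subject sign flips — each being the exchangeability
unit of its design), record the maximal |t| over valid pixels, and
threshold the observed map at the ⌈(1−α)·m⌉-th order statistic (no
interpolation) of the null collection. Pixels with zero variance get
t = 0 and can never reach significance, which keeps ±∞ out of the max
statistic.

Two conventions matter:

- *The observed statistic belongs to the null collection* (m = B + 1)
  when permutations are sampled randomly; this makes the implied
  p-value `(1 + #{perm ≥ obs})/(B + 1)` valid without asymptotics.
  When the design admits no more than B distinct permutations
  (2ⁿ sign flips, or `choose(n, n_a)` label splits), the collection
  enumerates all of them exactly instead, and the random procedure
  coincides with the exact test.
- *Resolution.* If α < 1/m the threshold is the collection's maximum
  and no pixel can exceed it: the procedure still controls the
  family-wise error (trivially) but has no power. The historical
  default settings (B = 500, α = 0.001) have exactly this property, so
  `maxt_threshold()` warns when they are used; analyses that need
  α = 0.001 to be resolvable should run B ≥ 1999, which is what the
  acceptance checks do for power comparisons.

**4. Segmental summary.** The apical segment is the disc out to 30 % of
the radius (the 2-D reading of "apex to 30 % of the distance to the
base"); the remaining ring is split into four angular quadrants
(anterior [45°,135°), septal [135°,225°), inferior [225°,315°), lateral
elsewhere), which on the symmetric 65-grid contain exactly 602 pixels
each; the outermost 10 % of radius is excluded to avoid basal
delineation artefacts. For two databases the table reports, per
segment, the mean of the difference map and twice its pixel-wise SD.
The "± 2 SD" is pixel scatter over the segment, not subject-level
variability — at the database level pixel scatter is the only
dispersion available; the raw difference map is accessible so the
subject-level alternative can be computed externally. Sign conventions
throughout: gender comparisons are **men minus women**, correction
comparisons **NC minus AC** (both orientations make attenuation
deficits negative, matching how published segmental tables read).

## The synthetic cohort generator

No public polar-map cohort exists, so the package ships a generator
whose defaults *are* its stated world:

| parameter | default | meaning |
|---|---|---|
| `base_level` | 100 | count level at the mid-wall perfusion peak |
| `radial_amp`, `radial_peak` | 0.10, 0.45 | smooth radial fall-off of the base pattern |
| `nc_effect_male_inferior` | 0.15 | peak fractional NC deficit, diaphragm window (270°) |
| `nc_effect_female_anterior` | 0.10 | breast window, 90° |
| `nc_effect_female_lateral` | 0.08 | chest-wall window, 0° |
| `nc_effect_female_inferior` | 0.08 | inferior window in women (see below) |
| `obesity_multiplier` | 1.5 | deficit amplification in obese subjects |
| `ac_residual` | 0.1 | fraction of each deficit surviving correction |
| `subject_sd` | 0.1 | SD of the per-subject log-normal scale |
| `pixel_noise_sd` | 8 | marginal SD of smoothed pixel noise (count units) |
| `noise_smooth_sigma` | 1.5 px | spatial correlation scale of the noise |
| `window_angle_sd`, `window_radius_sd` | 30°, 0.18 | attenuation-window widths |

Deficits are smooth Gaussian windows in (angle, radius) space because
attenuation shadows are smooth; they are centred in the walls where
each tissue lies, with the inferior windows at radius 0.6 (diaphragm
shadows sit basal of mid-wall). The per-subject scale is shared between
a subject's NC and AC maps, which induces the within-subject
correlation that makes the paired test more powerful than the
two-sample one. Counts are clipped at zero; at default settings the
clipping rate is below 0.1 % (tested). Default cohort sizes mirror a
331-patient normal population: 102/24 normal-weight/obese men,
165/40 women.

A female *inferior* deficit is included even though breast attenuation
is classically anterior/lateral: published NC-vs-AC segmental
differences in women show a clearly negative inferior cell, and without
it the four inferior-wall comparisons (men NC−AC, women NC−AC, NC and
AC gender differences) cannot be mutually consistent — the identity
(NC gender diff) ≈ (men NC−AC) + (AC gender diff) − (women NC−AC)
forces it.

**What the generator does *not* emulate:** reconstruction artefacts,
apical thinning, patient motion, extra-cardiac uptake, heteroscedastic
count noise, or any spatial covariance beyond Gaussian smoothing. A
green test therefore establishes that the *pipeline* recovers what the
generator put in — not that the generator is a physical model of SPECT.

## Calibration

`calibrate_to_segment_targets()` inverts the pipeline: given target
segmental differences, it root-finds the deficit amplitudes (and, for
AC targets, `ac_residual`) so that the pipeline's *population limit*
reproduces them. Two design points:

- The forward model is **not** the noise-free pipeline. The
  normalization reference — the median of the brightest decile — is
  selection-biased upward under pixel noise (on a flat-topped base
  pattern the bias is ≈ the 95th percentile of the noise, here ~15 %),
  which attenuates every normalized difference by the same factor.
  Calibrating against the noise-free model therefore *systematically
  under-recovers* targets at realistic noise (a −14.0 target came back
  at −11.6). Instead the forward model computes the expected top-decile
  median analytically from the Gaussian marginal at each pixel (the
  level t at which the expected number of exceedances equals half the
  top-set size), which is deterministic, costs microseconds, and
  reduces exactly to the noise-free selection as σ → 0. With it, all
  targets recover within ~0.35 units at the study's n.
- Each target cell is driven by one designated parameter, but
  normalization couples segments and window tails overlap, so the
  one-dimensional root finds are iterated Gauss–Seidel style until the
  parameter vector is stationary (tolerance 1e-8, monotone bisection
  within each step). Zero targets recover zero amplitudes to solver
  tolerance; unreachable targets (amplitude bounds [0, 0.95],
  residual [0, 1]) raise a calibration error naming the segment.

## Numerical and degenerate-input choices

- Even-sized median = mean of the two central order statistics.
- Normalization refuses maps with fewer than 10 positive valid pixels.
- Zero-variance pixels: t = 0, never significant.
- Permutation RNG: one seeded Mersenne-Twister stream per call,
  consumed in documented order (subject scale, NC noise, AC noise per
  subject; one draw per permutation), so every result is reproducible
  bit for bit; the global RNG state is saved and restored.
- Grid-edge noise pixels are slightly under-dispersed because the
  smoothing kernel is zero-padded; only the 4 cardinal rim pixels of
  the disc touch the grid edge, and database statistics are unaffected
  in practice.
- CSV map files store full decimal precision (`%.17g`); round trips
  are value-exact.

## Known limitations

- The paired and two-sample permutation schemes assume exchangeability
  under the null; covariate imbalance (e.g. BMI differing between
  gender groups) is not adjusted for, matching the original analysis
  design.
- Random two-sample permutations are sampled with replacement
  (duplicates allowed), standard for B ≪ the number of distinct
  relabellings.
- The segment "± 2 SD" cannot be compared to subject-level dispersion
  without the raw cohort.
- The polar map is treated as linearly radius-parameterized from apex
  to base; if real maps are volume-weighted the apical/basal boundaries
  shift slightly, affecting only segment membership near those rings.
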