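---
title: "Electrode density and seizure-onset-zone delineation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrode density and seizure-onset-zone delineation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sozdensity)
```

## The question this package addresses

Epilepsy surgery depends on delineating the seizure onset zone (SOZ) from
intracranial EEG. Clinical electrode arrays are spatially coarse — roughly
8–10 mm between contacts — while research systems record grids at 4 mm and
depth probes at 5 mm. Because a lower-density (LD) montage can be obtained
from a higher-density (HD) one by *removing* channels, the two conditions can
be compared on the *same* seizures: render each seizure's intensity as a
blinded heatmap on the reconstructed brain twice (once from all channels,
once from the decimated subset), have expert scorers annotate the SOZ under
both conditions without knowing which is which, and model the differences.
`sozdensity` implements that full chain — decimation, heatmap generation,
agreement statistics, crossover mixed models — together with a
synthetic-data layer that makes every step testable against known ground
truth, and a geometric simulation of how contact spacing biases estimated
SOZ volume.

## Seizure intensity and its anatomical projection

**Line length.** Seizure intensity per channel is the line-length transform:
the sum of absolute consecutive-sample differences in a trailing window,

$$LL_c(t) = \sum_{i \,\in\, \mathrm{win}(t)} |x_c[i] - x_c[i-1]|,$$

computed causally every `hop_s` seconds. Defaults are a 1.0 s window with a
0.1 s hop; both are configuration parameters, chosen as round numbers that
resolve ictal evolution at the 512 Hz working rate while smoothing over
individual spikes.

**Baseline z-scoring.** Line length is z-scored per channel against a
pre-ictal baseline (frames whose windows lie entirely inside the baseline
window), making channels with different impedances and gains comparable. A
channel with zero baseline variance is a recording fault and is rejected by
name — it should have been removed by bad-channel screening.

**Gaussian maximum projection.** Each target (mesh vertex or slice pixel)
takes the *maximum* over nearby contacts of the contact's z-value attenuated
by a Gaussian in distance:

$$h(\mathbf{p}) = \max_{e:\, d(e,\mathbf{p}) \le c} \; z_e \,
  e^{-d(e,\mathbf{p})^2 / 2\sigma^2},$$

with `sigma_mm = 5`, `cutoff_mm = 15` (about 3 sigma) by default. The
attenuation is applied *before* the maximum, so a distant strong contact can
be outranked by a near moderate one. A maximum — rather than a sum — is
essential to the design: summing would systematically brighten the HD
condition simply because it has more terms, unblinding the comparison.
Under a maximum, removing contacts can never *increase* any target's value,
which yields the central invariant: for nested LD ⊂ HD contact sets with
identical z-values on shared channels, the HD heatmap dominates the LD
heatmap pointwise. One caveat: targets with no contact within the cutoff
are assigned 0, while a target whose only in-range contacts carry negative
z gets a negative value; dominance is therefore asserted on display-clamped
(non-negative) values, which is also what scorers see — negative z is never
rendered.

**Blinding.** Rendered frames carry no electrode glyphs and no condition
metadata when `blinded = TRUE`; only the heat layer and the elapsed-time
stamp remain. Omni-planar slices (planes running parallel to each depth
probe) use the same projection evaluated at pixel 3D positions. The roll of
the slice plane about the probe axis is not determined by the probe itself;
we fix it with a hint vector (Gram–Schmidt against the probe direction),
which is a convention, not an estimate.

## Preprocessing

The signal chain mirrors a hybrid clinical/research acquisition: referential
recordings at 3052 Hz are low-pass filtered below 255 Hz (anti-aliasing) and
resampled to 512 Hz, then notch filtered at 60 Hz and harmonics, and
channels with poor signal are excluded. Order is fixed — resample, notch,
exclude — so the notches are designed at the final rate.

Numerical choices:

* The anti-alias filter is a 400-tap FIR applied forward–backward
  (zero-phase), so seizure-onset latency is not shifted; its coefficients
  are normalised to exactly unit DC gain.
* Rate conversion is band-limited FFT resampling at the exact rational
  ratio (128/763 for 3052 to 512 Hz), after odd-reflection padding and
  removal of a linear end-to-end ramp so the periodic junction is
  continuous; this keeps passband tones amplitude-accurate to well under 1%
  and constants exact.
* Notches are RBJ biquads with Q = 60 applied zero-phase. Zero-phase
  application squares the magnitude response, so the quality factor was
  chosen such that the *doubled* response still loses less than 1 dB
  outside ±2 Hz of each notch while exceeding 30 dB of attenuation at the
  notch. Note that for a finite record containing energy *at* the notch
  frequency, total RMS attenuation is limited by ring-in/ring-out at the
  record edges (about Q/f0 seconds each side), not by the steady-state
  response.
* Bad channels: the study states only that poor-signal channels were
  excluded. We adopt a flat-channel rule (SD below `flat_eps`) plus a
  robust amplitude-outlier rule (baseline SD above `outlier_k` = 10 times
  the median across channels); both thresholds are configuration.

## Density decimation

Grids lose every other row and column (4 mm spacing becomes 8 mm); depth
probes lose every other contact (5 mm becomes 10 mm); strips are carried
unchanged by default because the study recorded them identically on both
systems (decimation of strips is available behind a flag). The retained
set is anchored at row/column/contact 0; the anchor is configurable because
the clinical convention is undocumented. Decimation removes channels and
does nothing else: samples on shared channels are bit-identical, which the
tests assert, and which is what makes the heatmap dominance invariant an
exact property rather than an approximation.

## Agreement statistics

Annotations are polygons in screen coordinates, rasterised with the
even-odd rule (a pixel counts when its centre is inside; multiple rings OR
together for multifocal SOZs). Agreement between two scorers is unweighted
Cohen's kappa over *all* pixels of the raster — highlighted/not-highlighted
as the binary classes:

$$\kappa = \frac{p_o - p_e}{1 - p_e}, \qquad
  p_o = \frac{n_{11} + n_{00}}{N}, \qquad
  p_e = p_a p_b + (1 - p_a)(1 - p_b).$$

Using the full raster as the denominator follows the study's definition and
has a consequence worth stating: padding the raster with jointly-negative
pixels *changes* kappa (chance agreement rises with the shared negative
space). Raster dimensions are therefore fixed per view in configuration so
kappas are comparable. When chance agreement is 1 — both masks empty or
both full — kappa is undefined; such pairs are recorded as missing, never
coerced to zero. Six scorers yield 15 unordered pairs per seizure and
condition; intra-rater agreement compares one scorer's HD and LD masks of
the same seizure. Overlap with the clinically determined SOZ uses the
any-shared-pixel rule.

## Mixed-effects models

The observation unit is scorer x seizure x condition (6 x 10 x 2 = 120 rows,
a crossover in which every scorer sees every seizure under both densities).
Three outcomes are modelled with `lme4`, all with uncorrelated random
intercepts and REML:

* **log area**: `log_area ~ density + multifocal + overlaps_clinical +
  confidence + (1|scorer) + (1|seizure)`. Areas are natural-log transformed
  for positive skew; a log coefficient b means a `100 (e^b - 1)` percent
  difference.
* **confidence** (Likert 1–5, treated numeric): `confidence ~ density +
  multifocal + overlaps_clinical + scorer_mean_kappa + (1|scorer) +
  (1|seizure)`.
* **kappa**: pair-level rows (pair x seizure x condition) with
  `kappa ~ density + (1|pair) + (1|seizure)`. The study reports adjusting
  for scorer and seizure without specifying the pair-level structure; the
  pair-level model is our reading, and a per-scorer aggregation (mean kappa
  with all others) is available via `unit = "scorer"`.

Inference is Wald z (normal approximation) for coefficients, CIs and
p-values; the degrees-of-freedom method in the source study is not stated,
and we deliberately do not add Satterthwaite machinery. Non-convergence and
boundary (singular) fits are flagged on the result, never silently retried.
Rank-deficient fixed-effect designs (for example a constant density column)
are rejected with the offending terms named. A constant outcome yields a
flagged degenerate result. The carryover check refits a model with the
first-presented condition as an extra fixed effect — the standard concern
in crossover designs that the first exposure colours the second.

Two design utilities round this out: `effective_sample_size(n, deff)`
(n / DEFF; 120 clustered observations at a conservative design effect of
3.0 give 20 vs 20 effectively independent observations) and
`min_detectable_effect()`, which solves the noncentral-t power equation via
`power.t.test` (20 per arm, 80% power, two-sided alpha 0.05 gives d of
about 0.91, i.e. the design detects only rather large effects).

## The synthetic-data layer

Real ictal recordings and scorer annotations are not distributable, so each
input has a generator with known ground truth; all are pure functions of
(configuration, seed).

* **Seizures**: white noise plus, after onset, a sinusoid whose amplitude
  decays exponentially with distance from a focus
  (`A0 exp(-d / decay) `, ramped over `ramp_s`). Defaults: 3052 Hz, 100 uV
  at the focus, 10 mm decay constant, 8 Hz oscillation, 5 uV noise. This is
  the simplest model that makes line length spatially informative; it does
  not mimic ictal morphology (no low-voltage fast activity, no spread), so
  passing tests speak to the *pipeline*, not to waveform realism.
* **True SOZ masks**: discs or polygons; the source rings are kept with the
  mask so annotation simulation can jitter the smooth geometry rather than
  a pixelated boundary.
* **Simulated scorers**: each scorer's annotation is the true polygon,
  isotropically scaled so that the *expected* HD-LD log-area difference
  equals `area_log_multiplier_hd` (default 0.227, the study-scale density
  effect), then displaced along the outward normal by smoothed Gaussian
  noise (`boundary_jitter_px`, default 2 px) and re-rasterised; degenerate
  empty masks are regenerated up to 10 times, then error. Boundary jitter
  is a free parameter — the study does not quantify its scorers'
  variability — so kappa levels produced by the generator are controllable,
  not estimates. Confidence comes from a latent-normal Likert model whose
  multifocal effect defaults to -0.873, the study-scale coefficient.
* **Crossover schedules**: balanced first-pass condition assignment
  (exactly half the seizures HD-first), uniformly random given the seed,
  second pass complementary.
* **Score tables**: outcomes drawn from *exactly* the mixed models the
  inference module fits, with known coefficients and variance components —
  the parameter-recovery harness. Default variance components (scorer SD
  0.3, seizure SD 0.4, residual SD 0.35 on log area) give intraclass
  correlations in the range clinical rating data typically shows.

## The electrode-spacing volume simulation

A spherical "true" SOZ of radius r is placed in nested cubic lattices of
contacts at 1, 5 and 10 mm spacing (sharing the origin, so each coarser
lattice is a subset of each finer one). Contacts inside the sphere are
"positive", and the estimated SOZ is the convex hull of the positive
contacts (a voxel-union estimator — count times spacing cubed — is
available behind a switch). Three facts then hold *exactly*:

1. the hull of points inside a sphere is contained in the sphere, so the
   estimate never exceeds the truth;
2. nesting plus hull monotonicity means finer spacing never yields a
   smaller estimate;
3. hence the 5 mm estimate is always at least as close to the truth as the
   10 mm estimate, and strictly closer wherever the lattices disagree.

The default sweep uses radii 8–40 mm in 2 mm steps on a lattice of
half-width 40 mm with the sphere centred on a lattice node (off-node
centres via seed jitter). The HD-vs-LD percentage difference
`100 (V_5 - V_10) / V_10` is largest for small spheres and decays with
radius; its exact value depends on the estimator and geometry, so the
package checks the qualitative claims (positivity, shrinking with radius)
rather than a numeric band. The convex-hull volume itself is computed by an
incremental hull with outward-oriented facets, preceded by an exact pruning
step (points strictly between two others in the same vertical column are
never vertices); points within 1e-9 of the running hull are treated as
interior, which can perturb the volume only at that scale.

## Problem sizes used by the tests

The test suite and acceptance script run the full chain at deliberately
modest sizes: 4 x 4 to 16 x 16 grids, 10–16 s recordings at 256–512 Hz for
pipeline tests (with the acquisition-rate 3052 Hz path exercised on short
multi-tone records), 120 x 90 annotation rasters, 200 replicates for
parameter recovery, 20 000 replicates for the Monte-Carlo power check, and
the full default radius sweep for the volume simulation. These sizes keep
every property being tested in its asymptotically valid regime while
remaining quick on a single CPU.

## Known limitations

* The seizure generator produces a single stationary focus; no propagation,
  no multifocal onsets, no artefacts. Agreement levels among simulated
  scorers are set by jitter, not estimated from humans.
* Confidence is modelled numerically, as in the study's primary analysis;
  an ordinal cumulative-logit treatment is out of scope.
* Surface rendering is a per-vertex orthographic splat intended for
  numeric inspection and blinding checks, not publication graphics.
* Mesh I/O is ASCII PLY; recordings live as in-memory objects rather than
  EDF files.
* The kappa model's random structure at pair level is one defensible
  reading of "adjusting for scorer and seizure"; results for the
  alternative per-scorer aggregation are one switch away.
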