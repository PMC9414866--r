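---
title: "Bidimensional entropy analysis of equine thermograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidimensional entropy analysis of equine thermograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equitherm)
```

## The problem

When a horse carries a rider whose combined rider-plus-saddle weight is
large relative to the horse's own bodyweight, the thoracolumbar region is
overloaded during exercise. Infrared thermography (IRT) renders the heat
emitted by the back as a false-color image, and the *texture* of that
image — how irregular and complex the spatial pattern of warm and cold
pixels is — carries information about the load. `equitherm` implements a
complete workflow for asking whether image-texture irregularity can
detect the **rider:horse bodyweight ratio**,

\[
\mathrm{ratio} = 100 \times \frac{\text{rider kg} + \text{saddle kg}}{\text{horse kg}} \;(\%),
\]

with roughly 10–12% read as a fitting rider, 12–15% as overweight and
above 15% as obese relative to the horse.

The workflow has four stages, each exposed as package functions and as a
numbered driver script under `analysis/`:

1. **simulate** — generate a crossed horse-by-rider imaging study with
   planted texture effects (`make_design()`, `generate_thermogram()`);
2. **extract** — compute five bidimensional entropy measures and three
   GLCM entropy features per ROI and color component
   (`study_measures()`, `entropy_profile()`, `glcm()`);
3. **select** — apply three statistical criteria that narrow 40 candidate
   (measure, component, ROI) combinations down to the informative ones
   (`select_measures()`);
4. **classify** — score light-vs-heavy rider detection at three
   thresholds (`detection_accuracy()`).

## The five entropy measures

All five operate directly on a pixel matrix (one ROI × one color
component) and quantify irregularity: regular or periodic textures score
low, disordered textures score high. Throughout, `d[.]` is the Chebyshev
distance (maximum absolute difference of corresponding pixels) and
windows are dense, stride-1 squares.

**Sample entropy (SampEn).** The negative log of the conditional
probability that two $(m{+}1)\times(m{+}1)$ windows match within
tolerance $r$ given that their $m\times m$ sub-windows match:
$\mathrm{SampEn} = -\ln(\Phi_{m+1}/\Phi_m)$. Both stages share the same
top-aligned anchor grid (every anchor admits both window sizes), so the
ratio keeps its conditional reading; self-pairs are excluded. When no
pair matches at the larger size the measure is *undefined* — reported as
a classed error, or as `NA` in batch extraction — which genuinely happens
on small, noisy patches and is one of the measure's known weaknesses.

**Fuzzy entropy (FuzzEn).** Replaces the hard match by the continuous
membership $D = \exp(-d^n/r)$ computed on mean-centered windows (local
baseline removal), which keeps the measure defined everywhere and smooth
in the pixel values. Note that with this membership the measure is *not*
invariant to intensity rescaling even when $r$ is a fraction of the patch
SD (scaling intensities by $a$ turns the exponent into $a^{n-1}d^n/r$);
invariance holds only when the absolute tolerance is rescaled by $a^n$.
The printed form of the membership exponent is ambiguous in parts of the
literature; we expose $n$ as a parameter and default to $n = 2$.

**Permutation entropy (PermEn).** The Shannon entropy of the ordinal
patterns of all $d_n \times d_m$ windows, flattened row-major and ranked
with ties broken by position (a stable, deterministic rule). Normalized
by $\ln((d_n d_m)!)$ it lies in $[0, 1]$: 0 for any monotone gradient or
constant, near 1 for disordered pixels. Because the tie-break depends on
position, exact rotation invariance holds only on tie-free patches.

**Dispersion entropy (DispEn).** Pixels are mapped through the Gaussian
CDF with the patch mean and SD, discretized into $c$ classes via
$z = \mathrm{round}(c\,v + 0.5)$ (half-up, clamped to $[1, c]$), and the
Shannon entropy of the $d_n \times d_m$ dispersion-pattern census is
normalized by $\ln(c^{d_n d_m})$. A constant patch has $\sigma = 0$; by
documented rule all pixels then fall in one class and the entropy is 0
(a warning, not an error).

**Distribution entropy (DistEn).** The Shannon entropy (bits) of the
histogram of all pairwise Chebyshev distances between $m \times m$
windows, with $M$ equal bins spanning $(0, d_{\max}]$ per patch; zero
distances fall in the first bin. Binning relative to the per-patch
maximum makes the measure invariant to positive affine intensity maps.

Two normalization conventions circulate for the census measures: dividing
the Shannon sum by the log pattern count (default, keeps values in
$[0,1]$) or by the number of windows (`window_prefactor = TRUE`). Both
are provided because published formulations disagree; all downstream
statistics are invariant to which is chosen, being rank- and
location/scale-based.

### Parameter defaults

| parameter | default | role |
|---|---|---|
| `m` | 2 | template window for SampEn/FuzzEn/DistEn |
| `r` | 0.2 × patch SD | similarity tolerance (SampEn/FuzzEn) |
| `n` | 2 | fuzzy membership exponent |
| `dn`, `dm` | 2, 2 | embedding window (PermEn/DispEn) |
| `c` | 3 | dispersion classes (3⁴ = 81 patterns stay estimable on 24 × 24 ROIs) |
| `M` | 512 | DistEn histogram bins |

These are the prevailing conventions of the bidimensional-entropy
literature; no parameter was fitted to any outcome.

The three GLCM features (`SumEntrp`, `Entropy`, `DifEntrp`) are the
entropy-type Haralick statistics of the gray level co-occurrence matrix:
64 levels by uniform binning of [0, 255], four distance-1 directions
averaged after per-direction symmetric normalization, natural logs, with
$0\ln 0 = 0$. They serve as the *comparison baseline* in criterion 3,
representing the older matrix-based texture approach.

## The synthetic study

No public imaging data exist for this problem, so the package ships a
generator that emulates the study design rather than the physiology:

* **Design**: 12 horses × 6 riders (two each in light/moderate/heavy
  groups, 59.0/76.0/91.5 kg group means; 566.7 kg horses, 4.3 kg
  saddles), every pair imaged pre- and post-exercise → 144 images, and
  group-mean bodyweight ratios of 11.2% / 14.2% / 16.9%.
* **Texture model**: temperature field = smooth background
  (Gaussian-smoothed white noise, SD 4 intensity units, 8 px correlation
  length, circular edges) + i.i.d. Gaussian irregularity noise whose
  amplitude is the single effect dial: 0.5 for every group pre-exercise,
  and 1.0 / 1.5 / 2.0 for L / M / H post-exercise, with a 1.25×
  hot-region gain inside the ROI masks after exercise. The gain pushes
  the post-exercise ROIs into the warm (red-varying) part of the
  colormap, which concentrates the detectable texture change in the red
  component — mirroring where thermography actually carries the signal.
* **Rendering**: min–max normalization through a fixed 256-entry
  blue→green→red lookup table in which red is monotone non-decreasing
  and blue monotone non-increasing in temperature, so "hot ⇒ red,
  cold ⇒ blue" holds by construction. A constant field maps to the
  middle colormap entry by rule.
* **Geometry**: 64 × 64 images with two 24 × 24 ROIs (withers left,
  thoracic spine right), vertically centered with 4 px of separation.

What the generator does **not** emulate: anatomy, saddle shapes, gait,
ambient covariates, camera optics, or radiometric calibration. Passing
the recovery tests therefore shows that the *pipeline* detects planted
irregularity effects of plausible size under the stated noise model — it
does not validate the biological claim on real horses.

The effect amplitudes were chosen once, as study conditions, to give a
clear but unsaturated entropy separation at this ROI size; they are
deliberately not tuned. Sample entropy is undefined on a minority of
post-exercise patches at these settings (more noise → fewer window
matches), which the pipeline reports as `NA` and handles by requiring at
least three defined pairs per test — the same small-image fragility that
motivates dispersion entropy in this literature.

## The selection procedure

Each of the 40 entropy combinations (5 measures × 4 components × 2 ROIs)
passes through three gates at $\alpha = 0.05$:

1. **Exercise dependence** — the paired pre/post comparison must be
   significant in *all three* rider groups. Each series is routed by a
   Shapiro–Wilk gate (p ≥ 0.05 on every series entering the test →
   parametric branch): paired *t*-test or Wilcoxon matched-pairs
   signed-rank. If every paired difference is zero the Wilcoxon statistic
   is undefined and p = 1 is reported — no evidence, not an error.
2. **Rider-group dependence** — the post-exercise values must differ
   across L/M/H: one-way ANOVA + Tukey when all three series pass the
   gate, Kruskal–Wallis + Dunn (Bonferroni over the three pairs)
   otherwise. The pass rule is the omnibus test; pairwise p-values are
   recorded for inspection. Dunn's z-tests are implemented here (with the
   standard tie correction) since no installed package provides them.
3. **GLCM slope similarity** — post-exercise values are regressed on the
   bodyweight ratio and compared, via the ANCOVA slope-equality F-test,
   against the GLCM features that themselves showed group dependence. A
   GLCM feature whose slope falls below half the entropy slopes for more
   than half of the comparisons is dropped (the operationalization of the
   narrative "lower than at least half" exclusion); an entropy
   combination is selected if its slope is indistinguishable (p > 0.05)
   from at least two retained features.

Two genuinely open design points were resolved as follows. The regressor
for criterion 3 is the rider:horse bodyweight ratio of each post-exercise
observation — the only continuous ordering of the rider groups defined in
the design. And because normalized entropies (≤ 1) and GLCM entropies
(up to $\ln L^2$ nats) live on incommensurate scales, each series is
standardized to zero mean and unit SD before the slope comparison:
slope equality then compares *association strength* with the ratio rather
than raw units. `compare_slopes()` itself is scale-honest (raw ANCOVA);
the standardization is criterion 3's documented choice and can be
disabled.

No multiplicity correction is applied across the 40 combinations — the
procedure mirrors the screening character of the original analysis, and
the null calibration of the suite checks the per-combination level
(mean false-positive rate ≤ 7% at $\alpha = 0.05$ over 200 null
studies).

## The classifier

For each selected combination, light (0) and heavy (1) riders are
distinguished by thresholding the post-exercise value: **strictly above →
heavy** (ties to light, the literal reading of "above the threshold").
Three thresholds are placed at mean − SD, mean, and mean + SD of the
pooled light + heavy values — pooling is the only choice that uses no
group labels at threshold-setting time, recorded as this package's
interpretation. Sensitivity is non-increasing and specificity
non-decreasing in the threshold by construction; undefined predictive
values (empty prediction classes) are reported as `NA`, never as 0.

```{r classifier-example}
cs <- confusion_summary(22, 13, 11, 2)
round(c(Se = cs$Se, Sp = cs$Sp, PPV = cs$PPV, NPV = cs$NPV), 2)
```

## Numerical choices and degenerate inputs

* Chebyshev distance everywhere; stride-1 window enumeration, row-major
  anchors; SampEn's two stages share one anchor grid.
* Constant patch: SampEn 0 (σ = 0 ⇒ r = 0 and 0 ≤ 0 matches), FuzzEn 0
  (all memberships 1), PermEn 0 (single stable pattern), DispEn 0 with a
  warning (degenerate Gaussian map), DistEn 0 (single occupied bin).
* Constant rendered field: middle colormap entry. Constant series at the
  normality gate: `non_gaussian` by rule, routing to the rank branch.
* DistEn bin index: $\lceil d/d_{\max} \cdot M \rceil$ clamped to
  $[1, M]$, zero distances in bin 1.
* The nested-model F statistics in `compare_slopes()` are computed from
  residual deviances with the numerator clipped at zero, so exactly
  parallel series give F = 0, p = 1 instead of a rounding-sign artifact.
* Seed fan-out: a run's global seed seeds the design; image $i$ uses
  seed + $i$. All outputs are byte-reproducible under a fixed seed.
* 16-bit images are rescaled to 8 bits by integer division of the code
  by 257.

## Problem sizes used by the test suite

The suite verifies each entropy engine against independent brute-force
enumeration oracles on 50 seeded patches per measure (9 × 9 to 12 × 12
pixels — small enough for exhaustive pair enumeration in R), runs 20
replicate full synthetic studies (144 images each) for the end-to-end
recovery checks, and 200 directly simulated null measure tables for the
criterion-2 calibration check. These sizes were chosen so the whole suite
exercises every claim at meaningful power while remaining a routine local
run.

## Known limitations

* Not every measure responds to added noise in the same direction. On
  smooth-plus-noise ensembles the property suite finds FuzzEn, PermEn and
  DispEn monotone increasing in the noise amplitude, but SampEn becomes
  undefined on most patches once the noise is large (censoring its
  observed mean non-monotonically), and DistEn *decreases*: because its
  histogram spans the per-patch distance range, a smooth correlated field
  produces a broad distance distribution while i.i.d. noise produces a
  concentrated one. Treating "entropy goes up with irregularity" as a
  universal reading of all five measures would be wrong; the selection
  procedure uses two-sided tests and is agnostic to direction.
* SampEn/FuzzEn are only approximately rotation invariant under the
  shared-anchor windowing (the m-stage window multiset shifts by one
  pixel under rotation); exact rotation invariance is tested for the
  census measures (PermEn on tie-free patches, DispEn, DistEn).
* Numeric agreement with any particular published entropy values is not
  claimed: the measures' parameters in the motivating literature are
  unreported, and several normalization conventions circulate.
* The synthetic generator's effect sizes are free parameters of the
  emulation, not estimates of equine physiology.
* Real-data mode (`image_file_measures()`, `select_measures()` on an
  external `measures.csv`) accepts PNG and TIFF; BMP is not supported.
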