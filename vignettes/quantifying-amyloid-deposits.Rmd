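---
title: "Quantifying fluorescent amyloid deposits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescent amyloid deposits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abetamorph)
```

## The measurement problem

Fluorescently labelled probes against amyloid-beta stain two visually
distinct populations in transgenic mouse brain sections: small puncta
(soluble oligomer assemblies, an imaged footprint of roughly 2 µm, typically
hugging neuronal nuclei) and large irregular plaques (roughly 14–20 µm,
sitting in the extracellular matrix). Reported burden statistics are
per-region deposit densities (deposits/mm² inside hand-drawn regions of
interest), per-deposit morphometrics (area, equivalent diameter,
eccentricity), screening scores for candidate probes (positive pixels above
a background-eliminating threshold), group contrasts of total signal, and
the deposit–nucleus spatial relationship.

`abetamorph` implements that measurement chain as a tested, scriptable
pipeline. Because the original micrographs behind such studies are rarely
deposited, the package ships a synthetic-scene generator with exact ground
truth; every stage is validated by recovery against planted scenes and by
brute-force oracles, and the reported regional densities (cortex 89.72,
hippocampus 38.87, hypothalamus 170.90, thalamus 122.44 deposits/mm²) serve
as generator presets, not as values the package claims to reproduce from
real tissue.

## The segmentation model

A calibrated single-channel micrograph (integer intensities, known µm/px)
passes through four stages:

1. **Adaptive local-mean threshold.** Pixel `p` is foreground iff
   `I(p) > mean(window(p)) + offset`. The local mean (square window,
   symmetric reflection at borders) absorbs slowly varying
   autofluorescence that defeats any global cutoff. The statistic is the
   plain mean — not Gaussian-weighted, not median — as the simplest
   faithful reading of "adaptive threshold"; both parameters are exposed
   because the original analysis reports none.
2. **Morphological opening** (erosion then dilation) with the discrete
   disk `{(dx, dy) : dx² + dy² ≤ r²}`, default radius 1 px. It deletes
   speckle smaller than the element; it also, necessarily, shaves corner
   pixels off small objects (a radius-1 disk is the 5-pixel cross, so a
   solid square loses exactly its four corners). Anything opening-based
   cannot be a strict superset of tiny objects' pixel sets; the tests
   assert strict pixel superset for the threshold stage and per-object
   retention for the opened mask.
3. **Connected-component labelling**, 8-connectivity by default
   (conventional for blob detection; 4-connectivity available). Labels are
   assigned in raster-scan order of first-encountered pixels, so results
   are deterministic and directly comparable against a flood-fill oracle.
4. **Small-object filter**, default 4 px: removes remaining single-pixel
   noise while keeping 2 µm deposits, which cover ~12 px at the default
   0.5 µm/px calibration.

### Why the default window is 101 px

The window must be large enough that a deposit does not dominate its own
background estimate. If a plaque of diameter `d` px sits inside a window of
side `w`, the local mean rises by roughly `(fg − bg)·π(d/2)²/w²`; the
object's interior stays detectable only while that fraction is below
`(fg − bg − offset)/(fg − bg)` (≈ 0.49 at the defaults). For 20 µm plaques
(40 px), `w = 51` sits exactly at that edge — noiseless images pass, but
any realistic noise fragments plaque interiors, inflating object counts
and deflating plaque diameters. The default is therefore 101 px
(≈ 50 µm, ≈ 2.5× the largest expected deposit), clamped to the image for
small frames; runtime is independent of the window because the filter uses
a summed-area table.

The default offset is 10 grey levels on an 8-bit scale, rescaled ×257 for
16-bit input. For noisy data a useful rule is `offset ≈ 2×` the noise SD:
a per-pixel background false-positive rate of `Φ(−2) ≈ 2.3%` falls to
`≈ 10⁻⁹` per site after the radius-1 opening (five simultaneous
exceedances), while foreground pixels at SNR 5 are missed with probability
`< 1%`.

## Morphometrics

Per object the package reports pixel count, physical area
(`count × px²`), centroid (µm, image frame, origin at the top-left pixel
center, x = column axis), **equivalent diameter** `2·sqrt(area/π)` and
**moment eccentricity** `sqrt(1 − λ₂/λ₁)` from the eigenvalues of the
second-central-moment matrix. Two numerical choices matter:

* Each pixel is treated as a unit square, adding 1/12 per axis to the
  second moments. Single pixels and 1-px-wide bars then have defined,
  stable eccentricities (a lone pixel is exactly circular, e = 0), and
  rasterized shapes converge to their continuous moments.
* "Diameter" means the area-equivalent circle, not the major axis: the
  source quantity ("size in diameter") is undefined, so the choice is
  explicit and configurable downstream.

Deposits are assigned to the ROI that contains their **centroid**, so an
object straddling a boundary is counted exactly once. Labelling runs on
the full mask rather than per-ROI crops, which would double-count
straddlers. Density is object count over the plain polygon area
(shoelace formula × px²) — not the polygon∩tissue area — matching the
stated definition of the original measurement.

## Separating oligomers from plaques

The two populations are separated on **log** equivalent diameter, because
both are plausibly multiplicative in spread. The threshold is the Otsu
criterion (exhaustive two-class variance minimisation over all split
points), accepted only when the optimal split's between-class/total
variance ratio exceeds a bimodality floor of 0.75. The floor comes from a
closed form, not from tuning: the best split of *any* unimodal Gaussian
sample cannot exceed `2/π ≈ 0.64` (attained by splitting a normal at its
mean), while 2 µm vs 14 µm log-normal mixtures with geometric SD 1.3 score
≈ 0.93. Below the floor the sample is treated as single-population and a
fixed fallback cutoff of 6 µm applies — the rounded-up geometric midpoint
`sqrt(2·14) ≈ 5.3` of the two reported population centers. Objects below
the threshold are oligomers; at or above it, plaques.

## Clone screening and group comparison

The screening quantification makes the manual "raise the threshold until
background disappears" step deterministic: the threshold for each
replicate is the maximum grey level of its matched negative-control
reference (a 99.9th-percentile variant is available for hot pixels), the
clone's score is its count of pixels strictly above that threshold, and
clones are ranked by mean count across replicates (mean ± SD, competition
ranking with exact ties, alphabetical tie order for determinism).
"Repeated three times" is read as three replicate sections per clone;
under a deterministic threshold, re-thresholding one image is a no-op.

Group contrasts use Student's pooled-variance unpaired t-test
(`df = n₁ + n₂ − 2`, two-sided), mirroring the stated analysis; Welch's
form is a flag. Zero pooled variance with equal means returns `t = 0,
p = 1`; with unequal means it is an error rather than a fake infinity.

## Deposit–nucleus association

Nuclei are segmented from the second channel with the same chain, keeping
components of equivalent diameter 4–15 µm (speckle below, deposit
bleed-through above). Each deposit's nearest-nucleus centroid distance is
classified **perinuclear** iff ≤ 10 µm (boundary inclusive) —
approximately one neuronal-soma radius beyond the nucleus center. The
original observation is visual, so any metric cutoff is an
operationalisation; it is recorded in every output, and a
surface-distance variant is deliberately out of scope because it would
inherit nucleus-segmentation error.

## The synthetic-scene generator

`scene_spec()` describes a two-channel field; `plan_scene()` places ground
truth; `render_scene()` rasterizes it. What it emulates:

* **Two deposit populations.** Equivalent diameters are log-normal:
  geometric mean 2 µm (oligomers) and 14 µm (plaques), geometric SD 1.3.
  Oligomers are disks; plaques are ellipses with minor/major axis ratio
  uniform on [0.75, 0.97], calibrated so rasterized eccentricity averages
  ≈ 0.5 with an SD comparable to reported per-region spreads.
* **Placement.** Each oligomer center sits exactly
  `perinuclear_offset_um` (6 µm = nucleus radius + one oligomer diameter)
  from a nucleus in its ROI; every plaque center is ≥ 3 nucleus diameters
  from every nucleus; no two deposits come closer than the sum of their
  bounding radii plus 3 px, so rendered objects never touch. Placement is
  rejection sampling with an attempt cap and an explicit error naming the
  ROI when a density is geometrically infeasible.
* **Counts are deterministic**: exactly `round(density × area)` per ROI
  and class, so recovery tests have exact targets (a Poisson count mode
  would blur every downstream tolerance; determinism was chosen on
  purpose).
* **Rendering.** A pixel belongs to an object iff its center lies inside
  the ellipse (boundary inclusive); coordinates are 0-based, row-major,
  origin top-left. Noise is additive zero-mean Gaussian, then rounding
  and clipping to the bit-depth range — one parameter, adequate for
  threshold testing.

Defaults fixed once and why: pixel size 0.5 µm/px (acquisition scale
unknown in the source; a free, documented choice); 16-bit with background
1000, foreground 6000, noise SD 500 (SNR 10; 16-bit avoids the background
zero-clipping an 8-bit SNR-5 scene would add on top of the Gaussian
model); nuclei 150/mm² with 8 µm diameter (a sparse single optical
section — dense enough to host perinuclear oligomers, sparse enough that
plaque exclusion zones remain feasible). Diameter draws are truncated:
oligomers at ≥ 1.6 µm, the smallest disk guaranteed to survive the
radius-1 opening at any subpixel position (sub-resolution spots below
~3 px would otherwise be erased by design); plaques at ≤ 20 µm, the size
this mouse model's plaques are reported to reach, which also keeps every
deposit within the adaptive window's detection margin.

What it does **not** emulate — and therefore what passing tests do not
show about real tissue: no point-spread-function blur, no vignetting or
illumination gradients, no Poisson shot noise, no touching or overlapping
deposits (and hence no need for watershed splitting), no lobed plaque
shapes beyond ellipses, no 3-D structure, no spectral cross-talk. Tests
against these scenes certify the *measurement chain*, not the biology.

## Reproducibility and problem sizes

Scenes are pure functions of their specification including the seed
(planning and rendering derive independent streams from it), so repeated
runs are byte-identical, and a run's manifest (parameters + seed + input
checksums) suffices to replay it — both properties are tested. The test
suite works at deliberately modest sizes: oracle checks on 16×16–64×64
grids, recovery on 0.09–0.25 mm² fields (hundreds of deposits per
condition), ten simulated slides for the four-region density preset, and
the acceptance script uses five slides plus one association scene and a
six-clone panel. The suite runs in about a minute on one CPU.

## Known limitations

* Touching deposits merge into one object; densities near the geometric
  packing limit will error at the planning stage rather than silently
  overlap.
* Objects wider than the adaptive window would lose their interiors
  (ring detection); the generator's 20 µm plaque cap keeps real use far
  from that regime, but users with larger structures must raise
  `window_px`.
* ROI assignment by centroid can drop a deposit whose centroid sits a
  fraction of a pixel outside its region; at the preset densities this
  biases regional counts by well under 1%.
* The bimodality floor assumes roughly log-symmetric populations; heavy
  contamination between size classes degrades the Otsu split before the
  fallback engages.
* `n = 1` standard deviations are reported as 0 with a `single_slide`
  flag rather than NA, keeping CSV outputs numeric — consumers must check
  the flag before interpreting spreads.
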