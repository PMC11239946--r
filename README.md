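# abetamorph

Segmentation and morphometric profiling of fluorescent amyloid deposits in
calibrated brain-section micrographs.

## What problem this solves

Fluorescent probes against amyloid-beta (nanobodies, antibodies) stain two
populations in transgenic mouse brain sections: small soluble-oligomer
puncta (~2 µm imaged footprint, typically adjacent to neuronal nuclei) and
large plaques (~14–20 µm, in the extracellular matrix). Quantifying such
staining means answering, per slide and brain region: how many deposits per
mm², how large, how round, which size class, how close to nuclei — and,
when screening probe candidates, which clone gives the most signal over a
matched negative control. `abetamorph` implements this measurement chain
as composable, tibble-returning functions for people analysing (or
simulating) fluorescence histology: image analysts in neurodegeneration
labs and anyone validating a burden-quantification protocol.

## The method

Given a calibrated micrograph (integer intensities, known µm/px):

1. **Adaptive threshold** — pixel `p` is foreground iff
   `I(p) > mean(window(p)) + offset` (local mean over a square window,
   reflection at borders); suppresses slowly varying autofluorescence.
2. **Tissue mask** — morphological opening with a discrete disk
   (default radius 1 px) removes speckle.
3. **Labelling** — connected components (8-connectivity by default,
   deterministic raster-scan label order), minus objects under 4 px.
4. **Morphometrics** — per object: area `A = n·px²`, equivalent diameter
   `d = 2√(A/π)`, eccentricity `e = √(1 − λ₂/λ₁)` from the unit-square
   corrected second central moments; ROI assignment by centroid.
5. **Density** — deposits per mm² of the ROI polygon (shoelace area).
6. **Size split** — Otsu threshold on log-diameter when the sample is
   bimodal (between/total variance ≥ 0.75), else a fixed 6 µm cutoff:
   `d` below the threshold ⇒ oligomer, at/above ⇒ plaque.
7. **Clone ranking** — per replicate, threshold = max grey level of the
   matched control ("background disappeared" made deterministic); score =
   pixels above threshold; rank clones by mean ± SD with exact ties.
8. **Group comparison** — Student's pooled-variance unpaired t-test on
   positive-pixel counts.
9. **Spatial association** — nearest-nucleus centroid distance;
   perinuclear iff ≤ 10 µm (inclusive).

A synthetic-scene generator (`scene_spec()`, `plan_scene()`,
`render_scene()`) plants both populations with exact ground truth —
deterministic per-ROI counts `round(density × area)`, oligomers at a fixed
perinuclear offset, plaques away from nuclei, Gaussian noise — so the
whole chain is testable without microscope data. See the vignette in
`vignettes/` for every parameter, default and design rationale.

## Worked example

Simulate one coronal-section field with four regions at realistic deposit
densities (cortex 89.72, hippocampus 38.87, hypothalamus 170.90, thalamus
122.44 deposits/mm², 0.25 mm² each), then quantify it end to end:

```r
library(abetamorph)

sp    <- scene_spec_5xfad(seed = 1)
truth <- plan_scene(sp)
imgs  <- render_scene(truth, sp)
rois  <- lapply(sp$rois, function(s) s$roi)

res <- run_quantify(list(slide1 = imgs$deposits), rois)
res$regions[, c("roi_name", "n_objects", "density_mean",
                "diameter_mean_oligomer_um", "diameter_mean_plaque_um")]
#> # A tibble: 4 × 5
#>   roi_name     n_objects density_mean diameter_mean_oligomer_um diameter_mean_plaque_um
#>   <chr>            <int>        <dbl>                     <dbl>                   <dbl>
#> 1 cortex              22           88                      2.25                    16.1
#> 2 hippocampus         10           40                      1.84                    16.9
#> 3 hypothalamus        43          172                      2.08                    13.3
#> 4 thalamus            30          120                      2.25                    13.5
```

Densities recover the planted presets up to count rounding (e.g. 172 vs
170.90: exactly `round(170.90 × 0.25)/0.25`), and the two diameter columns
recover the planted ~2 µm and ~14 µm populations. The size split behind
the `class` column is inspectable:

```r
glance(attr(res$objects, "split"))
#> # A tibble: 1 × 4
#>   threshold_um method separation     n
#>          <dbl> <chr>       <dbl> <int>
#> 1         5.59 otsu        0.909   105
```

The sample was confidently bimodal (separation 0.909 ≥ 0.75), so the
data-driven threshold (5.59 µm) was used. Deposit–nucleus association from
the second channel:

```r
run_associate(imgs$deposits, imgs$nuclei, rois)$summary
#> # A tibble: 2 × 4
#>   class        n fraction_perinuclear median_distance_um
#>   <chr>    <int>                <dbl>              <dbl>
#> 1 oligomer    84                    1               6.01
#> 2 plaque      21                    0              41.3
```

Every oligomer sits within the 10 µm perinuclear cutoff (planted at a 6 µm
offset from a nucleus; the measured median, 6.01 µm, recovers it); every
plaque is extracellular. `autoplot()` methods exist for region summaries,
splits, rankings and association summaries, and `tidy()`/`glance()` for
fitted objects. A thin command-line wrapper lives at
`inst/cli/abetamorph.R` (`simulate | quantify | rank-clones | associate`).

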