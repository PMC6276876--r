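# furrowquant

Quantification pipeline for time-lapse fluorescence microscopy of
epithelial invagination, built around the image analysis used to study
optogenetic perturbation of basal myosin-II during *Drosophila* ventral
furrow formation.

During gastrulation, ventral mesodermal cells constrict apically, elongate,
and later shorten while myosin-II at their basal surface is progressively
disassembled. Experiments that optogenetically maintain basal myosin-II are
read out through a chain of image measurements, all implemented here:

- **Basal/apical myosin-II levels** — the axial (z) intensity profile of a
  region is fitted with a Gaussian `offset + A exp(-(z - mu)^2 / 2 sigma^2)`;
  the basal peak position anchors a 5-slice quantification window (mean
  integrated density per area), the FWHM `2.355 sigma` measures axial signal
  spreading ("z-spread"), and per-cell apical levels are integrated over 3
  slices and normalized by the combined-population mean.
- **Actomyosin-ring kinetics** — rings of the cellularization front are
  detected by a circular Hough transform with sub-pixel center/radius
  refinement; diameters normalized to the first-frame mean are fitted with a
  line whose slope is the constriction speed, and ring counts per unit area
  give the tissue-compaction density.
- **3D cell-shape features** — per-cell length, apical/basal cap areas, the
  A/B (apical/basal cap volume) ratio, volume with a 25% CV outlier filter,
  and apical anisotropy, from z-consistent label volumes.
- **Pulsatile/ratchet constriction** — local-maxima pulse detection with
  prominence filtering, mean inter-peak period, the ratchet extent (mean
  apical-area difference between consecutive peaks), and the
  constricting/non-constricting classification (final area < half initial).
- **Statistics** — pooled two-sample t-test, one-way ANOVA with post hoc
  Tukey HSD, Cohen's *d* with `d = |x1 - x2| / s`, `s` the maximal SD of the
  analyzed dataset, and notched-boxplot summaries.

Because the original movies are not deposited, the package ships a
synthetic-microscopy generator (`make_tissue()`, `make_myosin()`,
`make_ring_field()`, `make_pulse_traces()`) that reproduces the statistical
structure the analysis assumes — constant-volume columnar-to-wedge cell
geometry, decaying or saturating basal myosin layers, linearly constricting
ring fields with lateral compaction, and ratchet/non-ratchet pulse traces —
with exact ground truth for every estimator test.

## Worked example

Two synthetic ring fields — an activated region constricting at 4.8% of the
initial diameter per frame and a control at 1.0% — analyzed by the
detection + normalized-diameter pipeline:

```r
library(furrowquant)

slope_for <- function(slope, seed) {
  cfg <- ring_field_config(n_rings = 49, radius0 = 3, slope = slope,
                           n_frames = 5, pixel_size = 0.2, noise_sd = 0.1,
                           seed = seed)
  rf  <- make_ring_field(cfg)
  det <- detect_rings_series(rf$images, pixel_size = 0.2, rmin = 2, rmax = 3.6)
  constriction_speed(det)
}
fit_ar <- slope_for(-0.048, 101)   # activated region
fit_nr <- slope_for(-0.010, 102)   # non-activated control
fit_ar
#> constriction_fit (pooled): slope -0.04794 per frame, r^2 = 0.999
fit_nr
#> constriction_fit (pooled): slope -0.01012 per frame, r^2 = 0.970
fit_ar$slope / fit_nr$slope
#> [1] 4.734663
```

The fitted slopes recover the generating constriction speeds within about
1%, and their ratio (~4.7) the programmed 4.8-fold speed difference between
the activated and control fields.

A pulse cohort with an 85/15 non-ratchet/ratchet mixture:

```r
cfg <- pulse_config(n_traces = 100,
                    class_mix = c(non_ratchet = 0.85, ratchet = 0.15),
                    seed = 4)
ps <- analyze_pulses(make_pulse_traces(cfg)$traces, min_prominence = 1)
ps
#> pulse_stats: 100 cells, 720 pooled intervals
#>   pooled mean period: 95.0 s (per-cell mean: 97.8 s)
#>   mean ratchet extent: 1.26 um^2
#>   constricting: 22 / 100
```

Cells pulse with a ~90-95 s mean period; the cohort ratchet extent is pulled
up from ~0 by the 15% ratcheting subpopulation, and the cells that ratchet
are the ones classified as constricting.

An end-to-end run (simulate, segment, shapes, myosin, rings, pulses, stats)
from a config:

```r
cfg <- list(pixel_size = 0.25, dz = 1, seed = 5,
            tissue = list(grid_shape = c(8, 8), cell_footprint = 5,
                          n_slices = 10,
                          shape_program = shape_program(seq(0, 855, by = 95),
                                                        25, 25, 6)))
run_pipeline(cfg, "out/")   # writes 9 CSV tables, each stamped with seed + config hash
```

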