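---
title: "Quantifying basal myosin-II dynamics and apical constriction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying basal myosin-II dynamics and apical constriction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(furrowquant)
```

## Scope

During *Drosophila* ventral furrow formation, mesodermal cells constrict
apically, elongate, and then shorten while the myosin-II pool at their basal
surface is progressively lost. Optogenetic experiments that counteract this
basal relaxation produce phenotypes that are read out entirely through image
quantification: basal and apical myosin-II levels along the apico-basal (z)
axis, the constriction kinetics and density of basal actomyosin rings, 3D
cell-shape features from membrane label volumes, and the pulsatile "ratchet"
statistics of apical-area time series. `furrowquant` reimplements that
quantification chain as a tested, scriptable pipeline, together with a
synthetic-microscopy generator that provides ground truth in place of the
original (undeposited) movies.

Conventions used everywhere: image arrays are `[y, x, z]` with z slice 1 the
apical-most plane and z increasing toward the base; all outputs are in
physical units (micrometers, seconds) via the `pixel_size` and `dz`
calibration; 0-based physical z positions (`z_positions()`) start at 0 um on
the apical slice.

## The synthetic-data generator

The generator is first-class, tested code: its outputs carry exact ground
truth, and every estimator in the package is validated against it.

**Tissue geometry** (`make_tissue()`). Cells are generalized frusta on a
square grid: the cross-sectional area interpolates linearly from the apical
to the basal value over the occupied slices, and a cell's length is a whole
number of slices. With `constant_volume = TRUE` the per-slice areas are
rescaled — including a correction for the rounding of the slice count — so
each cell's volume is exactly time-invariant, emulating incompressible
embryonic cells (the truth-table volume CV over time is below 0.1%).
Rasterization selects, per cell and slice, the pixels with the largest
fractional coverage of the analytic square until the pixel count matches the
analytic area, so label-volume measurements agree with the truth table to
better than 2% at the pixel sizes used here (0.15-0.25 um). The membrane
channel is the label boundary, dilated to the configured membrane width,
blurred with a Gaussian PSF, plus additive Gaussian noise.

**Myosin volumes** (`make_myosin()`). The basal myosin pool is a laterally
uniform layer whose axial profile is Gaussian with configurable FWHM,
centered at the cell base, on a constant background. Region-specific
amplitude time-courses encode the biology: `amp_decay(fold, duration)` for
the developmental loss (5-fold in mesoderm, ~3-fold in ectoderm over the
course of internalization), `amp_saturating(fold, t_sat)` for optogenetic
recruitment (1.6-fold at 6 min under the standard activation protocol,
sampled at the 95-s activation cycle), `amp_constant()` for controls.

**Ring fields** (`make_ring_field()`). Actomyosin rings of the
cellularization front are bright circles with a Gaussian radial
cross-section on a jittered grid. Diameters change linearly per frame
(`radius0 * (1 + slope * frame)`); lateral tissue compaction contracts the
coordinates inside a designated region isotropically by `1/sqrt(factor)`,
so the areal ring density there increases exactly by `factor`. The
generator returns the compacted-extent and outside masks so density ratios
are measured over the correct areas.

**Pulse traces** (`make_pulse_traces()`). Apical areas pulse with a
configurable period (90 +/- 5 s by default, matching ventral-furrow
pulsation). Within each cycle the area falls by the pulse amplitude along a
half-sine and relaxes along a half-sine, either fully (non-ratchet) or
retaining `ratchet_lockin` um^2 per pulse (ratchet). The literature
describes this phenomenology without a waveform equation, so the half-sine
stair-step is a documented stand-in; statistics that only use peak
positions and peak areas are insensitive to the exact waveform. Ratcheting
cells stop pulsing at a floor of 10% of the baseline area — a fully
constricted cell — which also means the floor phase contributes no detected
peaks. Defaults: baseline 40 um^2, pulse amplitude 10 um^2, lock-in 6 um^2,
sampling every 35 s (the acquisition cadence of the pulsation protocol),
measurement noise 0.5 um^2.

What the generator does *not* emulate: curved embryo geometry (flat sheet
only), photobleaching, depth-dependent scattering, anisotropic PSFs, and
cell rearrangements (neighbor exchanges). Passing tests therefore
demonstrate estimator correctness under the stated statistical structure,
not robustness to every artifact of real embryo movies.

## Segmentation and tracking

`bandpass()` is a difference-of-Gaussians with feature band 2-10 um (the
sigma of each Gaussian is `size / (2 sqrt(2 ln 2))` in pixels); it has zero
response to constant input. `segment_slice()` runs a watershed on the
inverted filtered image; the watershed's intensity tolerance `h` (default
0.05 on the normalized inverted image) merges basins separated by ridges
shallower than `h`, playing the role of an h-minima marker depth. Regions
with equivalent diameter below 2 um are discarded, as are basins larger
than `max_cell_size` (default 30 um) — a field without a membrane lattice
produces one giant basin that is background, not a cell.

`link_labels()` links regions across adjacent frames or z-slices when
`|intersection| / min(|A|, |B|) >= 0.4`. The overlap denominator (smaller
region) and the greedy one-to-one tie-break (largest overlap first, then
lower label id) are our documented choices; only the 0.4 threshold itself
is prescribed. The same rule is used across time and across z
(`track_labels()`, `segment_volume()`). Manual vertex correction of the
original interactive workflow is replaced by accepting externally supplied
label volumes in `reconstruct_cells()`.

## Myosin quantification

`zprofile()` averages per-slice mean intensities over a subregion grid
(default 4x4, pixel-count weighted — the subdivision accommodates the
uneven morphology of a real embryo; on flat synthetic tissue it is a
no-op), then fits `offset + A exp(-(z - mu)^2 / (2 sigma^2))` by
Levenberg-Marquardt least squares. The fit is initialized at the argmax of
the basal half (`basal_from = 0.5` of the axial range), with sigma = 2
slices and amplitude = max - min, and `mu` is bounded to the basal half so
a brighter apical peak cannot capture the fit. "Width" of the fit is
reported as FWHM = 2.355 sigma. Profiles that are flat or that only
decrease toward the base raise a peak-not-found error.

`basal_level()` averages the integrated density per area over 5 slices
(5 um at unit spacing) centered at the fitted peak. Levels default to
per-pixel area (the mean ROI intensity per slice), with `per_um2 = TRUE`
for um^-2 units; a window clipped by the stack border is truncated with a
warning and flagged. Note that levels deliberately include the constant
background, as in the original protocol; fold-changes of
background-containing levels are therefore slightly compressed toward 1
relative to the amplitude fold (about 3% under the default synthetic
conditions).

`basal_projection()` sums the window and normalizes by the mean over the
analyzed area (mean 1 by construction). `apical_levels()` integrates 3
slices at the apical peak per cell and normalizes by the combined
population mean, so region comparisons are scale-free. `fit_timecourse()`
is ordinary polynomial least squares with `r^2 = 1 - SSres/SStot` and the
convention `r^2 = 0` for constant data.

Whether published fold *reductions* anchor on the first frame or on a
fitted curve is not stated in the sources we mirror; `fold_change()` takes
explicit numerator and denominator levels, so either convention is one
line of user code, and the examples use first-frame anchoring.

## Ring kinetics

`detect_rings()` is a circular Hough transform implemented as matched
filtering with zero-mean, unit-norm annulus kernels at one-pixel radius
steps (FFT convolution). Candidate peaks (8-neighborhood local maxima at or
above `threshold` = 0.5 of the global maximum by default) undergo greedy
non-maximum suppression jointly in center (minimum distance `rmin`) and
radius, then sub-pixel refinement: parabolic interpolation of the score
surface for the center and of the angular-mean radial intensity profile
for the radius. Refinement is what makes per-frame diameter changes of a
fraction of a pixel resolvable. Two verification passes follow: a contrast
check — the lower decile of the intensity along the refined circle must
reach `threshold` of the best detection's, which removes accumulator
side-lobes (e.g. between two concentric rings) that touch bright structure
only on short arcs — and a dedup pass that collapses candidates from
neighboring radius layers refining to the same circle (within 1 px) while
keeping genuinely concentric rings.

`constriction_speed()` normalizes diameters to the population mean of the
first frame and fits an ordinary least-squares line; the slope (negative =
constriction) is the speed, per frame and per second. Pooled fitting over
all detections is the default; `mode = "tracked"` first matches rings
across frames by nearest center (within `max_disp`, default `rmin`) and
uses only rings tracked from frame 1 — provided because it is unstated
whether published diameter series were pooled or tracked. `ring_density()`
counts detected centers inside a mask per unit mask area.

## Shape features

`reconstruct_cells()` measures per-slice areas and centroids of each cell
id in a z-consistent label volume. Cell length is the occupied slice count
times `dz` (not a centroid path length — the simplest measure consistent
with columnar cells); volume is the slice-area sum times `dz`. The A/B
ratio is the apical-cap volume over the basal-cap volume with 3-slice caps
by default, mirroring the 3-slice apical myosin window, since the cap size
behind "most apical/basal volume" is not defined in the sources; cap areas
default to the mean over the cap (`cap_mode = "extreme"` for the single
end slice). A ratio of 1 is columnar, < 1 an apically constricted wedge.
Cells with an axial gap of more than one slice are flagged incomplete.
`filter_volume_outliers()` retains cells within 25% of the mean volume in
a single pass. `anisotropy()` is the major/minor axis ratio of the
second-moment ellipse, computed in closed form for polygons and from pixel
moments for masks — a documented stand-in, since the original feature's
definition is not restated in the sources.

One unit ambiguity is inherited knowingly: published basal "areas" are
printed with micrometer units; we treat them as um^2 throughout.

## Pulse statistics

`find_pulses()` reports interior local maxima with topographic prominence
at least `min_prominence`. The default prominence is twice a robust noise
estimate (MAD of first differences over sqrt(2)); on traces whose pulse
period is only ~2.6 samples long, first differences are dominated by the
pulses themselves and this default is conservative, so cohort analyses of
the synthetic traces pass the analysis convention explicitly
(`min_prominence = 2 * noise SD`, i.e. 1 um^2 at the default noise).
`pulse_period()` is the mean inter-peak spacing; `analyze_pulses()` reports
both the pooled-interval and the per-cell-mean view, pooled being the
default summary, since the published averaging order is unstated.
`ratchet_extent()` is the mean area difference between consecutive peaks
with the sign convention positive = net constriction per pulse.
`classify_constriction()` calls a cell constricting iff its final area is
strictly below half its initial area (boundary cases are
non-constricting); initial/final areas are means over the first/last 2
samples (`edge_samples = 1` for the single-frame reading).

## Statistics

`ttest2()` is the pooled-variance two-sample t-test (two-sided), with the
degenerate convention p = 1 for two constant equal-mean samples.
`anova_tukey()` is one-way ANOVA with F(k-1, N-k) plus Tukey HSD adjusted
pairwise p-values. `cohens_d()` defaults to `d = |mean1 - mean2| / s` with
`s` the maximal SD over the analyzed dataset (the convention under which
d <= 0.5 reads as low and d >= 1 as large); because the defining formula
renders ambiguously in the source material ("(x1 - x2) 2s"), a
`max_sd_half` variant dividing by 2s is selectable, as is the textbook
pooled-SD denominator. `box_summary()` uses type-7 (linear interpolation)
quartiles, 1.5 IQR outliers, whiskers to the most extreme non-outliers
(with a literal `whiskers = "extremes"` mode, for legends that draw
whiskers to the extremes yet mark outliers), and notches at
`median +/- 1.57 IQR / sqrt(n)`.

## Pipeline, I/O and reproducibility

`run_pipeline()` executes simulate, segment, shapes, myosin, rings, pulses
and stats in order on a validated config (`pipeline_config()`; YAML/JSON or
a list). Every output CSV carries the config hash and seed as comment
lines, and a rerun with the same config byte-reproduces all tables. A
failing stage aborts with a stage-tagged error, leaving completed tables
in place. Stacks are multi-page 32-bit TIFFs (z as pages); samples
quantize at ~2e-10 of full scale, values above 1 are rescaled via a
plain-text `.scale` sidecar, and negative intensities are clipped with a
warning. All generators take integer seeds and restore the caller's RNG
stream, so identical seeds give bit-identical outputs.

A thin command-line wrapper (`inst/cli/furrowquant.R`) exposes
simulate/run/pulses/rings subcommands over these functions; the package
functions themselves are the primary interface.

## Problem sizes and numerical choices

The bundled tests and the acceptance script run on deliberately compact
problems chosen to estimate each quantity well: ring-speed ratios use two
fields of 49 rings over 5 frames at 0.2 um/px with 10% intensity noise;
the compaction ratio uses 400 rings; myosin fold-recovery uses paired
64x128 px stacks of 41 slices sampled at the 95-s activation cadence;
pulse cohorts use 100-407 traces of 15 min at 35-s sampling. Gaussian
z-profile fits are validated against dense grid-search oracles to within
1%; the watershed's segmentation quality is asserted as per-cell Jaccard
>= 0.9 on noiseless 10-um cells at 0.15 um/px.

## Known limitations

Segmentation is a minimal watershed stage reproducing stated parameters,
not a reimplementation of the original interactive tool; heavily noisy or
low-contrast membranes will need externally supplied labels. Ring
detection assumes approximately circular rings (no ellipse fitting, as in
the source analysis). The pulse waveform is a stand-in; only peak-based
statistics should be interpreted. Basal myosin levels include the imaging
background; subtract the fitted Gaussian offset explicitly if an
amplitude-pure fold is needed.
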