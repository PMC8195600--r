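---
title: "Methods: reporter segmentation, plate-screen normalization and cohort statistics"
author: "adipoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reporter segmentation, plate-screen normalization and cohort statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoquant)
```

# The measurement problem

Transparent (*casper*) zebrafish carrying a perilipin-2/tdTomato fusion
transgene express the reporter on the surface of adipocyte lipid droplets, so
visceral adipose tissue can be imaged repeatedly in live fish. The confound
is tissue autofluorescence: the intestinal loops and gallbladder fluoresce
strongly across GFP, tdTomato and Cy5 filter sets, while the reporter signal
is restricted to tdTomato. The package's segmentation, screen and cohort
modules implement the quantitative workflows around this reporter; a
simulator produces every input with planted ground truth so each step is
testable without a microscope.

# Reporter segmentation

`quantify_fish()` composes three steps:

1. **Autofluorescence gating** (`subtract_background()`). Any pixel whose
   GFP intensity reaches `gfp_background_thresh` is classified as
   autofluorescent background and its tdTomato value is set to zero.
   Two readings of "subtracting background" are possible — excluding the
   pixels or subtracting the intensities — and the default is mask exclusion,
   which matches the goal of removing gut signal entirely; intensity
   subtraction is available as `background_mode = "subtract"`.
2. **Fixed-size crop** (`detect_crop()`). If any background-subtracted
   tdTomato pixel reaches `tdt_detect_thresh`, a box of exactly `crop_size`
   is centered on the intensity-weighted centroid of the supra-threshold
   pixels. At image borders the box is shifted, never shrunk, so the crop
   area is always identical between fish. If nothing is detected the result
   is `detected = FALSE` with zero area.
3. **Masked high-threshold segmentation** (`segment_in_crop()`). Within the
   crop, the supra-detect-threshold pixels are dilated by `mask_dilation_px`
   (Chebyshev radius) to form a coarse adipose mask; the final mask keeps
   pixels inside it that reach the higher `tdt_segment_thresh`, then drops
   8-connected components smaller than `min_component_px`. The area is the
   surviving pixel count, and `area_um2 = area_px * pixel_size^2`. Multiple
   depots are summed into one total area per fish.

Defaults (`segmentation_config()`): GFP background threshold 300 AU,
tdTomato detect/segment thresholds 250/500 AU, crop 160 x 160 px, minimum
component 20 px, dilation 2 px. These are declared conventions for the
simulator's intensity scale (background 100 AU, reporter peak 900 AU):
no published threshold values exist for this assay, so real images need
thresholds calibrated to their own acquisition settings. The config travels
with every result (`thresholds_used`) so a measurement is always
reproducible from its record.

Two properties are worth knowing. Raising `tdt_segment_thresh` can only
shrink the area (monotonicity), and gating is idempotent. And in the
noiseless, unblurred limit, segmentation is *exact*: the final mask equals
the planted adipose mask pixel-for-pixel, with gut pixels contributing zero
— this is the regime the specificity tests run in.

The dye-stain variant (`bodipy_area()`) replaces fixed thresholds with
automatic ones: the dye (GFP) channel is thresholded by isodata — the
iteration `t <- (mean below + mean at/above) / 2` run to a 0.5 AU tolerance
from the midrange start, the historical default of interactive tools
(Otsu on a 256-bin histogram is selectable, and the report records which
method produced every threshold) — and autofluorescence is removed as a
mask-level set difference with the auto-thresholded Cy5 channel, optionally
intersected with a polygon ROI (even-odd rule, boundary-inclusive pixel
centers, 0-based coordinates). When no ROI is supplied the full image is
used, which replaces the interactive polygon step in batch runs.

# The image simulator

`generate_fish_image()` plants filled ellipses (hard edges, then Gaussian
blur of `blur_sigma`, default 1 px) as adipose blobs in the central field,
and one elongated elliptical gut region along the lower image edge. Channel
composition mirrors the biology: the reporter image puts adipose at
`adipose_peak` in tdTomato with a small configurable GFP leak; the gut
appears in all three fluorescence channels; `generate_bodipy_image()`
instead puts adipose in GFP only. Noise is additive Gaussian on a constant
background by default (Poisson selectable); no camera noise model is claimed
by the source assay, so this is a declared choice. Blob placement is
rejection-sampled so blobs never overlap the gut (bounded at 200 attempts,
then an error); explicit blob tables can be passed for geometric tests.

Ground-truth area is defined on the ideal rasterized ellipse *before*
blurring (pixel centers inside the quadratic form, boundary inclusive — a
radius-10 disc at an integer center covers exactly 317 lattice points, a
radius-5 disc 81). Blur moves the half-maximum contour slightly outside the
ideal boundary: with the default thresholds the segment threshold sits at
44% of the reporter peak above background, predicting a ~0.1-0.2 px outward
shift, i.e. a low-single-percent area overestimate for the default blob
sizes. The recovery suite (50 simulated fish at default noise) therefore
checks the *median* relative area error against a 5% envelope rather than
exactness; observed medians are ~0.2-0.3%.

What the simulator does not emulate: anatomy (fish outline, swim bladder,
skin iridophores), optical PSF structure, depth-dependent attenuation,
stage drift, or spatially correlated autofluorescence texture. Passing
tests demonstrate the algorithmic contract (specificity, monotonicity,
recovery under the stated noise), not performance on real micrographs,
where thresholds must be tuned and autofluorescence is messier.

Every generator takes one integer seed and restores RNG state afterwards
(`withr::with_seed`), so identical parameters give bit-identical outputs
and no global state leaks between calls.

# Plate-screen normalization and hit calling

The lipolysis screen reads secreted glycerol by a coupled colorimetric
assay at 540 nm. The analysis chain is:

* **Standard curve** (`fit_standard_curve()`): OLS of absorbance on the
  glycerol ladder; the simulator's ladder spans 0-1 mg/ml in six steps
  (the published assay does not print its ladder). Inversion
  (`absorbance_to_glycerol()`) clamps negative concentrations to zero with
  a warning — those arise from blank-level noise only.
* **Position normalization** (`position_normalize()`): the factor for well
  position (r, c) is the arithmetic mean of glycerol at that position
  across all plates, computed over compound and DMSO wells only; each well
  is divided by its factor. Division (not subtraction) is used so that
  "normalized value 1" means "no effect" and log2 reporting is coherent.
  Factors are computed on glycerol rather than raw absorbance so the curve
  intercept cannot leak into them. A purely positional multiplicative bias
  — e.g. the elevated outer ring `edge_bias_map()` plants — cancels exactly
  in the noiseless limit, which the suite verifies to 1e-9.
* **Hit calling** (`call_hits()`): fold change is the compound's normalized
  glycerol over the mean normalized DMSO of its plate (DMSO is the stated
  vehicle control; the baseline choice is configurable), reduction is
  `1 - fold`, and the default threshold of a 40% reduction is boundary
  inclusive — a fold of exactly 0.60 is a hit. Ranking uses ascending
  log2 fold with compound-id tie-breaks for determinism.
* **Control QC** (`control_qc()`): per plate, DMSO mean and CV and the
  positive-control (isoproterenol-stimulated) fold; plates with fold <= 1
  or excessive DMSO CV are flagged. QC works from raw glycerol because
  positive controls are excluded from normalization.

## Planted-effect recovery and the noise operating point

The simulator plants 29 inhibitors at 50% reduction among 1280 compounds on
16 plates (ids spread with step 43, coprime with the 80 compound wells per
plate, so all 29 occupy distinct plate positions). Because a compound well
participates in its own position factor, a planted 50% reduction measures
as `1 - 0.5 / ((15 + 0.5)/16) = 48.4%`, an 8.4-point margin over the 40%
threshold. Per-well lognormal noise of CV `c` propagates to a fold SD of
roughly `0.52 * c * sqrt(1 + 1/4)`; at `c = 0.05` that margin is only
~2.9 SD and a miss among 29 compounds is expected for a noticeable fraction
of random seeds, whereas at `c = 0.02` the margin is ~7 SD and recovery is
seed-independent. The recovery experiments therefore run at CV = 0.02
(within the assay-realistic <= 5% band; the simulator default stays 0.05);
false positives are ~9 SD away and never observed.

# Cohort statistics

`normalize_bmi()` forms the adiposity index area / standard length
(um^2/mm), the BMI-like normalization for growing fish.
`summarize_longitudinal()` reports per group and day the mean with a
t-based 95% CI (a declared convention; groups with n < 2 get an undefined
CI). `compare_groups()` uses the field's nonparametric tests: Mann-Whitney
for two groups — exact when samples are small and tie-free, otherwise the
normal approximation with tie correction — and Kruskal-Wallis with Dunn's
pairwise z-tests for more, with Holm adjustment by default (configurable;
both raw and adjusted p-values are emitted because published figures do not
always say which they star). Exact two-sided p-values match full
enumeration of rank assignments for all group sizes with n1 + n2 <= 8, and
the empirical size of the exact test at n = 10 per group is the discrete
0.0433 at nominal 0.05.

The cohort simulator encodes the observed feeding kinetics as its default
expected curves: fed fish (n = 46) grow in length and area over days 0, 2,
5, 7, while fasted fish (n = 57) hold area through day 2 — adiposity loss
begins only after two days of food deprivation — and decline steeply
afterwards, with standard length plateauing. A high-fat-diet preset
(`cohort_sim_params_hfd()`; days 0, 7, 14; n = 57 control / 61 HFD) raises
the area trajectory without separating the length curves. Between-fish
variation is a multiplicative per-fish effect (fractional SD 0.15 for area;
one third of that for length, which varies far less than adiposity across
siblings), within-fish measurement noise is 5%; the published work reports
no variance components, so these are realistic placeholders, and parameter
validation enforces the curve shapes (non-decreasing fed length; fasted
area >= 95% of baseline through day 2, strictly declining after).

`percent_positive()` implements the flow-cytometry gate: the
`control_quantile` (default 0.99) of the lipid-droplet-low control's
reporter intensities, taken as the inverse-ECDF quantile so the gate is an
actual control order statistic — this makes the reported fraction exactly
invariant under monotone transforms of the intensity axis (e.g. log
display scaling). The returned value is the fraction of sample events
strictly above the gate; by construction a sample identical to the control
reads ~1%, so a planted 30% mixture reads ~30.7% — the gate convention, not
an error — and the quantile is configurable and logged.

# Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col), row 0 at top; crop boxes half-open.
  ROI pixel membership is center-in-polygon, even-odd, boundary inclusive.
* Connected components use 8-connectivity throughout.
* Isodata stops when the threshold moves < 0.5 AU; constant images raise a
  degenerate-input error naming the channel.
* `detect_crop` rounds the centroid half-up (deterministic, no banker's
  rounding); even crop sizes bias the box half a pixel up-left, documented
  rather than hidden.
* TIFF round trips: integer data in [0, 65535] are stored as 16-bit pages
  and recovered exactly; other data are stored as float32 with a recorded
  scale (relative error < 1e-6). RGB pages are rejected — channels must be
  separate pages. Proprietary microscope formats are out of scope and must
  be converted externally.
* Standard-curve inversion requires a nonzero slope; all-equal standard
  concentrations are a fit error; a non-positive normalization factor names
  its well position.

# Problem sizes used by the test and acceptance runs

Specificity runs on three noiseless 256 x 256 images; recovery on 50
simulated fish at default noise; bias removal and hit recovery on full
16-plate, 1280-compound screens; the test-size experiment on 10,000 null
cohorts of 10 fish per group; threshold classification on 40,000-pixel
mixtures; flow recovery on 100,000 events. These sizes make every
stochastic check statistically decisive (binomial SE ~0.002 for the test
size; ~0.0015 for the flow fraction) while a full run stays in the
tens-of-seconds range.

# Known limitations

* Thresholds are absolute intensities; quantile-based auto-calibration for
  the reporter channel is not implemented (the dye workflow has it via
  isodata/Otsu).
* No per-adipocyte instance segmentation, no 3D stacks, no B-score or
  median-polish plate normalization (the per-position mean is the method
  under test; alternatives would be extensions).
* No mixed-effects longitudinal modeling; the repeated-measures structure
  is preserved in the data model but group comparisons are cross-sectional
  per day.
* The simulator's realism limits are listed above; exact-specificity
  results hold in its noiseless unblurred regime only.
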