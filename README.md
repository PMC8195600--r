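# adipoquant

Quantification tools for an in vivo lipid-droplet reporter in transparent
zebrafish and for high-throughput lipolysis screens.

A perilipin-2/tdTomato fusion transgene marks the surface of adipocyte lipid
droplets, so visceral adipose tissue can be imaged repeatedly in live
juvenile fish. Quantifying it is confounded by gut and gallbladder
autofluorescence, which bleeds across the GFP, tdTomato and Cy5 filter sets
while the reporter is tdTomato-only. `adipoquant` implements:

* **Reporter segmentation** — gate the tdTomato channel with a GFP
  background threshold (pixels with GFP ≥ *t*<sub>bg</sub> are zeroed), crop
  a fixed-size window around the detected signal, segment with a higher
  tdTomato threshold inside a dilated coarse mask, and report adipose area
  *A* in pixels and µm² (`quantify_fish()`).
* **Dye-stain quantification** — isodata/Otsu auto-thresholding of the dye
  (GFP) channel with Cy5-auto-thresholded autofluorescence removed as a mask
  set-difference, optionally inside a polygon ROI (`bodipy_area()`).
* **Plate-screen analysis** — glycerol standard curve *a* = β₁·*c* + β₀ and
  its inversion; per-position normalization factors
  *f*(r,c) = mean over plates of glycerol at (r,c), which cancel
  multiplicative edge effects exactly; fold change versus DMSO vehicle and
  hit calling at a reduction threshold, 1 − fold ≥ 0.40, boundary inclusive
  (`analyze_screen()`).
* **Cohort statistics** — the BMI-like adiposity index area/standard-length
  (µm²/mm), longitudinal group means with 95% CIs, Mann-Whitney /
  Kruskal-Wallis + Dunn comparisons, and flow-cytometry percent-positive
  gating on a control quantile (`compare_groups()`, `percent_positive()`).
* **Synthetic data with ground truth** — fish images with planted adipose
  ellipses and an autofluorescent gut region, screens with planted
  position bias and inhibitors, growth cohorts, and two-population flow
  samples (`generate_fish_image()`, `generate_screen()`,
  `generate_cohort()`, `generate_flow_sample()`), so the whole pipeline is
  testable against known truth.

## Worked example

```r
library(adipoquant)

## segment a synthetic reporter image and compare with planted truth
g   <- generate_fish_image(image_sim_params(seed = 42))
res <- quantify_fish(g$image)
res
#> <segmentation_result> detected = TRUE, area_px = 1773, area_um2 = 11081.2
#>   crop rows [40,200), cols [49,209)
g$truth$adipose_area_px
#> [1] 1773

## a 16-plate screen with 29 planted 50%-reduction inhibitors
ids <- sprintf("C%04d", 20 + 43 * (0:28))
scr <- generate_screen(screen_sim_params(cv = 0.02,
         inhibitor_effects = setNames(rep(0.5, 29), ids), seed = 42))
an  <- analyze_screen(scr$plates)
an$curve
#> <standard_curve> absorbance = 0.795143 * conc + 0.051089 (r2 = 0.9983, n = 96)
sum(an$hits$is_hit)
#> [1] 29
head(an$hits[, c("compound_id", "fold_vs_dmso", "reduction", "is_hit")], 3)
#>     compound_id fold_vs_dmso reduction is_hit
#> 20        C0020        0.493     0.507   TRUE
#> 708       C0708        0.495     0.505   TRUE
#> 63        C0063        0.496     0.504   TRUE

## fed vs fasted adiposity at day 7 of the simulated time course
co <- generate_cohort(cohort_sim_params(seed = 42))
compare_groups(co, "area_per_sl", day = 7)
#> <group_comparison> mann-whitney: statistic = 0, p = 3.514e-18 (n = 57, 46)
```

The segmentation recovers the planted area exactly here because the
measured mask and the planted mask coincide; at default noise the median
relative area error across 50 simulated fish is ~0.2%. All 29 planted
inhibitors are called with no false positives among the 1251 nulls: a
planted 50% reduction measures as ~48% because each compound well
participates in its own position factor (see the methods vignette).

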