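# pericap

Peripapillary capillary density (PCD) quantification for en-face OCT
angiography, with the cohort statistics used to compare optic neuropathies.

## What it measures, and for whom

The radial peripapillary capillaries (RPC) perfuse the retinal ganglion cell
axons inside the retinal nerve fiber layer (RNFL). Glaucoma (POAG) and
ischemic optic neuropathy (NAION) destroy those axons, and the capillary
dropout is visible on en-face OCT-A scans of the optic nerve head. `pericap`
turns a 4.5 × 4.5 mm grayscale angiogram into density percentages that
describe the *microvasculature only*:

```
PCD = 100 · |perfused capillary pixels ∩ region| / |region pixels|
```

with the major retinal vessels removed from both numerator and denominator.
Regions are the whole image minus the inner 1.95 mm circle, the annulus
between concentric 1.95 mm and 3.45 mm circles, and its four anatomical
quadrants (superior / nasal / inferior / temporal, laterality-aware).

The binarization follows the established en-face pipeline: ×6 bilinear
upscale → 1%/99% percentile contrast stretch → global threshold at 0.55
(strict) → caliber-based major-vessel removal (40 µm cutoff, measured by
distance transform) → 15 × 15 local adaptive threshold. A color-coded
density map (16 px windows, 8 px stride) accompanies each eye.

Downstream, the package fits the study-grade statistics: linear mixed
models with a subject-level random intercept (two eyes per subject) and
Bonferroni-corrected pairwise group contrasts adjusted for age, sex and
axial length; within-eye sector contrasts; univariable PCD–RNFL/MD
regressions; and Dunn–Clark z tests for differences between dependent
non-overlapping correlations, e.g.

```
z = (atanh(r₁) − atanh(r₂)) · sqrt((n − 3) / (2 − 2c))
```

with `c` the Pearson–Filon correlation between the two sample correlations.

Everything is testable without patient data: seeded simulators generate
angiograms with known per-pixel capillary ground truth and cohort tables
with prescribed group means, inter-eye correlation and sector-level
PCD–RNFL correlations.

## Worked example

```r
library(pericap)

## a synthetic eye with 40% true capillary fraction
sim <- simulateAngiogram(angiogramSimSpec(capillaryFraction = 0.40, seed = 7))
seg <- segmentCapillaries(sim$angiogram)          # x6, 0.55, 40 um, 15x15
roi <- makeAnnulus(nrow(capillaryBinary(seg)), scalePxPerMm(seg))
computePCD(seg, roi)
#> PCDResult (%):
#>   whole image     36.7
#>   whole annulus   37.1
#>   superior        32.6
#>   nasal           34.0
#>   inferior        40.9
#>   temporal        40.3
```

The whole-image value (36.7%) is lower than the annular one because the
frame corners carry the sparser far-peripheral mesh; the annular 37.1% sits
within 3 points of the 40% ground truth (the residual bias comes from
binarizing a sub-resolution mesh; see the vignette).

```r
## a cohort with the study's group structure, analysed end to end
tab <- simulateCohort(cohortSimSpec(seed = 1))
compareGroups(tab, "pcd_annulus_pct")
#> GroupComparison for 'pcd_annulus_pct' (181 eyes, 104 subjects)
#>   adjusted for: age_years, sex, axial_length_mm
#>          contrast estimate    SE  df   lower upper    p_raw    p_adj
#>   control - NAION   12.258 1.073  74  10.119 14.40 5.41e-18 3.25e-17
#>  control - fellow    1.668 1.059  74  -0.442  3.78 1.19e-01 7.17e-01
#>    control - POAG   12.806 0.985 100  10.852 14.76 3.23e-23 1.94e-22
#>    NAION - fellow  -10.590 1.143  74 -12.867 -8.31 5.19e-14 3.12e-13
#>      NAION - POAG    0.548 1.221  74  -1.884  2.98 6.55e-01 1.00e+00
#>     fellow - POAG   11.138 1.204  74   8.739 13.54 5.55e-14 3.33e-13
```

Both patient groups sit ~11–13 points below their comparators (p ≪ 0.001)
while NAION vs POAG and control vs fellow are null — the qualitative
pattern the simulator is parameterized to produce.

```r
## is the superior PCD-RNFL coupling stronger than the nasal one?
compareDependentCorrelations(r1 = sqrt(0.57), r2 = sqrt(0.18), n = 119)
#> CorrelationComparison: r1 = 0.755, r2 = 0.424, diff = 0.331 (n = 119)
#>   Dunn-Clark z = 4.048, two-sided p = 5.16e-05 [conservative: intercorrelations unknown]
```

`runQuantify()` batch-processes a directory of TIFF/PNG angiograms into a
per-eye CSV plus density-map PNGs, and `runAnalyze()` emits the full set of
group-comparison, regression and correlation-difference tables.

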