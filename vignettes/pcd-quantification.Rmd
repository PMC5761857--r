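---
title: "Quantifying peripapillary capillary density from OCT angiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peripapillary capillary density from OCT angiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericap)
```

## The measurement problem

The radial peripapillary capillaries (RPC) are a superficial capillary bed
inside the retinal nerve fiber layer (RNFL) that perfuses the retinal
ganglion cell axons as they converge on the optic nerve head (ONH). Both
glaucoma (POAG) and non-arteritic anterior ischemic optic neuropathy (NAION)
destroy these axons, and en-face OCT angiography shows the accompanying
capillary dropout. The quantity of interest is the *peripapillary capillary
density* (PCD): the percentage of image area occupied by perfused capillary
signal, after the large retinal vessels — which do not belong to the
microvasculature — have been removed.

`pericap` implements this measurement for 4.5 x 4.5 mm en-face scans
centered on the ONH, together with the cohort-level statistics used to
compare patient groups, and seeded simulators that make the whole pipeline
testable against known ground truth.

## The quantification pipeline

`segmentCapillaries()` runs the stages in order, each with its default:

1. **Upscale x6, bilinear** (`resizeFactor = 6`). A 304 px native grid
   becomes 1824 px (405.3 px/mm). Bilinear interpolation is monotone: no
   ringing, no overshoot, constants are preserved.
2. **Percentile contrast stretch** (`stretchLowPct = 1`,
   `stretchHighPct = 99`): the 1st percentile maps to 0, the 99th to 1,
   linear in between, clipped. Percentiles are the standard
   linearly-interpolated order statistics. A near-constant image, whose two
   percentiles coincide, is rejected as degenerate.
3. **Global threshold** (`globalT = 0.55`): pixels *strictly* above 0.55
   become white. Ties go to black at every threshold in the package.
4. **Major-vessel removal** (`caliberCutoffUm = 40`,
   `vesselDilationPx = 2`, `vesselCoreMinPx = 500`). The discriminator
   between a large vessel and an RPC capillary is physical caliber: RPC are
   below ~30 um on OCT-A while the major radial vessels are 60-150 um.
   Caliber is measured on the binary with the Euclidean distance transform:
   pixels deeper than `cutoff / 2` from background form vessel *cores*;
   the vessel body is reconstructed by dilating the cores by `cutoff / 2`
   inside the binary (equivalently, a morphological opening with a disc of
   the cutoff diameter), and finally dilated 2 px as a safety margin.
   Core components smaller than `vesselCoreMinPx` (500 px at the 1824 px
   grid, about 3000 um^2) are discarded: a true vessel core is a ridge
   running across the frame, while capillary crossings that barely exceed
   the cutoff produce only specks. The threshold scales with the square of
   the working resolution, so reduce it when using smaller grids.
5. **Local adaptive threshold** (`adaptiveWindowPx = 15`): a pixel survives
   if it strictly exceeds the mean of its 15 x 15 neighbourhood
   (mirror-padded at the borders, so edges are not darkened).

### Where the adaptive threshold acts: a design decision

The stage order above applies the adaptive threshold *after* vessel
removal, i.e. to the vessel-removed binary (`adaptiveOn = "binary"`, the
default). On a binary image the operation has a precise meaning: a white
pixel fails only when its entire window is white, so the stage erases
exactly the interiors of saturated solid blocks — residual large bright
structure — and provably cannot touch a capillary mesh that retains any
dark pixel per window.

The alternative reading (`adaptiveOn = "stretched"`) computes the local
means on the contrast-stretched grayscale (vessel pixels excluded from the
windows) and ANDs the result with the global binary. We implemented and
measured both. At the working resolution the 15 px window spans only 37 um
— smaller than a single major vessel — so on the grayscale it behaves as an
unsharp mask rather than an illumination correction: in dense capillary
meshes the local mean rises toward the capillary level itself and the
stage systematically erodes true capillary area. On synthetic angiograms
with known ground truth the grayscale variant under-measures dense meshes
by up to 8 percentage points at a 55% capillary fraction, while the binary
variant recovers 10-55% ground-truth fractions within about 2 points
(see `test-acceptance.R` and `scripts/acceptance.R`, which recompute this).
Both modes are kept because the choice is a genuine ambiguity of the
procedure the package reproduces; the default is the one that is both the
literal stage order and the unbiased estimator on simulated ground truth.

## ROI geometry

`makeAnnulus()` places an inner 1.95 mm and outer 3.45 mm circle at the ONH
center (the scan center by default), giving an annulus 0.75 mm wide whose
outer diameter matches the standard circumpapillary RNFL scan circle.
Conventions, chosen once and tested:

* distances from pixel centers; radial interval half-open
  (`inner <= d < outer`), so the inner disc and annulus never overlap;
* quadrant boundaries on the 45-degree diagonals, superior wedge centered
  at 12 o'clock — the quadrant convention of RNFL reports, against which
  sector PCD is correlated;
* on the diagonals the superior/inferior wedges are closed and the
  left/right wedges open: the partition is exact *and* symmetric under
  left-right mirroring, so OD/OS geometry is consistent;
* laterality maps the left image half to the temporal retina for OD (fundus
  orientation) and mirrors for OS; `flipNasalTemporal` overrides this for
  differently exported data.

`computePCD()` reports whole-image density (frame minus inner circle minus
vessels), whole-annulus and four sector densities. One denominator
convention applies to all regions: major-vessel pixels are excluded
(`excludeVessels = TRUE`), which keeps the whole-image and annular
definitions internally consistent; the alternative (vessels kept in the
denominator) remains available as a flag because the regional definition
is ambiguous in the source procedure. `densityMap()` computes the
color-coded sliding-window map (16 px window, 8 px stride) rendered by
`renderDensityMap()` on a fixed blue-to-red scale.

## The angiogram simulator

`simulateAngiogram()` provides ground truth the real instrument cannot: a
per-pixel capillary mask. It emulates what matters to the algorithm, not
acquisition physics:

* a dark disc cup (radius 0.6 mm) that anchors the low percentile of the
  stretch, as the physiological cup does;
* `nMajorVessels = 8` wavy radial vessels with Gaussian cross-profile,
  caliber 90 um FWHM — the arcades leaving the disc;
* a capillary mesh of curvilinear, radially oriented segments 1-2 px
  (15-30 um) wide, drawn until a target fraction of eligible area is
  covered. Segments never fill a solid 3 x 3 native block (real RPC form a
  mesh, not plates) and keep a 2 px perivascular capillary-free zone, as
  around real arterioles. Both properties also keep capillary-scale
  structure unambiguously below the 40 um caliber cutoff;
* capillary amplitude (0.92) close to the vessel amplitude (0.97) over a
  0.15 background: on OCT-A, capillaries and large vessels carry similar
  decorrelation signal and are distinguished by caliber, not brightness.

What it does *not* emulate: projection and motion artifacts, signal
fall-off, vessel shadowing, true speckle statistics. Passing recovery tests
on these images therefore validates the algorithm's arithmetic and its
behaviour on mesh-like textures — not its clinical accuracy on patient
scans.

The realized capillary fraction is counted from the returned mask and must
land within 0.02 of the request; fractions above 0.65 exceed the packing
limit of a thin mesh and are rejected. Identical spec and seed give
bit-identical images; OS laterality is the exact horizontal mirror of the
OD layout.

## The cohort simulator

`simulateCohort()` draws one row per eye with the group means and standard
deviations of the four study groups (control, NAION, fellow, POAG) over
age, sex ratio, axial length, visual-field mean deviation, global and
sector RNFL thickness, and the six PCD outcomes; the defaults in
`cohortGroupDefaults()` encode the study conditions. Structure:

* two eyes of a subject share a latent subject effect with weight
  `sqrt(withinSubjectRho)` in every outcome (`rho = 0.2` by default — a
  deliberately moderate inter-eye residual correlation, compatible with the
  strongest sector correlation target via the constraint
  `r <= 1 - rho`);
* each NAION subject contributes one affected and one fellow eye that share
  the subject effects, age and sex — the paired design of the study;
* within each eye, sector PCD and the matching sector RNFL share a latent
  factor with loading `sqrt(r / (1 - rho))`, which makes their marginal
  Pearson correlation converge to the target `r` (the square roots of the
  published within-set R^2 values);
* outcomes are truncated normals (PCD in \[0, 100\], RNFL and axial length
  positive); at the default parameters the truncated mass is negligible.

Group sizes default to the study layout (77/31/31/42 eyes from 46/31/31/27
subjects) and scale for convergence tests.

## Cohort statistics

* `compareGroups()` — linear mixed model `outcome ~ group + age + sex +
  axial length` with a subject random intercept, REML, containment degrees
  of freedom; all pairwise contrasts Bonferroni-corrected over the number
  of pairs (6 for four groups). With one eye per subject the fixed effects
  coincide with OLS exactly.
* `sectorContrasts()` — within-eye paired contrasts over the six sector
  pairs, Bonferroni x6; the estimate is the mean within-eye difference.
* `univariateFit()` — least-squares `y ~ x` reporting slope, 95% CI, R^2
  and `r = sign(slope) * sqrt(R^2)`.
* `compareDependentCorrelations()` — Dunn-Clark z for two dependent
  *non-overlapping* correlations (same eyes, no shared variable), using the
  Pearson-Filon covariance with the Fisher transformation. Given raw
  vectors it estimates the four cross-correlations from the data; given
  only `r1`, `r2`, `n` it falls back to independence, which is
  conservative under positive dependence, and flags the output. Tests
  check it against a within-eye permutation oracle (swap the two sector
  pairs eye-wise), with agreement within 0.02 at 5000 permutations.

Missing data are handled complete-case per analysis, with a warning
counting dropped eyes. Sex enters as a binary indicator; no interactions
are fitted.

## Numerical choices and edge cases

* Strict `>` at both thresholds; a tiny absolute guard (1e-9) protects the
  adaptive comparison from summed-area rounding so a constant image maps to
  all-black, as the tie-break demands.
* Local means use mirror padding and integral images, exact up to rounding.
* A blank (all-zero) angiogram yields an empty segmentation rather than a
  degenerate-stretch error; a constant *non-zero* image still errors in
  `contrastStretch()` itself.
* Density-map windows fully covered by vessels return `NA`, not 0.
* All randomness is seeded through the simulator specs; simulators restore
  the caller's RNG state.

## Problem sizes in the test-suite

The suite exercises the full-resolution pipeline (304 px native, x6) for
the ground-truth recovery study at capillary fractions 0.1-0.55, and
reduced grids (96-160 px) for unit tests. Statistical recovery uses 100
cohort replicates at the study's group sizes, 5000-eye groups for
correlation convergence, and 5000-permutation oracles at n = 1000 eyes.
`scripts/acceptance.R` recomputes all of these from scratch.

## Known limitations

* The vessel caliber measurement is resolution-limited near the cutoff;
  vessels below ~50 um are detected less reliably (their cores are thin),
  which is why the cutoff sits well below the caliber of real major
  vessels.
* At capillary fractions above ~0.55 the binarization saturates: thin
  meshes denser than that cannot be represented with sub-cutoff structure
  and preserved gaps, so densities in that regime are compressed. Clinical
  annular PCD rarely exceeds 45%.
* The ONH center is metadata (default: scan center); there is no disc
  segmentation.
* Sector correspondence between the density annulus and RNFL quadrants
  assumes a common orientation; instrument-specific rotations are the
  user's responsibility (`flipNasalTemporal`, `centerPx`).
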