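#' @include pericap-package.R
NULL

.GROUPS <- c("control", "NAION", "fellow", "POAG")
.SECTORS <- c("superior", "nasal", "inferior", "temporal")

# ---------------------------------------------------------------------------
# EnFaceAngiogram
# ---------------------------------------------------------------------------

#' En-face OCT-A angiogram
#'
#' A square grayscale intensity raster with physical scale and eye metadata.
#' Intensities are normalized to \[0, 1\]. The coordinate convention is
#' `(row, col)`, 1-based, with row 1 at the image top (superior retina in
#' fundus orientation).
#'
#' @slot pixels numeric matrix of intensities in \[0, 1\], square.
#' @slot widthMm physical width of the scan field in mm (default 4.5).
#' @slot centerPx optic nerve head center as `c(row, col)`; `NA` means the
#'   geometric image center.
#' @slot laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @slot subjectId,eyeId,group character metadata.
#'
#' @seealso [loadAngiogram()], [simulateAngiogram()], [resizeAngiogram()]
#' @export
setClass("EnFaceAngiogram",
  representation(
    pixels = "matrix",
    widthMm = "numeric",
    centerPx = "numeric",
    laterality = "character",
    subjectId = "character",
    eyeId = "character",
    group = "character"
  ),
  prototype(
    widthMm = 4.5,
    centerPx = c(NA_real_, NA_real_),
    laterality = "OD",
    subjectId = NA_character_,
    eyeId = NA_character_,
    group = NA_character_
  )
)

setValidity("EnFaceAngiogram", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) != ncol(p)) return("pixels must be square")
  rng <- range(p)
  if (rng[1] < 0 || rng[2] > 1) return("intensities must lie in [0, 1]")
  if (length(object@widthMm) != 1 || object@widthMm <= 0)
    return("widthMm must be a single positive number")
  if (!object@laterality %in% c("OD", "OS"))
    return("laterality must be 'OD' or 'OS'")
  if (length(object@centerPx) != 2) return("centerPx must have length 2")
  TRUE
})

#' Construct an EnFaceAngiogram
#'
#' @param pixels square numeric matrix with values in \[0, 1\].
#' @param widthMm physical scan width in mm.
#' @param centerPx optic nerve head center `c(row, col)` (1-based); defaults
#'   to the image center.
#' @param laterality `"OD"` or `"OS"`.
#' @param subjectId,eyeId,group optional metadata strings.
#' @return an [EnFaceAngiogram-class] object.
#' @examples
#' ang <- EnFaceAngiogram(matrix(runif(64^2), 64, 64))
#' scalePxPerMm(ang)
#' @export
EnFaceAngiogram <- function(pixels, widthMm = 4.5,
                            centerPx = c(NA_real_, NA_real_),
                            laterality = "OD",
                            subjectId = NA_character_,
                            eyeId = NA_character_,
                            group = NA_character_) {
  new("EnFaceAngiogram", pixels = pixels, widthMm = widthMm,
      centerPx = as.numeric(centerPx), laterality = laterality,
      subjectId = as.character(subjectId), eyeId = as.character(eyeId),
      group = as.character(group))
}

# ---------------------------------------------------------------------------
# PerfusionSegmentation
# ---------------------------------------------------------------------------

#' Binary perfused-capillary segmentation of an angiogram
#'
#' Result of [segmentCapillaries()]: the final capillary binary, the mask of
#' removed major vessels, and the retained intermediates. All grids are at the
#' working (resized) resolution and congruent in shape.
#'
#' @slot capillaryBinary logical matrix, `TRUE` = perfused capillary pixel.
#' @slot vesselMask logical matrix, `TRUE` = major vessel (excluded).
#' @slot globalBinary logical matrix from the global threshold.
#' @slot adaptiveBinary logical matrix from the local adaptive threshold.
#' @slot stretched numeric matrix, contrast-stretched grayscale.
#' @slot scalePxPerMm pixels per mm at the working resolution.
#' @slot params list echoing the segmentation parameters.
#' @export
setClass("PerfusionSegmentation",
  representation(
    capillaryBinary = "matrix",
    vesselMask = "matrix",
    globalBinary = "matrix",
    adaptiveBinary = "matrix",
    stretched = "matrix",
    scalePxPerMm = "numeric",
    params = "list"
  )
)

setValidity("PerfusionSegmentation", function(object) {
  d <- dim(object@capillaryBinary)
  for (s in c("vesselMask", "globalBinary", "adaptiveBinary", "stretched"))
    if (!identical(dim(slot(object, s)), d))
      return(sprintf("%s not congruent with capillaryBinary", s))
  if (any(object@capillaryBinary & object@vesselMask))
    return("a pixel is flagged both capillary and major vessel")
  TRUE
})

# ---------------------------------------------------------------------------
# AnnularROI
# ---------------------------------------------------------------------------

#' Annular region of interest with anatomical sector masks
#'
#' Concentric-circle geometry centered on the optic nerve head: an inner
#' circle (default diameter 1.95 mm), an outer circle (default 3.45 mm), the
#' annulus between them, and its partition into the four 90-degree anatomical
#' quadrants (superior, nasal, inferior, temporal). Quadrant boundaries lie on
#' the 45-degree diagonals, so the superior wedge is centered at 12 o'clock,
#' matching the quadrant convention of circumpapillary RNFL reports. The
#' nasal/temporal assignment of the left and right wedges depends on eye
#' laterality.
#'
#' @slot centerPx center `c(row, col)`, 1-based.
#' @slot innerMm,outerMm circle diameters in mm.
#' @slot scalePxPerMm pixels per mm.
#' @slot innerMask logical matrix covering the inner disc.
#' @slot annulusMask logical matrix covering the annulus.
#' @slot sectorMasks named list of four logical matrices.
#' @slot laterality `"OD"` or `"OS"`.
#' @seealso [makeAnnulus()]
#' @export
setClass("AnnularROI",
  representation(
    centerPx = "numeric",
    innerMm = "numeric",
    outerMm = "numeric",
    scalePxPerMm = "numeric",
    innerMask = "matrix",
    annulusMask = "matrix",
    sectorMasks = "list",
    laterality = "character"
  )
)

setValidity("AnnularROI", function(object) {
  if (object@innerMm >= object@outerMm)
    return("innerMm must be smaller than outerMm")
  if (!identical(sort(names(object@sectorMasks)), sort(.SECTORS)))
    return("sectorMasks must be named superior/nasal/inferior/temporal")
  u <- Reduce(`|`, object@sectorMasks)
  if (!identical(u, object@annulusMask))
    return("sector masks must union to the annulus exactly")
  tot <- Reduce(`+`, lapply(object@sectorMasks, function(m) m * 1L))
  if (any(tot > 1L)) return("sector masks overlap")
  if (any(object@innerMask & object@annulusMask))
    return("inner mask intersects annulus")
  TRUE
})

# ---------------------------------------------------------------------------
# PCDResult / DensityMap
# ---------------------------------------------------------------------------

#' Per-eye peripapillary capillary density result
#'
#' Density percentages for the whole image (inner circle and major vessels
#' removed), the whole annulus, and the four quadrants, together with the
#' pixel counts behind every percentage.
#'
#' @slot wholeImagePct,annulusPct numeric percentages in \[0, 100\].
#' @slot sectorPct named numeric vector (superior, nasal, inferior, temporal).
#' @slot counts data.frame with columns `region`, `numerator`, `denominator`.
#' @slot params list echoing metric parameters.
#' @export
setClass("PCDResult",
  representation(
    wholeImagePct = "numeric",
    annulusPct = "numeric",
    sectorPct = "numeric",
    counts = "data.frame",
    params = "list"
  )
)

setValidity("PCDResult", function(object) {
  v <- c(object@wholeImagePct, object@annulusPct, object@sectorPct)
  if (any(v < 0 | v > 100)) return("percentages must lie in [0, 100]")
  if (any(object@counts$numerator > object@counts$denominator))
    return("numerator exceeds denominator")
  TRUE
})

#' Sliding-window capillary density map
#'
#' Per-window density percentages computed over the capillary binary with a
#' square sampling window and overlapping stride. Windows whose denominator
#' is empty (fully covered by major vessels) are `NA`.
#'
#' @slot values numeric matrix of window densities in \[0, 100\] (or `NA`).
#' @slot windowPx,stridePx window size and stride in pixels.
#' @seealso [densityMap()], [renderDensityMap()]
#' @export
setClass("DensityMap",
  representation(values = "matrix", windowPx = "integer", stridePx = "integer")
)

setValidity("DensityMap", function(object) {
  v <- object@values
  if (any(v < 0 | v > 100, na.rm = TRUE))
    return("density values must lie in [0, 100]")
  if (object@windowPx < object@stridePx)
    return("window must be >= stride")
  TRUE
})

# ---------------------------------------------------------------------------
# Simulation specs
# ---------------------------------------------------------------------------

#' Specification for a synthetic angiogram
#'
#' Parameters of the seeded angiogram simulator. See [angiogramSimSpec()] for
#' the user-facing constructor and defaults.
#'
#' @slot imageSizePx native square side in pixels.
#' @slot scanFieldMm physical width in mm.
#' @slot capillaryFraction target perfused-capillary area fraction in
#'   \[0, 1\], measured over pixels outside the disc and the major vessels.
#' @slot nMajorVessels number of large radial vessels.
#' @slot vesselCaliberUm major-vessel full width at half maximum, micrometers.
#' @slot discRadiusMm optic-disc analog radius in mm.
#' @slot noiseSd additive intensity noise standard deviation.
#' @slot laterality `"OD"` or `"OS"`.
#' @slot seed integer RNG seed.
#' @export
setClass("AngiogramSimSpec",
  representation(
    imageSizePx = "integer",
    scanFieldMm = "numeric",
    capillaryFraction = "numeric",
    nMajorVessels = "integer",
    vesselCaliberUm = "numeric",
    discRadiusMm = "numeric",
    noiseSd = "numeric",
    laterality = "character",
    seed = "integer"
  )
)

setValidity("AngiogramSimSpec", function(object) {
  if (object@imageSizePx < 64) return("imageSizePx must be >= 64")
  if (object@capillaryFraction < 0 || object@capillaryFraction > 1)
    return("capillaryFraction must lie in [0, 1]")
  if (object@vesselCaliberUm <= 0) return("vesselCaliberUm must be > 0")
  if (object@nMajorVessels < 0) return("nMajorVessels must be >= 0")
  if (object@discRadiusMm <= 0) return("discRadiusMm must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (!object@laterality %in% c("OD", "OS"))
    return("laterality must be 'OD' or 'OS'")
  TRUE
})

#' Specification for a synthetic cohort
#'
#' Parameters of the seeded cohort simulator: per-group outcome means and
#' standard deviations, per-group target correlations between each sector
#' density and its corresponding RNFL thickness, the within-subject (inter-eye)
#' residual correlation, and group sizes. See [cohortSimSpec()].
#'
#' @slot groupParams named list (per group) of lists with numeric vectors
#'   `mean` and `sd` over the outcome columns, plus `sexFemale` (proportion).
#' @slot sectorCorrelations named list (per group) of numeric vectors giving
#'   the target Pearson r for superior/nasal/inferior/temporal.
#' @slot withinSubjectRho correlation of residuals between two eyes of one
#'   subject, in \[0, 1).
#' @slot nSubjects,nEyes named integer vectors per group.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSimSpec",
  representation(
    groupParams = "list",
    sectorCorrelations = "list",
    withinSubjectRho = "numeric",
    nSubjects = "integer",
    nEyes = "integer",
    seed = "integer"
  )
)

setValidity("CohortSimSpec", function(object) {
  for (g in names(object@groupParams)) {
    gp <- object@groupParams[[g]]
    if (any(gp$sd <= 0)) return(sprintf("all SDs must be > 0 (group %s)", g))
  }
  rho <- object@withinSubjectRho
  if (rho < 0 || rho >= 1) return("withinSubjectRho must lie in [0, 1)")
  for (g in names(object@sectorCorrelations)) {
    r <- object@sectorCorrelations[[g]]
    if (any(abs(r) > 1)) return("|r| must be <= 1")
    if (any(abs(r) > 1 - rho))
      return(sprintf(
        "sector correlation %.3f (group %s) not attainable with withinSubjectRho %.2f",
        max(abs(r)), g, rho))
  }
  if (any(object@nSubjects < 2)) return("need >= 2 subjects per group")
  if (any(object@nEyes < object@nSubjects))
    return("nEyes must be >= nSubjects in every group")
  if (any(object@nEyes > 2L * object@nSubjects))
    return("at most 2 eyes per subject")
  TRUE
})

# ---------------------------------------------------------------------------
# Statistics results
# ---------------------------------------------------------------------------

#' Adjusted group comparison of one outcome
#'
#' Result of [compareGroups()]: pairwise group contrasts from a linear mixed
#' model with covariate adjustment and a subject-level random intercept,
#' Bonferroni-corrected over the number of pairs.
#'
#' @slot outcome outcome column name.
#' @slot contrasts data.frame with columns `contrast`, `estimate`, `SE`, `df`,
#'   `lower`, `upper`, `p_raw`, `p_adj`.
#' @slot covariates character vector of adjustment covariates.
#' @slot groupMeans data.frame of adjusted group means.
#' @slot nObs,nSubjects integers.
#' @export
setClass("GroupComparison",
  representation(
    outcome = "character",
    contrasts = "data.frame",
    covariates = "character",
    groupMeans = "data.frame",
    nObs = "integer",
    nSubjects = "integer"
  )
)

setValidity("GroupComparison", function(object) {
  ct <- object@contrasts
  if (any(ct$p_adj < ct$p_raw - 1e-12))
    return("adjusted p must be >= raw p")
  if (any(ct$p_adj > 1 | ct$p_raw > 1 | ct$p_adj <= 0 | ct$p_raw < 0))
    return("p-values out of range")
  TRUE
})

#' Comparison of two dependent non-overlapping correlations
#'
#' Result of [compareDependentCorrelations()]: Dunn-Clark z test for the
#' difference between two correlations measured on the same eyes but sharing
#' no variable (e.g. superior PCD vs superior RNFL against nasal PCD vs nasal
#' RNFL).
#'
#' @slot r1,r2 the two correlations.
#' @slot difference `r1 - r2`.
#' @slot n number of paired observations (eyes).
#' @slot intercor named numeric vector of the four cross-correlations
#'   (`r_x1x2`, `r_x1y2`, `r_y1x2`, `r_y1y2`), or `NA` when unknown.
#' @slot z,p test statistic and two-sided p-value.
#' @slot conservative `TRUE` when the cross-correlations were unknown and the
#'   independence fallback (a conservative default for positively dependent
#'   data) was used.
#' @export
setClass("CorrelationComparison",
  representation(
    r1 = "numeric", r2 = "numeric", difference = "numeric",
    n = "integer", intercor = "numeric",
    z = "numeric", p = "numeric", conservative = "logical"
  )
)

setValidity("CorrelationComparison", function(object) {
  if (abs(object@r1) > 1 || abs(object@r2) > 1) return("|r| must be <= 1")
  if (abs(object@difference - (object@r1 - object@r2)) > 1e-12)
    return("difference must equal r1 - r2")
  TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "EnFaceAngiogram", function(object) {
  cat(sprintf("EnFaceAngiogram: %d x %d px, %.2f mm (%.1f px/mm), %s\n",
              nrow(object@pixels), ncol(object@pixels), object@widthMm,
              scalePxPerMm(object), object@laterality))
  if (!is.na(object@subjectId))
    cat(sprintf("  subject %s, eye %s, group %s\n", object@subjectId,
                object@eyeId, object@group))
})

setMethod("show", "PerfusionSegmentation", function(object) {
  d <- dim(object@capillaryBinary)
  cat(sprintf("PerfusionSegmentation: %d x %d px\n", d[1], d[2]))
  cat(sprintf("  capillary pixels: %d (%.1f%% of frame)\n",
              sum(object@capillaryBinary),
              100 * mean(object@capillaryBinary)))
  cat(sprintf("  major-vessel pixels: %d (%.1f%% of frame)\n",
              sum(object@vesselMask), 100 * mean(object@vesselMask)))
})

setMethod("show", "AnnularROI", function(object) {
  cat(sprintf("AnnularROI: %.2f / %.2f mm circles, %.1f px/mm, %s\n",
              object@innerMm, object@outerMm, object@scalePxPerMm,
              object@laterality))
  cat(sprintf("  annulus pixels: %d\n", sum(object@annulusMask)))
})

setMethod("show", "PCDResult", function(object) {
  cat("PCDResult (%):\n")
  v <- c("whole image" = object@wholeImagePct,
         "whole annulus" = object@annulusPct, object@sectorPct)
  for (i in seq_along(v))
    cat(sprintf("  %-14s %5.1f\n", names(v)[i], v[i]))
})

setMethod("show", "DensityMap", function(object) {
  cat(sprintf("DensityMap: %d x %d cells (window %d px, stride %d px)\n",
              nrow(object@values), ncol(object@values),
              object@windowPx, object@stridePx))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison for '%s' (%d eyes, %d subjects)\n",
              object@outcome, object@nObs, object@nSubjects))
  cat(sprintf("  adjusted for: %s\n",
              paste(object@covariates, collapse = ", ")))
  print(object@contrasts, row.names = FALSE, digits = 3)
})

setMethod("show", "CorrelationComparison", function(object) {
  cat(sprintf(
    "CorrelationComparison: r1 = %.3f, r2 = %.3f, diff = %.3f (n = %d)\n",
    object@r1, object@r2, object@difference, object@n))
  cat(sprintf("  Dunn-Clark z = %.3f, two-sided p = %.4g%s\n", object@z,
              object@p,
              if (object@conservative) " [conservative: intercorrelations unknown]"
              else ""))
})
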