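#' Build the annular region of interest and its sector masks
#'
#' Places concentric circles of `innerMm` and `outerMm` diameter (defaults
#' 1.95 and 3.45 mm, i.e. an annulus 0.75 mm wide) at `center` and partitions
#' the annulus into the four anatomical quadrants. Distances are measured
#' from pixel centers; the radial interval is half-open
#' (`inner <= d < outer`). On the 45-degree diagonals the superior and
#' inferior wedges are closed and the lateral wedges open, so no pixel is
#' double-counted, the sector masks partition the annulus exactly, and the
#' partition is symmetric under left-right mirroring.
#'
#' The superior wedge is centered at 12 o'clock (polar angle in
#' \[45, 135\] degrees, with up = 90), the inferior wedge opposite. For an OD
#' (right) eye displayed in fundus orientation the temporal retina is the
#' left image half; for OS the assignment is mirrored. `flipNasalTemporal`
#' overrides this for data exported in other orientations.
#'
#' @param sidePx image side length in pixels.
#' @param scalePxPerMm pixel scale.
#' @param center `c(row, col)` ONH center, 1-based; default image center.
#' @param innerMm,outerMm circle diameters in mm.
#' @param laterality `"OD"` or `"OS"`.
#' @param flipNasalTemporal logical; swap the nasal/temporal assignment.
#' @return an [AnnularROI-class].
#' @examples
#' roi <- makeAnnulus(sidePx = 304, scalePxPerMm = 304 / 4.5)
#' sum(annulusMask(roi))
#' @export
makeAnnulus <- function(sidePx, scalePxPerMm, center = NULL,
                        innerMm = 1.95, outerMm = 3.45, laterality = "OD",
                        flipNasalTemporal = FALSE) {
  if (!laterality %in% c("OD", "OS")) stop("unknown laterality: ", laterality)
  if (innerMm <= 0 || outerMm <= innerMm)
    stop("need 0 < innerMm < outerMm (empty or inverted annulus)")
  if (is.null(center)) center <- c((sidePx + 1) / 2, (sidePx + 1) / 2)
  rIn <- mmToPx(innerMm / 2, scalePxPerMm)
  rOut <- mmToPx(outerMm / 2, scalePxPerMm)
  if (center[1] - rOut < 0.5 || center[1] + rOut > sidePx + 0.5 ||
      center[2] - rOut < 0.5 || center[2] + rOut > sidePx + 0.5)
    stop("outer circle exceeds image bounds: the ROI must be fully imaged")

  dd <- pixelDistance(sidePx, center)
  inner <- dd < rIn
  annulus <- dd >= rIn & dd < rOut

  ang <- pixelAngle(sidePx, center)
  # vertical wedges own the diagonal boundary pixels (closed intervals),
  # the lateral wedges are open there: an exact partition that is also
  # symmetric under left-right mirroring
  superior <- annulus & (ang >= 45 & ang <= 135)
  inferior <- annulus & (ang >= -135 & ang <= -45)
  left <- annulus & (ang > 135 | ang < -135)
  right <- annulus & (ang > -45 & ang < 45)
  temporalLeft <- xor(laterality == "OD", flipNasalTemporal)
  sectors <- list(
    superior = superior,
    nasal = if (temporalLeft) right else left,
    inferior = inferior,
    temporal = if (temporalLeft) left else right
  )
  new("AnnularROI", centerPx = as.numeric(center), innerMm = innerMm,
      outerMm = outerMm, scalePxPerMm = scalePxPerMm, innerMask = inner,
      annulusMask = annulus, sectorMasks = sectors, laterality = laterality)
}

#' Annulus width in mm
#'
#' @param roi an [AnnularROI-class].
#' @return `(outerMm - innerMm) / 2`.
#' @export
annulusWidthMm <- function(roi) (roi@outerMm - roi@innerMm) / 2
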