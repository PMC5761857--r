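#' Whole-image capillary density
#'
#' Percentage of perfused-capillary pixels over the frame after removal of
#' the inner circle and (by default) the major vessels:
#' `100 * |capillary AND region| / |region|` with
#' `region = frame \ inner circle \ vessels` when `excludeVessels` is
#' `TRUE`, else `frame \ inner circle`.
#'
#' @param seg a [PerfusionSegmentation-class].
#' @param roi an [AnnularROI-class] congruent with `seg`.
#' @param excludeVessels drop major-vessel pixels from the denominator.
#' @return percentage in \[0, 100\].
#' @export
wholeImagePCD <- function(seg, roi, excludeVessels = TRUE) {
  stopifnot(is(seg, "PerfusionSegmentation"), is(roi, "AnnularROI"))
  .checkCongruent(seg, roi)
  region <- !roi@innerMask
  if (excludeVessels) region <- region & !seg@vesselMask
  .pcdPct(seg@capillaryBinary, region)
}

#' Capillary density within a mask
#'
#' `100 * |capillary AND mask'| / |mask'|` where `mask'` is `mask` with
#' major-vessel pixels removed when `excludeVessels` is `TRUE`. Used for the
#' whole annulus and each sector.
#'
#' @param seg a [PerfusionSegmentation-class].
#' @param mask logical matrix (nonempty).
#' @param excludeVessels drop major-vessel pixels from the denominator.
#' @return percentage in \[0, 100\].
#' @export
regionPCD <- function(seg, mask, excludeVessels = TRUE) {
  stopifnot(is(seg, "PerfusionSegmentation"))
  if (!identical(dim(mask), dim(seg@capillaryBinary)))
    stop("mask not congruent with segmentation")
  if (!any(mask)) stop("empty mask")
  region <- mask
  if (excludeVessels) region <- region & !seg@vesselMask
  .pcdPct(seg@capillaryBinary, region)
}

.pcdPct <- function(capillary, region) {
  den <- sum(region)
  if (den == 0) stop("zero denominator: region fully excluded")
  100 * sum(capillary & region) / den
}

.checkCongruent <- function(seg, roi) {
  if (!identical(dim(seg@capillaryBinary), dim(roi@annulusMask)))
    stop("segmentation and ROI grids are not congruent")
}

#' Compute the full per-eye density result
#'
#' Whole-image, whole-annulus and four sector densities with their pixel
#' counts. The same denominator convention (vessels excluded by default)
#' applies to every region.
#'
#' @param seg a [PerfusionSegmentation-class].
#' @param roi an [AnnularROI-class] congruent with `seg`.
#' @param excludeVessels drop major-vessel pixels from all denominators.
#' @return a [PCDResult-class].
#' @examples
#' sim <- simulateAngiogram(angiogramSimSpec(imageSizePx = 96,
#'                                           capillaryFraction = 0.3))
#' seg <- segmentCapillaries(sim$angiogram, resizeFactor = 2)
#' roi <- makeAnnulus(nrow(capillaryBinary(seg)), scalePxPerMm(seg))
#' computePCD(seg, roi)
#' @export
computePCD <- function(seg, roi, excludeVessels = TRUE) {
  .checkCongruent(seg, roi)
  regions <- c(list(
    whole_image = !roi@innerMask,
    whole_annulus = roi@annulusMask),
    setNames(roi@sectorMasks, names(roi@sectorMasks)))
  counts <- do.call(rbind, lapply(names(regions), function(nm) {
    region <- regions[[nm]]
    if (excludeVessels) region <- region & !seg@vesselMask
    data.frame(region = nm, numerator = sum(seg@capillaryBinary & region),
               denominator = sum(region))
  }))
  pct <- 100 * counts$numerator / counts$denominator
  names(pct) <- counts$region
  new("PCDResult",
      wholeImagePct = unname(pct["whole_image"]),
      annulusPct = unname(pct["whole_annulus"]),
      sectorPct = pct[names(roi@sectorMasks)],
      counts = counts,
      params = c(seg@params, list(excludeVessels = excludeVessels,
                                  innerMm = roi@innerMm,
                                  outerMm = roi@outerMm)))
}

#' Sliding-window density map
#'
#' Tiles the capillary binary with a `windowPx` square window moved by
#' `stridePx` (default 16 px window, 8 px overlap) starting at the top-left
#' corner, and reports per-window density
#' `100 * capillary / (window pixels not in the vessel mask)`. Windows fully
#' covered by vessels are `NA`. The grid has
#' `floor((side - window) / stride) + 1` cells per axis.
#'
#' @param seg a [PerfusionSegmentation-class].
#' @param windowPx,stridePx window size and stride (`window >= stride >= 1`).
#' @return a [DensityMap-class].
#' @export
densityMap <- function(seg, windowPx = 16, stridePx = 8) {
  stopifnot(is(seg, "PerfusionSegmentation"))
  side <- nrow(seg@capillaryBinary)
  if (windowPx > side) stop("window larger than image")
  if (stridePx < 1 || windowPx < stridePx) stop("need window >= stride >= 1")
  windowPx <- as.integer(windowPx); stridePx <- as.integer(stridePx)
  starts <- seq(1L, side - windowPx + 1L, by = stridePx)
  # cumulative-sum window totals
  capC <- .cumsum2(seg@capillaryBinary * 1)
  denC <- .cumsum2((!seg@vesselMask) * 1)
  winSum <- function(cs) {
    lo <- starts - 1L; hi <- starts + windowPx - 1L
    A <- cs[hi + 1L, hi + 1L, drop = FALSE]
    B <- cs[lo + 1L, hi + 1L, drop = FALSE]
    C <- cs[hi + 1L, lo + 1L, drop = FALSE]
    D <- cs[lo + 1L, lo + 1L, drop = FALSE]
    A - B - C + D
  }
  num <- winSum(capC)
  den <- winSum(denC)
  vals <- ifelse(den > 0, 100 * num / den, NA_real_)
  new("DensityMap", values = vals, windowPx = windowPx, stridePx = stridePx)
}

# 2-D cumulative sum with a leading zero row/col, for O(1) window sums
.cumsum2 <- function(m) {
  cs <- apply(m, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  rbind(0, cbind(0, cs))[, , drop = FALSE]
}

# fixed color scale: dark blue -> cyan -> green -> yellow -> red over 0..100%
.densityPalette <- function() {
  anchors <- rbind(c(0, 0, 0.55), c(0, 1, 1), c(0, 0.8, 0),
                   c(1, 1, 0), c(1, 0, 0))
  pos <- c(0, 0.25, 0.5, 0.75, 1)
  t(sapply(seq(0, 1, length.out = 256), function(x) {
    i <- findInterval(x, pos, rightmost.closed = TRUE)
    i <- min(i, 4)
    w <- (x - pos[i]) / (pos[i + 1] - pos[i])
    (1 - w) * anchors[i, ] + w * anchors[i + 1, ]
  }))
}

#' Render a density map to a color-coded PNG
#'
#' Maps 0-100% onto a fixed blue-cyan-green-yellow-red scale (0% = dark
#' blue, 100% = red); `NA` cells (vessel-only windows) are black. Optionally
#' overlays the annular ROI circle outlines in white. Output bytes depend
#' only on the input, so repeated rendering is byte-identical.
#'
#' @param dm a [DensityMap-class].
#' @param path output `.png` path.
#' @param roi optional [AnnularROI-class] (at the segmentation grid) whose
#'   circle outlines are drawn.
#' @return `path`, invisibly.
#' @export
renderDensityMap <- function(dm, path, roi = NULL) {
  stopifnot(is(dm, "DensityMap"))
  v <- dm@values
  pal <- .densityPalette()
  idx <- pmin(pmax(round(v / 100 * 255) + 1, 1), 256)
  rgb <- array(0, dim = c(nrow(v), ncol(v), 3))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(v), ncol(v))
    plane[ok] <- pal[idx[ok], ch]
    rgb[, , ch] <- plane
  }
  if (!is.null(roi)) {
    # map ROI circles into map-cell coordinates (window centers)
    ctrCell <- (roi@centerPx - (dm@windowPx + 1) / 2) / dm@stridePx + 1
    for (radMm in c(roi@innerMm, roi@outerMm) / 2) {
      radCell <- mmToPx(radMm, roi@scalePxPerMm) / dm@stridePx
      th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * radCell * 2))
      rr <- round(ctrCell[1] - radCell * sin(th))
      cc <- round(ctrCell[2] + radCell * cos(th))
      keep <- rr >= 1 & rr <= nrow(v) & cc >= 1 & cc <= ncol(v)
      for (ch in 1:3) rgb[cbind(rr[keep], cc[keep], ch)] <- 1
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}
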