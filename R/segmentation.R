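#' Percentile contrast stretch
#'
#' Linearly rescales intensities so the 1st percentile maps to 0 and the
#' 99th percentile to 1 (defaults), clipping to \[0, 1\]. Percentiles use the
#' standard linear interpolation between order statistics
#' (`quantile(type = 7)`).
#'
#' @param img an [EnFaceAngiogram-class] or a numeric matrix.
#' @param lowPct,highPct percentile limits (percent).
#' @return same type as `img`, stretched.
#' @examples
#' m <- matrix(seq(0, 1, length.out = 100), 10, 10)
#' range(contrastStretch(m))
#' @export
contrastStretch <- function(img, lowPct = 1, highPct = 99) {
  px <- if (is(img, "EnFaceAngiogram")) img@pixels else img
  q <- quantile(px, c(lowPct, highPct) / 100, type = 7, names = FALSE)
  if (q[2] - q[1] < .Machine$double.eps)
    stop("degenerate input: contrast stretch percentiles coincide (near-constant image)")
  out <- pmin(pmax((px - q[1]) / (q[2] - q[1]), 0), 1)
  if (is(img, "EnFaceAngiogram")) EnFaceAngiogram(out, widthMm = img@widthMm,
    centerPx = img@centerPx, laterality = img@laterality,
    subjectId = img@subjectId, eyeId = img@eyeId, group = img@group)
  else out
}

#' Global intensity threshold
#'
#' Binary map of pixels whose intensity is strictly above `t` (ties go to
#' black). Applying the threshold to its own output with any `t` in (0, 1)
#' returns the same binary.
#'
#' @param img numeric matrix (or [EnFaceAngiogram-class]) with values in
#'   \[0, 1\].
#' @param t threshold in \[0, 1\].
#' @return logical matrix.
#' @examples
#' globalThreshold(matrix(c(0.54, 0.55, 0.56), 1, 3))
#' @export
globalThreshold <- function(img, t = 0.55) {
  if (length(t) != 1 || t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  px <- if (is(img, "EnFaceAngiogram")) img@pixels else img
  px > t
}

#' Local adaptive threshold
#'
#' Binary map of pixels strictly exceeding the mean of their
#' `windowPx` x `windowPx` neighbourhood. Borders are mirror-padded, so edge
#' means are not darkened. A constant image yields an all-black result
#' (no pixel strictly exceeds its own mean).
#'
#' @param img numeric matrix (or [EnFaceAngiogram-class]).
#' @param windowPx odd window size >= 3, no larger than the image.
#' @param excludeMask optional logical matrix; `TRUE` pixels are excluded
#'   from the local means (e.g. major vessels).
#' @return logical matrix.
#' @examples
#' m <- matrix(0, 32, 32); m[16, 16] <- 1
#' sum(adaptiveThreshold(m, 15))  # isolated bright pixel survives
#' @export
adaptiveThreshold <- function(img, windowPx = 15, excludeMask = NULL) {
  px <- if (is(img, "EnFaceAngiogram")) img@pixels else img
  if (windowPx %% 2 != 1 || windowPx < 3)
    stop("window must be odd and >= 3")
  if (windowPx > nrow(px) || windowPx > ncol(px))
    stop("window larger than image")
  mask <- if (is.null(excludeMask)) NULL else !excludeMask
  # strict >, with an absolute guard against summed-area rounding noise
  px - boxMean(px, windowPx, mask = mask) > 1e-9
}

#' Detect major retinal vessels by local caliber
#'
#' Flags connected bright structure whose local caliber exceeds
#' `caliberCutoffUm`. Caliber is measured with the Euclidean distance
#' transform of the binary: core pixels lie deeper than `cutoff / 2` from
#' the background; the vessel body is reconstructed by dilating the cores by
#' `cutoff / 2` within the binary (a morphological opening), then dilated by
#' `dilationPx` to give a safety margin. Core components smaller than
#' `coreMinPx` are discarded: a major vessel's core is a long ridge spanning
#' the frame, whereas capillary crossings produce only specks barely past
#' the cutoff.
#'
#' @param binary logical matrix, typically from [globalThreshold()].
#' @param scalePxPerMm pixel scale of `binary`; required to convert the
#'   caliber cutoff to pixels.
#' @param caliberCutoffUm caliber cutoff in micrometers (default 40; radial
#'   peripapillary capillaries are well below, major vessels well above).
#' @param dilationPx extra dilation of the final mask in pixels.
#' @param coreMinPx minimum area (px) of a caliber-exceeding core component.
#' @return logical vessel mask, same shape as `binary`.
#' @examples
#' b <- matrix(FALSE, 200, 200); b[96:104, ] <- TRUE  # 9 px wide bar
#' vm <- detectMajorVessels(b, scalePxPerMm = 67.6, caliberCutoffUm = 40,
#'                          coreMinPx = 50)
#' any(vm)
#' @export
detectMajorVessels <- function(binary, scalePxPerMm, caliberCutoffUm = 40,
                               dilationPx = 2, coreMinPx = 500) {
  if (missing(scalePxPerMm) || is.null(scalePxPerMm) || is.na(scalePxPerMm))
    stop("scalePxPerMm missing: cannot convert the caliber cutoff to pixels")
  if (caliberCutoffUm <= 0) stop("caliberCutoffUm must be > 0")
  binary <- binary > 0
  if (!any(binary)) return(binary)
  radiusPx <- umToPx(caliberCutoffUm, scalePxPerMm) / 2
  dg <- asMat(EBImage::distmap(asImg(binary)))
  core <- dg > radiusPx
  if (any(core) && coreMinPx > 1) {
    lab <- EBImage::bwlabel(asImg(core))
    sizes <- tabulate(as.vector(EBImage::imageData(lab)))
    keep <- which(sizes >= coreMinPx)
    core <- matrix(as.vector(EBImage::imageData(lab)) %in% keep,
                   nrow(binary), ncol(binary))
  }
  if (!any(core)) return(matrix(FALSE, nrow(binary), ncol(binary)))
  vm <- discDilate(core, floor(radiusPx)) & binary
  if (dilationPx >= 1) vm <- discDilate(vm, dilationPx)
  vm
}

#' Segment perfused capillaries in an angiogram
#'
#' The full binarization pipeline: upscale by `resizeFactor` (bilinear),
#' stretch contrast between the 1st and 99th intensity percentiles, apply
#' the global threshold (> 0.55), remove major vessels by local caliber,
#' then apply the 15 x 15 local adaptive threshold. Two combination modes
#' are provided for the adaptive stage:
#' \describe{
#'   \item{`adaptiveOn = "binary"` (default)}{the adaptive threshold is
#'     applied to the vessel-removed binary itself, following the stage
#'     order literally; on a binary it removes exactly the interiors of
#'     saturated all-white windows (residual large bright blobs) and leaves
#'     capillary-scale structure untouched.}
#'   \item{`adaptiveOn = "stretched"`}{the adaptive threshold is computed on
#'     the contrast-stretched grayscale (vessel pixels excluded from the
#'     local means) and combined with the global binary by AND. This reading
#'     corrects slow illumination gradients but acts as an unsharp mask at
#'     the working resolution and compresses measured density in dense
#'     meshes; see the package vignette.}
#' }
#'
#' @param ang an [EnFaceAngiogram-class] at native resolution.
#' @param resizeFactor integer upscale factor (default 6).
#' @param globalT global threshold (default 0.55).
#' @param adaptiveWindowPx adaptive window size (default 15, at the working
#'   resolution).
#' @param caliberCutoffUm,vesselDilationPx,vesselCoreMinPx vessel-removal
#'   parameters, see [detectMajorVessels()].
#' @param adaptiveOn `"binary"` or `"stretched"`.
#' @param stretchLowPct,stretchHighPct contrast-stretch percentiles.
#' @return a [PerfusionSegmentation-class] with all intermediates.
#' @examples
#' sim <- simulateAngiogram(angiogramSimSpec(imageSizePx = 96,
#'                                           capillaryFraction = 0.3))
#' seg <- segmentCapillaries(sim$angiogram, resizeFactor = 2)
#' seg
#' @export
segmentCapillaries <- function(ang, resizeFactor = 6, globalT = 0.55,
                               adaptiveWindowPx = 15, caliberCutoffUm = 40,
                               vesselDilationPx = 2, vesselCoreMinPx = 500,
                               adaptiveOn = c("binary", "stretched"),
                               stretchLowPct = 1, stretchHighPct = 99) {
  stopifnot(is(ang, "EnFaceAngiogram"))
  adaptiveOn <- match.arg(adaptiveOn)
  big <- resizeAngiogram(ang, resizeFactor)
  scale <- scalePxPerMm(big)
  # a flat image (e.g. all-zero) cannot be stretched; pass it through so the
  # downstream thresholds produce the empty segmentation
  stretched <- if (diff(range(big@pixels)) < .Machine$double.eps)
    big@pixels
  else contrastStretch(big@pixels, stretchLowPct, stretchHighPct)
  gb <- globalThreshold(stretched, globalT)
  vm <- detectMajorVessels(gb, scale, caliberCutoffUm, vesselDilationPx,
                           vesselCoreMinPx)
  if (adaptiveOn == "binary") {
    pre <- gb & !vm
    ab <- adaptiveThreshold(pre * 1, adaptiveWindowPx)
    capb <- pre & ab
  } else {
    ab <- adaptiveThreshold(stretched, adaptiveWindowPx, excludeMask = vm)
    capb <- gb & ab & !vm
  }
  new("PerfusionSegmentation",
      capillaryBinary = capb, vesselMask = vm, globalBinary = gb,
      adaptiveBinary = ab, stretched = stretched, scalePxPerMm = scale,
      params = list(resizeFactor = resizeFactor, globalT = globalT,
                    adaptiveWindowPx = adaptiveWindowPx,
                    caliberCutoffUm = caliberCutoffUm,
                    vesselDilationPx = vesselDilationPx,
                    vesselCoreMinPx = vesselCoreMinPx,
                    adaptiveOn = adaptiveOn,
                    stretchLowPct = stretchLowPct,
                    stretchHighPct = stretchHighPct,
                    laterality = ang@laterality,
                    centerPx = centerPx(big)))
}
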