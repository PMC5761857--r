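#' @include AllClasses.R
NULL

#' Accessors for pericap objects
#'
#' `pixels()` returns the intensity matrix of an angiogram; `scalePxPerMm()`
#' the pixel scale derived from side length and physical width;
#' `laterality()` the eye side; `capillaryBinary()` and `vesselMask()` the
#' component grids of a segmentation; `sectorMasks()` the named list of
#' quadrant masks of an ROI; `annulusMask()` and `innerMask()` its circle
#' masks; `densityValues()` the cell grid of a density map.
#'
#' @param x a pericap object.
#' @return see details above.
#' @examples
#' ang <- EnFaceAngiogram(matrix(0.5, 64, 64))
#' scalePxPerMm(ang)  # 64 / 4.5
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "EnFaceAngiogram", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("scalePxPerMm", function(x) standardGeneric("scalePxPerMm"))
#' @rdname accessors
#' @export
setMethod("scalePxPerMm", "EnFaceAngiogram",
          function(x) nrow(x@pixels) / x@widthMm)
#' @rdname accessors
#' @export
setMethod("scalePxPerMm", "AnnularROI", function(x) x@scalePxPerMm)
#' @rdname accessors
#' @export
setMethod("scalePxPerMm", "PerfusionSegmentation", function(x) x@scalePxPerMm)

#' @rdname accessors
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))
#' @rdname accessors
#' @export
setMethod("laterality", "EnFaceAngiogram", function(x) x@laterality)
#' @rdname accessors
#' @export
setMethod("laterality", "AnnularROI", function(x) x@laterality)

#' @rdname accessors
#' @export
setGeneric("capillaryBinary", function(x) standardGeneric("capillaryBinary"))
#' @rdname accessors
#' @export
setMethod("capillaryBinary", "PerfusionSegmentation",
          function(x) x@capillaryBinary)

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))
#' @rdname accessors
#' @export
setMethod("vesselMask", "PerfusionSegmentation", function(x) x@vesselMask)

#' @rdname accessors
#' @export
setGeneric("sectorMasks", function(x) standardGeneric("sectorMasks"))
#' @rdname accessors
#' @export
setMethod("sectorMasks", "AnnularROI", function(x) x@sectorMasks)

#' @rdname accessors
#' @export
setGeneric("annulusMask", function(x) standardGeneric("annulusMask"))
#' @rdname accessors
#' @export
setMethod("annulusMask", "AnnularROI", function(x) x@annulusMask)

#' @rdname accessors
#' @export
setGeneric("innerMask", function(x) standardGeneric("innerMask"))
#' @rdname accessors
#' @export
setMethod("innerMask", "AnnularROI", function(x) x@innerMask)

#' @rdname accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))
#' @rdname accessors
#' @export
setMethod("densityValues", "DensityMap", function(x) x@values)

#' ONH center of an angiogram in pixel coordinates
#'
#' Returns the `c(row, col)` center, resolving the `NA` default to the
#' geometric image center `( (n + 1) / 2, (n + 1) / 2 )`.
#'
#' @param x an [EnFaceAngiogram-class].
#' @return numeric length-2 vector.
#' @export
setGeneric("centerPx", function(x) standardGeneric("centerPx"))
#' @rdname centerPx
#' @export
setMethod("centerPx", "EnFaceAngiogram", function(x) {
  if (anyNA(x@centerPx)) {
    n <- nrow(x@pixels)
    c((n + 1) / 2, (n + 1) / 2)
  } else x@centerPx
})
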