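#' Load an en-face angiogram from a grayscale TIFF or PNG
#'
#' Reads an 8- or 16-bit grayscale raster and rescales intensities to
#' \[0, 1\] by dividing by the bit-depth maximum (255 or 65535), as done by
#' the underlying reader. A JSON metadata sidecar (same path with `.json`
#' appended, as written by [saveAngiogram()]) is honoured when present;
#' explicit `metadata` entries override it.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param metadata optional named list with any of `widthMm`, `centerPx`,
#'   `laterality`, `subjectId`, `eyeId`, `group`.
#' @return an [EnFaceAngiogram-class].
#' @examples
#' sim <- simulateAngiogram(angiogramSimSpec(imageSizePx = 64,
#'                                           capillaryFraction = 0.2))
#' f <- tempfile(fileext = ".tif")
#' saveAngiogram(sim$angiogram, f)
#' ang <- loadAngiogram(f)
#' @export
loadAngiogram <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image '", path, "': ",
                                           conditionMessage(e)))
  d <- dim(img)
  if (length(d) > 2 && d[3] > 1)
    stop("RGB/multichannel image not supported: ", path)
  px <- asMat(img)
  if (nrow(px) != ncol(px))
    stop(sprintf("non-square image (%d x %d): %s", nrow(px), ncol(px), path))
  # readImage returns x (col) by y (row); transpose to (row, col)
  px <- t(px)
  px <- pmin(pmax(px, 0), 1)

  side <- paste0(path, ".json")
  meta <- list()
  if (file.exists(side))
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  meta[names(metadata)] <- metadata
  grab <- function(key, default) if (!is.null(meta[[key]])) meta[[key]] else default
  EnFaceAngiogram(px,
    widthMm = as.numeric(grab("widthMm", 4.5)),
    centerPx = as.numeric(grab("centerPx", c(NA_real_, NA_real_))),
    laterality = as.character(grab("laterality", "OD")),
    subjectId = grab("subjectId", NA_character_),
    eyeId = grab("eyeId", NA_character_),
    group = grab("group", NA_character_))
}

#' Save an angiogram with its metadata sidecar
#'
#' Writes the intensity raster as 16-bit grayscale TIFF (or PNG) and a JSON
#' sidecar (`<path>.json`) carrying the physical scale and eye metadata, so a
#' later [loadAngiogram()] restores the object.
#'
#' @param ang an [EnFaceAngiogram-class].
#' @param path output file path; the format follows the extension.
#' @param bitsPerSample bit depth, 8 or 16 (default 16 for TIFF).
#' @return `path`, invisibly.
#' @export
saveAngiogram <- function(ang, path, bitsPerSample = 16L) {
  stopifnot(is(ang, "EnFaceAngiogram"))
  EBImage::writeImage(EBImage::Image(t(ang@pixels)), path,
                      bits.per.sample = as.integer(bitsPerSample))
  meta <- list(widthMm = ang@widthMm, laterality = ang@laterality,
               subjectId = ang@subjectId, eyeId = ang@eyeId,
               group = ang@group)
  if (!anyNA(ang@centerPx)) meta$centerPx <- ang@centerPx
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Save a binary mask as 8-bit PNG
#'
#' @param mask logical matrix.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
saveMask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Upscale an angiogram by an integer factor
#'
#' Bilinear interpolation; the physical width is unchanged, so the pixel
#' scale (px/mm) is multiplied by the factor. Bilinear interpolation is
#' monotone: a constant image stays constant and no overshoot beyond the
#' input range can occur. Factor 1 returns the input unchanged.
#'
#' @param ang an [EnFaceAngiogram-class].
#' @param factor positive integer scale factor.
#' @return the resized [EnFaceAngiogram-class].
#' @examples
#' ang <- EnFaceAngiogram(matrix(runif(64^2), 64, 64))
#' big <- resizeAngiogram(ang, 6)
#' nrow(pixels(big))  # 384
#' @export
resizeAngiogram <- function(ang, factor) {
  stopifnot(is(ang, "EnFaceAngiogram"))
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(ang)
  n <- nrow(ang@pixels)
  big <- asMat(EBImage::resize(EBImage::Image(ang@pixels), w = n * factor,
                               h = n * factor, filter = "bilinear"))
  ctr <- ang@centerPx
  if (!anyNA(ctr)) ctr <- (ctr - 0.5) * factor + 0.5
  EnFaceAngiogram(pmin(pmax(big, 0), 1), widthMm = ang@widthMm,
                  centerPx = ctr, laterality = ang@laterality,
                  subjectId = ang@subjectId, eyeId = ang@eyeId,
                  group = ang@group)
}
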