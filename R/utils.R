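# Internal helpers shared across modules.

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Local box mean with mirror padding, computed with summed-area tables.
# `w` must be odd; with `mask` supplied the mean is taken over mask == TRUE
# pixels only (windows without any mask pixel return 0).
boxMean <- function(m, w, mask = NULL) {
  stopifnot(w %% 2 == 1, w >= 3)
  nr <- nrow(m); nc <- ncol(m)
  if (w > nr || w > nc) stop("window larger than image")
  h <- (w - 1) / 2
  pr <- c(h:1, 1:nr, nr:(nr - h + 1))
  pc <- c(h:1, 1:nc, nc:(nc - h + 1))
  boxSum <- function(x) {
    xp <- x[pr, pc]
    cs <- t(apply(xp, 1, cumsum))
    s1 <- cs[, (1:nc) + w - 1] - cbind(0, cs)[, 1:nc]
    cs2 <- apply(s1, 2, cumsum)
    cs2[(1:nr) + w - 1, ] - rbind(0, cs2)[1:nr, ]
  }
  if (is.null(mask)) {
    boxSum(m) / w^2
  } else {
    cnt <- boxSum(mask * 1)
    s <- boxSum(m * (mask * 1))
    out <- s / pmax(cnt, 1)
    out[cnt == 0] <- 0
    out
  }
}

# Squared-grid distance (in px) of every pixel center from `center` (row, col).
pixelDistance <- function(side, center) {
  dr <- (1:side) - center[1]
  dc <- (1:side) - center[2]
  sqrt(outer(dr^2, dc^2, `+`))
}

# Polar angle (degrees in (-180, 180]) of every pixel center around `center`,
# measured from the image-right axis with up (towards row 1) = +90 degrees.
pixelAngle <- function(side, center) {
  up <- -((1:side) - center[1])
  right <- (1:side) - center[2]
  ang <- atan2(outer(up, rep(1, side)), outer(rep(1, side), right))
  ang * 180 / pi
}

# Logical matrix -> EBImage Image and back, keeping plain matrices elsewhere.
asImg <- function(m) EBImage::Image(m * 1)
asMat <- function(im) {
  m <- EBImage::imageData(im)
  dim(m) <- dim(m)[1:2]
  m
}

# Dilate a logical matrix with a disc brush of the given radius (px).
discDilate <- function(mask, radiusPx) {
  if (radiusPx < 1) return(mask)
  br <- EBImage::makeBrush(2L * as.integer(radiusPx) + 1L, shape = "disc")
  asMat(EBImage::dilate(asImg(mask), br)) > 0
}

mmToPx <- function(mm, scalePxPerMm) mm * scalePxPerMm
umToPx <- function(um, scalePxPerMm) um * 1e-3 * scalePxPerMm
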