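#' Build an angiogram simulation specification
#'
#' Collects the parameters of the seeded angiogram simulator. The defaults
#' emulate a 4.5 x 4.5 mm en-face OCT-A scan of the optic nerve head on a
#' 304 x 304 native grid: a dark disc cup, eight large radial vessels of
#' 90 um caliber leaving the disc, and a radially oriented mesh of thin
#' (1-2 px, i.e. 15-30 um) capillary segments filling the target area
#' fraction outside the disc and the vessels.
#'
#' @param imageSizePx native square side in px (>= 64).
#' @param scanFieldMm physical scan width in mm.
#' @param capillaryFraction target capillary area fraction in \[0, 1\],
#'   measured over eligible pixels (outside disc and vessels). Fractions
#'   above 0.65 exceed the packing limit of the thin-mesh texture and are
#'   rejected.
#' @param nMajorVessels number of large radial vessels.
#' @param vesselCaliberUm vessel full width at half maximum in micrometers.
#' @param discRadiusMm radius of the optic-disc analog in mm.
#' @param noiseSd standard deviation of additive background noise.
#' @param laterality `"OD"` or `"OS"`; `"OS"` yields the exact horizontal
#'   mirror of the `"OD"` layout for the same seed.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return an [AngiogramSimSpec-class] object.
#' @seealso [simulateAngiogram()]
#' @examples
#' spec <- angiogramSimSpec(capillaryFraction = 0.4, seed = 1)
#' @export
angiogramSimSpec <- function(imageSizePx = 304L, scanFieldMm = 4.5,
                             capillaryFraction = 0.4, nMajorVessels = 8L,
                             vesselCaliberUm = 90, discRadiusMm = 0.6,
                             noiseSd = 0.035, laterality = "OD", seed = 1L) {
  new("AngiogramSimSpec",
      imageSizePx = as.integer(imageSizePx), scanFieldMm = scanFieldMm,
      capillaryFraction = capillaryFraction,
      nMajorVessels = as.integer(nMajorVessels),
      vesselCaliberUm = vesselCaliberUm, discRadiusMm = discRadiusMm,
      noiseSd = noiseSd, laterality = laterality, seed = as.integer(seed))
}

# Intensity model constants of the simulator. Capillaries carry nearly the
# same decorrelation signal as large vessels on real OCT-A; the large vessels
# are distinguished by caliber, not brightness.
.SIM <- list(
  background = 0.15,    # avascular tissue level
  capillary = 0.92,     # capillary amplitude
  capillarySd = 0.03,   # capillary speckle
  vessel = 0.97,        # major-vessel peak amplitude
  disc = 0.02,          # disc cup level (dark; anchors the low percentile)
  marginPx = 2          # perivascular capillary-free zone, native px
)

#' Simulate an en-face angiogram with known ground truth
#'
#' Draws the optic-disc analog, smooth radial major vessels with a Gaussian
#' cross profile (caliber = full width at half maximum), and a radially
#' biased mesh of curvilinear capillary segments 1-2 px wide, until the
#' requested area fraction of eligible pixels is covered. Capillary segments
#' never fill a solid 3 x 3 native block and keep a small capillary-free
#' margin around major vessels, mirroring the anatomy of the radial
#' peripapillary network (thin parallel vessels, periarterial capillary-free
#' zone) and keeping capillary-scale structure well below the caliber of the
#' major vessels.
#'
#' The realized capillary fraction (capillary pixels / eligible pixels) is
#' within 0.02 of the request, or an error is raised.
#'
#' @param spec an [AngiogramSimSpec-class] from [angiogramSimSpec()].
#' @param subjectId,eyeId,group optional metadata copied to the angiogram.
#' @return a list with elements
#'   \describe{
#'     \item{angiogram}{an [EnFaceAngiogram-class];}
#'     \item{capillaryMask}{logical matrix, ground-truth capillary pixels;}
#'     \item{vesselMask}{logical matrix, ground-truth major-vessel pixels
#'       (within the half-maximum width);}
#'     \item{eligibleMask}{logical matrix of pixels eligible for capillaries;}
#'     \item{capillaryFraction}{the realized fraction, computed from the
#'       returned masks.}
#'   }
#' @examples
#' sim <- simulateAngiogram(angiogramSimSpec(imageSizePx = 128,
#'                                           capillaryFraction = 0.3,
#'                                           seed = 7))
#' sim$capillaryFraction
#' @export
simulateAngiogram <- function(spec, subjectId = NA, eyeId = NA, group = NA) {
  stopifnot(is(spec, "AngiogramSimSpec"))
  validObject(spec)
  out <- withSeed(spec@seed, .drawAngiogram(spec))
  if (spec@laterality == "OS") {
    flip <- function(m) m[, ncol(m):1]
    out$img <- flip(out$img)
    out$cap <- flip(out$cap)
    out$vessel <- flip(out$vessel)
    out$elig <- flip(out$elig)
  }
  ang <- EnFaceAngiogram(out$img, widthMm = spec@scanFieldMm,
                         laterality = spec@laterality,
                         subjectId = subjectId, eyeId = eyeId, group = group)
  list(angiogram = ang, capillaryMask = out$cap, vesselMask = out$vessel,
       eligibleMask = out$elig,
       capillaryFraction = sum(out$cap) / sum(out$elig))
}

# Core drawing routine; always draws the OD layout.
.drawAngiogram <- function(spec) {
  n <- spec@imageSizePx
  scale <- n / spec@scanFieldMm
  ctr <- (n + 1) / 2
  dd <- pixelDistance(n, c(ctr, ctr))
  disc <- dd <= mmToPx(spec@discRadiusMm, scale)
  fwhmPx <- umToPx(spec@vesselCaliberUm, scale)

  # major vessels: wavy radial centerlines from the disc, Gaussian profile
  cl <- matrix(FALSE, n, n)
  if (spec@nMajorVessels > 0) {
    angs <- seq(0, 2 * pi, length.out = spec@nMajorVessels + 1)[seq_len(spec@nMajorVessels)]
    angs <- angs + runif(spec@nMajorVessels, -0.2, 0.2)
    r0 <- mmToPx(spec@discRadiusMm, scale) * 0.8
    for (a in angs) {
      th <- a; r <- r0
      while (r < n) {
        row <- round(ctr - r * sin(th)); col <- round(ctr + r * cos(th))
        if (row >= 1 && row <= n && col >= 1 && col <= n) cl[row, col] <- TRUE
        th <- th + rnorm(1, 0, 0.02 / (1 + r / 40))
        r <- r + 0.5
      }
    }
  }
  if (any(cl)) {
    d <- asMat(EBImage::distmap(asImg(!cl)))
    vessel <- d <= fwhmPx / 2
    profile <- exp(-d^2 / (2 * (fwhmPx / 2.355)^2))
    elig <- !disc & (d > fwhmPx / 2 + .SIM$marginPx)
  } else {
    vessel <- matrix(FALSE, n, n)
    profile <- matrix(0, n, n)
    elig <- !disc
  }
  if (sum(elig) == 0)
    stop("no eligible pixels: disc and vessels cover the frame")
  if (spec@capillaryFraction > 0.65)
    stop("capillaryFraction above the 0.65 packing limit of the capillary mesh")

  cap <- .drawCapillaries(spec, elig, ctr)
  realized <- sum(cap) / sum(elig)
  if (abs(realized - spec@capillaryFraction) > 0.02)
    stop(sprintf(
      "capillary fraction %.3f unattainable (realized %.3f): vessel and disc coverage too high",
      spec@capillaryFraction, realized))

  img <- matrix(.SIM$background + rnorm(n * n, 0, spec@noiseSd), n, n)
  img[disc] <- .SIM$disc + abs(rnorm(sum(disc), 0, 0.02))
  img[cap] <- .SIM$capillary + rnorm(sum(cap), 0, .SIM$capillarySd)
  img <- pmax(img, profile * .SIM$vessel)
  img <- pmin(pmax(img, 0), 1)
  list(img = img, cap = cap, vessel = vessel, elig = elig)
}

# Radially biased curvilinear segments, width 1-2 px, never filling a solid
# 3x3 block (keeps capillary caliber below the major-vessel range).
.drawCapillaries <- function(spec, elig, ctr) {
  n <- spec@imageSizePx
  cap <- matrix(FALSE, n, n)
  need <- round(spec@capillaryFraction * sum(elig))
  if (need == 0) return(cap)
  off <- as.matrix(expand.grid(-1:1, -1:1))
  cnt <- 0L; it <- 0L; maxIt <- 2e4L + 400L * need %/% 10L
  while (cnt < need && it < maxIt) {
    it <- it + 1L
    r0 <- runif(1, 2, n - 1); c0 <- runif(1, 2, n - 1)
    base <- atan2(-(r0 - ctr), c0 - ctr)
    th <- base + rnorm(1, 0, 0.25) + sample(c(0, pi), 1)
    len <- runif(1, 10, 30); cur <- rnorm(1, 0, 0.02)
    steps <- seq(0, len, by = 0.5)
    ths <- th + cur * steps
    rows <- round(r0 - cumsum(c(0, diff(steps)) * sin(ths)))
    cols <- round(c0 + cumsum(c(0, diff(steps)) * cos(ths)))
    if (runif(1) < 0.5) {   # half the segments are 2 px wide
      pr <- round(-cos(mean(ths))); pc <- round(-sin(mean(ths)))
      if (pr == 0 && pc == 0) pr <- 1
      rows <- c(rows, rows + pr); cols <- c(cols, cols + pc)
    }
    ok <- rows >= 2 & rows <= n - 1 & cols >= 2 & cols <= n - 1
    idx <- unique(cbind(rows[ok], cols[ok]))
    if (nrow(idx) == 0) next
    sel <- elig[idx] & !cap[idx]
    idx <- idx[sel, , drop = FALSE]
    for (k in seq_len(nrow(idx))) {
      p <- idx[k, ]
      nb <- cbind(p[1] + off[, 1], p[2] + off[, 2])
      if (sum(cap[nb]) >= 6) next     # would over-thicken the mesh
      cap[p[1], p[2]] <- TRUE
      cnt <- cnt + 1L
      if (cnt >= need) break
    }
  }
  cap
}
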