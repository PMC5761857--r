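test_that("region densities equal the brute-force pixel count exactly", {
  set.seed(17)
  n <- 192
  cap <- matrix(runif(n * n) < 0.5, n, n)
  ves <- matrix(FALSE, n, n); ves[, 90:108] <- TRUE   # ~10% vessel band
  seg <- makeSeg(cap, ves, scalePxPerMm = n / 4.5)
  roi <- makeAnnulus(n, n / 4.5)

  region <- !innerMask(roi) & !ves
  expect_equal(wholeImagePCD(seg, roi),
               bruteForcePct(capillaryBinary(seg), region))
  expect_equal(regionPCD(seg, annulusMask(roi)),
               bruteForcePct(capillaryBinary(seg), annulusMask(roi) & !ves))
  for (s in names(sectorMasks(roi)))
    expect_equal(regionPCD(seg, sectorMasks(roi)[[s]]),
                 bruteForcePct(capillaryBinary(seg),
                               sectorMasks(roi)[[s]] & !ves))
  # alternative denominator convention: vessels kept in the denominator
  expect_equal(regionPCD(seg, annulusMask(roi), excludeVessels = FALSE),
               bruteForcePct(capillaryBinary(seg), annulusMask(roi)))
})

test_that("degenerate binaries give the endpoint percentages", {
  n <- 96
  none <- matrix(FALSE, n, n)
  all_ <- matrix(TRUE, n, n)
  roi <- makeAnnulus(n, n / 4.5)
  expect_equal(wholeImagePCD(makeSeg(all_, none), roi), 100)
  expect_equal(wholeImagePCD(makeSeg(none, none), roi), 0)
  expect_equal(regionPCD(makeSeg(all_, none), annulusMask(roi)), 100)
  # exactly half the annulus white -> 50.0
  ann <- annulusMask(roi)
  idx <- which(ann)
  half <- none; half[idx[seq_len(floor(length(idx) / 2))]] <- TRUE
  expect_equal(regionPCD(makeSeg(half, none), ann),
               100 * floor(length(idx) / 2) / length(idx))
  expect_error(regionPCD(makeSeg(none, none), none), "empty mask")
  expect_error(wholeImagePCD(makeSeg(none, all_), roi), "zero denominator")
})

test_that("annulus counts decompose over sectors and bound the annulus value", {
  set.seed(3)
  n <- 128
  cap <- matrix(runif(n * n) < 0.4, n, n)
  seg <- makeSeg(cap, matrix(FALSE, n, n), n / 4.5)
  roi <- makeAnnulus(n, n / 4.5)
  res <- computePCD(seg, roi)
  counts <- res@counts
  annNum <- counts$numerator[counts$region == "whole_annulus"]
  secNum <- sum(counts$numerator[counts$region %in% names(sectorMasks(roi))])
  expect_identical(annNum, secNum)
  expect_gte(res@annulusPct, min(res@sectorPct))
  expect_lte(res@annulusPct, max(res@sectorPct))
})

test_that("density map cells match direct window counts", {
  set.seed(9)
  n <- 96
  cap <- matrix(runif(n * n) < 0.35, n, n)
  ves <- matrix(FALSE, n, n); ves[40:48, 1:30] <- TRUE
  seg <- makeSeg(cap, ves, n / 4.5)
  dm <- densityMap(seg, windowPx = 16, stridePx = 8)
  v <- densityValues(dm)
  expect_equal(dim(v), c(11, 11))   # floor((96 - 16) / 8) + 1
  starts <- seq(1, n - 16 + 1, by = 8)
  for (i in seq_along(starts)) for (j in seq_along(starts))
    expect_equal(v[i, j], bruteForceCell(capillaryBinary(seg), ves,
                                         starts[i], starts[j], 16))
})

test_that("density-map grid dimensions follow the stated formula", {
  mk <- function(side) makeSeg(matrix(TRUE, side, side),
                               matrix(FALSE, side, side), side / 4.5)
  expect_equal(dim(densityValues(densityMap(mk(304), 16, 8))),
               rep(floor((304 - 16) / 8) + 1, 2))
  expect_equal(dim(densityValues(densityMap(mk(100), 10, 3))),
               rep(floor((100 - 10) / 3) + 1, 2))
  expect_true(all(densityValues(densityMap(mk(64))) == 100))
  expect_error(densityMap(mk(64), windowPx = 128), "larger than image")
  expect_error(densityMap(mk(64), windowPx = 8, stridePx = 16), "stride")
})

test_that("mean cell density tracks the whole-frame density", {
  set.seed(5)
  n <- 160
  for (p in c(0.2, 0.5)) {
    cap <- matrix(runif(n * n) < p, n, n)
    seg <- makeSeg(cap, matrix(FALSE, n, n), n / 4.5)
    dm <- densityMap(seg)
    expect_lt(abs(mean(densityValues(dm)) - 100 * mean(cap)), 1)
  }
})

test_that("density-map rendering is deterministic with anchored colors", {
  seg <- makeSeg(matrix(c(TRUE, FALSE), 64, 64), matrix(FALSE, 64, 64),
                 64 / 4.5)
  dm <- densityMap(seg)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  renderDensityMap(dm, f1); renderDensityMap(dm, f2)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  # endpoints of the scale
  lo <- new("DensityMap", values = matrix(0, 4, 4), windowPx = 16L,
            stridePx = 8L)
  hi <- new("DensityMap", values = matrix(100, 4, 4), windowPx = 16L,
            stridePx = 8L)
  fl <- tempfile(fileext = ".png"); fh <- tempfile(fileext = ".png")
  renderDensityMap(lo, fl); renderDensityMap(hi, fh)
  plo <- png::readPNG(fl); phi <- png::readPNG(fh)
  expect_true(all(abs(plo[1, 1, ] - c(0, 0, 0.55)) < 0.01))  # 0% dark blue
  expect_true(all(abs(phi[1, 1, ] - c(1, 0, 0)) < 0.01))     # 100% red
  # a uniform map renders one single color
  expect_equal(length(unique(as.vector(phi[, , 1]))), 1)
})
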