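test_that("contrast stretch matches a direct percentile-affine oracle", {
  set.seed(4)
  ramp <- matrix(seq(0, 1, length.out = 10000), 100, 100)
  out <- contrastStretch(ramp)
  q <- quantile(ramp, c(0.01, 0.99), type = 7, names = FALSE)
  oracle <- pmin(pmax((ramp - q[1]) / (q[2] - q[1]), 0), 1)
  expect_equal(out, oracle)
  expect_equal(out[ramp <= 0.01], rep(0, sum(ramp <= 0.01)))
  expect_equal(out[ramp >= 0.99], rep(1, sum(ramp >= 0.99)))
})

test_that("contrast stretch fixes already-spanning images and rejects flat ones", {
  m <- matrix(runif(2500), 50, 50)
  m[1] <- 0; m[2] <- 1
  # 1st/99th percentiles at ~0/1: output equals input up to clipping
  q <- quantile(m, c(0.01, 0.99), type = 7, names = FALSE)
  out <- contrastStretch(m)
  expect_lt(max(abs(out - pmin(pmax((m - q[1]) / (q[2] - q[1]), 0), 1))),
            1e-12)
  expect_error(contrastStretch(matrix(0.5, 10, 10)), "degenerate")
})

test_that("global threshold is strict at the boundary", {
  m <- matrix(c(0.54, 0.55, 0.56, 0.9), 2, 2)
  b <- globalThreshold(m, 0.55)
  expect_identical(as.vector(b), c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(globalThreshold(matrix(0, 5, 5))))
  expect_error(globalThreshold(m, 1.5), "\\[0, 1\\]")
})

test_that("thresholding is idempotent and monotone", {
  set.seed(8)
  m <- matrix(runif(900), 30, 30)
  b <- globalThreshold(m, 0.55)
  expect_identical(globalThreshold(b * 1, 0.55), b)   # idempotent on {0,1}
  for (t2 in c(0.6, 0.7, 0.9)) {
    b2 <- globalThreshold(m, t2)
    expect_true(all(b | !b2))   # raising t never adds white pixels
  }
})

test_that("adaptive threshold handles flat, isolated and structured input", {
  expect_false(any(adaptiveThreshold(matrix(0.7, 40, 40), 15)))
  single <- matrix(0, 40, 40); single[20, 20] <- 1
  ab <- adaptiveThreshold(single, 15)
  expect_true(ab[20, 20])
  expect_error(adaptiveThreshold(single, 14), "odd")
  expect_error(adaptiveThreshold(single, 41), "larger than image")
})

test_that("adaptive threshold recovers bright lines on a brightness gradient", {
  set.seed(2)
  n <- 120
  grad <- matrix(rep(seq(0.1, 0.6, length.out = n), each = n), n, n)
  lines <- matrix(FALSE, n, n)
  lines[seq(10, n - 10, by = 9), ] <- TRUE      # 1-px horizontal lines
  img <- grad + 0.25 * lines
  ab <- adaptiveThreshold(img, 15)
  expect_gte(mean(ab[lines]), 0.95)             # lines recovered
  expect_lte(mean(ab[!lines]), 0.30)            # background mostly dark
})

test_that("caliber-based vessel detection separates wide from thin structure", {
  scale <- 405.33   # px/mm at the working grid
  n <- 400
  b <- matrix(FALSE, n, n)
  bar <- 183:218                                # ~36 px = 90 um wide vessel
  b[bar, ] <- TRUE
  thin <- seq(10, 160, by = 12)
  for (r in thin) b[r:(r + 3), ] <- TRUE        # 4 px = 10 um capillaries
  vm <- detectMajorVessels(b, scale, caliberCutoffUm = 40, dilationPx = 2,
                           coreMinPx = 500)
  truth <- matrix(FALSE, n, n); truth[bar, ] <- TRUE
  iou <- sum(vm & truth) / sum(vm | truth)
  expect_gte(iou, 0.8)
  expect_false(any(vm[1:170, ]))                # capillaries untouched
  # everything below the cutoff -> empty mask
  thinOnly <- b; thinOnly[bar, ] <- FALSE
  expect_false(any(detectMajorVessels(thinOnly, scale, 40)))
  expect_error(detectMajorVessels(b, NA), "scale")
})

test_that("two well-separated vessels give two components before dilation", {
  scale <- 405.33
  b <- matrix(FALSE, 400, 400)
  b[100:135, ] <- TRUE
  b[300:335, ] <- TRUE
  vm <- detectMajorVessels(b, scale, caliberCutoffUm = 40, dilationPx = 0,
                           coreMinPx = 500)
  lab <- EBImage::bwlabel(EBImage::Image(vm * 1))
  expect_equal(max(lab), 2)
})

test_that("full segmentation honors its invariants", {
  sim <- smallSim()
  # core-area threshold rescaled to the small working grid
  seg <- segmentCapillaries(sim$angiogram, resizeFactor = 2,
                            vesselCoreMinPx = 60)
  expect_false(any(capillaryBinary(seg) & vesselMask(seg)))
  # ground-truth vessel pixels (upsampled) are excluded from the capillary map
  f <- 2
  vgt <- sim$vesselMask[rep(seq_len(96), each = f), rep(seq_len(96), each = f)]
  expect_lt(mean(capillaryBinary(seg)[vgt]), 0.05)
  # blank image -> empty segmentation
  blank <- segmentCapillaries(EnFaceAngiogram(matrix(0, 96, 96)),
                              resizeFactor = 2)
  expect_false(any(capillaryBinary(blank)))
  expect_false(any(vesselMask(blank)))
})

test_that("measured fraction increases strictly with true fraction", {
  # reduced-size version of the recovery study (full size in acceptance)
  meas <- sapply(c(0.15, 0.35, 0.55), function(f) {
    sim <- simulateAngiogram(angiogramSimSpec(imageSizePx = 152,
                                              capillaryFraction = f,
                                              seed = 30 + round(100 * f)))
    seg <- segmentCapillaries(sim$angiogram, resizeFactor = 3,
                              vesselCoreMinPx = 150)
    roi <- makeAnnulus(nrow(capillaryBinary(seg)), scalePxPerMm(seg))
    regionPCD(seg, annulusMask(roi))
  })
  expect_true(all(diff(meas) > 0))
})
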