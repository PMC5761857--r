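# Independent brute-force oracles and small shared fixtures.

# density percentage by explicit pixel enumeration (independent of the
# summed-area-table implementation in the package)
bruteForcePct <- function(capillary, region) {
  num <- 0L; den <- 0L
  for (i in seq_len(nrow(capillary))) for (j in seq_len(ncol(capillary))) {
    if (region[i, j]) {
      den <- den + 1L
      if (capillary[i, j]) num <- num + 1L
    }
  }
  100 * num / den
}

# density-map cell by direct submatrix counting
bruteForceCell <- function(capillary, vessel, r0, c0, w) {
  sub <- capillary[r0:(r0 + w - 1), c0:(c0 + w - 1)]
  nv <- !vessel[r0:(r0 + w - 1), c0:(c0 + w - 1)]
  den <- sum(nv)
  if (den == 0) return(NA_real_)
  100 * sum(sub & nv) / den
}

# build a PerfusionSegmentation directly from given grids
makeSeg <- function(capillary, vessel, scalePxPerMm = 67.6) {
  new("PerfusionSegmentation",
      capillaryBinary = capillary & !vessel, vesselMask = vessel,
      globalBinary = capillary, adaptiveBinary = capillary,
      stretched = capillary * 1, scalePxPerMm = scalePxPerMm,
      params = list())
}

# small angiogram simulation reused across tests (computed once per run)
smallSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateAngiogram(angiogramSimSpec(
        imageSizePx = 96, capillaryFraction = 0.3, seed = 11))
    cache
  }
})

# within-eye permutation oracle for the dependent-correlation test: swap the
# two sector pairs eye-wise and recompute the correlation difference
permutationP <- function(d, B = 5000, seed = 1) {
  obs <- abs(cor(d$x1, d$y1) - cor(d$x2, d$y2))
  cnt <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    sw <- runif(nrow(d)) < 0.5
    X1 <- ifelse(sw, d$x2, d$x1); Y1 <- ifelse(sw, d$y2, d$y1)
    X2 <- ifelse(sw, d$x1, d$x2); Y2 <- ifelse(sw, d$y1, d$y2)
    if (abs(cor(X1, Y1) - cor(X2, Y2)) >= obs) cnt <- cnt + 1L
  }
  (cnt + 1) / (B + 1)
}

# latent-factor draw with equal marginals and prescribed within-pair
# correlations, for permutation-oracle datasets
drawCorrPairs <- function(n, r1, r2, seed) {
  set.seed(seed)
  L1 <- rnorm(n); L2 <- rnorm(n)
  data.frame(
    x1 = sqrt(r1) * L1 + sqrt(1 - r1) * rnorm(n),
    y1 = sqrt(r1) * L1 + sqrt(1 - r1) * rnorm(n),
    x2 = sqrt(r2) * L2 + sqrt(1 - r2) * rnorm(n),
    y2 = sqrt(r2) * L2 + sqrt(1 - r2) * rnorm(n))
}
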