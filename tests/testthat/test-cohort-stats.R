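test_that("with one eye per subject the mixed model reduces to OLS", {
  set.seed(31)
  n <- 120
  d <- data.frame(
    subject_id = sprintf("s%03d", 1:n), eye_id = sprintf("s%03d_OD", 1:n),
    group = rep(c("control", "POAG"), each = n / 2),
    age_years = rnorm(n, 58, 10), sex = rbinom(n, 1, 0.5),
    axial_length_mm = rnorm(n, 23, 1.4),
    pcd_whole_pct = rnorm(n, 40, 5))
  g <- compareGroups(d, "pcd_whole_pct")
  d$group <- factor(d$group, levels = c("control", "POAG"))
  ols <- lm(pcd_whole_pct ~ group + age_years + sex + axial_length_mm, d)
  # the group contrast equals the OLS coefficient
  expect_lt(abs(g@contrasts$estimate[1] - (-coef(ols)[["groupPOAG"]])), 1e-6)
})

test_that("identically drawn groups give null-like contrasts", {
  ps <- sapply(1:24, function(i) {
    set.seed(400 + i)
    n <- 200
    d <- data.frame(
      subject_id = sprintf("s%03d", rep(1:n, each = 2)),
      eye_id = paste0(sprintf("s%03d", rep(1:n, each = 2)), c("_OD", "_OS")),
      group = rep(c("control", "POAG"), each = n),
      age_years = rep(rnorm(n, 58, 10), each = 2),
      sex = rep(rbinom(n, 1, 0.5), each = 2),
      axial_length_mm = rnorm(2 * n, 23, 1.4),
      pcd_whole_pct = rep(rnorm(n, 40, 3), each = 2) * 0.5 +
        rnorm(2 * n, 20, 2.2))
    g <- compareGroups(d, "pcd_whole_pct")
    c(g@contrasts$p_raw[1], abs(g@contrasts$estimate[1]))
  })
  # raw p roughly uniform: the mean is near 0.5 and small p are not enriched
  expect_gt(mean(ps[1, ]), 0.3)
  expect_lt(mean(ps[1, ]), 0.7)
  expect_lt(mean(ps[1, ] < 0.1), 0.35)
  expect_lt(max(ps[2, ]), 1.5)   # |difference| stays at sampling-noise scale
})

test_that("an injected group difference is recovered with nominal coverage", {
  hits <- sapply(1:200, function(i) {
    set.seed(1000 + i)
    n <- 50
    d <- data.frame(
      subject_id = sprintf("s%03d", 1:(2 * n)),
      eye_id = sprintf("s%03d_OD", 1:(2 * n)),
      group = rep(c("control", "POAG"), each = n),
      age_years = rnorm(2 * n, 58, 10), sex = rbinom(2 * n, 1, 0.5),
      axial_length_mm = rnorm(2 * n, 23, 1.4),
      pcd_whole_pct = rnorm(2 * n, 40, 2) - 10 * rep(0:1, each = n))
    g <- compareGroups(d, "pcd_whole_pct")
    ct <- g@contrasts[1, ]   # control - POAG, truth +10
    ct$lower <= 10 && 10 <= ct$upper
  })
  expect_gte(mean(hits), 0.93)
})

test_that("contrast p-values respect the Bonferroni relation", {
  tab <- simulateCohort(cohortSimSpec(seed = 6))
  g <- compareGroups(tab, "pcd_annulus_pct")
  expect_true(all(g@contrasts$p_adj >= g@contrasts$p_raw - 1e-12))
  expect_true(all(g@contrasts$p_adj <= 1))
  expect_equal(g@contrasts$p_adj,
               pmin(1, g@contrasts$p_raw * nrow(g@contrasts)))
})

test_that("a constant covariate is reported by name", {
  tab <- simulateCohort(cohortSimSpec(seed = 2))
  tab$axial_length_mm <- 23
  expect_error(compareGroups(tab, "pcd_whole_pct"), "axial_length_mm")
})

test_that("sector contrasts are paired means of within-eye differences", {
  tab <- simulateCohort(cohortSimSpec(seed = 8))
  sc <- sectorContrasts(tab, "POAG")
  d <- tab[tab$group == "POAG", ]
  expect_equal(sc$estimate[sc$pair == "superior - inferior"],
               mean(d$pcd_sup_pct - d$pcd_inf_pct))
  expect_equal(sc$estimate[sc$pair == "nasal - temporal"],
               mean(d$pcd_nas_pct - d$pcd_temp_pct))
  expect_true(all(sc$p_adj == pmin(1, 6 * sc$p_raw)))
})

test_that("identical sectors give zero contrasts with p = 1", {
  tab <- simulateCohort(cohortSimSpec(seed = 5))
  for (cc in c("pcd_nas_pct", "pcd_inf_pct", "pcd_temp_pct"))
    tab[[cc]] <- tab$pcd_sup_pct
  sc <- sectorContrasts(tab, "control")
  expect_true(all(sc$estimate == 0))
  expect_true(all(sc$p_raw == 1))
})

test_that("a depressed superior sector is flagged at n = 100", {
  set.seed(77)
  n <- 100
  base <- rnorm(n, 42, 2)
  tab <- data.frame(
    subject_id = sprintf("s%03d", 1:n), eye_id = sprintf("s%03d_OD", 1:n),
    group = "control",
    pcd_sup_pct = base - 5 + rnorm(n, 0, 2),
    pcd_nas_pct = base + rnorm(n, 0, 2),
    pcd_inf_pct = base + rnorm(n, 0, 2),
    pcd_temp_pct = base + rnorm(n, 0, 2))
  sc <- sectorContrasts(tab, "control")
  supPairs <- grepl("superior", sc$pair)
  expect_true(all(sc$p_adj[supPairs] < 0.05))
  # missing sector values are dropped with a warning
  tab$pcd_nas_pct[1:3] <- NA
  expect_warning(sectorContrasts(tab, "control"), "3 eye")
})

test_that("univariate fits report consistent slope, r and R2", {
  d <- data.frame(x = 1:20, y = 2 * (1:20))
  f <- suppressWarnings(univariateFit(d, "y", "x"))  # exact fit warns
  expect_equal(f$r, 1)
  expect_equal(f$R2, 1)
  set.seed(12)
  d2 <- data.frame(x = rnorm(300), e = rnorm(300))
  d2$y <- -0.5 * d2$x + d2$e
  f2 <- univariateFit(d2, "y", "x")
  expect_lt(f2$r, 0)                      # r carries the slope sign
  expect_equal(f2$r^2, f2$R2, tolerance = 1e-12)
  expect_error(univariateFit(data.frame(x = rep(1, 10), y = rnorm(10)),
                             "y", "x"), "zero variance")
})

test_that("sample correlation lands in the sampling-error band", {
  set.seed(44)
  n <- 5000
  L <- rnorm(n)
  x <- sqrt(0.5) * L + sqrt(0.5) * rnorm(n)
  y <- sqrt(0.5) * L + sqrt(0.5) * rnorm(n)
  f <- univariateFit(data.frame(x = x, y = y), "y", "x")
  expect_gte(f$r, 0.47); expect_lte(f$r, 0.53)
})

test_that("equal correlations yield a null comparison", {
  cmp <- compareDependentCorrelations(r1 = 0.5, r2 = 0.5, n = 100)
  expect_identical(cmp@difference, 0)
  expect_identical(cmp@p, 1)
  expect_true(cmp@conservative)
})

test_that("the correlation comparison is antisymmetric", {
  d <- drawCorrPairs(400, 0.5, 0.3, seed = 7)
  a <- compareDependentCorrelations(d$x1, d$y1, d$x2, d$y2)
  b <- compareDependentCorrelations(d$x2, d$y2, d$x1, d$y1)
  expect_equal(a@difference, -b@difference)
  expect_equal(a@z, -b@z)
  expect_equal(a@p, b@p)
  expect_false(a@conservative)   # intercorrelations estimated from data
})

test_that("inadmissible inputs to the correlation comparison error out", {
  expect_error(compareDependentCorrelations(r1 = 0.5, r2 = 0.3, n = 3),
               "n > 3")
  expect_error(
    compareDependentCorrelations(r1 = 0.9, r2 = -0.9, n = 50,
                                 intercor = c(0.95, 0.95, 0.95, 0.95)),
    "positive semidefinite")
})

test_that("the conservative fallback never overstates the evidence", {
  d <- drawCorrPairs(500, 0.55, 0.35, seed = 9)
  full <- compareDependentCorrelations(d$x1, d$y1, d$x2, d$y2)
  cons <- compareDependentCorrelations(r1 = full@r1, r2 = full@r2,
                                       n = full@n)
  expect_gte(cons@p, full@p)   # positive dependence: independence loses power
})
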