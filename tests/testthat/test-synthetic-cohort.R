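test_that("group means converge to the requested values at large n", {
  spec <- cohortSimSpec(
    nSubjects = c(control = 10000L, NAION = 10000L, POAG = 10000L),
    nEyes = c(control = 20000L, POAG = 20000L), seed = 7)
  tab <- simulateCohort(spec)
  for (g in levels(tab$group)) {
    gp <- spec@groupParams[[g]]
    d <- tab[tab$group == g, ]
    for (o in c("pcd_whole_pct", "pcd_sup_pct", "rnfl_global_um",
                "axial_length_mm")) {
      relErr <- abs(mean(d[[o]]) - gp$mean[[o]]) / abs(gp$mean[[o]])
      expect_lt(relErr, 0.02)
      expect_lt(abs(sd(d[[o]]) - gp$sd[[o]]) / gp$sd[[o]], 0.05)
    }
  }
})

test_that("withinSubjectRho = 0 decouples the two eyes of a pair", {
  tab <- simulateCohort(cohortSimSpec(withinSubjectRho = 0,
                                      nSubjects = c(NAION = 10000L),
                                      seed = 3))
  aff <- tab[tab$group == "NAION", ]
  fel <- tab[tab$group == "fellow", ]
  fel <- fel[match(aff$subject_id, fel$subject_id), ]
  zAff <- (aff$pcd_whole_pct - mean(aff$pcd_whole_pct))
  zFel <- (fel$pcd_whole_pct - mean(fel$pcd_whole_pct))
  expect_lt(abs(cor(zAff, zFel)), 0.05)
})

test_that("inter-eye correlation approaches withinSubjectRho", {
  sect <- setNames(rep(0.3, 4),
                   c("superior", "nasal", "inferior", "temporal"))
  corrs <- list(control = sect, NAION = sect, fellow = sect, POAG = sect)
  tab <- simulateCohort(cohortSimSpec(withinSubjectRho = 0.4,
                                      sectorCorrelations = corrs,
                                      nSubjects = c(NAION = 8000L),
                                      seed = 13))
  aff <- tab[tab$group == "NAION", ]
  fel <- tab[tab$group == "fellow", ]
  fel <- fel[match(aff$subject_id, fel$subject_id), ]
  r <- cor(aff$md_db, fel$md_db)
  expect_gt(r, 0.35); expect_lt(r, 0.45)
})

test_that("sector density-thickness correlation hits its target", {
  tab <- simulateCohort(cohortSimSpec(nSubjects = c(control = 3000L),
                                      nEyes = c(control = 5000L), seed = 21))
  d <- tab[tab$group == "control", ]
  r <- cor(d$pcd_sup_pct, d$rnfl_sup_um)   # target sqrt(0.57) = 0.755
  expect_gte(r, 0.73)
  expect_lte(r, 0.78)
})

test_that("cohort generation is deterministic and validates its spec", {
  a <- simulateCohort(cohortSimSpec(seed = 2))
  b <- simulateCohort(cohortSimSpec(seed = 2))
  expect_identical(a, b)
  expect_error(cohortSimSpec(nSubjects = c(control = 1L)), "2 subjects")
  expect_error(cohortSimSpec(withinSubjectRho = 0.5), "not attainable")
  bad <- cohortGroupDefaults()$groupParams
  bad$control$sd[1] <- 0
  expect_error(cohortSimSpec(groupParams = bad), "SDs")
})

test_that("default cohort matches the study layout", {
  tab <- simulateCohort(cohortSimSpec(seed = 1))
  expect_equal(as.vector(table(tab$group)), c(77, 31, 31, 42))
  expect_equal(length(unique(tab$subject_id)), 46 + 31 + 27)
  expect_true(all(table(tab$subject_id) <= 2))
  # NAION and fellow eyes pair up within subjects, opposite lateralities
  aff <- tab[tab$group == "NAION", ]
  fel <- tab[tab$group == "fellow", ]
  expect_setequal(aff$subject_id, fel$subject_id)
  m <- merge(aff, fel, by = "subject_id")
  expect_true(all(m$laterality.x != m$laterality.y))
  expect_true(all(tab$pcd_whole_pct >= 0 & tab$pcd_whole_pct <= 100))
})
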