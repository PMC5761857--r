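#' Default per-group cohort parameters
#'
#' Study-condition parameters of the cohort simulator: mean and standard
#' deviation of every outcome in each of the four groups (healthy controls,
#' chronic NAION eyes, their unaffected fellow eyes, and moderate-to-severe
#' POAG eyes), the proportion of female subjects, and the target Pearson
#' correlation between each sector PCD and the corresponding sector RNFL
#' thickness. PCD values are area percentages, RNFL thickness is in
#' micrometers, visual field mean deviation (MD) in dB, axial length in mm.
#'
#' @return a list with elements `groupParams` (per-group `mean`/`sd` vectors
#'   and `sexFemale`), `sectorCorrelations` (per-group numeric vector over
#'   superior/nasal/inferior/temporal), `nSubjects` and `nEyes` (named
#'   integer vectors).
#' @seealso [cohortSimSpec()]
#' @export
cohortGroupDefaults <- function() {
  outc <- c("age_years", "axial_length_mm", "md_db",
            "rnfl_global_um", "rnfl_sup_um", "rnfl_nas_um", "rnfl_inf_um",
            "rnfl_temp_um",
            "pcd_whole_pct", "pcd_annulus_pct", "pcd_sup_pct", "pcd_nas_pct",
            "pcd_inf_pct", "pcd_temp_pct")
  mk <- function(mean, sd, sexFemale)
    list(mean = setNames(mean, outc), sd = setNames(sd, outc),
         sexFemale = sexFemale)
  groupParams <- list(
    NAION = mk(
      c(54.1, 22.4, -18.4, 59.8, 57.8, 52.7, 69.7, 48.4,
        30.1, 29.7, 26.8, 32.5, 31.2, 28.2),
      c(11, 1.5, 8.6, 16.3, 16.1, 23.1, 21.3, 26.5,
        6, 6.5, 9.3, 6.8, 7.6, 8.4),
      15 / 31),
    fellow = mk(
      c(54.1, 22.2, -1.0, 102.2, 126.4, 80.5, 133.1, 68.1,
        41.6, 42.3, 41.5, 42.9, 42.6, 42.5),
      c(11, 1.8, 2.7, 10.5, 19.1, 15.4, 17.3, 13.1,
        4.5, 5, 7.0, 4.3, 4.7, 4.9),
      15 / 31),
    POAG = mk(
      c(60.2, 23.2, -17.2, 64.0, 77.6, 59.0, 66.3, 52.2,
        30.2, 31.3, 29.1, 32.2, 36.1, 28.0),
      c(8, 1.3, 8.6, 14.1, 22.4, 15.1, 17.4, 14.6,
        5.1, 5.6, 7.6, 7.9, 6.9, 8.2),
      16 / 42),
    control = mk(
      c(58.4, 23.0, -0.6, 98.2, 121.3, 74.0, 127.0, 68.8,
        42.3, 43.9, 43.7, 43.3, 43.9, 44.6),
      c(10.3, 1.4, 1.7, 10.3, 20.4, 11.3, 17.4, 12.4,
        2.3, 2.0, 2.2, 2.7, 2.2, 2.2),
      42 / 77)
  )
  sect <- c("superior", "nasal", "inferior", "temporal")
  # within-group density-thickness correlations; the glaucoma spectrum
  # (POAG + control) couples more tightly than the ischemic one, most of all
  # in the superior and inferior sectors
  poagSet <- setNames(sqrt(c(0.57, 0.18, 0.46, 0.22)), sect)
  naionSet <- setNames(sqrt(c(0.45, 0.15, 0.36, 0.16)), sect)
  list(
    groupParams = groupParams,
    sectorCorrelations = list(control = poagSet, POAG = poagSet,
                              NAION = naionSet, fellow = naionSet),
    nSubjects = c(control = 46L, NAION = 31L, fellow = 31L, POAG = 27L),
    nEyes = c(control = 77L, NAION = 31L, fellow = 31L, POAG = 42L)
  )
}

#' Build a cohort simulation specification
#'
#' @param groupParams,sectorCorrelations,nSubjects,nEyes see
#'   [cohortGroupDefaults()], whose values are the defaults. `nSubjects` and
#'   `nEyes` may be partially overridden by name. The NAION and fellow groups
#'   are paired: each NAION subject contributes one affected and one fellow
#'   eye, so their sizes track each other.
#' @param withinSubjectRho correlation of residuals between the two eyes of
#'   one subject, in \[0, 1). Sector correlation targets must satisfy
#'   `|r| <= 1 - withinSubjectRho`.
#' @param seed integer RNG seed.
#' @return a [CohortSimSpec-class] object.
#' @seealso [simulateCohort()]
#' @export
cohortSimSpec <- function(groupParams = NULL, sectorCorrelations = NULL,
                          withinSubjectRho = 0.2, nSubjects = NULL,
                          nEyes = NULL, seed = 1L) {
  def <- cohortGroupDefaults()
  if (is.null(groupParams)) groupParams <- def$groupParams
  if (is.null(sectorCorrelations)) sectorCorrelations <- def$sectorCorrelations
  ns <- def$nSubjects
  if (!is.null(nSubjects)) ns[names(nSubjects)] <- as.integer(nSubjects)
  if (!is.null(nSubjects) && "NAION" %in% names(nSubjects) &&
      !"fellow" %in% names(nSubjects)) ns["fellow"] <- ns["NAION"]
  ne <- def$nEyes
  if (!is.null(nEyes)) ne[names(nEyes)] <- as.integer(nEyes)
  ne["NAION"] <- ns["NAION"]   # one affected + one fellow eye per pair
  ne["fellow"] <- ns["fellow"]
  if (ns["NAION"] != ns["fellow"])
    stop("NAION and fellow groups are paired and must have equal sizes")
  new("CohortSimSpec", groupParams = groupParams,
      sectorCorrelations = sectorCorrelations,
      withinSubjectRho = withinSubjectRho,
      nSubjects = ns, nEyes = ne, seed = as.integer(seed))
}

.SECTOR_PCD <- c(superior = "pcd_sup_pct", nasal = "pcd_nas_pct",
                 inferior = "pcd_inf_pct", temporal = "pcd_temp_pct")
.SECTOR_RNFL <- c(superior = "rnfl_sup_um", nasal = "rnfl_nas_um",
                  inferior = "rnfl_inf_um", temporal = "rnfl_temp_um")

#' Simulate a cohort table
#'
#' Generates one row per eye with subject structure: the two eyes of a
#' subject share a subject-level latent effect in every outcome (weight
#' `sqrt(withinSubjectRho)`), NAION subjects contribute one affected and one
#' unaffected fellow eye sharing their subject effects, and within each eye
#' every sector PCD shares a latent factor with the corresponding sector RNFL
#' thickness so that their Pearson correlation converges to the requested
#' target as the group grows. Outcomes are drawn from truncated normals
#' (PCD in \[0, 100\], RNFL and axial length positive); with the default
#' group parameters the truncation mass is negligible.
#'
#' @param spec a [CohortSimSpec-class] from [cohortSimSpec()].
#' @return a `data.frame` with one row per eye and columns `subject_id`,
#'   `eye_id`, `laterality`, `group` (factor control/NAION/fellow/POAG),
#'   `age_years`, `sex` (1 = female), `axial_length_mm`, `md_db`,
#'   `rnfl_global_um`, `rnfl_{sup,nas,inf,temp}_um`, `pcd_whole_pct`,
#'   `pcd_annulus_pct`, `pcd_{sup,nas,inf,temp}_pct`.
#' @examples
#' tab <- simulateCohort(cohortSimSpec(seed = 1))
#' table(tab$group)
#' aggregate(pcd_whole_pct ~ group, tab, mean)
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSimSpec"))
  validObject(spec)
  withSeed(spec@seed, .drawCohort(spec))
}

# eps redrawn (not clamped) on truncation violations, a vectorized rejection
.truncDraw <- function(mu, sd, structural, bWeight, bounds, n) {
  val <- mu + sd * (structural + bWeight * rnorm(n))
  bad <- which(val < bounds[1] | val > bounds[2])
  tries <- 0
  while (length(bad) > 0 && tries < 50) {
    val[bad] <- mu + sd * (structural[bad] + bWeight * rnorm(length(bad)))
    bad <- bad[val[bad] < bounds[1] | val[bad] > bounds[2]]
    tries <- tries + 1
  }
  pmin(pmax(val, bounds[1]), bounds[2])
}

.outcomeBounds <- function(outc) {
  if (grepl("^pcd_", outc)) return(c(0, 100))
  if (grepl("^rnfl_", outc) || outc == "axial_length_mm") return(c(1e-6, Inf))
  c(-Inf, Inf)
}

# Outcome matrix for one block of eyes of a single group.
# u: nSubj x nOutc subject latents; subjIdx maps eyes to rows of u.
.groupOutcomes <- function(spec, grp, u, subjIdx) {
  rho <- spec@withinSubjectRho
  a <- sqrt(rho); b <- sqrt(1 - rho)
  gp <- spec@groupParams[[grp]]
  rs <- spec@sectorCorrelations[[grp]]
  outc <- names(gp$mean)
  nE <- length(subjIdx)
  L <- matrix(rnorm(nE * 4), nE, 4,
              dimnames = list(NULL, names(.SECTOR_PCD)))
  Y <- matrix(NA_real_, nE, length(outc), dimnames = list(NULL, outc))
  for (o in outc) {
    sector <- names(.SECTOR_PCD)[match(o, .SECTOR_PCD)]
    if (is.na(sector)) sector <- names(.SECTOR_RNFL)[match(o, .SECTOR_RNFL)]
    if (!is.na(sector)) {
      r <- rs[[sector]]
      cc <- sqrt(abs(r) / (1 - rho)) * ifelse(r < 0, -1, 1)
      structural <- a * u[subjIdx, o] + b * cc * L[, sector]
      bW <- b * sqrt(1 - cc^2)
    } else {
      structural <- a * u[subjIdx, o]
      bW <- b
    }
    Y[, o] <- .truncDraw(gp$mean[[o]], gp$sd[[o]], structural, bW,
                         .outcomeBounds(o), nE)
  }
  Y
}

.drawCohort <- function(spec) {
  outc <- names(spec@groupParams[[1]]$mean)
  blocks <- list()

  # paired NAION / fellow subjects share subject latents, age and sex
  nP <- spec@nSubjects[["NAION"]]
  uP <- matrix(rnorm(nP * length(outc)), nP, length(outc),
               dimnames = list(NULL, outc))
  sexP <- rbinom(nP, 1, spec@groupParams$NAION$sexFemale)
  ageP <- .truncDraw(spec@groupParams$NAION$mean[["age_years"]],
                     spec@groupParams$NAION$sd[["age_years"]],
                     rep(0, nP), 1, c(18, Inf), nP)
  latAff <- ifelse(runif(nP) < 0.5, "OD", "OS")
  subjP <- sprintf("N%04d", seq_len(nP))
  for (k in 1:2) {
    grp <- c("NAION", "fellow")[k]
    Y <- .groupOutcomes(spec, grp, uP, seq_len(nP))
    Y[, "age_years"] <- ageP
    lat <- if (k == 1) latAff else ifelse(latAff == "OD", "OS", "OD")
    blocks[[grp]] <- data.frame(
      subject_id = subjP, eye_id = paste0(subjP, "_", lat), laterality = lat,
      group = grp, sex = sexP, Y, stringsAsFactors = FALSE)
  }

  # unpaired groups: the first (nEyes - nSubjects) subjects contribute 2 eyes
  for (grp in c("control", "POAG")) {
    nS <- spec@nSubjects[[grp]]; nE <- spec@nEyes[[grp]]
    nDual <- nE - nS
    u <- matrix(rnorm(nS * length(outc)), nS, length(outc),
                dimnames = list(NULL, outc))
    sex <- rbinom(nS, 1, spec@groupParams[[grp]]$sexFemale)
    age <- .truncDraw(spec@groupParams[[grp]]$mean[["age_years"]],
                      spec@groupParams[[grp]]$sd[["age_years"]],
                      rep(0, nS), 1, c(18, Inf), nS)
    subjIdx <- c(seq_len(nS), seq_len(nDual))
    firstLat <- ifelse(runif(nS) < 0.5, "OD", "OS")
    lat <- c(firstLat, ifelse(firstLat[seq_len(nDual)] == "OD", "OS", "OD"))
    Y <- .groupOutcomes(spec, grp, u, subjIdx)
    Y[, "age_years"] <- age[subjIdx]
    subj <- sprintf("%s%04d", toupper(substr(grp, 1, 1)), subjIdx)
    blocks[[grp]] <- data.frame(
      subject_id = subj, eye_id = paste0(subj, "_", lat), laterality = lat,
      group = grp, sex = sex[subjIdx], Y, stringsAsFactors = FALSE)
  }

  tab <- do.call(rbind, blocks[c("control", "NAION", "fellow", "POAG")])
  tab$group <- factor(tab$group,
                      levels = c("control", "NAION", "fellow", "POAG"))
  rownames(tab) <- NULL
  tab[, c("subject_id", "eye_id", "laterality", "group", "age_years", "sex",
          "axial_length_mm", "md_db", "rnfl_global_um", "rnfl_sup_um",
          "rnfl_nas_um", "rnfl_inf_um", "rnfl_temp_um", "pcd_whole_pct",
          "pcd_annulus_pct", "pcd_sup_pct", "pcd_nas_pct", "pcd_inf_pct",
          "pcd_temp_pct")]
}
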