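#' Default pipeline parameters
#'
#' One list collecting every tunable of the quantification and analysis
#' stages with its default: upscale factor 6, contrast-stretch percentiles
#' 1/99, global threshold 0.55, adaptive window 15 px, vessel caliber cutoff
#' 40 um with 2 px dilation, ROI circle diameters 1.95/3.45 mm, density-map
#' window 16 px with stride 8, vessels excluded from all denominators, and
#' Bonferroni correction over the pairwise group contrasts.
#'
#' @param ... overrides by name.
#' @return named list of parameters.
#' @examples
#' pcdParams(globalT = 0.5)$globalT
#' @export
pcdParams <- function(...) {
  p <- list(
    widthMm = 4.5,
    resizeFactor = 6L,
    stretchLowPct = 1, stretchHighPct = 99,
    globalT = 0.55,
    adaptiveWindowPx = 15L,
    adaptiveOn = "binary",
    caliberCutoffUm = 40,
    vesselDilationPx = 2L,
    vesselCoreMinPx = 500L,
    innerMm = 1.95, outerMm = 3.45,
    flipNasalTemporal = FALSE,
    excludeVessels = TRUE,
    densityWindowPx = 16L, densityStridePx = 8L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown) > 0)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

.quantifyOne <- function(ang, params) {
  seg <- segmentCapillaries(ang,
    resizeFactor = params$resizeFactor, globalT = params$globalT,
    adaptiveWindowPx = params$adaptiveWindowPx,
    caliberCutoffUm = params$caliberCutoffUm,
    vesselDilationPx = params$vesselDilationPx,
    vesselCoreMinPx = params$vesselCoreMinPx,
    adaptiveOn = params$adaptiveOn,
    stretchLowPct = params$stretchLowPct,
    stretchHighPct = params$stretchHighPct)
  side <- nrow(capillaryBinary(seg))
  roi <- makeAnnulus(side, scalePxPerMm(seg),
                     center = seg@params$centerPx,
                     innerMm = params$innerMm, outerMm = params$outerMm,
                     laterality = laterality(ang),
                     flipNasalTemporal = params$flipNasalTemporal)
  res <- computePCD(seg, roi, excludeVessels = params$excludeVessels)
  dm <- densityMap(seg, params$densityWindowPx, params$densityStridePx)
  list(seg = seg, roi = roi, pcd = res, dmap = dm)
}

#' Quantify a directory of angiograms
#'
#' Runs the full per-eye pipeline (segment, ROI, densities, density map) on
#' every TIFF/PNG angiogram in `imageDir` (metadata taken from the JSON
#' sidecars written by [saveAngiogram()]), writes one CSV row per eye and a
#' color-coded density-map PNG, and returns the results table. Per-image
#' failures are logged and skipped; the call fails only if no image
#' succeeds.
#'
#' @param imageDir directory containing `.tif`/`.tiff`/`.png` angiograms.
#' @param outDir output directory (created if needed).
#' @param params list from [pcdParams()].
#' @return data.frame with one row per eye (ids, group, laterality, the six
#'   density percentages and the annulus pixel counts), invisibly; also
#'   written to `outDir/pcd_results.csv`.
#' @export
runQuantify <- function(imageDir, outDir = file.path(imageDir, "out"),
                        params = pcdParams()) {
  files <- list.files(imageDir, pattern = "\\.(tif|tiff|png)$",
                      full.names = TRUE, ignore.case = TRUE)
  if (length(files) == 0) stop("no inputs: no TIFF/PNG images in ", imageDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); failures <- character()
  for (f in files) {
    res <- tryCatch({
      ang <- loadAngiogram(f, metadata = list(widthMm = params$widthMm))
      q <- .quantifyOne(ang, params)
      png <- file.path(outDir,
                       paste0(sub("\\.[^.]+$", "", basename(f)),
                              "_density.png"))
      renderDensityMap(q$dmap, png, roi = q$roi)
      ann <- q$pcd@counts[q$pcd@counts$region == "whole_annulus", ]
      data.frame(
        file = basename(f), subject_id = ang@subjectId, eye_id = ang@eyeId,
        laterality = ang@laterality, group = ang@group,
        pcd_whole_pct = q$pcd@wholeImagePct,
        pcd_annulus_pct = q$pcd@annulusPct,
        pcd_sup_pct = q$pcd@sectorPct[["superior"]],
        pcd_nas_pct = q$pcd@sectorPct[["nasal"]],
        pcd_inf_pct = q$pcd@sectorPct[["inferior"]],
        pcd_temp_pct = q$pcd@sectorPct[["temporal"]],
        annulus_numerator = ann$numerator,
        annulus_denominator = ann$denominator,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      message("skipping ", basename(f), ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, basename(f))
    else rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0)
    stop("all ", length(files), " image(s) failed quantification")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  write.csv(out, file.path(outDir, "pcd_results.csv"), row.names = FALSE)
  if (length(failures) > 0)
    warning(length(failures), " image(s) skipped: ",
            paste(failures, collapse = ", "))
  invisible(out)
}

.SECTOR_PAIRS <- list(
  c("superior", "nasal"), c("superior", "inferior"),
  c("superior", "temporal"), c("inferior", "nasal"),
  c("inferior", "temporal"), c("temporal", "nasal"))

#' Analyse a cohort table
#'
#' The full statistics stage on a quantified cohort: covariate-adjusted
#' mixed-model group comparisons for every density outcome, within-eye
#' sector contrasts per group, univariable density-structure and density-MD
#' regressions in the pooled diagnostic sets (POAG + control, NAION +
#' fellow), and Dunn-Clark comparisons of the sector density-thickness
#' correlations. Tables are written as CSV into `outDir` when given.
#'
#' @param cohort data.frame in the [simulateCohort()] schema, or a CSV path.
#' @param outDir optional output directory for the CSV tables.
#' @param covariates adjustment covariates for the group comparisons.
#' @return list with elements `groupComparisons` (data.frame over outcomes),
#'   `sectorContrasts` (per group), `regressions` (per pooled set and
#'   sector), `correlationDifferences` (per pooled set and sector pair),
#'   invisibly.
#' @export
runAnalyze <- function(cohort, outDir = NULL,
                       covariates = c("age_years", "sex",
                                      "axial_length_mm")) {
  if (is.character(cohort)) cohort <- read.csv(cohort)
  cohort <- validateCohort(cohort)
  outcomes <- c("pcd_whole_pct", "pcd_annulus_pct", "pcd_sup_pct",
                "pcd_nas_pct", "pcd_inf_pct", "pcd_temp_pct")
  groups <- levels(droplevels(cohort$group))

  gc <- NULL
  if (length(groups) >= 2) {
    gc <- do.call(rbind, lapply(outcomes, function(o) {
      g <- compareGroups(cohort, o, covariates)
      cbind(outcome = o, g@contrasts)
    }))
  } else {
    message("single group: group comparison skipped")
  }

  sc <- do.call(rbind, lapply(groups, function(g)
    cbind(group = g, sectorContrasts(cohort, g))))

  pooled <- list(
    "POAG_control" = cohort[cohort$group %in% c("POAG", "control"), ],
    "NAION_fellow" = cohort[cohort$group %in% c("NAION", "fellow"), ])
  pooled <- Filter(function(d) nrow(d) >= 3, pooled)
  sectors <- c(superior = "sup", nasal = "nas", inferior = "inf",
               temporal = "temp")
  reg <- do.call(rbind, lapply(names(pooled), function(nm) {
    d <- pooled[[nm]]
    rows <- lapply(names(sectors), function(s) {
      fit <- univariateFit(d, paste0("pcd_", sectors[[s]], "_pct"),
                           paste0("rnfl_", sectors[[s]], "_um"))
      data.frame(set = nm, y = paste0(s, " PCD"), x = paste0(s, " RNFL"),
                 slope = fit$slope, ci_low = fit$ci[1], ci_high = fit$ci[2],
                 r = fit$r, R2 = fit$R2, p = fit$p, n = fit$n)
    })
    md <- univariateFit(d, "pcd_whole_pct", "md_db")
    rows[[length(rows) + 1]] <- data.frame(
      set = nm, y = "whole PCD", x = "MD", slope = md$slope,
      ci_low = md$ci[1], ci_high = md$ci[2], r = md$r, R2 = md$R2,
      p = md$p, n = md$n)
    do.call(rbind, rows)
  }))

  cd <- do.call(rbind, lapply(names(pooled), function(nm) {
    d <- pooled[[nm]]
    do.call(rbind, lapply(.SECTOR_PAIRS, function(pr) {
      s1 <- sectors[[pr[1]]]; s2 <- sectors[[pr[2]]]
      cmp <- compareDependentCorrelations(
        x1 = d[[paste0("pcd_", s1, "_pct")]],
        y1 = d[[paste0("rnfl_", s1, "_um")]],
        x2 = d[[paste0("pcd_", s2, "_pct")]],
        y2 = d[[paste0("rnfl_", s2, "_um")]])
      data.frame(set = nm, pair = paste(pr[1], "vs", pr[2]),
                 r1 = cmp@r1, r2 = cmp@r2, difference = cmp@difference,
                 z = cmp@z, p = cmp@p, n = cmp@n)
    }))
  }))

  out <- list(groupComparisons = gc, sectorContrasts = sc,
              regressions = reg, correlationDifferences = cd)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      if (!is.null(out[[nm]]))
        write.csv(out[[nm]], file.path(outDir, paste0(nm, ".csv")),
                  row.names = FALSE)
  }
  invisible(out)
}
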