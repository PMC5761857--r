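.COHORT_COLS <- c("subject_id", "eye_id", "laterality", "group", "age_years",
                  "sex", "axial_length_mm", "md_db", "rnfl_global_um",
                  "rnfl_sup_um", "rnfl_nas_um", "rnfl_inf_um", "rnfl_temp_um",
                  "pcd_whole_pct", "pcd_annulus_pct", "pcd_sup_pct",
                  "pcd_nas_pct", "pcd_inf_pct", "pcd_temp_pct")

#' Validate a cohort table
#'
#' Checks the column schema, the at-most-two-eyes-per-subject constraint and
#' value ranges. Returns the table (with `group` coerced to factor)
#' invisibly, or raises an error listing the violations.
#'
#' @param table a data.frame in the [simulateCohort()] schema.
#' @param requireAll require every schema column (default); otherwise only
#'   the identifier columns are mandatory.
#' @return the validated table, invisibly.
#' @export
validateCohort <- function(table, requireAll = TRUE) {
  need <- if (requireAll) .COHORT_COLS
          else c("subject_id", "eye_id", "group")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0)
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  if (any(table(table$subject_id) > 2))
    stop("a subject has more than 2 eyes")
  table$group <- factor(as.character(table$group),
                        levels = c("control", "NAION", "fellow", "POAG"))
  if (anyNA(table$group)) stop("unknown group label in cohort table")
  pcdCols <- grep("^pcd_", names(table), value = TRUE)
  for (cc in pcdCols) {
    v <- table[[cc]]
    if (any(v < 0 | v > 100, na.rm = TRUE))
      stop("PCD outside [0, 100] in column ", cc)
  }
  invisible(table)
}

#' Covariate-adjusted group comparison with inter-eye correlation
#'
#' Fits a linear mixed model `outcome ~ group + covariates` with a
#' subject-level random intercept (restricted maximum likelihood,
#' containment degrees of freedom), and reports all pairwise group contrasts
#' with Bonferroni correction over the number of pairs. With one eye per
#' subject the random intercept degenerates and the fixed effects equal the
#' ordinary least-squares fit.
#'
#' @param table cohort data.frame (see [simulateCohort()]).
#' @param outcome outcome column name, e.g. `"pcd_whole_pct"`.
#' @param covariates adjustment covariate column names; default age, sex and
#'   axial length.
#' @return a [GroupComparison-class].
#' @examples
#' tab <- simulateCohort(cohortSimSpec(seed = 3))
#' compareGroups(tab, "pcd_whole_pct")
#' @export
compareGroups <- function(table, outcome,
                          covariates = c("age_years", "sex",
                                         "axial_length_mm")) {
  table <- validateCohort(table, requireAll = FALSE)
  cols <- c(outcome, covariates, "group", "subject_id")
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0)
    stop("missing columns: ", paste(missing, collapse = ", "))
  dat <- table[complete.cases(table[, cols]), cols]
  dat$group <- droplevels(dat$group)
  if (nlevels(dat$group) < 2) stop("need >= 2 groups")
  if (any(table(dat$group) < 3)) stop("need >= 3 eyes per group")
  for (cv in covariates)
    if (var(as.numeric(dat[[cv]])) < .Machine$double.eps)
      stop("singular design: covariate '", cv, "' is constant")
  fm <- as.formula(paste(outcome, "~ group +",
                         paste(covariates, collapse = " + ")))
  fit <- nlme::lme(fm, random = ~ 1 | subject_id, data = dat,
                   method = "REML")
  em <- emmeans::emmeans(fit, "group", data = dat)
  raw <- summary(emmeans::contrast(em, method = "pairwise"),
                 adjust = "none", infer = c(TRUE, TRUE))
  nPairs <- nrow(raw)
  ct <- data.frame(
    contrast = as.character(raw$contrast),
    estimate = raw$estimate, SE = raw$SE, df = raw$df,
    lower = raw$lower.CL, upper = raw$upper.CL,
    p_raw = raw$p.value,
    p_adj = pmin(1, raw$p.value * nPairs)
  )
  gm <- as.data.frame(summary(em))
  class(gm) <- "data.frame"
  new("GroupComparison", outcome = outcome, contrasts = ct,
      covariates = covariates, groupMeans = gm,
      nObs = nrow(dat), nSubjects = length(unique(dat$subject_id)))
}

#' Within-eye sector contrasts for one group
#'
#' Compares the four sector densities within each eye of one group across
#' the six sector pairs (paired t tests on the within-eye differences),
#' Bonferroni-corrected for the six comparisons. The contrast estimate is
#' the sample mean of the within-eye differences. Eyes with a missing sector
#' value are dropped with a warning stating the count.
#'
#' @param table cohort data.frame.
#' @param group one of control/NAION/fellow/POAG.
#' @return data.frame with columns `pair`, `estimate`, `t`, `df`, `p_raw`,
#'   `p_adj`, `n`.
#' @export
sectorContrasts <- function(table, group) {
  table <- validateCohort(table, requireAll = FALSE)
  sectors <- c(superior = "pcd_sup_pct", nasal = "pcd_nas_pct",
               inferior = "pcd_inf_pct", temporal = "pcd_temp_pct")
  missing <- setdiff(sectors, names(table))
  if (length(missing) > 0)
    stop("missing sector columns: ", paste(missing, collapse = ", "))
  dat <- table[table$group == group, sectors]
  cc <- complete.cases(dat)
  if (sum(!cc) > 0)
    warning(sum(!cc), " eye(s) dropped for missing sector values")
  dat <- dat[cc, ]
  if (nrow(dat) < 2) stop("need >= 2 complete eyes in group ", group)
  prs <- utils::combn(names(sectors), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    s1 <- prs[1, i]; s2 <- prs[2, i]
    d <- dat[[sectors[s1]]] - dat[[sectors[s2]]]
    n <- length(d); m <- mean(d); s <- sd(d)
    if (s < .Machine$double.eps) {
      tstat <- 0; p <- if (abs(m) < 1e-12) 1 else 0
    } else {
      tstat <- m / (s / sqrt(n))
      p <- 2 * pt(-abs(tstat), df = n - 1)
    }
    data.frame(pair = paste(s1, "-", s2), estimate = m, t = tstat,
               df = n - 1, p_raw = p, p_adj = min(1, 6 * p), n = n)
  }))
  rownames(out) <- NULL
  out
}

#' Univariable linear regression
#'
#' Least-squares fit of `y ~ x` reporting the slope with its 95% confidence
#' interval, the coefficient of determination and the Pearson correlation
#' (which carries the slope's sign and satisfies `r^2 == R2` to machine
#' precision).
#'
#' @param table cohort data.frame (or any data.frame).
#' @param y,x column names of the dependent and independent variable.
#' @return a list with `slope`, `ci` (length 2), `r`, `R2`, `p`, `n`.
#' @examples
#' tab <- simulateCohort(cohortSimSpec(seed = 2))
#' poag <- tab[tab$group %in% c("POAG", "control"), ]
#' univariateFit(poag, "pcd_sup_pct", "rnfl_sup_um")
#' @export
univariateFit <- function(table, y, x) {
  dat <- table[complete.cases(table[, c(y, x)]), c(y, x)]
  if (nrow(dat) < 3) stop("need >= 3 complete pairs")
  if (var(dat[[x]]) < .Machine$double.eps)
    stop("zero variance in x ('", x, "')")
  fit <- lm(as.formula(paste(y, "~", x)), data = dat)
  sm <- summary(fit)
  slope <- coef(fit)[[2]]
  ci <- confint(fit)[2, ]
  R2 <- sm$r.squared
  list(slope = slope, ci = unname(ci),
       r = sign(slope) * sqrt(R2), R2 = R2,
       p = sm$coefficients[2, 4], n = nrow(dat))
}

# Dunn-Clark z for two dependent non-overlapping correlations r.jk and r.hm.
# The covariance term follows Pearson-Filon; c is the correlation between
# the two sample correlations.
.dunnClark <- function(rjk, rhm, rjh, rjm, rkh, rkm, n) {
  cv <- 0.5 * rjk * rhm * (rjh^2 + rjm^2 + rkh^2 + rkm^2) +
    rjh * rkm + rjm * rkh -
    (rjk * rjh * rjm + rjk * rkh * rkm + rhm * rjh * rkh + rhm * rjm * rkm)
  cc <- cv / ((1 - rjk^2) * (1 - rhm^2))
  z <- (atanh(rjk) - atanh(rhm)) * sqrt((n - 3) / (2 - 2 * cc))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Compare two dependent non-overlapping correlations
#'
#' Tests whether `cor(x1, y1)` differs from `cor(x2, y2)` when all four
#' variables are measured on the same eyes and the two correlations share no
#' variable (e.g. the superior PCD-RNFL correlation against the nasal one).
#' Uses Dunn and Clark's z on Fisher-transformed correlations with the
#' Pearson-Filon covariance term. Supply either the four data vectors, or
#' the correlations `r1`, `r2` with `n` and (optionally) the four
#' cross-correlations; without cross-correlations the test falls back to
#' independence (a conservative default when the dependence is positive) and
#' flags the result.
#'
#' @param x1,y1,x2,y2 numeric vectors of equal length (first interface).
#' @param r1,r2 the two correlations (second interface).
#' @param n number of paired observations.
#' @param intercor named or positional numeric vector
#'   `(r_x1x2, r_x1y2, r_y1x2, r_y1y2)`.
#' @return a [CorrelationComparison-class]. Swapping the two correlations
#'   negates `difference` and `z` and leaves `p` unchanged.
#' @examples
#' r <- compareDependentCorrelations(r1 = sqrt(0.57), r2 = sqrt(0.18),
#'                                   n = 119)
#' round(r@difference, 2)
#' @export
compareDependentCorrelations <- function(x1 = NULL, y1 = NULL, x2 = NULL,
                                         y2 = NULL, r1 = NULL, r2 = NULL,
                                         n = NULL, intercor = NULL) {
  if (!is.null(x1)) {
    stopifnot(!is.null(y1), !is.null(x2), !is.null(y2))
    cc <- complete.cases(cbind(x1, y1, x2, y2))
    x1 <- x1[cc]; y1 <- y1[cc]; x2 <- x2[cc]; y2 <- y2[cc]
    n <- length(x1)
    if (n <= 3) stop("need n > 3")
    r1 <- cor(x1, y1); r2 <- cor(x2, y2)
    intercor <- c(r_x1x2 = cor(x1, x2), r_x1y2 = cor(x1, y2),
                  r_y1x2 = cor(y1, x2), r_y1y2 = cor(y1, y2))
  } else {
    stopifnot(!is.null(r1), !is.null(r2), !is.null(n))
    if (n <= 3) stop("need n > 3")
  }
  conservative <- is.null(intercor)
  if (conservative) {
    ic <- c(r_x1x2 = 0, r_x1y2 = 0, r_y1x2 = 0, r_y1y2 = 0)
  } else {
    ic <- intercor
    if (is.null(names(ic)))
      names(ic) <- c("r_x1x2", "r_x1y2", "r_y1x2", "r_y1y2")
    # full 4x4 correlation matrix (x1, y1, x2, y2) must be admissible
    R <- diag(4)
    R[1, 2] <- R[2, 1] <- r1
    R[3, 4] <- R[4, 3] <- r2
    R[1, 3] <- R[3, 1] <- ic[["r_x1x2"]]
    R[1, 4] <- R[4, 1] <- ic[["r_x1y2"]]
    R[2, 3] <- R[3, 2] <- ic[["r_y1x2"]]
    R[2, 4] <- R[4, 2] <- ic[["r_y1y2"]]
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("intercorrelations do not form a positive semidefinite matrix")
  }
  dc <- .dunnClark(r1, r2, ic[["r_x1x2"]], ic[["r_x1y2"]], ic[["r_y1x2"]],
                   ic[["r_y1y2"]], n)
  new("CorrelationComparison", r1 = r1, r2 = r2, difference = r1 - r2,
      n = as.integer(n), intercor = if (conservative)
        c(r_x1x2 = NA_real_, r_x1y2 = NA_real_, r_y1x2 = NA_real_,
          r_y1y2 = NA_real_) else ic,
      z = dc$z, p = dc$p, conservative = conservative)
}
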