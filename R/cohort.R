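#' @importFrom lme4 VarCorr
#' @importFrom lmerTest lmer
#' @importFrom emmeans emmeans contrast
NULL

ME_LOCI <- c("BOLA3", "FLJ20433", "PAX8", "SLITRK1", "ZFYVE28")
CONTROL_LOCI <- c("LINE1", "IGF2", "GNASAS", "IL10")

#' Arcsine square-root transform of percent methylation
#'
#' The variance-stabilizing transform for proportions:
#' `asin(sqrt(p / 100))`, in radians on `[0, pi/2]`.
#'
#' @param percent Percent methylation in `[0, 100]`.
#' @return Transformed values.
#' @seealso [invArcsineTransform()]
#' @export
arcsineTransform <- function(percent) {
  if (any(is.na(percent))) stop("NA percent methylation")
  if (any(percent < 0 | percent > 100))
    stop("percent methylation must lie in [0, 100]")
  asin(sqrt(percent / 100))
}

#' Inverse of the arcsine square-root transform
#'
#' @param x Values on the arcsine scale, `[0, pi/2]`.
#' @return Percent methylation in `[0, 100]`.
#' @export
invArcsineTransform <- function(x) 100 * sin(x)^2

.checkCohort <- function(records) {
  need <- c("individual_id", "season", "locus", "locus_type",
            "mean_methylation")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort records missing column(s): ", paste(miss, collapse = ", "))
  if (!all(records$season %in% c("rainy", "dry")))
    stop("season must be 'rainy' or 'dry'")
  if (!all(records$locus_type %in% c("ME", "control")))
    stop("locus_type must be 'ME' or 'control'")
  bad <- unique(records$locus[ave(as.integer(factor(records$locus_type)),
                                  records$locus, FUN = function(x)
                                    length(unique(x))) > 1])
  if (length(bad))
    stop("locus_type not constant within locus: ",
         paste(bad, collapse = ", "))
  invisible(records)
}

#' Shapiro-Wilk normality screen per locus-by-season group
#'
#' Tests each locus x season cell for normality and applies Holm's
#' step-down (sequential Bonferroni) correction across the family of tests.
#' Groups with fewer than 3 observations are skipped with a warning.
#'
#' @param records Cohort data.frame (see [fitSeasonModel()]); tested on the
#'   arcsine scale when `transform = TRUE` (default).
#' @param alpha Family-wise error level for the Holm decisions.
#' @param transform Apply [arcsineTransform()] before testing.
#' @return data.frame `locus season n w p_value p_holm reject`.
#' @export
normalityScreen <- function(records, alpha = 0.05, transform = TRUE) {
  .checkCohort(records)
  y <- if (transform) arcsineTransform(records$mean_methylation) else
    records$mean_methylation
  groups <- split(y, list(records$locus, records$season), drop = TRUE)
  keys <- strsplit(names(groups), ".", fixed = TRUE)
  small <- vapply(groups, length, 1L) < 3
  if (any(small))
    warning(sum(small), " group(s) with < 3 observations skipped")
  groups <- groups[!small]; keys <- keys[!small]
  res <- data.frame(
    locus = vapply(keys, `[`, "", 1L),
    season = vapply(keys, `[`, "", 2L),
    n = vapply(groups, length, 1L),
    w = vapply(groups, function(g) unname(shapiro.test(g)$statistic), 1),
    p_value = vapply(groups, function(g) shapiro.test(g)$p.value, 1),
    row.names = NULL
  )
  res$p_holm <- p.adjust(res$p_value, method = "holm")
  res$reject <- res$p_holm < alpha
  res
}

.fitLmer <- function(formula, data) {
  fit <- suppressMessages(lmerTest::lmer(formula, data = data, REML = TRUE))
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0)
    stop("REML fit did not converge (optimizer code ", conv, "): ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  fit
}

#' Fit the season-of-conception variance-components model
#'
#' REML linear mixed model for arcsine-transformed percent methylation with
#' random intercepts for individual and for locus (nested within locus
#' type), and fixed effects for season, locus type, and their interaction.
#' The season effect is reported separately within ME and within control
#' loci (estimated marginal means contrast, Satterthwaite degrees of
#' freedom), both on the arcsine scale and back-transformed to percentage
#' points (rainy minus dry). A per-locus table of season group means,
#' back-transformed mean differences and Welch t P values is also returned
#' (the per-locus view of the seasonal increments).
#'
#' @param records data.frame with columns `individual_id season locus
#'   locus_type mean_methylation` (percent scale, replicate-averaged).
#' @return A [SeasonModelFit-class].
#' @export
fitSeasonModel <- function(records) {
  .checkCohort(records)
  for (type in c("ME", "control")) {
    sub <- records[records$locus_type == type, ]
    if (length(unique(sub$locus)) < 2)
      stop("need >= 2 loci of type ", type)
  }
  if (any(table(unique(records[, c("individual_id", "season")])$season) < 2))
    stop("need >= 2 individuals per season")
  d <- data.frame(
    y = arcsineTransform(records$mean_methylation),
    season = factor(records$season, levels = c("dry", "rainy")),
    locus_type = factor(records$locus_type, levels = c("control", "ME")),
    locus = factor(records$locus),
    individual = factor(records$individual_id)
  )
  fit <- .fitLmer(y ~ season * locus_type + (1 | individual) + (1 | locus), d)
  an <- anova(fit)  # Satterthwaite type III
  tests <- list(season = an["season", "Pr(>F)"],
                season_by_type = an["season:locus_type", "Pr(>F)"])
  emm <- emmeans(fit, ~ season | locus_type, lmer.df = "satterthwaite")
  ctr <- as.data.frame(contrast(emm, method = list(rainy_vs_dry = c(-1, 1))))
  emmDf <- as.data.frame(emm)
  bt <- function(type, seas)
    invArcsineTransform(emmDf$emmean[emmDf$locus_type == type &
                                       emmDf$season == seas])
  typeEffects <- data.frame(
    locus_type = ctr$locus_type,
    estimate_arcsine = ctr$estimate,
    se_arcsine = ctr$SE,
    effect_pp = vapply(as.character(ctr$locus_type),
                       function(t) bt(t, "rainy") - bt(t, "dry"), 1),
    p_value = ctr$p.value,
    stringsAsFactors = FALSE
  )
  dt <- as.data.table(d)
  dt$raw <- records$mean_methylation
  perLocus <- dt[, {
    yr <- y[season == "rainy"]; yd <- y[season == "dry"]
    p <- if (length(yr) >= 2 && length(yd) >= 2)
      tryCatch(t.test(yr, yd)$p.value, error = function(e) NA_real_)
    else NA_real_
    .(locus_type = as.character(locus_type[1]),
      mean_dry_pp = mean(raw[season == "dry"]),
      mean_rainy_pp = mean(raw[season == "rainy"]),
      effect_pp = invArcsineTransform(mean(yr)) - invArcsineTransform(mean(yd)),
      p_value = p)
  }, by = locus]
  setDF(perLocus)
  vc <- as.data.frame(VarCorr(fit))
  # delta-method conversion to percentage points at the grand mean:
  # d(100 sin^2 theta)/d theta = 100 sin(2 theta)
  theta0 <- mean(d$y)
  varianceComponents <- data.frame(component = vc$grp, sd = vc$sdcor,
                                   sd_pp = vc$sdcor * 100 * sin(2 * theta0))
  new("SeasonModelFit", model = fit, typeEffects = typeEffects,
      locusEffects = perLocus, tests = tests,
      varianceComponents = varianceComponents)
}

#' Screen for a season-by-year interaction
#'
#' Augments the season model with year and season x year fixed terms and
#' reports the interaction P, plus a leave-one-year-out table identifying
#' the year whose removal maximizes the interaction P (the year driving any
#' inconsistency of the seasonal effect).
#'
#' @param records Cohort data.frame including `year_of_conception`.
#' @return List `interaction_p`, `leave_one_out` (data.frame `year_dropped
#'   interaction_p`), `recommended_exclusion`, `incomplete_years` (years
#'   missing a season, flagged rather than dropped).
#' @export
interactionScreen <- function(records) {
  .checkCohort(records)
  if (!"year_of_conception" %in% names(records))
    stop("records must include year_of_conception")
  years <- sort(unique(records$year_of_conception))
  if (length(years) < 2) stop("need >= 2 years of conception")
  if (length(unique(records$season)) < 2) stop("need both seasons present")
  seasonsByYear <- tapply(records$season, records$year_of_conception,
                          function(s) length(unique(s)))
  incomplete <- as.integer(names(seasonsByYear)[seasonsByYear < 2])
  interP <- function(recs) {
    d <- data.frame(
      y = arcsineTransform(recs$mean_methylation),
      season = factor(recs$season, levels = c("dry", "rainy")),
      locus_type = factor(recs$locus_type, levels = c("control", "ME")),
      year = factor(recs$year_of_conception),
      locus = factor(recs$locus),
      individual = factor(recs$individual_id)
    )
    fit <- .fitLmer(
      y ~ season * locus_type + year + season:year +
        (1 | individual) + (1 | locus), d)
    anova(fit)["season:year", "Pr(>F)"]
  }
  overall <- interP(records)
  loo <- data.frame(year_dropped = years, interaction_p = NA_real_)
  for (i in seq_along(years)) {
    sub <- records[records$year_of_conception != years[i], ]
    if (length(unique(sub$year_of_conception)) < 2) next
    loo$interaction_p[i] <- interP(sub)
  }
  best <- loo$year_dropped[which.max(loo$interaction_p)]
  list(interaction_p = overall, leave_one_out = loo,
       recommended_exclusion = best, incomplete_years = incomplete)
}
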