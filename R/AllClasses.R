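#' @import methods
#' @importFrom stats aggregate anova aov ave binom.test chisq.test coef cor
#'   cor.test lm median p.adjust pnorm pt qnorm quantile rbeta rbinom rchisq
#'   rlnorm rnorm rpois runif sd setNames shapiro.test t.test var
#' @importFrom utils head read.delim write.table
NULL

#' Configuration for the in-silico SmaI/XmaI digest
#'
#' Holds the informative-length bounds for restriction intervals. Fragments
#' outside `[minLen, maxLen]` (bounds inclusive) are dropped as
#' uninformative for the microarray screen.
#'
#' @slot minLen Minimum fragment length in bp (default 60).
#' @slot maxLen Maximum fragment length in bp (default 1500).
#' @export
setClass("DigestConfig",
  representation(minLen = "numeric", maxLen = "numeric"),
  prototype(minLen = 60, maxLen = 1500)
)

setValidity("DigestConfig", function(object) {
  if (length(object@minLen) != 1L || length(object@maxLen) != 1L)
    return("minLen and maxLen must be scalars")
  if (is.na(object@minLen) || is.na(object@maxLen))
    return("minLen and maxLen must not be NA")
  if (object@minLen <= 0)
    return("minLen must be positive")
  if (object@minLen > object@maxLen)
    return("minLen must not exceed maxLen")
  TRUE
})

#' Construct a DigestConfig
#'
#' @param minLen,maxLen Informative fragment length bounds in bp, inclusive.
#' @return A [DigestConfig-class] object.
#' @examples
#' DigestConfig()           # the 60-1500 bp screen defaults
#' DigestConfig(100, 1000)
#' @export
DigestConfig <- function(minLen = 60, maxLen = 1500) {
  new("DigestConfig", minLen = as.numeric(minLen), maxLen = as.numeric(maxLen))
}

setMethod("show", "DigestConfig", function(object) {
  cat("DigestConfig: informative interval length", object@minLen, "-",
      object@maxLen, "bp (inclusive)\n")
})

#' Configuration for the two-tissue MSAM candidate screen
#'
#' Thresholds for per-comparison candidate calling and the between-tissue
#' ratio-of-ratios concordance filter. All comparisons are strict
#' inequalities; values exactly on a bound fail.
#'
#' @slot ratioHi Upper mean signal-ratio threshold (default 1.8).
#' @slot ratioLo Lower mean signal-ratio threshold (default 0.556, the
#'   reciprocal of 1.8 to three significant figures).
#' @slot pMax Median per-probe P threshold (default 2e-4).
#' @slot rrHi Upper ratio-of-ratios (PBL:HF) concordance bound (default 2.25,
#'   corresponding to ratios of 1.5 and 0.667 in the two tissues).
#' @slot rrLo Lower concordance bound (default 0.445).
#' @slot rrDigits Significant digits at which the ratio of ratios is rounded
#'   before comparing against the bounds (default 3, so 1.5/0.667 rounds to
#'   2.25 and is excluded).
#' @slot geometricMean Summarise probe ratios by geometric rather than
#'   arithmetic mean (default FALSE).
#' @export
setClass("ScreenConfig",
  representation(ratioHi = "numeric", ratioLo = "numeric", pMax = "numeric",
                 rrHi = "numeric", rrLo = "numeric", rrDigits = "numeric",
                 geometricMean = "logical"),
  prototype(ratioHi = 1.8, ratioLo = 0.556, pMax = 2e-4,
            rrHi = 2.25, rrLo = 0.445, rrDigits = 3, geometricMean = FALSE)
)

setValidity("ScreenConfig", function(object) {
  if (!(object@ratioLo < 1 && 1 < object@ratioHi))
    return("need ratioLo < 1 < ratioHi")
  if (!(object@rrLo < 1 && 1 < object@rrHi))
    return("need rrLo < 1 < rrHi")
  if (!(object@pMax > 0 && object@pMax <= 1))
    return("pMax must be in (0, 1]")
  TRUE
})

#' Construct a ScreenConfig
#'
#' @param ratioHi,ratioLo Mean signal-ratio thresholds (a candidate must be
#'   above `ratioHi` or below `ratioLo` in both tissues, same side).
#' @param pMax Median probe-level P threshold.
#' @param rrHi,rrLo Bounds on the PBL:HF ratio of ratios for the
#'   concordance filter.
#' @param rrDigits Significant digits for the ratio of ratios before the
#'   bound comparison.
#' @param geometricMean Use the geometric mean of probe ratios.
#' @return A [ScreenConfig-class] object.
#' @examples
#' ScreenConfig()
#' @export
ScreenConfig <- function(ratioHi = 1.8, ratioLo = 0.556, pMax = 2e-4,
                         rrHi = 2.25, rrLo = 0.445, rrDigits = 3,
                         geometricMean = FALSE) {
  new("ScreenConfig", ratioHi = ratioHi, ratioLo = ratioLo, pMax = pMax,
      rrHi = rrHi, rrLo = rrLo, rrDigits = rrDigits,
      geometricMean = geometricMean)
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig\n")
  cat("  primary hit: mean ratio >", object@ratioHi, "or <", object@ratioLo,
      "and median P <", object@pMax, "in both tissues (same side)\n")
  cat("  concordance: ratio of ratios in (", object@rrLo, ",", object@rrHi,
      ") for all comparisons (rounded to", object@rrDigits, "sig. digits)\n")
})

#' Result of the two-tissue MSAM screen
#'
#' @slot candidates data.frame of surviving candidate MEs (one row per
#'   interval: id, direction, triggering comparisons).
#' @slot hits data.frame of primary per-comparison hits before the
#'   concordance filter.
#' @slot ratioOfRatios data.frame of PBL:HF ratio-of-ratios per interval and
#'   comparison for all primary hits.
#' @slot classSummary Named integer vector counting invariant,
#'   tissue-specific and systemic intervals (Table-S1-style summary).
#' @slot stats data.frame of per interval x comparison x tissue summary
#'   statistics (the full audit trail).
#' @slot config The [ScreenConfig-class] used.
#' @export
setClass("ScreenResult",
  representation(candidates = "data.frame", hits = "data.frame",
                 ratioOfRatios = "data.frame", classSummary = "integer",
                 stats = "data.frame", config = "ScreenConfig")
)

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult:", nrow(object@candidates), "candidate ME interval(s)\n")
  cat("  primary hits before concordance filter:",
      length(unique(object@hits$interval_id)), "\n")
  cat("  interval classes:",
      paste(names(object@classSummary), object@classSummary,
            sep = "=", collapse = ", "), "\n")
})

#' @describeIn ScreenResult-class Candidate table accessor.
#' @param x A `ScreenResult`.
#' @export
candidates <- function(x) {
  stopifnot(is(x, "ScreenResult"))
  x@candidates
}

#' @describeIn ScreenResult-class Interval class summary (invariant /
#'   tissue-specific / systemic counts).
#' @export
classSummary <- function(x) {
  stopifnot(is(x, "ScreenResult"))
  x@classSummary
}

#' Result of the SNP/CNV exclusion cascade
#'
#' @slot stages data.frame with one row per cascade stage: stage name,
#'   removed count, remaining count.
#' @slot surviving Character vector of interval ids after the cascade
#'   (including any re-added retained loci).
#' @slot removedSnp,removedStructural Character vectors of removed ids.
#' @slot retainedBack Ids removed by a stage but re-added via the allow-list.
#' @export
setClass("CascadeResult",
  representation(stages = "data.frame", surviving = "character",
                 removedSnp = "character", removedStructural = "character",
                 retainedBack = "character")
)

setMethod("show", "CascadeResult", function(object) {
  cat("Candidate exclusion cascade\n")
  for (i in seq_len(nrow(object@stages))) {
    cat(sprintf("  %-22s removed %3d -> %3d remain\n",
                object@stages$stage[i], object@stages$removed[i],
                object@stages$remaining[i]))
  }
  cat("  final:", length(object@surviving), "candidate(s)\n")
})

#' @describeIn CascadeResult-class Surviving candidate ids.
#' @param x A `CascadeResult`.
#' @export
surviving <- function(x) {
  stopifnot(is(x, "CascadeResult"))
  x@surviving
}

#' Fitted season-of-conception variance-components model
#'
#' @slot model The underlying `lmerModLmerTest` REML fit (arcsine scale).
#' @slot typeEffects data.frame of the season effect within each locus type
#'   (ME, control): estimate on the arcsine scale, back-transformed
#'   percentage-point difference (rainy minus dry), and P value.
#' @slot locusEffects data.frame of per-locus season means and
#'   back-transformed mean differences with per-locus Welch t P values.
#' @slot tests Named list of overall P values: `season`, `season_by_type`.
#' @slot varianceComponents data.frame of estimated random-effect and
#'   residual standard deviations (arcsine scale).
#' @export
setClass("SeasonModelFit",
  representation(model = "ANY", typeEffects = "data.frame",
                 locusEffects = "data.frame", tests = "list",
                 varianceComponents = "data.frame")
)

setMethod("show", "SeasonModelFit", function(object) {
  cat("Season-of-conception REML model (arcsine-transformed % methylation)\n")
  cat(sprintf("  overall season P = %.4g; season x locus-type P = %.4g\n",
              object@tests$season, object@tests$season_by_type))
  for (i in seq_len(nrow(object@typeEffects))) {
    cat(sprintf("  %s loci: rainy - dry = %+.2f pct points (P = %.4g)\n",
                object@typeEffects$locus_type[i],
                object@typeEffects$effect_pp[i],
                object@typeEffects$p_value[i]))
  }
})

#' @describeIn SeasonModelFit-class Within-type season effects.
#' @param x A `SeasonModelFit`.
#' @export
seasonEffects <- function(x) {
  stopifnot(is(x, "SeasonModelFit"))
  x@typeEffects
}

#' @describeIn SeasonModelFit-class Per-locus season means and
#'   back-transformed differences.
#' @export
locusEffects <- function(x) {
  stopifnot(is(x, "SeasonModelFit"))
  x@locusEffects
}

#' @describeIn SeasonModelFit-class Random-effect / residual standard
#'   deviations.
#' @export
varianceComponents <- function(x) {
  stopifnot(is(x, "SeasonModelFit"))
  x@varianceComponents
}
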