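#' @import data.table
NULL

.checkProbeTable <- function(probes) {
  need <- c("probe_id", "interval_id", "comparison_id", "tissue", "ratio",
            "p_value")
  miss <- setdiff(need, names(probes))
  if (length(miss))
    stop("probe table missing column(s): ", paste(miss, collapse = ", "))
  if (any(probes$ratio <= 0)) stop("probe ratios must be positive")
  if (any(probes$p_value <= 0 | probes$p_value > 1))
    stop("probe p-values must lie in (0, 1]")
  invisible(probes)
}

.checkDesign <- function(design) {
  need <- c("comparison_id", "tissue", "dye_swapped")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design[, c("comparison_id", "tissue")]))
    stop("duplicated hybridization (comparison x tissue) in design")
  invisible(design)
}

#' Harmonize probe ratio orientation across dye swaps
#'
#' Re-expresses every probe ratio as individual 1 / individual 2 regardless
#' of dye assignment: ratios from dye-swapped hybridizations are inverted,
#' others pass through. Applying the operation twice returns the input.
#'
#' @param probes data.frame with columns `probe_id interval_id comparison_id
#'   tissue ratio p_value`.
#' @param design data.frame with one row per hybridization: `comparison_id
#'   tissue dye_swapped` (plus optional `individual_1`, `individual_2`).
#' @return The probe table with harmonized `ratio`.
#' @export
orientRatios <- function(probes, design) {
  .checkProbeTable(probes)
  .checkDesign(design)
  key <- paste(probes$comparison_id, probes$tissue)
  dkey <- paste(design$comparison_id, design$tissue)
  idx <- match(key, dkey)
  if (anyNA(idx)) {
    stop("probe(s) reference hybridization(s) absent from design: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  swap <- design$dye_swapped[idx]
  probes$ratio <- ifelse(swap, 1 / probes$ratio, probes$ratio)
  probes
}

#' Summarize probe measurements per interval, comparison and tissue
#'
#' Computes the interval-level statistics the screen operates on: mean and
#' median of the linear probe signal ratios, median probe P value, and the
#' probe count. Intervals with no probes are simply absent.
#'
#' @param probes Harmonized probe table (see [orientRatios()]).
#' @param geometricMean Summarise ratios by geometric mean instead of the
#'   default arithmetic mean.
#' @return data.frame `interval_id comparison_id tissue mean_ratio
#'   median_ratio median_p n_probes`.
#' @export
summarizeIntervals <- function(probes, geometricMean = FALSE) {
  .checkProbeTable(probes)
  dt <- as.data.table(probes)
  stats <- dt[, .(
    mean_ratio = if (geometricMean) exp(mean(log(ratio))) else mean(ratio),
    median_ratio = median(ratio),
    median_p = median(p_value),
    n_probes = .N
  ), by = .(interval_id, comparison_id, tissue)]
  setDF(stats)
  stats
}

#' Call primary per-comparison hits
#'
#' An interval is a primary hit for a comparison when, in both tissues, the
#' mean signal ratio exceeds `ratioHi` or falls below `ratioLo` (strictly,
#' and on the same side of 1 in both tissues) and the median probe P is
#' strictly below `pMax`. Intervals measured in only one tissue of a
#' comparison are not callable and are skipped.
#'
#' @param stats Summary table from [summarizeIntervals()].
#' @param config A [ScreenConfig-class].
#' @return data.frame `interval_id comparison_id direction` of hits.
#' @export
callPrimaryHits <- function(stats, config = ScreenConfig()) {
  validObject(config)
  dt <- as.data.table(stats)
  wide <- dcast(dt, interval_id + comparison_id ~ tissue,
                value.var = c("mean_ratio", "median_p"))
  if (!all(c("mean_ratio_PBL", "mean_ratio_HF") %in% names(wide)))
    stop("stats must contain both PBL and HF tissues")
  ok <- !is.na(wide$mean_ratio_PBL) & !is.na(wide$mean_ratio_HF)
  w <- wide[ok]
  up <- w$mean_ratio_PBL > config@ratioHi & w$mean_ratio_HF > config@ratioHi
  down <- w$mean_ratio_PBL < config@ratioLo & w$mean_ratio_HF < config@ratioLo
  sig <- w$median_p_PBL < config@pMax & w$median_p_HF < config@pMax
  hit <- (up | down) & sig
  data.frame(interval_id = w$interval_id[hit],
             comparison_id = w$comparison_id[hit],
             direction = ifelse(up[hit], "up", "down"),
             stringsAsFactors = FALSE)
}

#' Ratio-of-ratios concordance filter
#'
#' A primary hit survives only if, for every comparison, the PBL:HF ratio of
#' mean signal ratios lies strictly inside `(rrLo, rrHi)` after rounding to
#' `rrDigits` significant digits (so a 1.5 vs 0.667 tissue pair, ratio of
#' ratios 2.25, is excluded). Hits missing any comparison or tissue are
#' dropped with a message.
#'
#' @param hits Primary hit table from [callPrimaryHits()].
#' @param stats Full summary table from [summarizeIntervals()].
#' @param config A [ScreenConfig-class].
#' @param comparisons The comparisons every hit must satisfy (default: all
#'   comparisons present in `stats`; [runScreen()] passes the design's).
#' @return List with `candidates` (data.frame `interval_id direction
#'   triggering_comparisons`) and `ratioOfRatios` (long data.frame of the
#'   per-comparison values for every primary-hit interval).
#' @export
concordanceFilter <- function(hits, stats, config = ScreenConfig(),
                              comparisons = NULL) {
  validObject(config)
  if (is.null(comparisons))
    comparisons <- sort(unique(stats$comparison_id))
  dt <- as.data.table(stats)
  wide <- dcast(dt, interval_id + comparison_id ~ tissue,
                value.var = "mean_ratio")
  wide <- wide[wide$interval_id %in% unique(hits$interval_id)]
  wide$rr <- signif(wide$PBL / wide$HF, config@rrDigits)
  rrTab <- as.data.frame(wide[, .(interval_id, comparison_id,
                                  ratio_of_ratios = rr)])
  byInt <- split(wide, wide$interval_id)
  pass <- vapply(byInt, function(w) {
    if (!setequal(w$comparison_id, comparisons) || anyNA(w$rr)) return(FALSE)
    all(w$rr > config@rrLo & w$rr < config@rrHi)
  }, TRUE)
  incomplete <- names(byInt)[vapply(byInt, function(w)
    !setequal(w$comparison_id, comparisons) || anyNA(w$rr), TRUE)]
  if (length(incomplete))
    message(length(incomplete),
            " hit interval(s) dropped: missing comparison/tissue data")
  keep <- names(byInt)[pass]
  hits <- hits[hits$interval_id %in% keep, , drop = FALSE]
  if (nrow(hits)) {
    agg <- aggregate(comparison_id ~ interval_id + direction, data = hits,
                     FUN = function(x) paste(sort(unique(x)), collapse = ","))
    candidates <- data.frame(interval_id = agg$interval_id,
                             direction = agg$direction,
                             triggering_comparisons = agg$comparison_id,
                             stringsAsFactors = FALSE)
    candidates <- candidates[order(candidates$interval_id), , drop = FALSE]
    rownames(candidates) <- NULL
  } else {
    candidates <- data.frame(interval_id = character(),
                             direction = character(),
                             triggering_comparisons = character())
  }
  list(candidates = candidates, ratioOfRatios = rrTab)
}

.classifyIntervals <- function(stats, config) {
  dt <- as.data.table(stats)
  wide <- dcast(dt, interval_id + comparison_id ~ tissue,
                value.var = c("mean_ratio", "median_p"))
  passTissue <- function(r, p) {
    !is.na(r) & !is.na(p) & (r > config@ratioHi | r < config@ratioLo) &
      p < config@pMax
  }
  pbl <- passTissue(wide$mean_ratio_PBL, wide$median_p_PBL)
  hf <- passTissue(wide$mean_ratio_HF, wide$median_p_HF)
  sameSide <- (wide$mean_ratio_PBL > 1) == (wide$mean_ratio_HF > 1)
  systemic <- pbl & hf & sameSide
  single <- xor(pbl, hf)
  dtc <- data.table(interval_id = wide$interval_id, systemic = systemic,
                    single = single)
  cls <- dtc[, .(systemic = any(systemic), single = any(single)),
             by = interval_id]
  c(invariant = sum(!cls$systemic & !cls$single),
    tissue_specific = sum(!cls$systemic & cls$single),
    systemic = sum(cls$systemic))
}

#' Run the full two-tissue MSAM candidate screen
#'
#' Validates inputs, harmonizes dye orientation, summarizes probes per
#' interval, calls primary hits per comparison, applies the ratio-of-ratios
#' concordance filter, and tabulates interval classes (invariant /
#' tissue-specific / systemic).
#'
#' @param probes Probe table `probe_id interval_id comparison_id tissue
#'   ratio p_value` (ratios in dye orientation as hybridized).
#' @param design Hybridization design `comparison_id tissue dye_swapped`.
#' @param config A [ScreenConfig-class].
#' @return A [ScreenResult-class].
#' @export
runScreen <- function(probes, design, config = ScreenConfig()) {
  .checkProbeTable(probes)
  .checkDesign(design)
  if (!all(unique(probes$tissue) %in% design$tissue) ||
      !all(unique(probes$comparison_id) %in% design$comparison_id))
    stop("probe table references comparisons/tissues absent from design")
  oriented <- orientRatios(probes, design)
  stats <- summarizeIntervals(oriented, geometricMean = config@geometricMean)
  hits <- callPrimaryHits(stats, config)
  conc <- concordanceFilter(hits, stats, config,
                            comparisons = unique(design$comparison_id))
  new("ScreenResult",
      candidates = conc$candidates,
      hits = hits,
      ratioOfRatios = conc$ratioOfRatios,
      classSummary = .classifyIntervals(stats, config),
      stats = stats,
      config = config)
}
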