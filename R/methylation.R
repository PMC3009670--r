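.avgReplicates <- function(measurements, by) {
  dt <- as.data.table(measurements)
  out <- dt[, .(percent = mean(percent_methylation)), by = by]
  setDF(out)
  out
}

#' Assay linearity against methylation standards
#'
#' Least-squares line of measured percent methylation on the expected
#' methylated fraction of mixed standards, verifying quantitative assay
#' performance.
#'
#' @param standards data.frame with columns `expected_fraction` (0-1) and
#'   `measured_percent` (0-100).
#' @return List `slope`, `intercept`, `r` (Pearson correlation; `NA` with a
#'   warning when the measured values are constant).
#' @export
assayLinearity <- function(standards) {
  stopifnot(all(c("expected_fraction", "measured_percent") %in%
                  names(standards)))
  if (length(unique(standards$expected_fraction)) < 3)
    stop("need standards at >= 3 distinct expected fractions")
  if (any(standards$expected_fraction < 0 | standards$expected_fraction > 1))
    stop("expected_fraction must lie in [0, 1]")
  fit <- lm(measured_percent ~ expected_fraction, data = standards)
  r <- if (sd(standards$measured_percent) == 0) {
    warning("measured values constant; correlation undefined")
    NA_real_
  } else {
    cor(standards$expected_fraction, standards$measured_percent)
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]), r = r)
}

#' Inter-tissue correlation of interindividual methylation variation
#'
#' Averages replicates per individual and tissue, then correlates
#' individual means between the two tissues at one locus (Pearson, two-sided
#' P).
#'
#' @param measurements data.frame with columns `sample_id tissue locus
#'   percent_methylation` (plus anything else, e.g. `replicate_id`).
#' @param locus Locus name.
#' @param tissues Character vector of the two tissues to correlate.
#' @return List `r`, `p_value`, `n`, and logical `degenerate` flagging a
#'   zero-variance tissue (in which case `r` is `NA`).
#' @export
interTissueCorrelation <- function(measurements, locus,
                                   tissues = c("PBL", "HF")) {
  stopifnot(length(tissues) == 2)
  m <- measurements[measurements$locus == locus &
                      measurements$tissue %in% tissues, ]
  avg <- .avgReplicates(m, by = c("sample_id", "tissue"))
  x <- avg[avg$tissue == tissues[1], ]
  y <- avg[avg$tissue == tissues[2], ]
  common <- intersect(x$sample_id, y$sample_id)
  if (length(common) < 3)
    stop("need >= 3 individuals measured in both tissues (got ",
         length(common), ")")
  xv <- x$percent[match(common, x$sample_id)]
  yv <- y$percent[match(common, y$sample_id)]
  if (sd(xv) == 0 || sd(yv) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(common),
                degenerate = TRUE))
  }
  ct <- cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(common),
       degenerate = FALSE)
}

#' Monozygotic-twin concordance versus technical error
#'
#' Correlates methylation within twin pairs (member order randomized under
#' a seeded convention, or double-entered) and between independent
#' technical replicate measurements, and reports the nonshared variance
#' fraction, defined as `1 - intra-pair r` clipped to `[0, 1]`.
#'
#' @param pairMeasurements data.frame `pair_id member percent_methylation`
#'   (replicates, if present, are averaged per member first; a `locus`
#'   column restricts via `locus`). Twins without a partner are excluded
#'   with a message.
#' @param replicateMeasurements data.frame `sample_id replicate_id
#'   percent_methylation`; the first two replicates per sample form a
#'   technical pair.
#' @param locus Optional locus to restrict both tables to.
#' @param seed Seed for the random member ordering.
#' @param method `"random"` (default) or `"double_entry"` (each pair
#'   entered both ways).
#' @return List `intra_pair_r`, `technical_r`, `nonshared_fraction`,
#'   `n_pairs`, `n_replicate_pairs`.
#' @export
twinConcordance <- function(pairMeasurements, replicateMeasurements,
                            locus = NULL, seed = 1,
                            method = c("random", "double_entry")) {
  method <- match.arg(method)
  pm <- pairMeasurements
  rm_ <- replicateMeasurements
  if (!is.null(locus)) {
    if ("locus" %in% names(pm)) pm <- pm[pm$locus == locus, ]
    if ("locus" %in% names(rm_)) rm_ <- rm_[rm_$locus == locus, ]
  }
  pm <- .avgReplicates(pm, by = c("pair_id", "member"))
  counts <- table(pm$pair_id)
  incomplete <- names(counts)[counts != 2]
  if (length(incomplete)) {
    message("excluded ", length(incomplete),
            " twin(s) without a partner")
    pm <- pm[!pm$pair_id %in% incomplete, ]
  }
  pairs <- split(pm$percent, pm$pair_id)
  if (length(pairs) < 3) stop("need >= 3 complete twin pairs")
  mat <- do.call(rbind, pairs)
  if (method == "random") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    flip <- sample(c(TRUE, FALSE), nrow(mat), replace = TRUE)
    mat[flip, ] <- mat[flip, 2:1]
    x <- mat[, 1]; y <- mat[, 2]
  } else {
    x <- c(mat[, 1], mat[, 2])
    y <- c(mat[, 2], mat[, 1])
  }
  intra <- cor(x, y)
  dtr <- as.data.table(rm_)
  setorderv(dtr, c("sample_id", "replicate_id"))
  repWide <- dtr[, .(r1 = percent_methylation[1],
                     r2 = percent_methylation[2]), by = sample_id]
  repWide <- repWide[!is.na(r1) & !is.na(r2)]
  if (nrow(repWide) < 3) stop("need >= 3 technical replicate pairs")
  tech <- cor(repWide$r1, repWide$r2)
  list(intra_pair_r = intra, technical_r = tech,
       nonshared_fraction = min(1, max(0, 1 - intra)),
       n_pairs = length(pairs), n_replicate_pairs = nrow(repWide))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Association of methylation with genotype at a nearby SNP
#'
#' One-way ANOVA of per-sample mean methylation across genotype groups,
#' reporting group means, F, P, and the variance explained (R squared).
#'
#' @param measurements data.frame `sample_id locus percent_methylation`.
#' @param genotypes data.frame `sample_id snp_id genotype` with genotypes in
#'   `{AA, AB, BB}`.
#' @param locus Locus name.
#' @param snp SNP id.
#' @return List `group_means` (data.frame), `f`, `p_value`, `r_squared`,
#'   `n`.
#' @export
genotypeAssociation <- function(measurements, genotypes, locus, snp) {
  m <- measurements[measurements$locus == locus, ]
  avg <- .avgReplicates(m, by = "sample_id")
  g <- genotypes[genotypes$snp_id == snp, ]
  avg$genotype <- g$genotype[match(avg$sample_id, g$sample_id)]
  avg <- avg[!is.na(avg$genotype), ]
  tab <- table(avg$genotype)
  tab <- tab[tab > 0]
  if (length(tab) < 2) stop("need >= 2 genotype groups with data")
  if (any(tab < 2)) stop("every genotype group needs >= 2 samples")
  fit <- aov(percent ~ factor(genotype), data = avg)
  an <- anova(fit)
  ss <- an$`Sum Sq`
  gm <- aggregate(percent ~ genotype, data = avg, FUN = mean)
  names(gm) <- c("genotype", "mean_percent")
  gm$n <- as.integer(tab[gm$genotype])
  list(group_means = gm, f = an$`F value`[1], p_value = an$`Pr(>F)`[1],
       r_squared = ss[1] / sum(ss), n = nrow(avg))
}

#' Cross-population distribution summary of methylation at a locus
#'
#' Box-plot style summary per population: median, quartiles, and the
#' 5th-95th percentile whiskers, over per-sample replicate means.
#'
#' @param measurements data.frame `sample_id population locus
#'   percent_methylation`.
#' @param locus Locus name.
#' @return data.frame `population n p5 q25 median q75 p95`.
#' @export
populationCompare <- function(measurements, locus) {
  m <- measurements[measurements$locus == locus, ]
  avg <- .avgReplicates(m, by = c("sample_id", "population"))
  parts <- split(avg$percent, avg$population)
  res <- lapply(names(parts), function(p) {
    q <- quantile(parts[[p]], c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(population = p, n = length(parts[[p]]), p5 = q[1], q25 = q[2],
               median = q[3], q75 = q[4], p95 = q[5])
  })
  do.call(rbind, res)
}
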