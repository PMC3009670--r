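meas <- function(sample, tissue, locus, percent, rep = 1,
                 population = "synthetic") {
  data.frame(sample_id = sample, population = population, tissue = tissue,
             locus = locus, replicate_id = rep,
             percent_methylation = percent)
}

test_that("assay linearity recovers the standards line", {
  perfect <- data.frame(expected_fraction = c(0, 0.5, 1),
                        measured_percent = c(0, 50, 100))
  fit <- assayLinearity(perfect)
  expect_equal(fit$slope, 100)
  expect_equal(fit$r, 1)

  const <- data.frame(expected_fraction = c(0, 0.5, 1),
                      measured_percent = c(40, 40, 40))
  expect_warning(fc <- assayLinearity(const), "constant")
  expect_equal(fc$slope, 0)
  expect_true(is.na(fc$r))

  # noisy standards against the closed-form least-squares solution
  set.seed(5)
  x <- c(0, 0.25, 0.5, 0.75, 1); y <- 100 * x + rnorm(5, 0, 2)
  noisy <- data.frame(expected_fraction = x, measured_percent = y)
  nf <- assayLinearity(noisy)
  bHat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(nf$slope, bHat, tolerance = 1e-10)
  expect_equal(nf$intercept, mean(y) - bHat * mean(x), tolerance = 1e-10)

  expect_error(assayLinearity(perfect[1:2, ]), "3 distinct")
})

test_that("inter-tissue correlation works on individual means and flags degeneracy", {
  v <- c(10, 30, 50, 70)
  m <- rbind(meas(paste0("s", 1:4), "PBL", "BOLA3", v),
             meas(paste0("s", 1:4), "HF", "BOLA3", v))
  expect_equal(interTissueCorrelation(m, "BOLA3")$r, 1)

  m2 <- rbind(meas(paste0("s", 1:4), "PBL", "BOLA3", v),
              meas(paste0("s", 1:4), "HF", "BOLA3", 100 - v))
  expect_equal(interTissueCorrelation(m2, "BOLA3")$r, -1)

  flat <- rbind(meas(paste0("s", 1:4), "PBL", "BOLA3", v),
                meas(paste0("s", 1:4), "HF", "BOLA3", rep(42, 4)))
  expect_true(interTissueCorrelation(flat, "BOLA3")$degenerate)

  expect_error(interTissueCorrelation(m[c(1, 2, 5), ], "BOLA3"), ">= 3")

  # replicates averaged before correlating: replicate scatter cancels
  m3 <- rbind(meas(paste0("s", 1:4), "PBL", "BOLA3", v + 5, rep = 1),
              meas(paste0("s", 1:4), "PBL", "BOLA3", v - 5, rep = 2),
              meas(paste0("s", 1:4), "HF", "BOLA3", v))
  expect_equal(interTissueCorrelation(m3, "BOLA3")$r, 1)
})

test_that("systemic loci show high inter-tissue r matching the closed-form oracle", {
  set.seed(9)
  n <- 8
  indiv <- rnorm(n, 50, 10)                  # shared individual state
  pbl <- indiv + rnorm(n, 0, 2)
  hf <- indiv + rnorm(n, 0, 2)
  m <- rbind(meas(paste0("s", 1:n), "PBL", "PAX8", pbl),
             meas(paste0("s", 1:n), "HF", "PAX8", hf))
  res <- interTissueCorrelation(m, "PAX8")
  expect_gt(res$r, 0.8)
  manual <- sum((pbl - mean(pbl)) * (hf - mean(hf))) /
    sqrt(sum((pbl - mean(pbl))^2) * sum((hf - mean(hf))^2))
  expect_equal(res$r, manual, tolerance = 1e-12)
})

test_that("twin concordance separates biological from technical variation", {
  # identical co-twins: intra-pair r = 1, nonshared 0
  tw <- simTwins(nPairs = 10, intraCorr = 1, techSd = 0, seed = 2)
  reps <- simTwins(nPairs = 10, intraCorr = 0, techSd = 1, seed = 3)
  res <- twinConcordance(tw$measurements, reps$measurements, seed = 1)
  expect_equal(res$intra_pair_r, 1, tolerance = 1e-12)
  expect_equal(res$nonshared_fraction, 0)

  # independent members: r near 0, nonshared near 1 (averaged over seeds)
  rs <- sapply(1:12, function(s) {
    tw0 <- simTwins(nPairs = 30, intraCorr = 0, seed = s)
    twinConcordance(tw0$measurements, tw0$measurements, seed = s)$intra_pair_r
  })
  expect_lt(abs(mean(rs)), 0.12)

  # planted correlation 0.5 recovered within +-0.15 at 23 pairs (over seeds)
  r5 <- sapply(1:40, function(s) {
    tw5 <- simTwins(nPairs = 23, intraCorr = 0.5, seed = 100 + s)
    twinConcordance(tw5$measurements, tw5$measurements,
                    seed = s)$intra_pair_r
  })
  expect_lt(abs(mean(r5) - 0.5), 0.15)

  # technical replicates correlate more tightly than co-twins
  tw6 <- simTwins(nPairs = 23, intraCorr = 0.5, techSd = 1,
                  biologicalSd = 10, seed = 6)
  res6 <- twinConcordance(tw6$measurements, tw6$measurements, seed = 1)
  expect_gt(res6$technical_r, res6$intra_pair_r)

  # unpaired twin excluded with a message
  odd <- tw$measurements[!(tw$measurements$pair_id == "T01" &
                             tw$measurements$member == 2), ]
  expect_message(twinConcordance(odd, reps$measurements, seed = 1),
                 "without a partner")
})

test_that("member-order randomization seed barely moves intra-pair r", {
  tw <- simTwins(nPairs = 25, intraCorr = 0.5, seed = 42)
  rs <- sapply(1:100, function(s)
    twinConcordance(tw$measurements, tw$measurements,
                    seed = s)$intra_pair_r)
  expect_lt(max(rs) - min(rs), 0.05 * 10)  # spread over ordering seeds
  expect_lt(sd(rs), 0.05)
})

test_that("genotype association recovers planted effects and matches a hand ANOVA", {
  # 6-observation toy: groups {10,12}, {20,22}, {30,32}
  m <- meas(paste0("s", 1:6), "PBL", "ZNF696", c(10, 12, 20, 22, 30, 32))
  g <- data.frame(sample_id = paste0("s", 1:6), snp_id = "rs1",
                  genotype = rep(c("AA", "AB", "BB"), each = 2))
  res <- genotypeAssociation(m, g, "ZNF696", "rs1")
  grand <- mean(c(10, 12, 20, 22, 30, 32))
  ssb <- 2 * sum((c(11, 21, 31) - grand)^2)
  ssw <- 6 * 1  # each group contributes 2 * 1^2
  expect_equal(res$f, (ssb / 2) / (ssw / 3), tolerance = 1e-10)
  expect_equal(res$r_squared, ssb / (ssb + ssw), tolerance = 1e-10)

  # equal group means: R^2 near zero
  m0 <- meas(paste0("s", 1:6), "PBL", "ZNF696", c(10, 12, 10, 12, 10, 12))
  expect_lt(genotypeAssociation(m0, g, "ZNF696", "rs1")$r_squared, 0.05)

  # planted 20-point separation at n = 25/10/5 explains most variance
  set.seed(17)
  n <- c(25, 10, 5)
  gt <- rep(c("AA", "AB", "BB"), n)
  mu <- rep(c(20, 40, 60), n)
  ids <- paste0("g", seq_len(sum(n)))
  mP <- meas(ids, "PBL", "ZNF696", mu + rnorm(sum(n), 0, 3))
  gP <- data.frame(sample_id = ids, snp_id = "rs1", genotype = gt)
  expect_gt(genotypeAssociation(mP, gP, "ZNF696", "rs1")$r_squared, 0.7)

  gSingle <- data.frame(sample_id = paste0("s", 1:6), snp_id = "rs1",
                        genotype = "AA")
  expect_error(genotypeAssociation(m, gSingle, "ZNF696", "rs1"), "groups")
})

test_that("population summaries match sort-based quantiles", {
  one <- meas("s1", "PBL", "BOLA3", 37, population = "Gambian")
  res1 <- populationCompare(one, "BOLA3")
  expect_true(all(res1[, c("p5", "q25", "median", "q75", "p95")] == 37))

  set.seed(23)
  vals <- runif(400, 0, 100)
  m <- meas(paste0("s", 1:400), "PBL", "BOLA3", vals,
            population = rep(c("Caucasian", "Asian"), each = 200))
  res <- populationCompare(m, "BOLA3")
  expect_equal(res$median[res$population == "Caucasian"],
               unname(quantile(vals[1:200], 0.5)), tolerance = 1e-10)
  expect_equal(res$p95[res$population == "Asian"],
               unname(quantile(vals[201:400], 0.95)), tolerance = 1e-10)
  expect_true(all(abs(res$median - 50) < 10))
})

test_that("correlations are invariant under affine rescaling", {
  set.seed(2)
  v1 <- rnorm(8, 50, 10); v2 <- v1 + rnorm(8, 0, 3)
  m <- rbind(meas(paste0("s", 1:8), "PBL", "L", v1),
             meas(paste0("s", 1:8), "HF", "L", v2))
  mScaled <- m
  mScaled$percent_methylation <- 0.5 * m$percent_methylation + 10
  expect_equal(interTissueCorrelation(m, "L")$r,
               interTissueCorrelation(mScaled, "L")$r, tolerance = 1e-12)
})
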