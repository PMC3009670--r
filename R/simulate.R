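.withSeed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

.randomBackground <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with planted SmaI/XmaI intervals
#'
#' Builds one contig of random background sequence (spurious CCCGGG
#' occurrences scrubbed) with recognition motifs planted so that the
#' cut-to-cut fragment lengths realize `nIntervals` informative intervals
#' inside the digest length bounds, plus decoy fragments below and above the
#' bounds. The ground-truth table gives every planted fragment with its
#' eligibility flag.
#'
#' @param nIntervals Number of eligible (informative) intervals to plant.
#' @param nDecoys Number of decoy fragments (half shorter than `minLen`,
#'   half longer than `maxLen`).
#' @param seed Integer seed.
#' @param minLen,maxLen Digest length bounds the truth is scored against.
#' @param contig Contig name.
#' @return List `genome` (`DNAStringSet`), `truth` (data.frame
#'   `interval_id length eligible`).
#' @export
simGenome <- function(nIntervals = 100, nDecoys = 20, seed = 1,
                      minLen = 60, maxLen = 1500, contig = "chrS") {
  .withSeed(seed, {
    lens <- integer(0)
    if (nIntervals > 0)
      lens <- sample(seq(minLen, maxLen), nIntervals, replace = TRUE)
    if (nDecoys > 0) {
      nShort <- ceiling(nDecoys / 2)
      nLong <- nDecoys - nShort
      short <- sample(seq(7, minLen - 1), nShort, replace = TRUE)
      long <- sample(seq(maxLen + 1, maxLen + 1500), nLong, replace = TRUE)
      lens <- sample(c(lens, short, long))
    }
    if (any(lens < 7))
      stop("fragment lengths below 7 bp would overlap planted motifs")
    if (length(lens) == 0) {
      seq <- .scrubMotifs(.randomBackground(2000), integer(0))
      list(genome = DNAStringSet(setNames(seq, contig)),
           truth = data.frame(interval_id = character(),
                              length = integer(), eligible = logical()))
    } else {
      pieces <- character(2 * length(lens) + 2)
      pieces[1] <- .randomBackground(300)
      pieces[2] <- RECOGNITION_MOTIF
      for (i in seq_along(lens)) {
        pieces[2 * i + 1] <- .randomBackground(lens[i] - 6L)
        pieces[2 * i + 2] <- RECOGNITION_MOTIF
      }
      seq <- paste(c(pieces, .randomBackground(300)), collapse = "")
      # planted 1-based motif starts
      starts <- 301L + cumsum(c(0L, lens))
      seq <- .scrubMotifs(seq, starts)
      cuts <- starts + 2L  # 0-based cut offsets
      left <- cuts[-length(cuts)]
      right <- cuts[-1L]
      truth <- data.frame(
        interval_id = sprintf("%s:%d-%d", contig, left, right),
        length = right - left,
        eligible = (right - left) >= minLen & (right - left) <= maxLen
      )
      list(genome = DNAStringSet(setNames(seq, contig)), truth = truth)
    }
  })
}

# mutate the centre base of any CCCGGG occurrence that is not planted
.scrubMotifs <- function(seq, plantedStarts) {
  repeat {
    hits <- start(matchPattern(RECOGNITION_MOTIF, DNAString(seq)))
    extra <- setdiff(hits, plantedStarts)
    if (length(extra) == 0) break
    for (s in extra) substr(seq, s + 2L, s + 2L) <- "A"
  }
  if (!setequal(start(matchPattern(RECOGNITION_MOTIF, DNAString(seq))),
                plantedStarts))
    stop("motif scrubbing failed to preserve planted sites")
  seq
}

#' Plant site-disrupting and benign variants on simulated intervals
#'
#' Picks random intervals and places one SNP inside a flanking recognition
#' motif (truth: `disrupts_site`), and places benign SNPs inside interval
#' bodies at positions where the substitution creates no new recognition
#' site (truth: clean).
#'
#' @param intervals `GRanges` from [enumerateIntervals()].
#' @param genome `DNAStringSet` the intervals came from.
#' @param nDisrupt,nBenign Counts of each variant type.
#' @param seed Integer seed.
#' @return List `variants` (data.frame `contig pos ref alt`, 1-based) and
#'   `truth` (one row per interval with the expected `disrupts_site` flag;
#'   a motif shared by two adjacent intervals flags both).
#' @export
simSiteVariants <- function(intervals, genome, nDisrupt = 10, nBenign = 10,
                            seed = 1) {
  genome <- readGenome(genome)
  .withSeed(seed, {
    n <- length(intervals)
    stopifnot(nDisrupt + nBenign <= n)
    pick <- sample(n, nDisrupt + nBenign)
    rows <- list()
    bases <- c("A", "C", "G", "T")
    for (k in seq_len(nDisrupt)) {
      i <- pick[k]
      chr <- as.character(seqnames(intervals)[i])
      ms <- if (runif(1) < 0.5) mcols(intervals)$left_motif_start[i] else
        mcols(intervals)$right_motif_start[i]
      pos <- ms + sample(0:5, 1)
      ref <- as.character(subseq(genome[[chr]], pos, pos))
      alt <- sample(setdiff(bases, ref), 1)
      rows[[k]] <- data.frame(contig = chr, pos = pos, ref = ref, alt = alt)
    }
    for (k in seq_len(nBenign)) {
      i <- pick[nDisrupt + k]
      chr <- as.character(seqnames(intervals)[i])
      body <- (start(intervals)[i] + 4L):(end(intervals)[i] - 7L)
      repeat {
        pos <- sample(body, 1)
        ref <- as.character(subseq(genome[[chr]], pos, pos))
        alt <- sample(setdiff(bases, ref), 1)
        lo <- max(1L, pos - 5L)
        hi <- min(length(genome[[chr]]), pos + 5L)
        win <- as.character(subseq(genome[[chr]], lo, hi))
        substr(win, pos - lo + 1L, pos - lo + 1L) <- alt
        if (length(matchPattern(RECOGNITION_MOTIF, DNAString(win))) == 0)
          break
      }
      rows[[nDisrupt + k]] <- data.frame(contig = chr, pos = pos, ref = ref,
                                         alt = alt)
    }
    variants <- do.call(rbind, rows)
    # interval-level truth from planted positions: any variant inside a
    # flank motif flags every interval sharing that motif
    lm <- mcols(intervals)$left_motif_start
    rm_ <- mcols(intervals)$right_motif_start
    chr <- as.character(seqnames(intervals))
    dpos <- variants$pos[seq_len(nDisrupt)]
    dchr <- variants$contig[seq_len(nDisrupt)]
    flag <- vapply(seq_len(n), function(i) {
      any(dchr == chr[i] &
            ((dpos >= lm[i] & dpos <= lm[i] + 5L) |
               (dpos >= rm_[i] & dpos <= rm_[i] + 5L)))
    }, TRUE)
    truth <- data.frame(interval_id = mcols(intervals)$interval_id,
                        disrupts_site = flag)
    list(variants = variants, truth = truth)
  })
}

#' Default two-tissue hybridization design
#'
#' Four two-individual comparisons (A-D) hybridized in both tissues, with
#' the dye swap incorporated in the hair-follicle set.
#'
#' @return data.frame `comparison_id tissue individual_1 individual_2
#'   dye_swapped`.
#' @export
defaultDesign <- function() {
  comp <- c("A", "B", "C", "D")
  data.frame(
    comparison_id = rep(comp, 2),
    tissue = rep(c("PBL", "HF"), each = 4),
    individual_1 = rep(paste0("ind", c(1, 3, 5, 7)), 2),
    individual_2 = rep(paste0("ind", c(2, 4, 6, 8)), 2),
    dye_swapped = rep(c(FALSE, TRUE), each = 4)
  )
}

#' Simulate a two-tissue MSAM probe table with ground truth
#'
#' Each interval belongs to a planted class: `invariant` (no interindividual
#' contrast anywhere), `tissue_specific` (a contrast in one tissue of one
#' comparison), `systemic` (the same contrast in both tissues of one
#' comparison, the ME signature), or the artifact classes `snp_artifact` /
#' `cnv_artifact` (systemic-looking signal of genetic rather than epigenetic
#' origin; flagged in the annotation table). Tissue-specific contrasts
#' outnumber systemic ones by default, as observed on real arrays.
#'
#' Per probe, each channel is measured as `nrep` log-intensity replicates
#' with Gaussian noise; the probe ratio is the back-transformed difference
#' of channel means and the probe P value the pooled two-sample t-test of
#' the replicates, so null probes yield uniform P values. Probe counts per
#' interval are `1 + Poisson(probesPerInterval - 1)`. Ratios are emitted in
#' hybridization dye orientation (inverted on dye-swapped arrays).
#'
#' @param nIntervals Total intervals on the array.
#' @param classCounts Named counts for `tissue_specific`, `systemic`,
#'   `snp_artifact`, `cnv_artifact` (the remainder is invariant).
#' @param contrast Linear fold-contrast of planted differences (default 2.5).
#' @param probesPerInterval Mean probes per interval (default 2.3).
#' @param channelSd Per-replicate log-intensity noise sd (default 0.1).
#' @param nrep Replicate measurements per channel (default 4).
#' @param design Hybridization design (default [defaultDesign()]).
#' @param seed Integer seed.
#' @return List `probes` (data.frame), `design`, `truth` (data.frame
#'   `interval_id class contrast comparison_id tissue direction`),
#'   `annotations` (exclusion flags for the artifact classes).
#' @export
simMsam <- function(nIntervals = 1000,
                    classCounts = c(tissue_specific = 60, systemic = 10,
                                    snp_artifact = 0, cnv_artifact = 0),
                    contrast = 2.5, probesPerInterval = 2.3,
                    channelSd = 0.1, nrep = 4, design = defaultDesign(),
                    seed = 1) {
  full <- c(tissue_specific = 0, systemic = 0, snp_artifact = 0,
            cnv_artifact = 0)
  full[names(classCounts)] <- classCounts
  if (sum(full) > nIntervals)
    stop("class counts exceed the number of intervals")
  .withSeed(seed, {
    cls <- rep("invariant", nIntervals)
    idx <- sample(nIntervals, sum(full))
    cls[idx] <- rep(names(full), full)
    ids <- sprintf("int%05d", seq_len(nIntervals))
    comps <- unique(design$comparison_id)
    tissues <- unique(design$tissue)
    trigComp <- sample(comps, nIntervals, replace = TRUE)
    trigTissue <- sample(tissues, nIntervals, replace = TRUE)
    dirn <- sample(c(1, -1), nIntervals, replace = TRUE)
    systemicLike <- cls %in% c("systemic", "snp_artifact", "cnv_artifact")
    truth <- data.frame(
      interval_id = ids, class = cls,
      contrast = ifelse(cls == "invariant", 1,
                        ifelse(dirn > 0, contrast, 1 / contrast)),
      comparison_id = ifelse(cls == "invariant", NA, trigComp),
      tissue = ifelse(systemicLike, "both",
                      ifelse(cls == "tissue_specific", trigTissue, NA)),
      direction = ifelse(cls == "invariant", NA,
                         ifelse(dirn > 0, "up", "down"))
    )
    nProbes <- 1L + rpois(nIntervals, max(0, probesPerInterval - 1))
    probeInterval <- rep(seq_len(nIntervals), nProbes)
    nP <- length(probeInterval)
    hyb <- design[rep(seq_len(nrow(design)), each = nP), ]
    pi2 <- rep(probeInterval, nrow(design))
    N <- nrow(hyb)
    active <- (cls[pi2] != "invariant") &
      (hyb$comparison_id == trigComp[pi2]) &
      (systemicLike[pi2] | hyb$tissue == trigTissue[pi2])
    delta <- ifelse(active, dirn[pi2] * log(contrast), 0)
    se <- channelSd / sqrt(nrep)
    mA <- rnorm(N, delta / 2, se)
    mB <- rnorm(N, -delta / 2, se)
    vA <- channelSd^2 * rchisq(N, nrep - 1) / (nrep - 1)
    vB <- channelSd^2 * rchisq(N, nrep - 1) / (nrep - 1)
    sp <- sqrt(((nrep - 1) * vA + (nrep - 1) * vB) / (2 * nrep - 2))
    tstat <- (mA - mB) / (sp * sqrt(2 / nrep))
    pval <- 2 * pt(-abs(tstat), df = 2 * nrep - 2)
    ratio <- exp(mA - mB)
    ratio <- ifelse(hyb$dye_swapped, 1 / ratio, ratio)
    probes <- data.frame(
      probe_id = paste0("p", seq_len(N)),
      interval_id = ids[pi2],
      comparison_id = hyb$comparison_id,
      tissue = hyb$tissue,
      ratio = ratio,
      p_value = pmax(pval, .Machine$double.xmin),
      row.names = NULL
    )
    annotations <- .emptyAnnotation(ids)
    annotations$disrupts_site <- cls == "snp_artifact"
    annotations$in_cnv <- cls == "cnv_artifact"
    list(probes = probes, design = design, truth = truth,
         annotations = annotations)
  })
}

#' Simulate a season-of-conception cohort with ground truth
#'
#' Percent methylation per individual x locus is a grand mean plus a locus
#' random effect, an individual random effect, the locus-specific seasonal
#' increment for rainy-season conceptions, and residual noise, clipped to
#' `[0, 100]` (clipped values are counted and reported in the truth). The
#' default increments place >10-point rises at PAX8 and ZFYVE28 and
#' moderate rises at the other ME loci, with no effect at the control loci.
#'
#' @param seed Integer seed.
#' @param meIncrements Named percentage-point rainy-season increments for
#'   the ME loci.
#' @param controlIncrements Named increments for the control loci (zero by
#'   default).
#' @param grandMean Baseline percent methylation.
#' @param individualSd,locusSd,residSd Random-effect and residual standard
#'   deviations (percent scale).
#' @param nPerSeason Individuals per season of conception.
#' @param years Years of conception, cycled over individuals within season.
#' @param aberrantYear Optional year whose seasonal increment is reversed
#'   (for interaction-screen testing).
#' @return List `records` (data.frame `individual_id sex year_of_conception
#'   season age_at_sampling locus locus_type mean_methylation`) and `truth`
#'   (the generating parameters plus the clipped-value count).
#' @export
simCohort <- function(seed = 1,
                      meIncrements = c(BOLA3 = 6, FLJ20433 = 6, PAX8 = 12,
                                       SLITRK1 = 6, ZFYVE28 = 12),
                      controlIncrements = c(LINE1 = 0, IGF2 = 0, GNASAS = 0,
                                            IL10 = 0),
                      grandMean = 50, individualSd = 5, locusSd = 8,
                      residSd = 3, nPerSeason = 25,
                      years = c(1991, 1994, 1995, 1998),
                      aberrantYear = NULL) {
  if (individualSd < 0 || locusSd < 0 || residSd < 0)
    stop("standard deviations must be non-negative")
  .withSeed(seed, {
    inc <- c(meIncrements, controlIncrements)
    loci <- names(inc)
    type <- c(rep("ME", length(meIncrements)),
              rep("control", length(controlIncrements)))
    nInd <- 2 * nPerSeason
    individuals <- sprintf("G%03d", seq_len(nInd))
    season <- rep(c("rainy", "dry"), each = nPerSeason)
    year <- rep(rep(years, length.out = nPerSeason), 2)
    sex <- rep(rep(c("M", "F"), length.out = nPerSeason), 2)
    age <- round(rnorm(nInd, 8.9, 2), 1)
    locusEff <- rnorm(length(loci), 0, locusSd)
    indEff <- rnorm(nInd, 0, individualSd)
    grid <- expand.grid(i = seq_len(nInd), l = seq_along(loci))
    effInc <- inc[grid$l] * (season[grid$i] == "rainy")
    if (!is.null(aberrantYear)) {
      ab <- year[grid$i] == aberrantYear & season[grid$i] == "rainy"
      effInc[ab] <- -effInc[ab]
    }
    y <- grandMean + locusEff[grid$l] + indEff[grid$i] + effInc +
      rnorm(nrow(grid), 0, residSd)
    nClipped <- sum(y < 0 | y > 100)
    if (nClipped > 0.01 * length(y))
      warning("more than 1% of simulated values clipped to [0, 100]")
    y <- pmin(100, pmax(0, y))
    records <- data.frame(
      individual_id = individuals[grid$i],
      sex = sex[grid$i],
      year_of_conception = year[grid$i],
      season = season[grid$i],
      age_at_sampling = age[grid$i],
      locus = loci[grid$l],
      locus_type = type[grid$l],
      mean_methylation = y
    )
    truth <- list(increments = inc, locus_type = setNames(type, loci),
                  grandMean = grandMean, individualSd = individualSd,
                  locusSd = locusSd, residSd = residSd,
                  nPerSeason = nPerSeason, years = years,
                  aberrantYear = aberrantYear, nClipped = nClipped)
    list(records = records, truth = truth)
  })
}

#' Simulate monozygotic-twin methylation with technical replicates
#'
#' Latent co-twin values per pair and locus are bivariate normal with the
#' stated intra-pair correlation; each member is then measured
#' `nReplicates` times with technical noise. Values are clipped to
#' `[0, 100]`.
#'
#' @param nPairs Twin pairs.
#' @param loci Locus names.
#' @param intraCorr Latent intra-pair correlation, in `[-1, 1]`.
#' @param mean,biologicalSd Latent mean and between-individual sd
#'   (percent).
#' @param techSd Technical replicate noise sd (percent).
#' @param nReplicates Replicate measurements per member.
#' @param seed Integer seed.
#' @return List `measurements` (data.frame `pair_id member sample_id locus
#'   replicate_id percent_methylation`) and `truth`.
#' @export
simTwins <- function(nPairs = 23, loci = "BOLA3", intraCorr = 0.5,
                     mean = 50, biologicalSd = 10, techSd = 1,
                     nReplicates = 2, seed = 1) {
  if (intraCorr < -1 || intraCorr > 1)
    stop("intraCorr must lie in [-1, 1]")
  .withSeed(seed, {
    rows <- list()
    for (loc in loci) {
      z1 <- rnorm(nPairs)
      z2 <- intraCorr * z1 + sqrt(1 - intraCorr^2) * rnorm(nPairs)
      lat <- cbind(mean + biologicalSd * z1, mean + biologicalSd * z2)
      for (memb in 1:2) {
        for (r in seq_len(nReplicates)) {
          v <- lat[, memb] + rnorm(nPairs, 0, techSd)
          rows[[length(rows) + 1]] <- data.frame(
            pair_id = sprintf("T%02d", seq_len(nPairs)),
            member = memb,
            sample_id = sprintf("T%02d_%d", seq_len(nPairs), memb),
            locus = loc,
            replicate_id = r,
            percent_methylation = pmin(100, pmax(0, v))
          )
        }
      }
    }
    measurements <- do.call(rbind, rows)
    list(measurements = measurements,
         truth = list(nPairs = nPairs, intraCorr = intraCorr,
                      biologicalSd = biologicalSd, techSd = techSd))
  })
}

#' Simulate a SNP genotype panel for twin verification
#'
#' Hardy-Weinberg genotypes at `nMarkers` biallelic markers for pairs that
#' are monozygotic (duplicated genotypes, with optional per-genotype error
#' flips) or unrelated (independent draws).
#'
#' @param pairTypes Character vector of `"MZ"` / `"unrelated"`, one per
#'   pair.
#' @param nMarkers Panel size (default 48).
#' @param maf Minor-allele frequency, scalar or per-marker vector, in
#'   (0, 0.5].
#' @param errorRate Probability a genotype call flips to one of the other
#'   two genotypes.
#' @param seed Integer seed.
#' @return List `genotypes` (long data.frame `pair_id member marker
#'   genotype` with dosage coding 0/1/2), `freqs` (data.frame `marker
#'   freq`), `truth` (data.frame `pair_id relationship`).
#' @export
simGenotypePanel <- function(pairTypes = c("MZ", "unrelated"), nMarkers = 48,
                             maf = 0.3, errorRate = 0, seed = 1) {
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  stopifnot(all(pairTypes %in% c("MZ", "unrelated")))
  .withSeed(seed, {
    p <- rep(maf, length.out = nMarkers)
    markers <- sprintf("rs%04d", seq_len(nMarkers))
    drawInd <- function() rbinom(nMarkers, 2, p)
    flip <- function(g) {
      doFlip <- runif(nMarkers) < errorRate
      g[doFlip] <- vapply(g[doFlip],
                          function(x) sample(setdiff(0:2, x), 1), 0L)
      g
    }
    rows <- list()
    for (i in seq_along(pairTypes)) {
      g1 <- drawInd()
      # the duplicated MZ copy receives per-genotype error flips
      g2 <- if (pairTypes[i] == "MZ") flip(g1) else drawInd()
      rows[[i]] <- data.frame(
        pair_id = rep(sprintf("P%03d", i), 2 * nMarkers),
        member = rep(1:2, each = nMarkers),
        marker = rep(markers, 2),
        genotype = c(g1, g2)
      )
    }
    list(genotypes = do.call(rbind, rows),
         freqs = data.frame(marker = markers, freq = p),
         truth = data.frame(pair_id = sprintf("P%03d", seq_along(pairTypes)),
                            relationship = pairTypes))
  })
}

#' Simulate pyrosequencing methylation standards
#'
#' Known mixtures of unmethylated and fully methylated DNA measured with
#' Gaussian noise, for assay-linearity checks.
#'
#' @param expected Expected methylated fractions.
#' @param noiseSd Measurement noise sd (percentage points).
#' @param slope,intercept True assay response (percent per unit fraction).
#' @param seed Integer seed.
#' @return data.frame `expected_fraction measured_percent`.
#' @export
simStandards <- function(expected = c(0, 0.25, 0.5, 0.75, 1), noiseSd = 2,
                         slope = 100, intercept = 0, seed = 1) {
  .withSeed(seed, {
    data.frame(
      expected_fraction = expected,
      measured_percent = pmin(100, pmax(0, intercept + slope * expected +
                                          rnorm(length(expected), 0, noiseSd)))
    )
  })
}
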