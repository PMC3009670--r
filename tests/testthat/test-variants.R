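# a tiny genome with two intervals whose flanks are known exactly
toyGenome <- function() {
  # motifs at 1-based starts 11, 111, 311 -> cuts 13, 113, 313
  seq <- paste0(strrep("A", 10), "CCCGGG", strrep("AT", 47),
                "CCCGGG", strrep("TA", 97), "CCCGGG", strrep("A", 10))
  dss(chr1 = seq)
}

toyIntervals <- function() {
  digestGenome(toyGenome(), DigestConfig(60, 1500), quiet = TRUE)
}

test_that("site-SNP flagging is exact positional overlap with flank motifs", {
  iv <- toyIntervals()
  expect_equal(length(iv), 2)
  lm <- S4Vectors::mcols(iv)$left_motif_start[1]  # 11
  v <- function(pos) data.frame(contig = "chr1", pos = pos, ref = "N",
                                alt = "A")
  expect_true(flagSiteSnps(iv, v(lm + 2))[1])     # inside the motif
  expect_false(any(flagSiteSnps(iv, v(lm - 1))))  # 1 bp left of motif
  expect_true(flagSiteSnps(iv, v(lm + 5))[1])     # last motif base
  expect_false(flagSiteSnps(iv, v(lm + 6))[1])    # 1 bp right of motif
  # middle motif belongs to both intervals
  mm <- S4Vectors::mcols(iv)$right_motif_start[1]
  expect_equal(flagSiteSnps(iv, v(mm)), c(TRUE, TRUE))
})

test_that("creating-SNP flag matches brute-force rescan for all substitutions of a toy sequence", {
  # interval body contains CCCGGA, one substitution from a new site
  seq <- paste0("CCCGGG", strrep("A", 20), "CCCGGA", strrep("T", 40),
                "CCCGGG")
  g <- dss(chr1 = seq)
  iv <- digestGenome(g, DigestConfig(10, 1500), quiet = TRUE)
  expect_equal(length(iv), 1)

  # the forced example: A->G at the 6th base of CCCGGA
  pos <- 6 + 20 + 6  # 1-based position of that A
  expect_true(flagCreatingSnps(iv, data.frame(contig = "chr1", pos = pos,
                                              ref = "A", alt = "G"), g))
  expect_false(flagCreatingSnps(iv, data.frame(contig = "chr1", pos = pos,
                                               ref = "A", alt = "T"), g))

  # exhaustive scan: every single-base substitution, flag vs naive rescan
  chars <- strsplit(seq, "")[[1]]
  refMotifCuts <- naiveMotifStarts(seq) + 2L
  s0 <- GenomicRanges::start(iv) - 1L
  e0 <- GenomicRanges::end(iv)
  for (pos in seq_along(chars)) {
    for (alt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars; mut[pos] <- alt
      mutCuts <- naiveMotifStarts(paste(mut, collapse = "")) + 2L
      wantNew <- setdiff(mutCuts, refMotifCuts)
      want <- any(wantNew > s0 & wantNew < e0)
      got <- flagCreatingSnps(iv, data.frame(contig = "chr1", pos = pos,
                                             ref = chars[pos], alt = alt), g)
      expect_equal(unname(got), want,
                   label = sprintf("pos %d %s>%s", pos, chars[pos], alt))
    }
  }
})

test_that("variant validation drops reference mismatches with a warning", {
  g <- toyGenome()
  v <- data.frame(contig = "chr1", pos = c(11, 12), ref = c("C", "T"),
                  alt = c("A", "G"))
  expect_warning(out <- validateVariants(v, g), "mismatch")
  expect_equal(nrow(out), 1)
  expect_error(validateVariants(
    data.frame(contig = "chr1", pos = 11, ref = "C", alt = "C"), g),
    "ref == alt")
})

test_that("structural overlap uses half-open abutment semantics", {
  iv <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 200))  # [100,200)
  S4Vectors::mcols(iv)$interval_id <- "c1:100-200"
  reg <- function(s0, e0, cls) {
    r <- GenomicRanges::GRanges("c1", IRanges::IRanges(s0 + 1, e0))
    S4Vectors::mcols(r)$region_class <- cls
    r
  }
  expect_true(flagStructuralOverlap(iv, reg(150, 160, "CNV"))$in_cnv)
  expect_false(flagStructuralOverlap(iv, reg(200, 300, "CNV"))$in_cnv)
  expect_true(flagStructuralOverlap(iv, reg(0, 5000, "segdup"))$in_segdup)
  # full-containment mode
  expect_false(flagStructuralOverlap(iv, reg(150, 160, "CNV"),
                                     containment = "full")$in_cnv)
  expect_true(flagStructuralOverlap(iv, reg(50, 250, "CNV"),
                                    containment = "full")$in_cnv)
})

test_that("planted variant truth is recovered exactly by annotation", {
  g <- simGenome(nIntervals = 60, nDecoys = 10, seed = 21)
  iv <- digestGenome(g$genome, quiet = TRUE)
  pv <- simSiteVariants(iv, g$genome, nDisrupt = 12, nBenign = 12, seed = 5)
  ann <- annotateIntervals(iv, variants = pv$variants, genome = g$genome)
  flagged <- ann$interval_id[ann$disrupts_site]
  expect_setequal(flagged, pv$truth$interval_id[pv$truth$disrupts_site])
  # benign body variants are built not to create a recognition site
  benign <- pv$variants[13:24, ]
  expect_false(any(flagCreatingSnps(iv, benign, g$genome)))
})

test_that("exclusion cascade reproduces the printed stage counts", {
  # 107 candidates; 34 SNP-flagged -> 73; 35 of those CNV/segdup -> 38;
  # two validated loci retained -> 40
  ids <- sprintf("cand%03d", 1:107)
  ann <- data.frame(interval_id = ids, disrupts_site = FALSE,
                    creates_site = FALSE, in_cnv = FALSE, in_segdup = FALSE)
  ann$disrupts_site[1:34] <- TRUE
  ann$in_cnv[35:69] <- TRUE
  retain <- c(ids[1], ids[35])  # one lost at each stage
  res <- filterCandidates(ids, ann, retain = retain)
  expect_equal(res@stages$remaining, c(107, 73, 38, 40))
  expect_length(surviving(res), 40)
  expect_true(all(retain %in% surviving(res)))

  # no flags, empty retain: identity
  ann0 <- ann; ann0$disrupts_site <- FALSE; ann0$in_cnv <- FALSE
  expect_equal(surviving(filterCandidates(ids, ann0)), ids)
  expect_error(filterCandidates(ids, ann, retain = "nope"), "retain")
})

test_that("cascade is idempotent and removes all truth-flagged loci", {
  s <- simMsam(nIntervals = 400,
               classCounts = c(tissue_specific = 20, systemic = 10,
                               snp_artifact = 8, cnv_artifact = 8),
               seed = 9)
  cand <- s$truth$interval_id[s$truth$class != "invariant"]
  res <- filterCandidates(cand, s$annotations)
  artifacts <- s$truth$interval_id[s$truth$class %in%
                                     c("snp_artifact", "cnv_artifact")]
  expect_length(intersect(surviving(res), artifacts), 0)
  clean <- setdiff(cand, artifacts)
  expect_setequal(surviving(res), clean)
  # idempotent
  res2 <- filterCandidates(surviving(res), s$annotations)
  expect_identical(surviving(res2), surviving(res))
})

test_that("chi-square enrichment matches a hand-computed oracle", {
  # oracle: Pearson X2 from first principles on the 2x2 table
  pearson <- function(tab) {
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    x2 <- sum((tab - exp)^2 / exp)
    c(x2 = x2, p = pchisq(x2, df = 1, lower.tail = FALSE))
  }
  # hits: 10/100 flagged; non-hits: 100/10000 flagged
  res <- enrichmentTest(10, 100, 110, 10100)
  want <- pearson(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE))
  expect_equal(res$chi_square, unname(want["x2"]), tolerance = 1e-12)
  expect_equal(res$p_value, unname(want["p"]), tolerance = 1e-12)

  # equal fractions: X2 = 0, P = 1
  null <- enrichmentTest(10, 100, 1000, 10000)
  expect_equal(null$chi_square, 0, tolerance = 1e-12)
  expect_equal(null$p_value, 1)

  # screen-scale counts give an enrichment P on the 1e-8 scale
  res2 <- enrichmentTest(34, 107, 11943, 90807)
  expect_lt(res2$p_value, 1e-7)
  expect_gt(res2$p_value, 1e-10)

  # invariance to transposing the 2x2 table
  resT <- enrichmentTest(10, 110, 100, 10100)
  expect_equal(resT$p_value, res$p_value, tolerance = 1e-12)

  expect_error(enrichmentTest(0, 0, 10, 100), "margin")
})

test_that("variant and region readers handle TSV and VCF input", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chr1\t10\tC\tA", "chr1\t20\tG\tT"),
             tsv)
  v <- readSnvTable(tsv)
  expect_equal(v$pos, c(11, 21))  # 0-based input to 1-based internal

  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t11\trs1\tC\tA\t.\t.\t.",
               "chr1\t15\trs2\tCT\tC\t.\t.\t.",
               "chr1\t21\trs3\tG\tT,C\t.\t.\t."), vcf)
  expect_message(v2 <- readSnvTable(vcf), "non-SNV")
  expect_equal(v2$pos, 11)  # VCF already 1-based; indel and multi-allelic dropped

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tCNV", "chr1\t300\t400\tsegdup"), bed)
  reg <- readRegionsBed(bed)
  expect_equal(GenomicRanges::start(reg), c(101, 301))
  expect_equal(S4Vectors::mcols(reg)$region_class, c("CNV", "segdup"))
})
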