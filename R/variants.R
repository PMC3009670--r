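#' Read single-nucleotide variants from TSV or VCF
#'
#' The TSV schema is `chrom pos ref alt` with 0-based positions (converted
#' to the package's internal 1-based convention on read). VCF input (1-based
#' `POS`) keeps SNV records only; indels and multi-allelic records are
#' dropped with a message.
#'
#' @param path Variant file (`.vcf` detected by extension; anything else is
#'   read as TSV).
#' @return data.frame with columns `contig`, `pos` (1-based), `ref`, `alt`.
#' @export
readSnvTable <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (length(lines) == 0) {
      return(data.frame(contig = character(), pos = integer(),
                        ref = character(), alt = character()))
    }
    f <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(
      contig = vapply(f, `[`, "", 1L),
      pos = as.integer(vapply(f, `[`, "", 2L)),
      ref = toupper(vapply(f, `[`, "", 4L)),
      alt = toupper(vapply(f, `[`, "", 5L))
    )
    snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L &
      !grepl(",", df$alt, fixed = TRUE)
    if (any(!snv)) message("dropped ", sum(!snv), " non-SNV VCF record(s)")
    df[snv, , drop = FALSE]
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    names(df) <- tolower(names(df))
    data.frame(contig = df$chrom, pos = as.integer(df$pos) + 1L,
               ref = toupper(df$ref), alt = toupper(df$alt))
  }
}

#' Validate variants against the genome
#'
#' Checks that each variant's reference allele matches the genome at its
#' position; mismatches are dropped with a warning carrying the count.
#' Non-single-nucleotide and ref==alt records are rejected.
#'
#' @param variants data.frame `contig pos ref alt` (1-based pos).
#' @param genome `DNAStringSet`.
#' @return The validated variant data.frame.
#' @export
validateVariants <- function(variants, genome) {
  genome <- readGenome(genome)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(variants)))
  if (any(nchar(variants$ref) != 1L | nchar(variants$alt) != 1L))
    stop("only single-nucleotide variants are supported")
  if (any(variants$ref == variants$alt))
    stop("variant with ref == alt")
  if (!all(variants$contig %in% names(genome)))
    stop("variant contig(s) absent from genome: ",
         paste(setdiff(variants$contig, names(genome)), collapse = ", "))
  obs <- vapply(seq_len(nrow(variants)), function(i) {
    as.character(subseq(genome[[variants$contig[i]]],
                        variants$pos[i], variants$pos[i]))
  }, "")
  ok <- obs == variants$ref
  if (any(!ok)) {
    warning(sum(!ok), " variant(s) with reference-allele mismatch skipped")
  }
  variants[ok, , drop = FALSE]
}

.emptyAnnotation <- function(ids) {
  data.frame(interval_id = ids, disrupts_site = FALSE, creates_site = FALSE,
             in_cnv = FALSE, in_segdup = FALSE, stringsAsFactors = FALSE)
}

#' Flag intervals whose flanking recognition motifs carry a SNP
#'
#' `disrupts_site` is set when any variant position falls within either
#' flanking 6-bp CCCGGG motif of an interval (positional overlap with the
#' motif, as in SNP-track annotation; whether the alternate allele actually
#' destroys the motif is not required).
#'
#' @param intervals `GRanges` from [enumerateIntervals()].
#' @param variants Validated variant data.frame (1-based `pos`).
#' @return Logical vector `disrupts_site`, parallel to `intervals`.
#' @export
flagSiteSnps <- function(intervals, variants) {
  n <- length(intervals)
  if (n == 0 || nrow(variants) == 0) return(logical(n))
  motifs <- GRanges(
    rep(as.character(seqnames(intervals)), 2L),
    IRanges(c(mcols(intervals)$left_motif_start,
              mcols(intervals)$right_motif_start), width = 6L),
    interval_idx = rep(seq_len(n), 2L)
  )
  vr <- GRanges(variants$contig, IRanges(variants$pos, width = 1L))
  hit <- findOverlaps(motifs, vr)
  out <- logical(n)
  out[mcols(motifs)$interval_idx[queryHits(hit)]] <- TRUE
  out
}

#' Flag intervals where a SNP introduces a new recognition site
#'
#' `creates_site` is set when substituting the alternate allele yields a
#' CCCGGG match in the 11-bp window centred on the variant that does not
#' exist in the reference, with the new site's cut position strictly inside
#' the interval body.
#'
#' @param intervals `GRanges` from [enumerateIntervals()].
#' @param variants Validated variant data.frame.
#' @param genome `DNAStringSet`.
#' @return Logical vector `creates_site`, parallel to `intervals`.
#' @export
flagCreatingSnps <- function(intervals, variants, genome) {
  genome <- readGenome(genome)
  n <- length(intervals)
  out <- logical(n)
  if (n == 0 || nrow(variants) == 0) return(out)
  istart0 <- start(intervals) - 1L   # 0-based half-open interval span
  iend0 <- end(intervals)
  ichr <- as.character(seqnames(intervals))
  for (i in seq_len(nrow(variants))) {
    chr <- variants$contig[i]
    pos <- variants$pos[i]
    contig <- genome[[chr]]
    lo <- max(1L, pos - 5L)
    hi <- min(length(contig), pos + 5L)
    refWin <- as.character(subseq(contig, lo, hi))
    mutWin <- refWin
    substr(mutWin, pos - lo + 1L, pos - lo + 1L) <- variants$alt[i]
    refHits <- start(matchPattern(RECOGNITION_MOTIF, DNAString(refWin)))
    mutHits <- start(matchPattern(RECOGNITION_MOTIF, DNAString(mutWin)))
    newHits <- setdiff(mutHits, refHits)
    if (length(newHits) == 0) next
    cut0 <- (lo - 1L) + (newHits - 1L) + 3L  # 0-based cut offset of new site
    for (c0 in cut0) {
      inside <- which(ichr == chr & istart0 < c0 & c0 < iend0)
      out[inside] <- TRUE
    }
  }
  out
}

#' Read structural-variant regions from BED with a class column
#'
#' Expects BED3 plus a 4th column with the region class (`CNV` or
#' `segdup`); coordinates 0-based half-open.
#'
#' @param path BED-like file (no header).
#' @return `GRanges` with metadata column `region_class`.
#' @export
readRegionsBed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
  mcols(gr)$region_class <- df[[4]]
  gr
}

#' Flag intervals overlapping CNVs or segmental duplications
#'
#' @param intervals `GRanges`.
#' @param regions `GRanges` with metadata column `region_class` in
#'   `{CNV, segdup}`.
#' @param containment `"any"` (default: >= 1 bp overlap sets the flag) or
#'   `"full"` (interval must lie entirely within a region).
#' @return data.frame with logical columns `in_cnv`, `in_segdup`.
#' @export
flagStructuralOverlap <- function(intervals, regions,
                                  containment = c("any", "full")) {
  containment <- match.arg(containment)
  type <- if (containment == "any") "any" else "within"
  n <- length(intervals)
  out <- data.frame(in_cnv = logical(n), in_segdup = logical(n))
  if (n == 0 || length(regions) == 0) return(out)
  for (cls in c("CNV", "segdup")) {
    sub <- regions[mcols(regions)$region_class == cls]
    if (length(sub) == 0) next
    hit <- findOverlaps(intervals, sub, type = type)
    col <- if (cls == "CNV") "in_cnv" else "in_segdup"
    out[[col]][unique(queryHits(hit))] <- TRUE
  }
  out
}

#' Annotate intervals with all exclusion flags
#'
#' Convenience wrapper building one [IntervalAnnotation] record per interval:
#' `disrupts_site`, `creates_site` (from SNPs), `in_cnv`, `in_segdup` (from
#' structural regions).
#'
#' @param intervals `GRanges` from [enumerateIntervals()].
#' @param variants Optional variant data.frame (validated against `genome`
#'   if given).
#' @param regions Optional structural-region `GRanges`.
#' @param genome Optional `DNAStringSet` (required with `variants`).
#' @param containment Passed to [flagStructuralOverlap()].
#' @return data.frame `interval_id disrupts_site creates_site in_cnv
#'   in_segdup`.
#' @export
annotateIntervals <- function(intervals, variants = NULL, regions = NULL,
                              genome = NULL, containment = "any") {
  ann <- .emptyAnnotation(mcols(intervals)$interval_id)
  if (!is.null(variants) && nrow(variants) > 0) {
    if (is.null(genome)) stop("genome required to annotate variants")
    variants <- validateVariants(variants, genome)
    ann$disrupts_site <- flagSiteSnps(intervals, variants)
    ann$creates_site <- flagCreatingSnps(intervals, variants, genome)
  }
  if (!is.null(regions)) {
    st <- flagStructuralOverlap(intervals, regions, containment)
    ann$in_cnv <- st$in_cnv
    ann$in_segdup <- st$in_segdup
  }
  ann
}

#' Run the candidate exclusion cascade
#'
#' Stage 1 removes candidates whose interval carries a recognition-site SNP
#' (`disrupts_site` or `creates_site`); stage 2 removes remaining candidates
#' overlapping a CNV or segmental duplication. Candidates on the `retain`
#' allow-list that were removed at either stage are re-added at the end
#' (mirroring ad-hoc retention of independently validated loci).
#'
#' @param candidateIds Character vector of candidate interval ids.
#' @param annotations Annotation data.frame from [annotateIntervals()] (one
#'   row per candidate at least).
#' @param retain Character vector of ids to re-add if removed.
#' @return A [CascadeResult-class].
#' @export
filterCandidates <- function(candidateIds, annotations, retain = character()) {
  if (!all(retain %in% candidateIds))
    stop("retain id(s) not among candidates: ",
         paste(setdiff(retain, candidateIds), collapse = ", "))
  if (!all(candidateIds %in% annotations$interval_id))
    stop("unannotated candidate(s): ",
         paste(head(setdiff(candidateIds, annotations$interval_id)),
               collapse = ", "))
  ann <- annotations[match(candidateIds, annotations$interval_id), ]
  snpFlag <- ann$disrupts_site | ann$creates_site
  removedSnp <- candidateIds[snpFlag]
  afterSnp <- candidateIds[!snpFlag]
  ann2 <- ann[!snpFlag, , drop = FALSE]
  structFlag <- ann2$in_cnv | ann2$in_segdup
  removedStruct <- afterSnp[structFlag]
  afterStruct <- afterSnp[!structFlag]
  retainedBack <- intersect(retain, c(removedSnp, removedStruct))
  final <- candidateIds[candidateIds %in% c(afterStruct, retainedBack)]
  stages <- data.frame(
    stage = c("input", "site SNPs", "CNV/segdup", "retained back"),
    removed = c(0L, length(removedSnp), length(removedStruct),
                -length(retainedBack)),
    remaining = c(length(candidateIds), length(afterSnp),
                  length(afterStruct), length(final))
  )
  new("CascadeResult", stages = stages, surviving = final,
      removedSnp = removedSnp, removedStructural = removedStruct,
      retainedBack = retainedBack)
}

#' Chi-square enrichment test of an exclusion flag among screen hits
#'
#' Builds the 2x2 table (hits vs non-hits) x (flagged vs unflagged), with
#' the background understood as the full interval universe containing the
#' hits, and runs a Pearson chi-square test (1 df).
#'
#' @param observedFlagged Flagged hits.
#' @param nHits Total hits.
#' @param backgroundFlagged Flagged intervals in the whole background
#'   (including hits).
#' @param nBackground Total background intervals (including hits).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return data.frame `observed_flagged n_hits background_flagged
#'   n_background chi_square p_value`.
#' @export
enrichmentTest <- function(observedFlagged, nHits, backgroundFlagged,
                           nBackground, correct = FALSE) {
  stopifnot(observedFlagged <= nHits, backgroundFlagged <= nBackground,
            nHits <= nBackground, observedFlagged <= backgroundFlagged)
  tab <- matrix(c(
    observedFlagged, nHits - observedFlagged,
    backgroundFlagged - observedFlagged,
    (nBackground - nHits) - (backgroundFlagged - observedFlagged)
  ), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: a margin is zero")
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  data.frame(observed_flagged = observedFlagged, n_hits = nHits,
             background_flagged = backgroundFlagged,
             n_background = nBackground,
             chi_square = unname(ct$statistic), p_value = unname(ct$p.value))
}
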