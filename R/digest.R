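#' @importFrom Biostrings readDNAStringSet DNAStringSet DNAString
#'   vmatchPattern matchPattern alphabetFrequency subseq replaceLetterAt
#' @importFrom GenomicRanges GRanges seqnames start end width mcols "mcols<-"
#'   findOverlaps resize
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame
NULL

RECOGNITION_MOTIF <- "CCCGGG"

#' Load and validate a genome FASTA
#'
#' Reads a (multi-contig) FASTA, uppercases the sequence, and rejects any
#' character outside the A/C/G/T/N alphabet, naming the offending contig and
#' offset.
#'
#' @param fasta Path to a FASTA file, or a `DNAStringSet` (validated in
#'   place).
#' @return A named `DNAStringSet`.
#' @export
readGenome <- function(fasta) {
  if (is(fasta, "DNAStringSet")) {
    genome <- fasta
  } else {
    if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
    if (file.size(fasta) == 0) stop("FASTA file is empty: ", fasta)
    genome <- readDNAStringSet(fasta)
    if (length(genome) == 0) stop("no sequences in FASTA: ", fasta)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome <- DNAStringSet(toupper(genome))
  af <- alphabetFrequency(genome)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(af[, setdiff(colnames(af), allowed), drop = FALSE])
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    off <- regexpr("[^ACGTN]", as.character(genome[[i]]))
    stop(sprintf(
      "invalid character in contig '%s' at offset %d (0-based %d): only A/C/G/T/N allowed",
      names(genome)[i], off, off - 1L))
  }
  if (any(width(genome) == 0)) {
    stop("empty sequence for contig '",
         names(genome)[which(width(genome) == 0)[1]], "'")
  }
  genome
}

#' Locate SmaI/XmaI recognition sites
#'
#' Finds all exact CCCGGG occurrences in each contig. The motif is
#' palindromic so one strand suffices; motifs overlapping N never match.
#' SmaI cuts bluntly between CCC and GGG, so the cut falls after the third
#' motif base.
#'
#' @param genome A `DNAStringSet` (see [readGenome()]).
#' @return A `GRanges` of width-6 motif hits, sorted by position within
#'   contig, with metadata column `cut`: the 1-based position of the last
#'   base before the blunt cut (equivalently the 0-based cut offset).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ACCCGGGT"))
#' findRecognitionSites(g)  # motif at 2 (1-based), cut offset 4
#' @export
findRecognitionSites <- function(genome) {
  genome <- readGenome(genome)
  m <- vmatchPattern(RECOGNITION_MOTIF, genome, fixed = TRUE)
  hits <- lapply(seq_along(genome), function(i) {
    s <- start(m[[i]])
    GRanges(rep(names(genome)[i], length(s)), IRanges(s, width = 6L),
            cut = s + 2L)
  })
  out <- sort(do.call(c, hits))
  out
}

#' Enumerate informative restriction intervals
#'
#' Pairs consecutive recognition sites on each contig into cut-to-cut
#' fragments and keeps those whose length lies within the configured bounds
#' (inclusive). Interval ids are deterministic `contig:start-end` strings in
#' 0-based half-open coordinates.
#'
#' @param sites `GRanges` from [findRecognitionSites()], sorted per contig.
#' @param config A [DigestConfig-class].
#' @return A `GRanges` of intervals with metadata columns `interval_id`,
#'   `frag_length`, and the 1-based start positions of the two flanking
#'   motifs (`left_motif_start`, `right_motif_start`).
#' @export
enumerateIntervals <- function(sites, config = DigestConfig()) {
  stopifnot(is(sites, "GRanges"), is(config, "DigestConfig"))
  validObject(config)
  parts <- split(sites, droplevels(seqnames(sites)))
  res <- lapply(names(parts), function(chr) {
    s <- parts[[chr]]
    if (length(s) < 2L) return(GRanges())
    cuts <- mcols(s)$cut
    if (is.unsorted(cuts, strictly = TRUE))
      stop("recognition sites on contig '", chr, "' are not sorted")
    left <- cuts[-length(cuts)]
    right <- cuts[-1L]
    len <- right - left
    keep <- len >= config@minLen & len <= config@maxLen
    if (!any(keep)) return(GRanges())
    left <- left[keep]; right <- right[keep]; len <- len[keep]
    gr <- GRanges(chr, IRanges(left + 1L, right))
    mcols(gr)$interval_id <- sprintf("%s:%d-%d", chr, left, right)
    mcols(gr)$frag_length <- len
    mcols(gr)$left_motif_start <- left - 2L
    mcols(gr)$right_motif_start <- right - 2L
    gr
  })
  res <- res[vapply(res, length, 1L) > 0]
  if (length(res) == 0) {
    return(GRanges(interval_id = character(), frag_length = integer(),
                   left_motif_start = integer(), right_motif_start = integer()))
  }
  sort(do.call(c, res))
}

#' Digest a genome in silico
#'
#' Orchestrates [findRecognitionSites()] and [enumerateIntervals()] over all
#' contigs of a FASTA, optionally writing the interval table as TSV and/or
#' BED.
#'
#' @param fasta FASTA path or `DNAStringSet`.
#' @param config A [DigestConfig-class].
#' @param outTsv,outBed Optional output paths.
#' @param quiet Suppress the summary message.
#' @return `GRanges` of informative intervals (invisibly if written).
#' @export
digestGenome <- function(fasta, config = DigestConfig(), outTsv = NULL,
                         outBed = NULL, quiet = FALSE) {
  genome <- readGenome(fasta)
  sites <- findRecognitionSites(genome)
  intervals <- enumerateIntervals(sites, config)
  if (!quiet) {
    message(sprintf(
      "digest: %d recognition site(s), %d informative interval(s) of %d-%d bp",
      length(sites), length(intervals), config@minLen, config@maxLen))
  }
  if (!is.null(outTsv)) writeIntervalTsv(intervals, outTsv)
  if (!is.null(outBed)) writeIntervalBed(intervals, outBed)
  if (is.null(outTsv) && is.null(outBed)) intervals else invisible(intervals)
}

#' Write an interval table as TSV (0-based half-open coordinates)
#'
#' @param intervals `GRanges` from [enumerateIntervals()].
#' @param path Output file.
#' @export
writeIntervalTsv <- function(intervals, path) {
  df <- data.frame(
    interval_id = mcols(intervals)$interval_id,
    contig = as.character(seqnames(intervals)),
    start = start(intervals) - 1L,
    end = end(intervals),
    length = mcols(intervals)$frag_length
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as 6-column BED
#'
#' @param intervals `GRanges` from [enumerateIntervals()].
#' @param path Output file.
#' @export
writeIntervalBed <- function(intervals, path) {
  df <- data.frame(
    chrom = as.character(seqnames(intervals)),
    start = start(intervals) - 1L,
    end = end(intervals),
    name = mcols(intervals)$interval_id,
    score = 0L,
    strand = "."
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an interval TSV written by [writeIntervalTsv()] back into GRanges
#'
#' @param path TSV path with columns `interval_id contig start end length`
#'   (0-based half-open).
#' @return `GRanges` with the digest metadata columns reconstructed.
#' @export
readIntervalTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gr <- GRanges(df$contig, IRanges(df$start + 1L, df$end))
  mcols(gr)$interval_id <- df$interval_id
  mcols(gr)$frag_length <- df$length
  mcols(gr)$left_motif_start <- df$start - 2L
  mcols(gr)$right_motif_start <- df$end - 2L
  gr
}
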