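# shared fixture builders for the test suite

dss <- function(...) Biostrings::DNAStringSet(c(...))

# naive motif scan: direct 6-base window comparison on a character split,
# independent of the Biostrings matching used by the implementation
naiveMotifStarts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < 6) return(integer(0))
  idx <- seq_len(n - 5)
  hit <- ch[idx] == "C" & ch[idx + 1] == "C" & ch[idx + 2] == "C" &
    ch[idx + 3] == "G" & ch[idx + 4] == "G" & ch[idx + 5] == "G"
  idx[hit]
}

# brute-force digest oracle: pair consecutive naive motif matches
naiveIntervals <- function(seq, contig, minLen = 60, maxLen = 1500) {
  starts <- naiveMotifStarts(seq)
  cuts <- starts + 2L
  if (length(cuts) < 2) {
    return(data.frame(interval_id = character(), length = integer()))
  }
  left <- cuts[-length(cuts)]
  right <- cuts[-1L]
  len <- right - left
  keep <- len >= minLen & len <= maxLen
  data.frame(interval_id = sprintf("%s:%d-%d", contig, left[keep],
                                   right[keep]),
             length = len[keep])
}

# a tiny probe table with one interval in a fully crossed design
probeRow <- function(interval, comp, tissue, ratio, p, probe = NULL) {
  data.frame(probe_id = if (is.null(probe))
    paste(interval, comp, tissue, signif(ratio, 4), sep = "_") else probe,
    interval_id = interval, comparison_id = comp, tissue = tissue,
    ratio = ratio, p_value = p)
}

# stats table for one interval: same ratio/p in every comparison x tissue,
# with per-comparison overrides
flatStats <- function(interval, ratio, p,
                      comps = c("A", "B", "C", "D"),
                      tissues = c("PBL", "HF")) {
  g <- expand.grid(comparison_id = comps, tissue = tissues,
                   stringsAsFactors = FALSE)
  data.frame(interval_id = interval, comparison_id = g$comparison_id,
             tissue = g$tissue, mean_ratio = ratio, median_ratio = ratio,
             median_p = p, n_probes = 2L)
}

noSwapDesign <- function() {
  d <- defaultDesign()
  d$dye_swapped <- FALSE
  d
}
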