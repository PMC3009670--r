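#' Read genomic annotations (CpG islands, repeats) from BED-like TSV
#'
#' BED3 plus a feature-class column (`CGI`, `SINE`, `Alu`, `LINE`, `LTR`,
#' `simple_repeat`, `low_complexity`) and an optional 5th column with CGI
#' percent GC.
#'
#' @param path BED-like file without header, 0-based half-open coordinates.
#' @return `GRanges` with metadata columns `feature_class` and (if present)
#'   `percent_gc`.
#' @export
readAnnotationBed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
  mcols(gr)$feature_class <- df[[4]]
  if (ncol(df) >= 5) mcols(gr)$percent_gc <- df[[5]]
  gr
}

.midpoint0 <- function(gr) {
  # midpoint in 0-based coordinates: floor((start0 + end0) / 2)
  floor((start(gr) - 1 + end(gr)) / 2)
}

#' Profile annotations around interval midpoints
#'
#' For every interval, records each annotation whose reference point lies
#' within `window` bp of the interval midpoint, with a signed distance
#' (negative = upstream, i.e. lower coordinate). Midpoints are computed in
#' 0-based coordinates as `floor((start + end) / 2)`.
#'
#' @param intervals `GRanges` with metadata column `interval_id`.
#' @param annotations `GRanges` with metadata column `feature_class` (and
#'   optionally `percent_gc`).
#' @param window Half-width of the profiled window in bp (default 3000).
#' @param reference `"midpoint"` (default) measures to the annotation
#'   midpoint; `"edge"` measures to the nearest annotation edge.
#' @return data.frame `interval_id feature_class signed_distance
#'   annotation_length` (plus `percent_gc` when available).
#' @export
distanceProfile <- function(intervals, annotations, window = 3000,
                            reference = c("midpoint", "edge")) {
  reference <- match.arg(reference)
  if (is.null(mcols(intervals)$interval_id))
    stop("intervals must carry an interval_id metadata column")
  imid <- .midpoint0(intervals)
  amid <- .midpoint0(annotations)
  ipoints <- GRanges(seqnames(intervals), IRanges(imid + 1L, width = 1L))
  win <- GRanges(seqnames(ipoints),
                 IRanges(pmax(1L, start(ipoints) - window),
                         start(ipoints) + window))
  if (reference == "midpoint") {
    apoints <- GRanges(seqnames(annotations), IRanges(amid + 1L, width = 1L))
    hit <- findOverlaps(win, apoints)
    d <- amid[subjectHits(hit)] - imid[queryHits(hit)]
  } else {
    hit <- findOverlaps(win, annotations)
    a <- annotations[subjectHits(hit)]
    m <- imid[queryHits(hit)]
    dLeft <- (start(a) - 1) - m
    dRight <- end(a) - m
    d <- ifelse(abs(dLeft) < abs(dRight), dLeft, dRight)
    d[sign(dLeft) != sign(dRight)] <- 0L   # midpoint inside the annotation
  }
  keep <- abs(d) <= window
  hit <- hit[keep]; d <- d[keep]
  out <- data.frame(
    interval_id = mcols(intervals)$interval_id[queryHits(hit)],
    feature_class = mcols(annotations)$feature_class[subjectHits(hit)],
    signed_distance = as.integer(d),
    annotation_length = width(annotations)[subjectHits(hit)],
    stringsAsFactors = FALSE
  )
  if (!is.null(mcols(annotations)$percent_gc))
    out$percent_gc <- mcols(annotations)$percent_gc[subjectHits(hit)]
  out
}

#' Compare the positional distribution of a feature class around ME versus
#' control intervals
#'
#' One-way ANOVA of signed midpoint distances with set (ME vs control) as
#' the factor, plus per-set means and upstream/downstream counts and a
#' secondary binomial test of upstream/downstream asymmetry within the ME
#' set.
#'
#' @param meProfiles,controlProfiles Profile data.frames from
#'   [distanceProfile()].
#' @param featureClass Annotation class to compare (e.g. `"LTR"`).
#' @return List with `f`, `df`, `p_value`, per-set summary data.frame, and
#'   `binomial_p` for ME upstream-vs-downstream counts.
#' @export
compareSets <- function(meProfiles, controlProfiles, featureClass) {
  me <- meProfiles[meProfiles$feature_class == featureClass, ]
  ctrl <- controlProfiles[controlProfiles$feature_class == featureClass, ]
  if (nrow(me) < 2) stop("ME set empty or too small for class ", featureClass)
  if (nrow(ctrl) < 2)
    stop("control set empty or too small for class ", featureClass)
  d <- c(me$signed_distance, ctrl$signed_distance)
  set <- factor(c(rep("ME", nrow(me)), rep("control", nrow(ctrl))))
  fit <- aov(d ~ set)
  an <- anova(fit)
  summ <- data.frame(
    set = c("ME", "control"),
    n = c(nrow(me), nrow(ctrl)),
    mean_signed_distance = c(mean(me$signed_distance),
                             mean(ctrl$signed_distance)),
    n_upstream = c(sum(me$signed_distance < 0), sum(ctrl$signed_distance < 0)),
    n_downstream = c(sum(me$signed_distance > 0),
                     sum(ctrl$signed_distance > 0))
  )
  nUp <- sum(me$signed_distance < 0)
  nDown <- sum(me$signed_distance > 0)
  binp <- if (nUp + nDown > 0) binom.test(nUp, nUp + nDown)$p.value else NA_real_
  list(f = an$`F value`[1], df = unname(an$Df), p_value = an$`Pr(>F)`[1],
       summary = summ, binomial_p = binp)
}

#' Compare CGI attributes between ME-associated and control-associated
#' islands
#'
#' One-way ANOVA per attribute (length, distance, percent GC) between the
#' two sets. Attributes missing from the input are skipped with a warning;
#' an attribute with fewer than 2 values per group is an error.
#'
#' @param meCgis,controlCgis CGI profile data.frames from
#'   [distanceProfile()] restricted to `feature_class == "CGI"`.
#' @param attributes Columns to compare (defaults to `annotation_length`,
#'   `signed_distance`, `percent_gc`).
#' @return data.frame `attribute mean_me mean_control f p_value`.
#' @export
cgiFeatureCompare <- function(meCgis, controlCgis,
                              attributes = c("annotation_length",
                                             "signed_distance",
                                             "percent_gc")) {
  res <- lapply(attributes, function(a) {
    if (!a %in% names(meCgis) || !a %in% names(controlCgis)) {
      warning("attribute '", a, "' missing; skipped")
      return(NULL)
    }
    x <- meCgis[[a]]; y <- controlCgis[[a]]
    if (length(x) < 2 || length(y) < 2)
      stop("attribute '", a, "': need >= 2 values per group")
    v <- c(x, y)
    g <- factor(c(rep("ME", length(x)), rep("control", length(y))))
    an <- anova(aov(v ~ g))
    data.frame(attribute = a, mean_me = mean(x), mean_control = mean(y),
               f = an$`F value`[1], p_value = an$`Pr(>F)`[1])
  })
  do.call(rbind, res)
}
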