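#' Kinship coefficient from IBD sharing probabilities
#'
#' `phi = 0.25 * p1 + 0.5 * p2`. An error-free monozygotic pair has
#' `p0 = p1 = 0, p2 = 1` and hence `phi = 0.5`; an unrelated pair has
#' `p0 = 1` and `phi = 0`.
#'
#' @param p0,p1,p2 Probabilities of sharing 0, 1 or 2 alleles identical by
#'   descent; must form a probability vector.
#' @param tol Tolerance on `p0 + p1 + p2 = 1`.
#' @return The kinship coefficient phi.
#' @examples
#' kinshipFromIbd(0, 0, 1)  # monozygotic: 0.5
#' kinshipFromIbd(1, 0, 0)  # unrelated: 0
#' @export
kinshipFromIbd <- function(p0, p1, p2, tol = 1e-6) {
  p <- c(p0, p1, p2)
  if (any(p < -tol | p > 1 + tol)) stop("IBD probabilities must be in [0, 1]")
  if (abs(sum(p) - 1) > tol) stop("IBD probabilities must sum to 1")
  0.25 * p1 + 0.5 * p2
}

.genoToDosage <- function(g) {
  if (is.numeric(g)) {
    if (any(!g %in% c(0, 1, 2) & !is.na(g)))
      stop("numeric genotypes must be allele dosages 0/1/2")
    return(as.numeric(g))
  }
  map <- c(AA = 0, AB = 1, BA = 1, BB = 2)
  out <- unname(map[toupper(g)])
  if (any(is.na(out) & !is.na(g)))
    stop("unrecognized genotype code(s): ",
         paste(unique(g[is.na(out) & !is.na(g)]), collapse = ", "))
  out
}

# P(IBS = s | IBD = k) for a biallelic marker with allele-B frequency p,
# assuming Hardy-Weinberg genotypes and a randomly drawn shared allele.
.ibsGivenIbd <- function(p) {
  q <- 1 - p
  rbind(
    ibd0 = c(2 * p^2 * q^2, 4 * p^3 * q + 4 * p * q^3,
             p^4 + q^4 + 4 * p^2 * q^2),
    ibd1 = c(0, 2 * p * q, p^2 + q^2),
    ibd2 = c(0, 0, 1)
  )
}

# P(g1, g2 | IBD = k) for one biallelic marker (dosages of allele B),
# assuming Hardy-Weinberg genotypes and allele-B frequency p. Rows of the
# result: ibd0, ibd1, ibd2.
.pairLikGivenIbd <- function(g1, g2, p) {
  q <- 1 - p
  gp <- function(g) ifelse(g == 0, q^2, ifelse(g == 1, 2 * p * q, p^2))
  condA <- function(g) ifelse(g == 0, q, ifelse(g == 1, p, 0))
  condB <- function(g) ifelse(g == 0, 0, ifelse(g == 1, q, p))
  l0 <- gp(g1) * gp(g2)
  l1 <- q * condA(g1) * condA(g2) + p * condB(g1) * condB(g2)
  l2 <- gp(g1) * (g1 == g2)
  cbind(ibd0 = l0, ibd1 = l1, ibd2 = l2)
}

#' IBD sharing and kinship estimate for one pair
#'
#' Estimates the probabilities of sharing 0, 1 or 2 alleles identical by
#' descent across a panel of biallelic markers and derives the kinship
#' coefficient `phi = 0.25 p1 + 0.5 p2`. Monomorphic markers (frequency 0
#' or 1) and markers with a missing genotype are excluded with a message.
#'
#' The default (`method = "ml"`) maximizes the mixture likelihood of the
#' observed genotype pairs over the IBD simplex by EM, using the
#' Hardy-Weinberg genotype-pair distribution given each IBD state at the
#' supplied allele frequencies; the constraint is enforced by construction.
#' `method = "moments"` instead solves the identity-by-state (IBS) moment
#' equations in triangular order (p0 from IBS0, p1 from IBS1, p2 by
#' complement) and projects onto the simplex; it is simpler but markedly
#' noisier on small panels, where the projection inflates phi for unrelated
#' pairs.
#'
#' @param genotypes1,genotypes2 Genotype vectors for the two individuals,
#'   as allele-B dosages 0/1/2 or codes `AA`/`AB`/`BB`, parallel to `freqs`.
#' @param freqs Allele-B frequencies per marker, in (0, 1).
#' @param minMarkers Minimum informative markers required (default 10).
#' @param method `"ml"` (default) or `"moments"`.
#' @param tol EM convergence tolerance on the IBD probabilities.
#' @return data.frame `p0 p1 p2 phi n_markers`.
#' @export
estimateIbdPair <- function(genotypes1, genotypes2, freqs, minMarkers = 10,
                            method = c("ml", "moments"), tol = 1e-8) {
  method <- match.arg(method)
  g1 <- .genoToDosage(genotypes1)
  g2 <- .genoToDosage(genotypes2)
  stopifnot(length(g1) == length(g2), length(g1) == length(freqs))
  keep <- !is.na(g1) & !is.na(g2) & freqs > 0 & freqs < 1
  nDrop <- sum(!keep)
  if (nDrop > 0)
    message("excluded ", nDrop, " monomorphic/missing marker(s)")
  g1 <- g1[keep]; g2 <- g2[keep]; p <- freqs[keep]
  m <- length(g1)
  if (m < minMarkers)
    stop("need >= ", minMarkers, " informative co-typed markers (got ", m, ")")
  if (method == "ml") {
    lik <- .pairLikGivenIbd(g1, g2, p)
    pk <- rep(1 / 3, 3)
    for (it in seq_len(1000)) {
      w <- sweep(lik, 2, pk, `*`)
      rs <- rowSums(w)
      if (any(rs == 0)) stop("zero-likelihood genotype pair encountered")
      w <- w / rs
      newp <- colMeans(w)
      done <- max(abs(newp - pk)) < tol
      pk <- newp
      if (done) break
    }
    est <- unname(pk)
  } else {
    ibs <- 2 - abs(g1 - g2)
    obs <- c(mean(ibs == 0), mean(ibs == 1), mean(ibs == 2))
    E <- Reduce(`+`, lapply(p, .ibsGivenIbd)) / m  # rows ibd, cols ibs
    p0 <- obs[1] / E["ibd0", 1]
    p1 <- (obs[2] - p0 * E["ibd0", 2]) / E["ibd1", 2]
    p2 <- 1 - p0 - p1
    est <- c(p0, p1, p2)
    est[est < 0] <- 0
    est <- est / sum(est)
  }
  data.frame(p0 = est[1], p1 = est[2], p2 = est[3],
             phi = kinshipFromIbd(est[1], est[2], est[3]),
             n_markers = m)
}

#' IBD and kinship estimates for a table of pairs
#'
#' @param genotypes Long data.frame `pair_id member marker genotype` with
#'   `member` in `{1, 2}`.
#' @param freqs data.frame `marker freq` of allele-B frequencies.
#' @param minMarkers,method Passed to [estimateIbdPair()].
#' @return data.frame with one row per pair: `pair_id p0 p1 p2 phi
#'   n_markers`.
#' @export
estimateIbdPairs <- function(genotypes, freqs, minMarkers = 10,
                             method = "ml") {
  res <- lapply(split(genotypes, genotypes$pair_id), function(g) {
    g1 <- g[g$member == 1, ]
    g2 <- g[g$member == 2, ]
    mk <- intersect(g1$marker, g2$marker)
    f <- freqs$freq[match(mk, freqs$marker)]
    est <- suppressMessages(estimateIbdPair(
      g1$genotype[match(mk, g1$marker)],
      g2$genotype[match(mk, g2$marker)], f, minMarkers, method = method))
    cbind(pair_id = g$pair_id[1], est)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
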