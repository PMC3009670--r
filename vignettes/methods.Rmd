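---
title: "Screening and validating metastable epialleles: models and design choices"
author: "MEscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and validating metastable epialleles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MEscreen)
```

# The problem

Metastable epialleles (MEs) are loci whose DNA-methylation state is set
stochastically in the very early embryo and then propagated through all
germ-layer lineages. Their hallmark is therefore *systemic* interindividual
variation: two people differ at the locus, but within one person every
tissue agrees. MEscreen implements a complete analysis chain for finding
such loci with a restriction-enzyme microarray screen and validating them
with quantitative methylation, twin, genotype and cohort statistics. All
stages run on synthetic data with known truth, which is how the test suite
exercises them.

# In-silico digest

The screen's unit of analysis is the SmaI/XmaI interval: the span between
two consecutive CCCGGG recognition sites. SmaI cuts bluntly between CCC and
GGG, so fragment length is the difference of cut positions, and the
interval is bounded by the cuts of two *consecutive* sites. The motif is
palindromic, so a single-strand scan suffices; motifs overlapping N never
match, but intervals are allowed to span N runs (otherwise every assembly
gap would silently split a contig). Only fragments of 60–1500 bp, bounds
inclusive, are informative for amplification and retained.

Internally intervals live in `GRanges` (1-based, closed, the native
Bioconductor convention); interval identifiers and all TSV/BED output use
0-based half-open coordinates, so `chr:start-end` ids match BED rows
byte-for-byte. This keeps the in-memory objects idiomatic for R users while
files on disk interoperate with standard genome-arithmetic tools.

# Two-tissue screen

Probe-level inputs are linear two-channel signal ratios (individual 1 over
individual 2) with a per-probe *P* value, in four two-individual
comparisons (A–D) hybridized in parallel in two tissues (PBL, HF), with a
dye swap in one tissue set. The screen:

1. re-orients ratios so dye assignment is transparent (`orientRatios()`,
   an involution);
2. summarizes probes per interval × comparison × tissue: arithmetic mean
   and median of linear ratios, median *P*, probe count ("average signal
   ratio" is read as the arithmetic mean of linear ratios, because the
   thresholds 1.8 and 0.556 are themselves linear; a geometric-mean mode is
   available via `ScreenConfig(geometricMean = TRUE)`);
3. calls a primary hit when, in *both* tissues, the mean ratio clears
   1.8 (or falls below 0.556 = 1/1.8 to three significant figures) on the
   *same side of 1* and the median probe *P* is below 2×10⁻⁴. Directional
   concordance is required even though a literal reading of the threshold
   rule alone would admit opposite-direction passes — an interval methylated
   up in blood and down in hair is precisely *not* systemic;
4. retains a hit only if the PBL:HF ratio of mean ratios lies strictly
   inside (0.445, 2.25) for **all four** comparisons. The upper bound is
   the ratio arising from 1.5 in one tissue and 0.667 in the other; because
   1.5/0.667 = 2.2489 only reaches 2.25 after rounding, the ratio of ratios
   is rounded to three significant figures (`rrDigits = 3`) before the
   strict comparison, so the defining boundary pair is excluded as
   intended. All thresholds are strict inequalities; values exactly on a
   bound fail.

Intervals missing a tissue or a comparison are disqualified rather than
imputed — with only four comparisons there is no basis for imputation, and
silently passing partially observed intervals would inflate the candidate
list. The screen also tabulates interval classes (invariant /
tissue-specific / systemic) from the per-tissue threshold calls, the
summary used to describe how much more often interindividual differences
appear in one tissue than in both.

# Genetic-artifact exclusion

A restriction-based methylation assay also detects genetics: a SNP in a
CCCGGG site abolishes cutting regardless of methylation, a SNP that
*creates* a site inside an interval changes the fragment structure, and
copy-number differences change signal dose. Annotation flags are:

* `disrupts_site` — a variant's position overlaps either flanking 6-bp
  motif. This is deliberately positional (SNP-track style) rather than
  checking that the alternate allele destroys the motif: any allele at a
  motif position is suspect, and the positional rule is strictly more
  conservative.
* `creates_site` — substituting the alternate allele yields a CCCGGG match
  in the 11-bp window around the variant that is absent from the reference,
  with the new cut strictly inside the interval body.
* `in_cnv` / `in_segdup` — ≥1 bp overlap with a CNV or segmental
  duplication. "Within" is ambiguous for long regions; any-overlap is the
  default and full containment is a switch (`containment = "full"`).

The cascade removes SNP-flagged candidates first, then structural overlaps,
and re-adds allow-listed loci whose methylation variation was validated
independently before filtering (mirroring the retention of two such loci in
the original candidate list: one with a site SNP, one inside a CNV). The
cascade is idempotent, and on synthetic data it removes 100% of
truth-flagged artifact loci and no clean locus. Flag enrichment among hits
is tested by Pearson chi-square on the 2×2 (hits vs non-hits) × (flagged vs
unflagged) table; the background defaults to the full interval universe
containing the hits, with no continuity correction (switchable). Published
enrichment *P* values of this kind are reproducible only to order of
magnitude because the exact background set behind them is not stated.

# Genomic context

`distanceProfile()` records every annotation (CpG island or repeat class)
whose midpoint lies within ±3000 bp of an interval midpoint, as a signed
distance (negative = lower coordinate = upstream; the intervals are
unstranded, so "upstream" is a pure coordinate convention). Midpoints are
`floor((start + end)/2)` in 0-based coordinates; a nearest-edge reference
is available. ME-vs-control positional differences are tested by one-way
ANOVA on signed distances — the literal reading of an
"analysis-of-variance" comparison of annotation positions — with a
binomial upstream/downstream test reported alongside as a
distribution-free check.

# Validation statistics

Replicate measurements are always averaged per individual before
correlation, matching how repeated pyrosequencing measurements are handled
in practice. Inter-tissue correlation is Pearson's *r* over individual
means with a two-sided *P*. Twin concordance correlates co-twin values with
member order randomized under a caller-supplied seed (the natural pairing
has no intrinsic order; double entry of each pair in both orders is
available as `method = "double_entry"`); the comparison value is the
correlation between independent technical replicate pairs. The "nonshared
variance fraction" is *defined* as 1 − intra-pair *r*, clipped to [0, 1] —
a declared operationalization, since clipping is needed whenever sampling
noise pushes *r* outside the unit interval. Genotype association is one-way
ANOVA with *R²* = SS(between)/SS(total); population comparison reports
median, quartiles and 5th–95th percentiles per population.

# Season-of-conception model

Percent methylation is arcsine transformed, `asin(sqrt(p/100))` — the
standard variance-stabilizer for proportions (the alternative reading
`asin(p)` is not defined for percent inputs above 1 and was rejected).
The REML linear mixed model is

```
asin(sqrt(p/100)) ~ season * locus_type + (1 | individual) + (1 | locus)
```

with locus nested in locus type by construction (locus labels are unique),
individual and locus as random intercepts, and season × locus-type as the
single a-priori interaction. The season effect is reported separately
within ME and within control loci via estimated-marginal-means contrasts
with Satterthwaite degrees of freedom, both on the arcsine scale and
back-transformed to percentage points (difference of back-transformed
season means). A per-locus table gives season group means, back-transformed
mean differences and Welch *t* *P* values — the per-locus view in which
double-digit increments at individual loci are visible even when the
within-type average is smaller. Variance components are reported on the
arcsine scale and, via the delta method at the grand mean
(d/dθ of 100·sin²θ = 100·sin 2θ), in percentage points.

Normality is screened per locus × season cell by Shapiro–Wilk with Holm's
step-down procedure ("sequential Bonferroni" in the classical
terminology) at family-wise α = 0.05. The season × year interaction screen
adds year and season × year as fixed effects to the same mixed model and
automates the identification of an aberrant year by leave-one-year-out:
the year whose removal maximizes the interaction *P* is recommended for
exclusion. Years missing a season are flagged, never silently dropped.
Non-convergence of the optimizer is an explicit error with the optimizer
diagnostics attached; there is no silent fallback.

# Kinship estimator

Putative MZ twin pairs are verified on a 48-SNP panel. For each pair the
package estimates the IBD-sharing probabilities (p0, p1, p2) and reports
the kinship coefficient φ = 0.25·p1 + 0.5·p2, with φ = 0.5 expected for
error-free MZ duplicates and φ = 0 for unrelated pairs.

The default estimator maximizes the mixture likelihood of the observed
genotype pairs over the IBD simplex by EM, using the Hardy–Weinberg
genotype-pair distribution given each IBD state at the supplied allele
frequencies. A triangular method-of-moments estimator on identity-by-state
counts (p0 from IBS0, p1 from IBS1, p2 by complement, projected onto the
simplex) is included as `method = "moments"`, but it is not the default
for a measured reason: with only 48 markers the IBS0 moment equation is
extremely noisy (IBS0 is a rare event), and projecting the noisy estimate
onto the simplex corner inflates mean φ for truly unrelated pairs to
≈ 0.07. The genotype-pair likelihood uses strictly more information than
the IBS collapse, concentrates the estimate near the corner, and brings
the unrelated-pair bias under 0.05 (duplicate pairs are recovered at
φ = 0.5 exactly in either method). Monomorphic and missing markers are
excluded; fewer than 10 informative markers is an error.

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of `(parameters, seed)` and emit
ground-truth tables sufficient to score every downstream call.

* `simGenome()` plants motifs into scrubbed random background so the
  digest must recover exactly the requested eligible intervals among
  sub-60 bp and >1500 bp decoys.
* `simMsam()` draws per-probe channel log-intensities (4 replicates per
  channel, Gaussian noise, sd 0.1) so that probe ratios are lognormal
  around the planted class contrast and probe *P* values come from a real
  two-sample *t* statistic — uniform under the null, which is what makes
  the null false-positive-rate property meaningful. Class structure
  follows the observed biology: tissue-specific differences (default 6:1
  over systemic), systemic ME loci with the same latent contrast in both
  tissues, artifact classes for the exclusion cascade, ~2.3 probes per
  interval (1 + Poisson(1.3)), dye swap applied in the HF set.
* `simCohort()` defaults *are* the study conditions: ME increments
  {12, 12, 6, 6, 6} percentage points (the two largest at PAX8 and
  ZFYVE28), zero at the four control loci, individual sd 5, locus sd 8,
  residual sd 3, n = 25 per season over conception years
  1991/1994/1995/1998, with an optional aberrant year whose increment is
  reversed for interaction-screen testing. Values are generated additively
  on the percent scale and clipped to [0, 100] with a logged count
  (warning above 1% clipped).
* `simTwins()` draws latent co-twin values bivariate-normally at the
  stated intra-pair correlation (default 0.5, biological sd 10) plus
  technical replicates (sd 1), reproducing the ordering technical *r* >
  intra-pair *r*.
* `simGenotypePanel()` draws Hardy–Weinberg genotypes at MAF 0.3 and
  duplicates MZ pairs, with per-genotype error flips applied to the
  duplicated copy (so the expected discordant-marker count is
  48 × error rate).

What the generators do **not** emulate: spatial probe effects and
normalization artifacts on real arrays, linkage disequilibrium among the
48 markers, bisulfite-conversion failure, U-shaped interindividual
methylation distributions in their full generality (latent states are
Gaussian by default), or population structure. Passing tests therefore
demonstrate that the *statistical machinery* behaves as specified under
the declared data-generating process — not that any particular biological
dataset would yield particular candidate counts, which additionally depend
on how upstream feature extraction computes probe-level *P* values.

# Numerical choices and problem sizes

* All screen threshold comparisons are strict; the ratio of ratios is
  rounded to 3 significant figures before comparison (see above).
* REML fits use lme4's default optimizer; convergence failures raise
  errors. Occasional gradient-check warnings on null simulations are
  tolerated as long as the optimizer reports success.
* The EM kinship estimator iterates to 1e-8 on the IBD probabilities.
* The test suite sizes its simulations to what the properties need:
  digest-oracle equivalence on a 1 Mb random sequence; screen false-positive
  rate on twenty 19,000-interval null arrays and recall on twenty
  2,000-interval arrays with 20 planted systemic loci each; 500 null cohort
  replicates for type-I calibration, 40 for power, 60 for effect-size bias;
  500 simulated pairs each for unrelated and duplicate kinship bias.

# Known limitations

* Candidate counts on real arrays depend on the unspecified origin of
  probe-level *P* values and are not reproduced here; the screen consumes
  them as input.
* Enrichment and context-asymmetry *P* values depend on annotation tracks
  and background sets; the package reproduces the statistics, not specific
  published magnitudes.
* "Upstream/downstream" for unstranded intervals is coordinate-based only.
* The variance-partition reading of twin discordance (1 − intra-pair *r*)
  is a declared definition, one of several defensible choices.
* Indels, multi-allelic variants and haplotype-aware logic are out of
  scope; the recognition motif is palindromic, so variant logic is
  strand-free.
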