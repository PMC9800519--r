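#' @import methods
NULL

.SUMSTAT_COLS <- c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta", "se",
                   "pval", "n")

#' SumStats: GWAS summary statistics for one trait
#'
#' One row per variant: identifier, genomic location (1-based), effect and
#' other allele, effect-allele frequency, per-allele effect estimate with its
#' standard error, p-value and sample size. All instrument selection,
#' harmonization and MR estimation in this package starts from objects of
#' this class.
#'
#' @slot traitLabel single character, the trait/cohort name.
#' @slot records data.frame with columns `snp`, `chrom`, `pos`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `pval`, `n`. `eaf` and `n` may be `NA`.
#' @slot source free-form provenance string (consortium, ancestry, ...).
#' @slot parseReport list describing how the object was parsed from disk
#'   (row counts and per-reason drop counts); empty for programmatically
#'   built objects.
#'
#' @seealso [readSumStats()], [sumStats()], [selectInstruments()]
#' @exportClass SumStats
setClass("SumStats",
         representation(traitLabel = "character",
                        records    = "data.frame",
                        source     = "character",
                        parseReport = "list"),
         prototype(traitLabel = "", source = "", parseReport = list()))

setValidity("SumStats", function(object) {
  msg <- character()
  r <- object@records
  if (!all(.SUMSTAT_COLS %in% names(r)))
    return(paste("records must contain columns:",
                 paste(setdiff(.SUMSTAT_COLS, names(r)), collapse = ", ")))
  if (length(object@traitLabel) != 1L)
    msg <- c(msg, "traitLabel must be a single string")
  if (anyDuplicated(r$snp))
    msg <- c(msg, "snp identifiers must be unique")
  if (nrow(r)) {
    if (any(!is.finite(r$se) | r$se <= 0))
      msg <- c(msg, "all se must be finite and > 0")
    if (any(r$ea == r$oa))
      msg <- c(msg, "effect and other allele must differ")
    bad_eaf <- !is.na(r$eaf) & (r$eaf < 0 | r$eaf > 1)
    if (any(bad_eaf)) msg <- c(msg, "eaf must lie in [0, 1]")
    if (any(!is.finite(r$pval) | r$pval <= 0 | r$pval > 1))
      msg <- c(msg, "pval must lie in (0, 1]")
    if (any(!is.finite(r$beta)))
      msg <- c(msg, "beta must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' LDTable: precomputed pairwise linkage disequilibrium
#'
#' Sparse symmetric table of pairwise r-squared values. A pair absent from
#' the table is treated as r-squared = 0 (independent); the diagonal is never
#' stored. Clumping consumes this table; the package never computes LD from
#' genotypes.
#'
#' @slot pairs data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @seealso [ldTable()], [readLDTable()], [clumpVariants()]
#' @exportClass LDTable
setClass("LDTable",
         representation(pairs = "data.frame"),
         prototype(pairs = data.frame(snp_a = character(),
                                      snp_b = character(),
                                      r2 = numeric())))

setValidity("LDTable", function(object) {
  p <- object@pairs
  if (!all(c("snp_a", "snp_b", "r2") %in% names(p)))
    return("pairs must have columns snp_a, snp_b, r2")
  if (nrow(p)) {
    if (any(!is.finite(p$r2) | p$r2 < 0 | p$r2 > 1))
      return("r2 must lie in [0, 1]")
    if (any(p$snp_a == p$snp_b))
      return("self pairs must not be stored")
  }
  TRUE
})

#' InstrumentSet: the selected instrumental variables for one trait
#'
#' @slot snpIds character, index SNPs ordered by ascending p-value.
#' @slot selectionParams list with `pThreshold`, `r2Threshold`, `windowBp`,
#'   `minVariants`.
#' @slot perSnpF named numeric, per-SNP F-statistic (beta/se)^2.
#' @seealso [selectInstruments()]
#' @exportClass InstrumentSet
setClass("InstrumentSet",
         representation(snpIds = "character",
                        selectionParams = "list",
                        perSnpF = "numeric"))

#' HarmonizedPairs: allele-aligned effects across two or more studies
#'
#' Per retained SNP, the effect and standard error in each exposure study
#' (one column of `betaX`/`seX` per exposure; the first exposure is the
#' alignment reference) and in the outcome study. SNPs that could not be
#' aligned are listed in `dropped` with a reason. This is the input type of
#' every MR estimator in the package.
#'
#' @slot snp character, retained SNP identifiers.
#' @slot betaX,seX numeric matrices (SNP x exposure), columns named by
#'   exposure trait label.
#' @slot betaY,seY numeric vectors, outcome effects aligned to the reference
#'   effect allele.
#' @slot exposures,outcome trait labels.
#' @slot dropped data.frame with columns `snp_id`, `reason`.
#' @seealso [harmonize()], [mrIVW()], [mvmrFit()]
#' @exportClass HarmonizedPairs
setClass("HarmonizedPairs",
         representation(snp = "character",
                        betaX = "matrix", seX = "matrix",
                        betaY = "numeric", seY = "numeric",
                        exposures = "character", outcome = "character",
                        dropped = "data.frame"))

setValidity("HarmonizedPairs", function(object) {
  msg <- character()
  j <- length(object@snp)
  if (nrow(object@betaX) != j || nrow(object@seX) != j ||
      length(object@betaY) != j || length(object@seY) != j)
    msg <- c(msg, "betaX/seX/betaY/seY must all have one entry per SNP")
  if (!identical(dim(object@betaX), dim(object@seX)))
    msg <- c(msg, "betaX and seX must have identical dimensions")
  if (ncol(object@betaX) != length(object@exposures))
    msg <- c(msg, "one betaX column per exposure required")
  if (anyDuplicated(object@snp))
    msg <- c(msg, "snp identifiers must be unique")
  if (j && any(!is.finite(object@seY) | object@seY <= 0))
    msg <- c(msg, "outcome standard errors must be positive")
  if (!all(c("snp_id", "reason") %in% names(object@dropped)))
    msg <- c(msg, "dropped must have columns snp_id, reason")
  if (length(msg)) msg else TRUE
})

#' MREstimate: a single causal-effect estimate
#'
#' @slot method one of "IVW", "Egger", "WeightedMedian", "Ratio", "MVMR".
#' @slot beta causal effect (outcome units per exposure unit).
#' @slot se standard error of `beta`.
#' @slot ciLow,ciHigh 95% confidence bounds.
#' @slot pval two-sided p-value.
#' @slot nSnp number of SNPs the estimate is based on.
#' @exportClass MREstimate
setClass("MREstimate",
         representation(method = "character", beta = "numeric",
                        se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                        pval = "numeric", nSnp = "integer"))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (is.finite(object@ciLow) && is.finite(object@ciHigh) &&
      object@ciLow >= object@ciHigh)
    msg <- c(msg, "ciLow must be below ciHigh")
  if (is.finite(object@pval) && (object@pval <= 0 || object@pval > 1))
    msg <- c(msg, "pval must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' IVWResult: inverse-variance-weighted estimate plus heterogeneity
#'
#' @slot estimate the [MREstimate-class] for the causal effect.
#' @slot model "fixed" or "multiplicative_random".
#' @slot Q Cochran's Q heterogeneity statistic.
#' @slot df degrees of freedom (number of SNPs minus one).
#' @slot QPval upper-tail chi-square p-value for Q.
#' @exportClass IVWResult
setClass("IVWResult",
         representation(estimate = "MREstimate", model = "character",
                        Q = "numeric", df = "integer", QPval = "numeric"))

#' EggerResult: MR-Egger slope and pleiotropy intercept test
#'
#' @slot slope [MREstimate-class] for the causal slope.
#' @slot interceptEst,interceptSE,interceptP the intercept estimate, its
#'   standard error and two-sided t p-value; a nonzero intercept indicates
#'   directional horizontal pleiotropy.
#' @slot residualScale multiplicative standard-error inflation actually
#'   applied, `max(1, sqrt(RSS/(J-2)))`.
#' @exportClass EggerResult
setClass("EggerResult",
         representation(slope = "MREstimate",
                        interceptEst = "numeric", interceptSE = "numeric",
                        interceptP = "numeric", residualScale = "numeric"))

#' PressoResult: MR-PRESSO global and outlier test
#'
#' @slot globalRSS observed leave-one-out weighted residual sum of squares.
#' @slot globalPval add-one Monte-Carlo p-value of the global test.
#' @slot outlierSnps SNPs flagged at the Bonferroni-adjusted level.
#' @slot corrected IVW [MREstimate-class] after removing flagged SNPs.
#' @slot nSim,seed simulation count and seed used.
#' @exportClass PressoResult
setClass("PressoResult",
         representation(globalRSS = "numeric", globalPval = "numeric",
                        outlierSnps = "character", corrected = "MREstimate",
                        nSim = "integer", seed = "integer"))

#' MVMRResult: multivariable MR fit
#'
#' @slot estimates named list of [MREstimate-class], one per exposure; each
#'   beta is the effect of that exposure on the outcome conditional on the
#'   other exposures.
#' @slot conditionalF named numeric, conditional F-statistic per exposure.
#' @slot residualScale multiplicative SE inflation, `max(1, sqrt(RSS/(J-K)))`.
#' @slot nSnp number of SNPs in the joint fit.
#' @exportClass MVMRResult
setClass("MVMRResult",
         representation(estimates = "list", conditionalF = "numeric",
                        residualScale = "numeric", nSnp = "integer"))

setValidity("MVMRResult", function(object) {
  if (length(object@estimates) != length(object@conditionalF))
    return("one conditional F per exposure estimate required")
  TRUE
})

#' MediationResult: two-step MR effect decomposition for one trait
#'
#' Total effect (univariable trait to outcome), the two mediation-path
#' coefficients (trait to mediator; mediator to outcome adjusted for the
#' trait), the direct effect (trait coefficient of the same multivariable
#' fit), the indirect effect as their product with a Sobel (delta-method)
#' standard error, and the mediation proportion indirect/total.
#'
#' @slot traitLabel trait name.
#' @slot total,beta1,direct,beta2 [MREstimate-class] objects (see above).
#' @slot indirect,indirectSE product-of-coefficients estimate and Sobel SE.
#' @slot indirectP two-sided normal p-value for the indirect effect.
#' @slot proportion indirect/total as a fraction (NA when undefined).
#' @slot proportionDefined FALSE when |total| is below machine tolerance.
#' @slot directionConsistent TRUE when the indirect effect has the sign of
#'   the total effect (zero indirect counts as consistent).
#' @slot conditionalF named numeric from the multivariable fit.
#' @exportClass MediationResult
setClass("MediationResult",
         representation(traitLabel = "character",
                        total = "MREstimate", beta1 = "MREstimate",
                        direct = "MREstimate", beta2 = "MREstimate",
                        indirect = "numeric", indirectSE = "numeric",
                        indirectP = "numeric",
                        proportion = "numeric",
                        proportionDefined = "logical",
                        directionConsistent = "logical",
                        conditionalF = "numeric"))

#' SimConfig: parameters of the synthetic three-cohort GWAS generator
#'
#' Encodes a linear structural model exposure -> mediator -> outcome with
#' per-SNP effects, optional invalid (pleiotropic) instruments and analytic
#' per-SNP sampling noise; see [simulateSummaryStats()].
#'
#' @slot nSnpExposure,nSnpMediator,nNullSnps SNP counts: causal for the
#'   exposure, causal for the mediator only, and null background.
#' @slot mafRange interval in (0, 0.5] for uniform minor-allele frequencies.
#' @slot gammaSd,deltaSd SD of per-SNP exposure effects / mediator-only
#'   effects.
#' @slot alpha exposure -> mediator effect.
#' @slot betaM mediator -> outcome effect.
#' @slot tauPrime direct exposure -> outcome effect.
#' @slot nX,nM,nY cohort sample sizes (non-overlapping cohorts).
#' @slot fractionInvalid,etaMean,etaSd pleiotropy: fraction of exposure SNPs
#'   given a direct SNP -> outcome effect drawn N(etaMean, etaSd^2).
#' @slot palindromeStress inject A/T SNPs with cross-cohort EAF jitter to
#'   exercise harmonization.
#' @slot seed RNG seed; identical config + seed gives bit-identical output.
#' @exportClass SimConfig
setClass("SimConfig",
         representation(nSnpExposure = "integer", nSnpMediator = "integer",
                        nNullSnps = "integer", mafRange = "numeric",
                        gammaSd = "numeric", deltaSd = "numeric",
                        alpha = "numeric", betaM = "numeric",
                        tauPrime = "numeric",
                        nX = "numeric", nM = "numeric", nY = "numeric",
                        fractionInvalid = "numeric", etaMean = "numeric",
                        etaSd = "numeric", palindromeStress = "logical",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSnpExposure <= 0L || object@nSnpMediator <= 0L)
    msg <- c(msg, "SNP counts must be positive")
  if (object@nNullSnps < 0L)
    msg <- c(msg, "nNullSnps must be non-negative")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be an interval within (0, 0.5]")
  if (object@fractionInvalid < 0 || object@fractionInvalid > 1)
    msg <- c(msg, "fractionInvalid must lie in [0, 1]")
  if (any(c(object@nX, object@nM, object@nY) <= 0))
    msg <- c(msg, "cohort sizes must be positive")
  if (object@gammaSd <= 0 || object@deltaSd <= 0)
    msg <- c(msg, "effect-size SDs must be positive")
  if (length(msg)) msg else TRUE
})

#' SimTruth: generating parameters of a synthetic dataset
#'
#' The estimands of the mediation decomposition under the generating model:
#' direct = tauPrime, indirect = alpha * betaM, total = direct + indirect
#' (exactly), proportion = indirect/total, plus the per-SNP true effect
#' triples used by parameter-recovery tests.
#'
#' @slot total,direct,indirect,proportion the generating-model effects.
#' @slot perSnp data.frame with columns `snp`, `class`, `trueX`, `trueM`,
#'   `trueY`.
#' @exportClass SimTruth
setClass("SimTruth",
         representation(total = "numeric", direct = "numeric",
                        indirect = "numeric", proportion = "numeric",
                        perSnp = "data.frame"))

setValidity("SimTruth", function(object) {
  if (abs(object@total - (object@direct + object@indirect)) > 1e-12)
    return("total must equal direct + indirect exactly")
  TRUE
})
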