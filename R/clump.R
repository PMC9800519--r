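#' @include AllClasses.R sumstats-io.R
NULL

#' Greedy LD clumping
#'
#' Standard p-value-ordered greedy pruning: repeatedly take the unremoved
#' variant with the smallest p-value as an index SNP (ties broken by
#' chromosome, position, then identifier — the output is invariant to input
#' row order), then remove every variant on the same chromosome within
#' `windowBp` basepairs of it whose pairwise r-squared with the index is at
#' least `r2Threshold`. Pairs absent from the LD table count as r-squared 0,
#' so an empty table keeps every variant.
#'
#' @param stats a [SumStats-class] object with chromosome/position filled in.
#' @param ld an [LDTable-class] object.
#' @param r2Threshold r-squared above/at which a neighbour is removed
#'   (default 0.001).
#' @param windowBp window, in basepairs, around the index SNP within which
#'   LD is considered (`|pos - pos_index| <= windowBp`; default 1e7, i.e.
#'   10 Mb).
#' @return character vector of index SNP ids, ordered by ascending p-value.
#' @export
clumpVariants <- function(stats, ld, r2Threshold = 0.001, windowBp = 1e7) {
  stopifnot(r2Threshold > 0, r2Threshold <= 1, windowBp > 0)
  r <- records(stats)
  if (!nrow(r)) return(character())
  if (any(is.na(r$chrom) | is.na(r$pos)))
    stop("clumping requires chromosome and position for every variant")

  ord <- order(r$pval, r$chrom, r$pos, r$snp)
  r <- r[ord, , drop = FALSE]
  pos <- stats::setNames(r$pos, r$snp)
  chrom <- stats::setNames(r$chrom, r$snp)

  # adjacency restricted to pairs actually stored in the LD table
  p <- ld@pairs
  p <- p[p$r2 >= r2Threshold &
           (p$snp_a %in% r$snp) & (p$snp_b %in% r$snp), , drop = FALSE]
  partners <- list()
  if (nrow(p)) {
    partners <- split(c(p$snp_b, p$snp_a), c(p$snp_a, p$snp_b))
  }

  active <- stats::setNames(rep(TRUE, nrow(r)), r$snp)
  keep <- character()
  for (s in r$snp) {
    if (!active[[s]]) next
    keep <- c(keep, s)
    active[[s]] <- FALSE
    nb <- partners[[s]]
    if (length(nb)) {
      hit <- nb[chrom[nb] == chrom[[s]] &
                  abs(pos[nb] - pos[[s]]) <= windowBp]
      active[hit] <- FALSE
    }
  }
  keep
}

#' Per-SNP instrument-strength F-statistic
#'
#' The conventional single-SNP strength screen `F = (beta/se)^2`.
#'
#' @param beta,se per-allele effect and its standard error (`se > 0`);
#'   vectorized.
#' @return numeric F values.
#' @export
#' @examples
#' perSnpF(0.1, 0.02)   # 25
perSnpF <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Select instrumental variables for a trait
#'
#' Applies the instrument-selection criteria used throughout the package:
#' genome-wide significance (`pval < pThreshold`), the biallelic-SNP rule
#' (both alleles single nucleotides among A/C/G/T, which excludes indels),
#' and LD independence via [clumpVariants()]. When fewer than `minVariants`
#' index SNPs survive, a classed condition `insufficientInstruments`
#' carrying the surviving count is signalled — this is the trait-exclusion
#' rule of the screening stage, catchable with
#' `tryCatch(..., insufficientInstruments = )`.
#'
#' @inheritParams clumpVariants
#' @param pThreshold significance threshold (default 5e-8).
#' @param minVariants minimum number of surviving index SNPs (default 10).
#' @return an [InstrumentSet-class] with per-SNP F-statistics.
#' @export
selectInstruments <- function(stats, ld, pThreshold = 5e-8,
                              r2Threshold = 0.001, windowBp = 1e7,
                              minVariants = 10) {
  r <- records(stats)
  biallelic <- grepl("^[ACGT]$", r$ea) & grepl("^[ACGT]$", r$oa)
  pass <- r$pval < pThreshold & biallelic
  sub <- subsetSnps(stats, r$snp[pass])
  idx <- clumpVariants(sub, ld, r2Threshold, windowBp)
  if (length(idx) < minVariants)
    stop(insufficientInstruments(traitLabel(stats), length(idx), minVariants))
  rr <- records(sub)
  rr <- rr[match(idx, rr$snp), ]
  new("InstrumentSet",
      snpIds = idx,
      selectionParams = list(pThreshold = pThreshold,
                             r2Threshold = r2Threshold,
                             windowBp = windowBp,
                             minVariants = minVariants),
      perSnpF = stats::setNames(perSnpF(rr$beta, rr$se), idx))
}

#' @rdname selectInstruments
#' @param trait trait label for the condition message.
#' @param count number of surviving variants.
#' @return `insufficientInstruments` returns the condition object itself
#'   (of classes `insufficientInstruments`, `error`, `condition`).
#' @export
insufficientInstruments <- function(trait, count, minVariants) {
  structure(
    class = c("insufficientInstruments", "error", "condition"),
    list(message = sprintf(
      "trait '%s': only %d independent genome-wide-significant variant(s), fewer than the required %d",
      trait, count, minVariants),
      call = NULL, trait = trait, count = count))
}
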