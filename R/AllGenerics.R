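#' @include AllClasses.R
NULL

#' Accessors for mrmediate objects
#'
#' Small accessor generics used across the package: `traitLabel` returns the
#' trait name of a [SumStats-class] object, `records` its per-SNP table,
#' `nVariants` its row count; `snpIds` returns the variant identifiers of an
#' [InstrumentSet-class] or [HarmonizedPairs-class]; `nSnp` the number of
#' retained SNPs of a [HarmonizedPairs-class] or the SNP count behind an
#' [MREstimate-class]; `droppedSnps` the drop report of a harmonization.
#'
#' @param x an mrmediate object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases traitLabel records nVariants snpIds nSnp droppedSnps
NULL

#' @rdname accessors
#' @export
setGeneric("traitLabel", function(x) standardGeneric("traitLabel"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))
#' @rdname accessors
#' @export
setGeneric("droppedSnps", function(x) standardGeneric("droppedSnps"))

setMethod("traitLabel", "SumStats", function(x) x@traitLabel)
setMethod("records", "SumStats", function(x) x@records)
setMethod("nVariants", "SumStats", function(x) nrow(x@records))
setMethod("snpIds", "SumStats", function(x) x@records$snp)
setMethod("snpIds", "InstrumentSet", function(x) x@snpIds)
setMethod("snpIds", "HarmonizedPairs", function(x) x@snp)
setMethod("nSnp", "HarmonizedPairs", function(x) length(x@snp))
setMethod("nSnp", "MREstimate", function(x) x@nSnp)
setMethod("droppedSnps", "HarmonizedPairs", function(x) x@dropped)

#' Subset harmonized pairs by SNP
#'
#' @param x a [HarmonizedPairs-class] object.
#' @param i integer, logical or character (SNP id) index.
#' @param j,... ignored.
#' @param drop ignored.
#' @return a [HarmonizedPairs-class] with the selected SNPs.
#' @export
setMethod("[", "HarmonizedPairs", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@snp)
  new("HarmonizedPairs",
      snp = x@snp[i],
      betaX = x@betaX[i, , drop = FALSE],
      seX = x@seX[i, , drop = FALSE],
      betaY = x@betaY[i], seY = x@seY[i],
      exposures = x@exposures, outcome = x@outcome,
      dropped = x@dropped)
})

setMethod("show", "SumStats", function(object) {
  cat("SumStats object\n",
      "  trait:    ", object@traitLabel, "\n",
      "  variants: ", nrow(object@records), "\n", sep = "")
  if (nzchar(object@source)) cat("  source:   ", object@source, "\n", sep = "")
  if (length(object@parseReport))
    cat("  parsed:   ", object@parseReport$nValid, "valid /",
        object@parseReport$nRows, "rows\n")
})

setMethod("show", "HarmonizedPairs", function(object) {
  cat("HarmonizedPairs object\n",
      "  exposures: ", paste(object@exposures, collapse = ", "), "\n",
      "  outcome:   ", object@outcome, "\n",
      "  retained:  ", length(object@snp), " SNPs\n",
      "  dropped:   ", nrow(object@dropped), " SNPs\n", sep = "")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("MREstimate [%s]  beta = %.4g (se %.3g), 95%% CI [%.4g, %.4g], p = %.3g, nSNP = %d\n",
              object@method, object@beta, object@se, object@ciLow,
              object@ciHigh, object@pval, object@nSnp))
})

setMethod("show", "IVWResult", function(object) {
  show(object@estimate)
  cat(sprintf("  model %s; Q = %.4g on %d df (p = %.3g)\n",
              object@model, object@Q, object@df, object@QPval))
})

setMethod("show", "EggerResult", function(object) {
  show(object@slope)
  cat(sprintf("  intercept = %.4g (se %.3g), p = %.3g\n",
              object@interceptEst, object@interceptSE, object@interceptP))
})

setMethod("show", "MVMRResult", function(object) {
  cat("MVMRResult (", object@nSnp, " SNPs)\n", sep = "")
  for (lab in names(object@estimates)) {
    e <- object@estimates[[lab]]
    cat(sprintf("  %-20s beta = %.4g (se %.3g), p = %.3g, cond. F = %.3g\n",
                lab, e@beta, e@se, e@pval, object@conditionalF[[lab]]))
  }
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult:", object@traitLabel, "\n")
  cat(sprintf("  total    = %.4g (se %.3g)\n", object@total@beta, object@total@se))
  cat(sprintf("  direct   = %.4g (se %.3g)\n", object@direct@beta, object@direct@se))
  cat(sprintf("  indirect = %.4g (Sobel se %.3g, p = %.3g)\n",
              object@indirect, object@indirectSE, object@indirectP))
  if (object@proportionDefined)
    cat(sprintf("  proportion mediated = %.1f%%%s\n", 100 * object@proportion,
                if (!object@directionConsistent) "  [direction-inconsistent]" else ""))
  else cat("  proportion mediated: undefined (|total| ~ 0)\n")
})
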