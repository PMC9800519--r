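#' @include AllClasses.R uvmr.R presso.R
NULL

#' Export scatter- and funnel-plot data
#'
#' Produces the plain tables needed to redraw the standard MR diagnostic
#' figure pair: a scatter table of per-SNP exposure/outcome effects with
#' fitted lines per estimator (slope through the origin for IVW and the
#' weighted median; slope plus intercept for Egger), and a funnel table of
#' per-SNP ratio estimates against their precision `1/se`. Drawing itself is
#' left to the caller.
#'
#' @param pairs a single-exposure [HarmonizedPairs-class].
#' @param estimates list of [IVWResult-class], [EggerResult-class] and/or
#'   [MREstimate-class] objects.
#' @return list with data.frames `scatter` (snp, betaX, seX, betaY, seY),
#'   `lines` (method, slope, intercept) and `funnel` (snp, ratio,
#'   precision).
#' @export
exportPlotData <- function(pairs, estimates) {
  if (!length(estimates)) stop("at least one estimate is required")
  lines <- do.call(rbind, lapply(estimates, function(e) {
    if (is(e, "IVWResult"))
      data.frame(method = "IVW", slope = e@estimate@beta, intercept = 0)
    else if (is(e, "EggerResult"))
      data.frame(method = "Egger", slope = e@slope@beta,
                 intercept = e@interceptEst)
    else data.frame(method = e@method, slope = e@beta, intercept = 0)
  }))
  rat <- ratioEstimates(pairs)
  list(scatter = data.frame(snp = pairs@snp, betaX = pairs@betaX[, 1],
                            seX = pairs@seX[, 1], betaY = pairs@betaY,
                            seY = pairs@seY, stringsAsFactors = FALSE),
       lines = lines,
       funnel = data.frame(snp = rat$snp, ratio = rat$ratio,
                           precision = 1 / rat$se,
                           stringsAsFactors = FALSE))
}

.estimate_as_list <- function(e) {
  list(method = e@method, beta = e@beta, se = e@se, ci_low = e@ciLow,
       ci_high = e@ciHigh, pval = e@pval, n_snp = e@nSnp)
}

#' Full univariable MR report for one exposure-outcome pair
#'
#' Runs the complete univariable battery on one pair of studies: instrument
#' selection, harmonization, IVW (with Cochran's Q), MR-Egger with the
#' intercept pleiotropy test, weighted median, leave-one-out flags and
#' MR-PRESSO. Deterministic given `seed`.
#'
#' @param exposure,outcome [SumStats-class] objects.
#' @param ld an [LDTable-class].
#' @param pThreshold,r2Threshold,windowBp,minVariants instrument-selection
#'   parameters, as in [selectInstruments()].
#' @param palindromeMafLimit passed to [harmonize()].
#' @param nBoot weighted-median bootstrap replicates.
#' @param nSim MR-PRESSO simulation count.
#' @param seed RNG seed recorded in the report.
#' @return a nested list (the report), serializable with
#'   [writeUvmrReport()].
#' @export
uvmrReport <- function(exposure, outcome, ld = ldTable(),
                       pThreshold = 5e-8, r2Threshold = 0.001,
                       windowBp = 1e7, minVariants = 10,
                       palindromeMafLimit = 0.30,
                       nBoot = 1000, nSim = 1000, seed = 1) {
  inst <- selectInstruments(exposure, ld, pThreshold, r2Threshold,
                            windowBp, minVariants)
  pairs <- harmonize(subsetSnps(exposure, snpIds(inst)), outcome,
                     palindromeMafLimit = palindromeMafLimit)
  ivw <- mrIVW(pairs)
  egger <- mrEgger(pairs)
  wm <- mrWeightedMedian(pairs, nBoot = nBoot, seed = seed)
  loo <- leaveOneOut(pairs)
  presso <- mrPresso(pairs, nSim = nSim, seed = seed)
  list(
    exposure = traitLabel(exposure), outcome = traitLabel(outcome),
    params = list(p_threshold = pThreshold, r2_threshold = r2Threshold,
                  window_bp = windowBp, min_variants = minVariants,
                  palindrome_maf_limit = palindromeMafLimit,
                  n_boot = nBoot, n_sim = nSim, seed = seed),
    n_instruments = length(snpIds(inst)),
    n_harmonized = nSnp(pairs),
    ivw = c(.estimate_as_list(ivw@estimate),
            list(model = ivw@model, Q = ivw@Q, Q_df = ivw@df,
                 Q_pval = ivw@QPval)),
    egger = c(.estimate_as_list(egger@slope),
              list(intercept = egger@interceptEst,
                   intercept_se = egger@interceptSE,
                   intercept_pval = egger@interceptP)),
    weighted_median = .estimate_as_list(wm),
    leave_one_out = list(n_flagged = sum(loo$flagged),
                         flagged_snps = loo$left_out[loo$flagged]),
    presso = list(global_rss = presso@globalRSS,
                  global_pval = presso@globalPval,
                  outlier_snps = presso@outlierSnps,
                  corrected = .estimate_as_list(presso@corrected)))
}

#' Serialize univariable MR reports
#'
#' `writeUvmrReport` writes one or more reports as JSON;
#' `uvmrSummaryRow` flattens a report to the one-row TSV summary shape
#' (method, beta, se, ci, p, nsnp, Q, Egger intercept p, PRESSO global p).
#'
#' @param report a report from [uvmrReport()] (or a list of them).
#' @param path output path.
#' @return the path (invisibly), or the flat data.frame.
#' @export
writeUvmrReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeUvmrReport
#' @export
uvmrSummaryRow <- function(report) {
  do.call(rbind, lapply(list(report$ivw, report$egger,
                             report$weighted_median), function(e) {
    data.frame(exposure = report$exposure, outcome = report$outcome,
               method = e$method, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               n_snp = e$n_snp,
               Q = report$ivw$Q, Q_pval = report$ivw$Q_pval,
               egger_intercept_p = report$egger$intercept_pval,
               presso_global_p = report$presso$global_pval,
               stringsAsFactors = FALSE)
  }))
}
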