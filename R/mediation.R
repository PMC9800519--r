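#' @include AllClasses.R uvmr.R mvmr.R
NULL

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values: with sorted p-values, `q_(i)` is the minimum
#' over `k >= i` of `p_(k) * m / k`, capped at 1, returned in input order.
#' Delegates to `stats::p.adjust(method = "BH")` after validating the
#' inputs.
#'
#' @param pvals numeric p-values in (0, 1].
#' @return q-values in the input order; an empty input returns an empty
#'   vector.
#' @export
#' @examples
#' fdrAdjust(c(0.005, 0.01, 0.03, 0.04))  # 0.02 0.02 0.04 0.04
fdrAdjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

.default_params <- function() {
  list(pThreshold = 5e-8, r2Threshold = 0.001, windowBp = 1e7,
       minVariants = 10, palindromeMafLimit = 0.30)
}

# one IVW leg: instruments from `from`, tested against `to`; returns the
# IVWResult or an insufficientInstruments condition
.ivw_leg <- function(from, to, ld, params, inst = NULL) {
  tryCatch({
    if (is.null(inst))
      inst <- selectInstruments(from, ld, params$pThreshold,
                                params$r2Threshold, params$windowBp,
                                params$minVariants)
    pairs <- harmonize(subsetSnps(from, snpIds(inst)), to,
                       palindromeMafLimit = params$palindromeMafLimit)
    if (nSnp(pairs) < 2L)
      stop(insufficientInstruments(traitLabel(from), nSnp(pairs), 2L))
    mrIVW(pairs)
  }, insufficientInstruments = function(c) c,
     error = function(e) {
       if (grepl("empty SNP intersection", conditionMessage(e)))
         insufficientInstruments(traitLabel(from), 0L, 2L)
       else stop(e)
     })
}

.leg_stats <- function(leg) {
  if (is(leg, "IVWResult"))
    c(beta = leg@estimate@beta, se = leg@estimate@se,
      pval = leg@estimate@pval, n_snp = leg@estimate@nSnp)
  else c(beta = NA_real_, se = NA_real_, pval = NA_real_, n_snp = NA_real_)
}

#' Screen candidate traits for two-step mediation eligibility
#'
#' First step of the two-step MR design. For every candidate trait three
#' univariable IVW legs are fitted: trait -> mediator, trait -> outcome
#' (the total effect), and the reverse leg mediator -> trait (the mediator's
#' instruments, the trait as outcome) — a trait reversely caused by the
#' mediator cannot be a mediation exposure. Benjamini-Hochberg FDR is
#' applied separately per leg across traits, and each trait receives exactly
#' one status: `insufficient_instruments` when any leg lacks instruments,
#' else `not_assoc_mediator` (mediator q-value not significant), else
#' `not_assoc_outcome`, else `reverse_caused` (reverse q-value significant),
#' else `eligible`. Venn-style association counts are attached as
#' `attr(, "venn")`.
#'
#' @param traits list of candidate-trait [SumStats-class] objects.
#' @param mediator,outcome [SumStats-class] objects.
#' @param ld an [LDTable-class].
#' @param params list of selection/harmonization parameters (see
#'   [selectInstruments()]); defaults: p 5e-8, r2 0.001, window 1e7,
#'   at least 10 variants, palindrome MAF limit 0.30.
#' @param fdrLevel FDR significance level (default 0.05).
#' @return data.frame, one row per trait: per-leg beta/se/p/q/n_snp and
#'   `status`.
#' @export
screenTraits <- function(traits, mediator, outcome, ld = ldTable(),
                         params = list(), fdrLevel = 0.05) {
  stopifnot(length(traits) >= 1L)
  params <- utils::modifyList(.default_params(), params)

  med_inst <- tryCatch(
    selectInstruments(mediator, ld, params$pThreshold, params$r2Threshold,
                      params$windowBp, params$minVariants),
    insufficientInstruments = function(c) c)

  rows <- lapply(traits, function(tr) {
    med <- .ivw_leg(tr, mediator, ld, params)
    out <- .ivw_leg(tr, outcome, ld, params)
    rev <- if (is(med_inst, "condition")) med_inst
           else .ivw_leg(mediator, tr, ld, params, inst = med_inst)
    insufficient <- is(med, "condition") || is(out, "condition") ||
      is(rev, "condition")
    m <- .leg_stats(med); o <- .leg_stats(out); v <- .leg_stats(rev)
    data.frame(trait = traitLabel(tr),
               beta_mediator = m[["beta"]], se_mediator = m[["se"]],
               p_mediator = m[["pval"]], nsnp_mediator = m[["n_snp"]],
               beta_outcome = o[["beta"]], se_outcome = o[["se"]],
               p_outcome = o[["pval"]], nsnp_outcome = o[["n_snp"]],
               beta_reverse = v[["beta"]], se_reverse = v[["se"]],
               p_reverse = v[["pval"]], nsnp_reverse = v[["n_snp"]],
               insufficient = insufficient, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  # FDR per leg, across the traits with an estimate for that leg
  for (leg in c("mediator", "outcome", "reverse")) {
    p <- tab[[paste0("p_", leg)]]
    q <- rep(NA_real_, length(p))
    q[!is.na(p)] <- fdrAdjust(p[!is.na(p)])
    tab[[paste0("q_", leg)]] <- q
  }

  status <- ifelse(tab$insufficient, "insufficient_instruments",
            ifelse(tab$q_mediator >= fdrLevel, "not_assoc_mediator",
            ifelse(tab$q_outcome >= fdrLevel, "not_assoc_outcome",
            ifelse(tab$q_reverse < fdrLevel, "reverse_caused", "eligible"))))
  tab$status <- status
  tab$insufficient <- NULL

  ok <- !is.na(tab$q_mediator) & !is.na(tab$q_outcome)
  am <- ok & tab$q_mediator < fdrLevel
  ao <- ok & tab$q_outcome < fdrLevel
  attr(tab, "venn") <- c(assoc_mediator = sum(am),
                         assoc_outcome = sum(ao),
                         assoc_both = sum(am & ao),
                         eligible = sum(status == "eligible"))
  tab
}

#' Product-of-coefficients mediation arithmetic
#'
#' The effect-decomposition core shared by [twoStepMediation()]: the
#' indirect effect is `beta1 * beta2` with the Sobel (delta-method)
#' standard error `sqrt(beta2^2 se1^2 + beta1^2 se2^2)`; the mediation
#' proportion is indirect/total, undefined when |total| is below machine
#' tolerance (returned as `NA` with `proportion_defined = FALSE`, never as
#' NaN).
#'
#' @param beta1,se1 exposure -> mediator effect and SE.
#' @param beta2,se2 mediator -> outcome effect (mediator-adjusted-for-trait
#'   coefficient) and SE.
#' @param total total exposure -> outcome effect.
#' @return list with `indirect`, `sobel_se`, `indirect_p`, `proportion`,
#'   `proportion_defined`, `direction_consistent`.
#' @export
#' @examples
#' mediationDecompose(0.2, 0.05, 0.5, 0.1, total = 0.4)
mediationDecompose <- function(beta1, se1, beta2, se2, total) {
  indirect <- beta1 * beta2
  sobel_se <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)
  indirect_p <- if (sobel_se > 0)
    2 * stats::pnorm(-abs(indirect / sobel_se)) else 1
  defined <- abs(total) > sqrt(.Machine$double.eps)
  list(indirect = indirect, sobel_se = sobel_se,
       indirect_p = max(indirect_p, .Machine$double.xmin),
       proportion = if (defined) indirect / total else NA_real_,
       proportion_defined = defined,
       direction_consistent = indirect == 0 || sign(indirect) == sign(total))
}

#' Two-step MR causal-mediation decomposition for one trait
#'
#' Second step of the design. The total effect is the univariable IVW of
#' trait on outcome; `beta1` is the univariable IVW of trait on mediator;
#' one joint multivariable fit of the outcome on (trait, mediator) yields
#' the direct effect (trait coefficient) and `beta2` (the mediator
#' coefficient, i.e. mediator -> outcome adjusted for the trait). The
#' indirect effect is the product of coefficients `beta1 * beta2` with the
#' Sobel (delta-method) standard error
#' `sqrt(beta2^2 se1^2 + beta1^2 se2^2)`, and the mediation proportion is
#' indirect/total (undefined, and flagged, when |total| is at machine
#' tolerance).
#'
#' @param trait,mediator,outcome [SumStats-class] objects.
#' @param ld an [LDTable-class].
#' @param params parameter list as in [screenTraits()].
#' @return a [MediationResult-class].
#' @export
twoStepMediation <- function(trait, mediator, outcome, ld = ldTable(),
                             params = list()) {
  params <- utils::modifyList(.default_params(), params)
  inst <- selectInstruments(trait, ld, params$pThreshold, params$r2Threshold,
                            params$windowBp, params$minVariants)
  tsub <- subsetSnps(trait, snpIds(inst))
  total <- mrIVW(harmonize(tsub, outcome,
                           palindromeMafLimit = params$palindromeMafLimit))@estimate
  beta1 <- mrIVW(harmonize(tsub, mediator,
                           palindromeMafLimit = params$palindromeMafLimit))@estimate

  mv_pairs <- mvmrInstruments(list(trait, mediator), outcome, ld,
                              params$pThreshold, params$r2Threshold,
                              params$windowBp, params$palindromeMafLimit)
  fit <- mvmrFit(mv_pairs)
  direct <- fit@estimates[[1]]
  beta2 <- fit@estimates[[2]]

  dec <- mediationDecompose(beta1@beta, beta1@se, beta2@beta, beta2@se,
                            total@beta)
  new("MediationResult",
      traitLabel = traitLabel(trait),
      total = total, beta1 = beta1, direct = direct, beta2 = beta2,
      indirect = dec$indirect, indirectSE = dec$sobel_se,
      indirectP = dec$indirect_p,
      proportion = dec$proportion, proportionDefined = dec$proportion_defined,
      directionConsistent = dec$direction_consistent,
      conditionalF = fit@conditionalF)
}

#' Flat mediation summary table
#'
#' One row per trait, ordered by trait label, with the total/direct/
#' indirect decomposition, the Sobel SE, the mediation proportion as a
#' percentage (one decimal) and a caveat flag for direction-inconsistent
#' decompositions.
#'
#' @param results list of [MediationResult-class] objects.
#' @return data.frame (header-only when `results` is empty).
#' @export
mediationTable <- function(results) {
  cols <- data.frame(trait = character(), total = numeric(),
                     total_se = numeric(), beta1 = numeric(),
                     beta1_se = numeric(), direct = numeric(),
                     direct_se = numeric(), beta2 = numeric(),
                     beta2_se = numeric(), indirect = numeric(),
                     sobel_se = numeric(), indirect_p = numeric(),
                     proportion_pct = numeric(),
                     direction_consistent = logical(),
                     caveat = character(), stringsAsFactors = FALSE)
  if (!length(results)) return(cols)
  rows <- lapply(results, function(r) {
    data.frame(trait = r@traitLabel,
               total = r@total@beta, total_se = r@total@se,
               beta1 = r@beta1@beta, beta1_se = r@beta1@se,
               direct = r@direct@beta, direct_se = r@direct@se,
               beta2 = r@beta2@beta, beta2_se = r@beta2@se,
               indirect = r@indirect, sobel_se = r@indirectSE,
               indirect_p = r@indirectP,
               proportion_pct = if (r@proportionDefined)
                 round(100 * r@proportion, 1) else NA_real_,
               direction_consistent = r@directionConsistent,
               caveat = if (!r@proportionDefined) "total-effect-near-zero"
                        else if (!r@directionConsistent) "direction-inconsistent"
                        else "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$trait), , drop = FALSE]
}
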