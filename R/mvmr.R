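#' @include AllClasses.R harmonize.R clump.R
NULL

#' Build a joint instrument set for multivariable MR
#'
#' Takes the union of each exposure's genome-wide-significant biallelic
#' SNPs, restricts it to SNPs present in every dataset (exposures and
#' outcome; SNPs missing somewhere are recorded as dropped with reason
#' `missing-in-<label>`), clumps jointly using the minimum p-value across
#' exposures per SNP, and harmonizes everything to the first exposure's
#' effect allele.
#'
#' @param exposures list of two or more [SumStats-class] objects.
#' @param outcome the outcome [SumStats-class].
#' @param ld an [LDTable-class].
#' @param pThreshold,r2Threshold,windowBp selection parameters, as in
#'   [selectInstruments()].
#' @param palindromeMafLimit passed to [harmonize()].
#' @return a multi-exposure [HarmonizedPairs-class]. Signals the classed
#'   condition `insufficientInstruments` when fewer than `K + 2` SNPs
#'   survive (K = number of exposures).
#' @export
mvmrInstruments <- function(exposures, outcome, ld, pThreshold = 5e-8,
                            r2Threshold = 0.001, windowBp = 1e7,
                            palindromeMafLimit = 0.30) {
  if (length(exposures) < 2L)
    stop("multivariable MR requires at least 2 exposures")
  K <- length(exposures)

  sig <- lapply(exposures, function(s) {
    r <- records(s)
    r$snp[r$pval < pThreshold &
            grepl("^[ACGT]$", r$ea) & grepl("^[ACGT]$", r$oa)]
  })
  cand <- Reduce(union, sig)
  if (!length(cand))
    stop(insufficientInstruments("joint", 0L, K + 2L))

  # present in every dataset
  all_sets <- c(exposures, list(outcome))
  labels <- vapply(all_sets, traitLabel, character(1))
  present <- cand
  missing_drop <- data.frame(snp_id = character(), reason = character(),
                             stringsAsFactors = FALSE)
  for (i in seq_along(all_sets)) {
    absent <- setdiff(present, snpIds(all_sets[[i]]))
    if (length(absent))
      missing_drop <- rbind(missing_drop, data.frame(
        snp_id = absent, reason = paste0("missing-in-", labels[i]),
        stringsAsFactors = FALSE))
    present <- setdiff(present, absent)
  }

  # joint clumping: min p across exposures per SNP
  ref <- records(exposures[[1]])
  ref <- ref[match(present, ref$snp), , drop = FALSE]
  minp <- Reduce(pmin, lapply(exposures, function(s) {
    r <- records(s)
    r$pval[match(present, r$snp)]
  }))
  clump_in <- exposures[[1]]
  clump_in@records <- transform(ref, pval = minp)
  idx <- clumpVariants(clump_in, ld, r2Threshold, windowBp)

  subs <- lapply(all_sets, subsetSnps, ids = idx)
  pairs <- do.call(harmonize, c(subs,
                                list(palindromeMafLimit = palindromeMafLimit)))
  pairs@dropped <- rbind(missing_drop, pairs@dropped)
  if (nSnp(pairs) < K + 2L)
    stop(insufficientInstruments("joint", nSnp(pairs), K + 2L))
  pairs
}

#' Multivariable MR: joint weighted-least-squares fit
#'
#' Regresses the SNP-outcome effects on the J x K matrix of SNP-exposure
#' effects without intercept, weights `1/seY^2`. Each coefficient is the
#' effect of that exposure on the outcome conditional on the others.
#' Standard errors come from the WLS covariance inflated multiplicatively by
#' `max(1, RSS/(J-K))` on the variance scale; p-values and confidence
#' bounds are t on `J - K` degrees of freedom. The per-exposure conditional
#' F-statistics (see [conditionalF()]) are computed alongside.
#'
#' @param pairs a multi-exposure [HarmonizedPairs-class] with
#'   `nSnp >= K + 2`.
#' @return an [MVMRResult-class].
#' @export
mvmrFit <- function(pairs) {
  X <- pairs@betaX
  K <- ncol(X)
  J <- nrow(X)
  if (J < K + 2L)
    stop("multivariable fit requires at least K + 2 = ", K + 2L,
         " SNPs, got ", J)
  w <- 1 / pairs@seY^2
  # an exposure with no instrument signal at all contributes nothing to the
  # fit; leave it out of the solve (beta 0, no SE) instead of reporting it
  # as collinearity
  live <- colSums(X != 0) > 0L
  Xl <- X[, live, drop = FALSE]
  Kl <- ncol(Xl)
  qr_x <- qr(sqrt(w) * Xl)
  if (qr_x$rank < Kl)
    stop("rank-deficient design: exposure effect columns are collinear")
  XtWX <- crossprod(Xl, w * Xl)
  bl <- drop(solve(XtWX, crossprod(Xl, w * pairs@betaY)))
  resid <- pairs@betaY - drop(Xl %*% bl)
  rss <- sum(w * resid^2)
  df <- J - Kl
  phi <- max(1, rss / df)
  sel <- sqrt(diag(solve(XtWX)) * phi)
  b <- se <- numeric(K)
  b[live] <- bl
  se[live] <- sel
  se[!live] <- Inf
  tv <- ifelse(is.finite(se), b / se, 0)
  pv <- 2 * stats::pt(-abs(tv), df = df)
  crit <- stats::qt(0.975, df = df)
  est <- stats::setNames(lapply(seq_len(K), function(k) {
    .mk_estimate("MVMR", b[k], se[k], pv[k], J, crit = crit)
  }), pairs@exposures)
  cf <- stats::setNames(
    vapply(seq_len(K), function(k) conditionalF(pairs, k), numeric(1)),
    pairs@exposures)
  new("MVMRResult", estimates = est, conditionalF = cf,
      residualScale = max(1, sqrt(rss / df)), nSnp = as.integer(J))
}

#' Conditional F-statistic for instrument strength in multivariable MR
#'
#' How much instrument signal the target exposure retains after the other
#' exposures are accounted for: the target exposure's SNP effects are
#' regressed (with intercept) on the other exposures' SNP effects, weighted
#' by the inverse squared standard errors of the target exposure, and
#' `F = Q_x / (J - K + 1)` where `Q_x` is the weighted residual sum of
#' squares. The statistic is invariant to jointly rescaling the target
#' betas and standard errors, and to the units of the other exposures;
#' larger is stronger, with ~10 the conventional adequacy rule of thumb.
#'
#' @param pairs a multi-exposure [HarmonizedPairs-class].
#' @param exposureIndex column (or exposure label) whose strength is
#'   assessed.
#' @return the conditional F-statistic (single numeric).
#' @export
conditionalF <- function(pairs, exposureIndex) {
  X <- pairs@betaX
  K <- ncol(X)
  J <- nrow(X)
  if (J < K + 2L)
    stop("conditional F requires at least K + 2 SNPs")
  if (is.character(exposureIndex))
    exposureIndex <- match(exposureIndex, pairs@exposures)
  target <- X[, exposureIndex]
  v <- 1 / pairs@seX[, exposureIndex]^2
  others <- X[, -exposureIndex, drop = FALSE]
  others <- others[, colSums(others != 0) > 0L, drop = FALSE]
  Z <- cbind(1, others)
  g <- solve(crossprod(Z, v * Z), crossprod(Z, v * target))
  resid <- target - drop(Z %*% g)
  sum(v * resid^2) / (J - K + 1L)
}
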