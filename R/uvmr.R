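#' @include AllClasses.R
NULL

.assert_univariable <- function(pairs) {
  if (ncol(pairs@betaX) != 1L)
    stop("this estimator is univariable; got ", ncol(pairs@betaX),
         " exposure columns (use mvmrFit for joint fits)")
}

.mk_estimate <- function(method, beta, se, pval, nSnp, crit = stats::qnorm(0.975)) {
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - crit * se, ciHigh = beta + crit * se,
      pval = max(pval, .Machine$double.xmin), nSnp = as.integer(nSnp))
}

#' Per-SNP Wald ratio estimates
#'
#' `ratio_j = betaY_j / betaX_j` with the first-order standard error
#' `seY_j / |betaX_j|`. SNPs with a zero exposure effect are dropped with a
#' warning (their ratio is undefined).
#'
#' @param pairs a single-exposure [HarmonizedPairs-class].
#' @return data.frame with columns `snp`, `ratio`, `se`.
#' @export
ratioEstimates <- function(pairs) {
  .assert_univariable(pairs)
  bx <- pairs@betaX[, 1]
  zero <- bx == 0
  if (all(zero)) stop("all exposure betas are zero; no ratio is defined")
  if (any(zero))
    warning(sum(zero), " SNP(s) with zero exposure beta dropped from ratio estimates")
  data.frame(snp = pairs@snp[!zero],
             ratio = pairs@betaY[!zero] / bx[!zero],
             se = pairs@seY[!zero] / abs(bx[!zero]),
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted (IVW) estimator
#'
#' Precision-weighted regression of SNP-outcome on SNP-exposure effects
#' through the origin, with weights `1/seY^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`, `se_fixed = 1/sqrt(sum(w bx^2))`.
#' Heterogeneity is summarised by Cochran's
#' `Q = sum(w (by - beta bx)^2)` on `J - 1` degrees of freedom; under the
#' default multiplicative random-effects model the standard error is
#' inflated by `max(1, sqrt(Q/df))`. P-values are two-sided normal.
#'
#' @param pairs a single-exposure [HarmonizedPairs-class] with at least two
#'   SNPs.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an [IVWResult-class].
#' @export
mrIVW <- function(pairs, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  .assert_univariable(pairs)
  bx <- pairs@betaX[, 1]; by <- pairs@betaY; w <- 1 / pairs@seY^2
  J <- length(bx)
  if (J < 2L) stop("IVW requires at least 2 SNPs, got ", J)
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fixed <- sqrt(1 / sxx)
  Q <- sum(w * (by - beta * bx)^2)
  df <- J - 1L
  se <- if (model == "multiplicative_random")
    se_fixed * max(1, sqrt(Q / df)) else se_fixed
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new("IVWResult",
      estimate = .mk_estimate("IVW", beta, se, pval, J),
      model = model, Q = Q, df = df,
      QPval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' MR-Egger regression and intercept (pleiotropy) test
#'
#' Weighted least squares of outcome on exposure effects with a free
#' intercept, weights `1/seY^2`, after orienting every pair to a
#' non-negative exposure effect (both betas negated where needed) — the
#' orientation required by Egger's InSIDE identifying assumption. Standard
#' errors come from the WLS covariance inflated multiplicatively by
#' `max(1, RSS/(J-2))` on the variance scale; p-values are two-sided t on
#' `J - 2` degrees of freedom. A non-null intercept estimates the average
#' directional pleiotropic effect.
#'
#' @param pairs a single-exposure [HarmonizedPairs-class] with at least
#'   three SNPs.
#' @return an [EggerResult-class].
#' @export
mrEgger <- function(pairs) {
  .assert_univariable(pairs)
  bx <- pairs@betaX[, 1]; by <- pairs@betaY; w <- 1 / pairs@seY^2
  J <- length(bx)
  if (J < 3L) stop("MR-Egger requires at least 3 SNPs, got ", J)
  flip <- bx < 0
  bx[flip] <- -bx[flip]; by[flip] <- -by[flip]
  if (max(bx) - min(bx) < .Machine$double.eps * max(1, max(abs(bx))))
    stop("zero spread in exposure betas after orientation; Egger design is singular")

  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coefs
  rss <- sum(w * resid^2)
  sigma2 <- rss / (J - 2L)
  vcv <- solve(XtWX) * max(1, sigma2)
  se <- sqrt(diag(vcv))
  tstat <- coefs / se
  pv <- 2 * stats::pt(-abs(tstat), df = J - 2L)
  crit <- stats::qt(0.975, df = J - 2L)
  new("EggerResult",
      slope = .mk_estimate("Egger", coefs[2], se[2], pv[2], J, crit = crit),
      interceptEst = coefs[1], interceptSE = se[1],
      interceptP = max(pv[1], .Machine$double.xmin),
      residualScale = max(1, sqrt(sigma2)))
}

# weighted-median point estimate from ratios/weights (weights need not be
# normalized); linear interpolation of sorted ratios at cumulative midpoint
# score 0.5
.weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  k <- length(r)
  if (s[k] <= 0.5) return(r[k])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Consistent when at least half the weight comes from valid instruments.
#' Per-SNP ratio estimates are sorted ascending with inverse-variance
#' weights `w_j = betaX_j^2 / seY_j^2` (the precision of the ratio),
#' normalized to sum to one; with cumulative midpoint scores
#' `S_j = sum_{i<=j} w_i - w_j/2` the estimate is the linear interpolation
#' of the ratios at `S = 0.5`. The standard error is the SD of the estimate
#' over `nBoot` parametric-bootstrap replicates, resampling each study beta
#' from `N(observed, se^2)`; the p-value is two-sided normal.
#'
#' @param pairs a single-exposure [HarmonizedPairs-class] with at least
#'   three SNPs.
#' @param nBoot bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an [MREstimate-class].
#' @export
mrWeightedMedian <- function(pairs, nBoot = 1000, seed = 1) {
  .assert_univariable(pairs)
  bx <- pairs@betaX[, 1]; sx <- pairs@seX[, 1]
  by <- pairs@betaY; sy <- pairs@seY
  J <- length(bx)
  if (J < 3L) stop("weighted median requires at least 3 SNPs, got ", J)
  stopifnot(nBoot >= 2)
  est <- .weighted_median_point(by / bx, bx^2 / sy^2)
  set.seed(seed)
  bxs <- matrix(stats::rnorm(J * nBoot, bx, sx), J, nBoot)
  bys <- matrix(stats::rnorm(J * nBoot, by, sy), J, nBoot)
  boots <- vapply(seq_len(nBoot), function(b) {
    .weighted_median_point(bys[, b] / bxs[, b], bxs[, b]^2 / sy^2)
  }, numeric(1))
  se <- stats::sd(boots)
  pval <- 2 * stats::pnorm(-abs(est / se))
  .mk_estimate("WeightedMedian", est, se, pval, J)
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Refits the IVW estimator once per omitted SNP and flags omissions that
#' flip the sign of the causal estimate or move it outside the full-sample
#' 95% confidence interval — either indicates a single variant driving the
#' result.
#'
#' @param pairs a single-exposure [HarmonizedPairs-class] with at least
#'   three SNPs.
#' @param model IVW model, as in [mrIVW()].
#' @return data.frame with columns `left_out`, `beta`, `se`, `pval`,
#'   `flagged`.
#' @export
leaveOneOut <- function(pairs, model = "multiplicative_random") {
  if (nSnp(pairs) < 3L)
    stop("leave-one-out requires at least 3 SNPs")
  full <- mrIVW(pairs, model)@estimate
  res <- lapply(seq_len(nSnp(pairs)), function(j) {
    e <- mrIVW(pairs[-j], model)@estimate
    data.frame(left_out = pairs@snp[j], beta = e@beta, se = e@se,
               pval = e@pval,
               flagged = sign(e@beta) != sign(full@beta) ||
                 e@beta < full@ciLow || e@beta > full@ciHigh,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
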