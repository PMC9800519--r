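#' @include AllClasses.R uvmr.R
NULL

# leave-one-out IVW slopes for all SNPs at once, given precomputed sums
.loo_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO residual-sum-of-squares pleiotropy test
#'
#' Global test: the observed statistic is
#' `RSS = sum_j w_j (betaY_j - bhat_{-j} betaX_j)^2` with `bhat_{-j}` the
#' leave-one-out IVW slope and `w_j = 1/seY_j^2`; its null distribution is
#' obtained by simulating `betaY_j* ~ N(bhat_{-j} betaX_j, seY_j^2)` `nSim`
#' times and recomputing the statistic (including the leave-one-out slopes)
#' on each replicate. The reported p-value uses the add-one Monte-Carlo
#' convention `(1 + #\{RSS_sim >= RSS_obs\}) / (nSim + 1)`.
#'
#' Outlier test: each SNP's observed weighted squared residual is compared
#' with its own simulated distribution; SNPs whose Bonferroni-adjusted
#' empirical p-value falls below `outlierAlpha` are flagged, and the
#' corrected estimate is the IVW fit on the unflagged SNPs.
#'
#' @param pairs a single-exposure [HarmonizedPairs-class] with at least four
#'   SNPs.
#' @param nSim Monte-Carlo replicates (default 1000).
#' @param seed RNG seed.
#' @param outlierAlpha significance level for the Bonferroni-adjusted
#'   per-SNP test (default 0.05).
#' @return a [PressoResult-class].
#' @export
mrPresso <- function(pairs, nSim = 1000, seed = 1, outlierAlpha = 0.05) {
  .assert_univariable(pairs)
  bx <- pairs@betaX[, 1]; by <- pairs@betaY; sy <- pairs@seY
  w <- 1 / sy^2
  J <- length(bx)
  if (J < 4L) stop("MR-PRESSO requires at least 4 SNPs, got ", J)
  if (nSim < 1) stop("nSim must be a positive integer")

  loo <- .loo_slopes(bx, by, w)
  obs_resid <- w * (by - loo * bx)^2
  rss_obs <- sum(obs_resid)

  set.seed(seed)
  mu <- loo * bx
  ysim <- matrix(stats::rnorm(J * nSim, mean = mu, sd = sy), J, nSim)
  # leave-one-out slopes per replicate, vectorized over replicates
  sxx <- sum(w * bx^2)
  sxy_sim <- colSums(w * bx * ysim)                       # length nSim
  term <- (w * bx) * ysim                                 # J x nSim
  loo_sim <- (matrix(sxy_sim, J, nSim, byrow = TRUE) - term) /
    (sxx - w * bx^2)
  resid_sim <- w * (ysim - loo_sim * bx)^2
  rss_sim <- colSums(resid_sim)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (nSim + 1)
  p_snp <- (1 + rowSums(resid_sim >= obs_resid)) / (nSim + 1)
  flagged <- pmin(p_snp * J, 1) < outlierAlpha
  keep <- !flagged
  corrected <- if (sum(keep) >= 2L)
    mrIVW(pairs[keep])@estimate else mrIVW(pairs)@estimate

  new("PressoResult",
      globalRSS = rss_obs, globalPval = global_p,
      outlierSnps = pairs@snp[flagged], corrected = corrected,
      nSim = as.integer(nSim), seed = as.integer(seed))
}
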