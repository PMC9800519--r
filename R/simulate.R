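#' @include AllClasses.R sumstats-io.R
NULL

#' Configure the synthetic GWAS generator
#'
#' Builds a [SimConfig-class] describing a linear structural model
#' exposure -> mediator -> outcome observed through three non-overlapping
#' GWAS cohorts. The defaults describe a well-powered biobank-scale study:
#' 150 exposure-causal SNPs and 100 mediator-only SNPs with per-SNP effects
#' of SD 0.05 on unit-variance traits, 50 null background SNPs, cohorts of
#' 200,000, a direct effect `tauPrime = 0.2`, an exposure -> mediator effect
#' `alpha = 0.3` and a mediator -> outcome effect `betaM = 0.5` (so total
#' 0.35, indirect 0.15, proportion mediated 42.9%), and no pleiotropy.
#'
#' @param nSnpExposure,nSnpMediator,nNullSnps SNP counts.
#' @param mafRange uniform minor-allele-frequency interval within (0, 0.5].
#' @param gammaSd,deltaSd SD of per-SNP exposure / mediator-only effects.
#' @param alpha,betaM,tauPrime structural coefficients (see above).
#' @param nX,nM,nY cohort sample sizes.
#' @param fractionInvalid,etaMean,etaSd pleiotropy: fraction of exposure
#'   SNPs receiving a direct SNP -> outcome effect `N(etaMean, etaSd^2)`.
#' @param palindromeStress inject A/T variants with cross-cohort EAF jitter.
#' @param seed RNG seed.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nSnpExposure = 150, nSnpMediator = 100,
                      nNullSnps = 50, mafRange = c(0.05, 0.5),
                      gammaSd = 0.05, deltaSd = 0.05,
                      alpha = 0.3, betaM = 0.5, tauPrime = 0.2,
                      nX = 2e5, nM = 2e5, nY = 2e5,
                      fractionInvalid = 0, etaMean = 0, etaSd = 0,
                      palindromeStress = FALSE, seed = 1) {
  new("SimConfig",
      nSnpExposure = as.integer(nSnpExposure),
      nSnpMediator = as.integer(nSnpMediator),
      nNullSnps = as.integer(nNullSnps),
      mafRange = as.numeric(mafRange),
      gammaSd = gammaSd, deltaSd = deltaSd,
      alpha = alpha, betaM = betaM, tauPrime = tauPrime,
      nX = nX, nM = nM, nY = nY,
      fractionInvalid = fractionInvalid, etaMean = etaMean, etaSd = etaSd,
      palindromeStress = isTRUE(palindromeStress), seed = as.integer(seed))
}

.ALLELE_PAIRS <- cbind(ea = c("A", "A", "T", "T", "G", "C"),
                       oa = c("G", "C", "G", "C", "A", "A"))

# assemble one cohort's SumStats: observed beta = true + N(0, se^2),
# se = 1/sqrt(2 p (1-p) N) under unit trait variance; p-values two-sided
# normal, clamped away from exact 0 so extreme z-scores keep pval in (0, 1]
.make_cohort <- function(label, snp, chrom, pos, ea, oa, eaf, true_beta, n) {
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * n)
  beta <- true_beta + stats::rnorm(length(se), 0, se)
  pval <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  sumStats(label, data.frame(
    snp = snp, chrom = chrom, pos = pos, ea = ea, oa = oa, eaf = eaf,
    beta = beta, se = se, pval = pval, n = n,
    stringsAsFactors = FALSE), source = "synthetic")
}

.snp_scaffold <- function(m, maf_range, stress) {
  idx <- seq_len(m)
  ap <- .ALLELE_PAIRS[(idx - 1L) %% nrow(.ALLELE_PAIRS) + 1L, , drop = FALSE]
  ea <- ap[, "ea"]; oa <- ap[, "oa"]
  if (stress) {
    # every 10th SNP palindromic, to exercise frequency-based alignment
    pal <- idx %% 10L == 0L
    ea[pal] <- "A"; oa[pal] <- "T"
  }
  list(snp = sprintf("rs%06d", idx),
       chrom = as.character((idx - 1L) %% 22L + 1L),
       pos = ((idx - 1L) %/% 22L + 1L) * 25000000L,
       ea = ea, oa = oa,
       eaf = stats::runif(m, maf_range[1], maf_range[2]))
}

#' Simulate three-cohort GWAS summary statistics with known truth
#'
#' Generates summary statistics directly at the summary level: per SNP j
#' with MAF `p_j ~ U(mafRange)`, the true exposure effect is
#' `gamma_j ~ N(0, gammaSd^2)` for exposure-causal SNPs (0 otherwise), the
#' true mediator effect is `alpha * gamma_j + delta_j` with mediator-only
#' effects `delta_j ~ N(0, deltaSd^2)`, and the true outcome effect is
#' `tauPrime * gamma_j + betaM * (alpha gamma_j + delta_j) + eta_j`, where
#' `eta_j` is nonzero only for the invalid (pleiotropic) fraction of
#' exposure SNPs. Each cohort observes `true + N(0, se_j^2)` independently
#' with the analytic standard error `1/sqrt(2 p_j (1-p_j) N_cohort)` (unit
#' trait variance). All SNPs are mutually independent (use an empty
#' [LDTable-class] downstream). Bit-identical output for identical config
#' and seed.
#'
#' @param config a [SimConfig-class].
#' @return list with elements `exposure`, `mediator`, `outcome`
#'   ([SumStats-class] each) and `truth` ([SimTruth-class]).
#' @export
simulateSummaryStats <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nE <- config@nSnpExposure; nMd <- config@nSnpMediator
  nN <- config@nNullSnps
  m <- nE + nMd + nN
  sc <- .snp_scaffold(m, config@mafRange, config@palindromeStress)
  cls <- rep(c("exposure", "mediator_only", "null"), c(nE, nMd, nN))

  gamma <- c(stats::rnorm(nE, 0, config@gammaSd), numeric(nMd + nN))
  delta <- c(numeric(nE), stats::rnorm(nMd, 0, config@deltaSd), numeric(nN))
  # pleiotropic effects are drawn relative to the exposure-increasing
  # allele (sign-linked to gamma): a nonzero etaMean then means directional
  # pleiotropy in the sense the Egger intercept estimates
  eta <- numeric(m)
  n_invalid <- round(config@fractionInvalid * nE)
  if (n_invalid > 0) {
    inv <- sample.int(nE, n_invalid)
    eta[inv] <- stats::rnorm(n_invalid, config@etaMean, config@etaSd) *
      ifelse(gamma[inv] < 0, -1, 1)
  }

  true_x <- gamma
  true_m <- config@alpha * gamma + delta
  true_y <- config@tauPrime * gamma + config@betaM * true_m + eta

  jitter_eaf <- function(eaf) {
    if (!config@palindromeStress) return(eaf)
    pmin(pmax(eaf + stats::rnorm(length(eaf), 0, 0.01), 0.01), 0.99)
  }
  exposure <- .make_cohort("exposure", sc$snp, sc$chrom, sc$pos, sc$ea,
                           sc$oa, sc$eaf, true_x, config@nX)
  mediator <- .make_cohort("mediator", sc$snp, sc$chrom, sc$pos, sc$ea,
                           sc$oa, jitter_eaf(sc$eaf), true_m, config@nM)
  outcome <- .make_cohort("outcome", sc$snp, sc$chrom, sc$pos, sc$ea,
                          sc$oa, jitter_eaf(sc$eaf), true_y, config@nY)

  indirect <- config@alpha * config@betaM
  total <- config@tauPrime + indirect
  truth <- new("SimTruth",
               total = total, direct = config@tauPrime, indirect = indirect,
               proportion = if (abs(total) > 0) indirect / total else NA_real_,
               perSnp = data.frame(snp = sc$snp, class = cls,
                                   trueX = true_x, trueM = true_m,
                                   trueY = true_y, stringsAsFactors = FALSE))
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate a candidate-trait panel for screening tests
#'
#' Generates one trait dataset per entry of `traitSpecs` under the same
#' summary-level machinery as [simulateSummaryStats()], sharing one mediator and one
#' outcome. Each trait has its own block of causal SNPs
#' (`gamma ~ N(0, gammaSd^2)`); `effectOnMediator` and `effectOnOutcome`
#' scale those SNPs' true effects in the mediator and outcome datasets, and
#' `reverseEffect` realizes reverse causation by giving the mediator's own
#' instruments true effects on the trait. Every dataset contains every SNP
#' (with zero true effect where no path exists), so all pairwise
#' intersections are complete.
#'
#' @param config a [SimConfig-class] (its `nSnpExposure` is the default
#'   per-trait SNP count, `nSnpMediator` the mediator's own instrument
#'   count).
#' @param traitSpecs list of specs, each a list with
#'   `effectOnMediator`, `effectOnOutcome`, `reverseEffect`, and optionally
#'   `label` and `nSnp`.
#' @return list with `traits` (list of [SumStats-class]), `mediator`,
#'   `outcome`, and `truth`: a data.frame with per-trait generating effects
#'   and the `expected_status` each spec is engineered to produce in
#'   [screenTraits()] (using the default minimum of 10 instruments).
#' @export
simulateTraitPanel <- function(config, traitSpecs) {
  validObject(config)
  if (!length(traitSpecs)) stop("at least one trait spec is required")
  set.seed(config@seed)
  nT <- length(traitSpecs)
  labels <- vapply(seq_len(nT), function(i) {
    s <- traitSpecs[[i]]
    if (!is.null(s$label)) s$label else sprintf("trait%02d", i)
  }, character(1))
  n_per <- vapply(traitSpecs, function(s)
    if (!is.null(s$nSnp)) as.integer(s$nSnp) else config@nSnpExposure,
    integer(1))
  em <- vapply(traitSpecs, function(s) s$effectOnMediator, numeric(1))
  eo <- vapply(traitSpecs, function(s) s$effectOnOutcome, numeric(1))
  rv <- vapply(traitSpecs, function(s) s$reverseEffect, numeric(1))

  nMd <- config@nSnpMediator
  m <- sum(n_per) + nMd + config@nNullSnps
  sc <- .snp_scaffold(m, config@mafRange, config@palindromeStress)
  block <- rep(c(labels, "mediator", "null"),
               c(n_per, nMd, config@nNullSnps))

  gamma <- numeric(m)
  for (i in seq_len(nT))
    gamma[block == labels[i]] <- stats::rnorm(n_per[i], 0, config@gammaSd)
  delta <- numeric(m)
  delta[block == "mediator"] <- stats::rnorm(nMd, 0, config@deltaSd)

  true_m <- delta
  true_y <- config@betaM * delta
  for (i in seq_len(nT)) {
    sel <- block == labels[i]
    true_m[sel] <- em[i] * gamma[sel]
    true_y[sel] <- eo[i] * gamma[sel]
  }

  traits <- lapply(seq_len(nT), function(i) {
    tx <- numeric(m)
    tx[block == labels[i]] <- gamma[block == labels[i]]
    tx[block == "mediator"] <- rv[i] * delta[block == "mediator"]
    .make_cohort(labels[i], sc$snp, sc$chrom, sc$pos, sc$ea, sc$oa,
                 sc$eaf, tx, config@nX)
  })
  mediator <- .make_cohort("mediator", sc$snp, sc$chrom, sc$pos, sc$ea,
                           sc$oa, sc$eaf, true_m, config@nM)
  outcome <- .make_cohort("outcome", sc$snp, sc$chrom, sc$pos, sc$ea,
                          sc$oa, sc$eaf, true_y, config@nY)

  expected <- ifelse(n_per < 10L, "insufficient_instruments",
              ifelse(em == 0, "not_assoc_mediator",
              ifelse(eo == 0, "not_assoc_outcome",
              ifelse(rv != 0, "reverse_caused", "eligible"))))
  list(traits = traits, mediator = mediator, outcome = outcome,
       truth = data.frame(trait = labels, n_snp = n_per,
                          effect_on_mediator = em, effect_on_outcome = eo,
                          reverse_effect = rv, expected_status = expected,
                          stringsAsFactors = FALSE))
}
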