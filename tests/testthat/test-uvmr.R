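# univariable estimators and the sensitivity suite

test_that("ratio estimates follow the first-order formula", {
  p <- make_pairs(bx = c(0.5, 0.2), by = c(0.25, 0), sy = c(0.05, 0.01))
  r <- ratioEstimates(p)
  expect_equal(r$ratio, c(0.5, 0))
  expect_equal(r$se, c(0.1, 0.05))
  pz <- make_pairs(bx = c(0, 0.2), by = c(0.1, 0.1), sy = c(0.01, 0.01))
  expect_warning(rz <- ratioEstimates(pz), "zero exposure beta")
  expect_equal(nrow(rz), 1L)
  expect_error(suppressWarnings(
    ratioEstimates(make_pairs(0, 0.1, 0.01))), "all exposure betas")
})

test_that("IVW recovers exact proportionality with zero heterogeneity", {
  bx <- c(0.1, 0.2, 0.3, 0.15)
  r <- mrIVW(make_pairs(bx, 0.7 * bx, rep(0.01, 4)))
  expect_equal(r@estimate@beta, 0.7)
  expect_equal(r@Q, 0, tolerance = 1e-20)
  # with Q ~ 0 the random-effects SE equals the fixed SE
  rf <- mrIVW(make_pairs(bx, 0.7 * bx, rep(0.01, 4)), model = "fixed")
  expect_equal(r@estimate@se, rf@estimate@se)
})

test_that("IVW matches its closed form and the WLS oracle", {
  p <- make_pairs(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.12, 0.15),
                  sy = c(0.01, 0.01, 0.01))
  r <- mrIVW(p)
  expect_equal(r@estimate@beta, 0.074 / 0.14, tolerance = 1e-12)
  expect_equal(r@estimate@beta, ivw_oracle(p@betaX[, 1], p@betaY, p@seY),
               tolerance = 1e-12)
  # Q from the definition, cross-checked against the oracle residuals
  w <- 1 / p@seY^2
  bhat <- ivw_oracle(p@betaX[, 1], p@betaY, p@seY)
  expect_equal(r@Q, sum(w * (p@betaY - bhat * p@betaX[, 1])^2))
  expect_error(mrIVW(make_pairs(0.1, 0.05, 0.01)), "at least 2")
})

test_that("random-effects SE never falls below the fixed SE, Q = 0 iff equal ratios", {
  for (seed in 1:10) {
    p <- random_pairs(12, seed)
    expect_gte(mrIVW(p)@estimate@se, mrIVW(p, "fixed")@estimate@se)
    expect_gt(mrIVW(p)@Q, 0)
  }
})

test_that("Egger reproduces exact linear data with scale 1", {
  bx <- c(0.05, 0.1, 0.2, 0.3)
  e <- mrEgger(make_pairs(bx, 0.02 + 0.5 * bx, rep(0.01, 4)))
  expect_equal(e@slope@beta, 0.5, tolerance = 1e-12)
  expect_equal(e@interceptEst, 0.02, tolerance = 1e-12)
  expect_equal(e@residualScale, 1)
  expect_error(mrEgger(make_pairs(c(0.1, 0.2), c(0.1, 0.2), c(0.01, 0.01))),
               "at least 3")
  expect_error(mrEgger(make_pairs(rep(0.1, 4), rnorm(4), rep(0.01, 4))),
               "singular")
})

test_that("Egger is invariant to the reported allele orientation", {
  p <- random_pairs(15, 3)
  q <- p
  flip <- c(1, 4, 9)
  q@betaX[flip, 1] <- -q@betaX[flip, 1]
  q@betaY[flip] <- -q@betaY[flip]
  ep <- mrEgger(p); eq <- mrEgger(q)
  expect_equal(ep@slope@beta, eq@slope@beta)
  expect_equal(ep@interceptEst, eq@interceptEst)
  expect_equal(ep@slope@se, eq@slope@se)
})

test_that("Egger slope equals the IVW slope when the intercept is exactly zero", {
  for (seed in 1:5) {
    p <- random_pairs(10, seed)
    p@betaX[, 1] <- abs(p@betaX[, 1])
    e0 <- mrEgger(p)
    # remove the fitted intercept; the refit has intercept 0 exactly
    p2 <- p
    p2@betaY <- p@betaY - e0@interceptEst
    e <- mrEgger(p2)
    expect_equal(e@interceptEst, 0, tolerance = 1e-12)
    expect_equal(e@slope@beta, mrIVW(p2, "fixed")@estimate@beta,
                 tolerance = 1e-10)
  }
})

test_that("Egger intercept centres on zero without pleiotropy", {
  set.seed(101)
  ints <- replicate(200, {
    J <- 25
    bx <- rnorm(J, 0.06, 0.015)
    sy <- runif(J, 0.004, 0.01)
    mrEgger(make_pairs(bx, 0.4 * bx + rnorm(J, 0, sy), sy))@interceptEst
  })
  expect_lt(abs(mean(ints)), 3 * sd(ints) / sqrt(length(ints)))
})

test_that("weighted median interpolates the cumulative midpoint scores", {
  # ratios (0.4, 0.5, 0.9) with normalized weights (0.2, 0.3, 0.5)
  sy <- rep(1, 3)
  bx <- sqrt(c(0.2, 0.3, 0.5))
  by <- c(0.4, 0.5, 0.9) * bx
  est <- mrWeightedMedian(make_pairs(bx, by, sy, sx = rep(1e-6, 3)),
                          nBoot = 10, seed = 1)
  expect_equal(est@beta, 0.65, tolerance = 1e-12)
  expect_equal(est@beta, wm_oracle(by / bx, bx^2 / sy^2), tolerance = 1e-12)
})

test_that("weighted median follows dominant weight and degenerate spread", {
  # one SNP carries 98% of the weight
  w <- c(0.98, 0.01, 0.01)
  bx <- sqrt(w)
  by <- c(0.7, 0.1, 1.3) * bx
  est <- mrWeightedMedian(make_pairs(bx, by, rep(1, 3), sx = rep(1e-6, 3)),
                          nBoot = 10, seed = 1)
  expect_equal(est@beta, 0.7, tolerance = 1e-9)
  # all ratios equal c -> estimate c with small bootstrap SE
  bx2 <- c(0.1, 0.15, 0.2, 0.25)
  est2 <- mrWeightedMedian(make_pairs(bx2, 0.3 * bx2, rep(0.001, 4),
                                      sx = rep(0.001, 4)),
                           nBoot = 200, seed = 2)
  expect_equal(est2@beta, 0.3, tolerance = 1e-12)
  expect_lt(est2@se, 0.02)
})

test_that("weighted median stays within the ratio range; equal weights give the middle ratio", {
  for (seed in 1:10) {
    p <- random_pairs(9, seed)
    est <- mrWeightedMedian(p, nBoot = 5, seed = seed)@beta
    r <- p@betaY / p@betaX[, 1]
    expect_gte(est, min(r)); expect_lte(est, max(r))
  }
  # equal weights, odd J
  bx <- rep(0.2, 5)
  by <- c(0.02, 0.08, 0.06, 0.12, 0.04)
  est <- mrWeightedMedian(make_pairs(bx, by, rep(0.01, 5)), nBoot = 5,
                          seed = 1)@beta
  expect_equal(est, sort(by / bx)[3])
})

test_that("leave-one-out refits per omission and flags influential SNPs", {
  bx <- rep(0.2, 4)
  p <- make_pairs(bx, 0.5 * bx, rep(0.01, 4))
  loo <- leaveOneOut(p)
  expect_equal(nrow(loo), 4L)
  expect_true(all(abs(loo$beta - 0.5) < 1e-12))
  expect_false(any(loo$flagged))
  p3 <- make_pairs(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15), rep(0.01, 3))
  expect_equal(nrow(leaveOneOut(p3)), 3L)
  # a single high-leverage outlier whose omission flips the sign
  bx <- c(0.05, 0.06, 0.055, 1)
  by <- c(-0.01, -0.012, -0.011, 0.5)
  p_out <- make_pairs(bx, by, rep(0.01, 4))
  loo2 <- leaveOneOut(p_out)
  full <- mrIVW(p_out)@estimate@beta
  drop4 <- mrIVW(p_out[-4])@estimate@beta   # direct computation
  expect_gt(full, 0); expect_lt(drop4, 0)
  expect_true(loo2$flagged[4])
  expect_equal(loo2$beta[4], drop4)
})

test_that("MR-PRESSO flags a gross outlier and corrects the estimate", {
  set.seed(8)
  J <- 20
  bx <- rnorm(J, 0.06, 0.01)
  sy <- rep(0.005, J)
  by <- 0.4 * bx + rnorm(J, 0, sy)
  by[7] <- by[7] + 0.12   # ~ 24 sigma residual
  p <- make_pairs(bx, by, sy)
  res <- mrPresso(p, nSim = 600, seed = 4)
  expect_true("s07" %in% res@outlierSnps)
  expect_lt(res@globalPval, 0.01)
  expect_equal(res@corrected@beta,
               mrIVW(p[setdiff(p@snp, res@outlierSnps)])@estimate@beta)
  expect_error(mrPresso(p, nSim = 0), "positive")
  expect_error(mrPresso(make_pairs(bx[1:3], by[1:3], sy[1:3])), "at least 4")
})

test_that("plot-data export mirrors the estimates", {
  p <- random_pairs(8, 2)
  ivw <- mrIVW(p)
  egger <- mrEgger(p)
  pd <- exportPlotData(p, list(ivw, egger))
  expect_equal(nrow(pd$scatter), 8L)
  expect_equal(nrow(pd$funnel), 8L)
  expect_equal(pd$lines$slope[pd$lines$method == "IVW"], ivw@estimate@beta)
  expect_equal(pd$lines$intercept[pd$lines$method == "Egger"],
               egger@interceptEst)
  expect_equal(pd$funnel$ratio, ratioEstimates(p)$ratio)
})

test_that("the univariable report is deterministic and round-trips", {
  sim <- simulateSummaryStats(simConfig(nSnpExposure = 40, nSnpMediator = 10,
                                        nNullSnps = 5, seed = 21))
  rep1 <- uvmrReport(sim$exposure, sim$outcome, nBoot = 200, nSim = 200,
                     seed = 9)
  rep2 <- uvmrReport(sim$exposure, sim$outcome, nBoot = 200, nSim = 200,
                     seed = 9)
  expect_identical(rep1, rep2)
  path <- tempfile(fileext = ".json")
  writeUvmrReport(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$ivw$beta, rep1$ivw$beta)
  expect_equal(back$params$seed, 9)
  row <- uvmrSummaryRow(rep1)
  expect_equal(nrow(row), 3L)
  expect_setequal(row$method, c("IVW", "Egger", "WeightedMedian"))
})

test_that("all three estimators are near zero on null data", {
  sim <- simulateSummaryStats(simConfig(alpha = 0, tauPrime = 0, seed = 33))
  rep <- uvmrReport(sim$exposure, sim$outcome, nBoot = 300, nSim = 300,
                    seed = 5)
  for (e in list(rep$ivw, rep$egger, rep$weighted_median))
    expect_lt(abs(e$beta), 3 * e$se)
})
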