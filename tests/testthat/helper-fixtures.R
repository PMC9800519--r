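# shared fixture builders and independent oracles

empty_drop <- function() data.frame(snp_id = character(),
                                    reason = character(),
                                    stringsAsFactors = FALSE)

make_pairs <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                       snp = sprintf("s%02d", seq_along(bx))) {
  new("HarmonizedPairs", snp = snp,
      betaX = cbind(X = bx), seX = cbind(X = sx),
      betaY = by, seY = sy, exposures = "X", outcome = "Y",
      dropped = empty_drop())
}

make_mv_pairs <- function(X, by, sy, SX = matrix(0.01, nrow(X), ncol(X))) {
  labs <- paste0("X", seq_len(ncol(X)))
  colnames(X) <- colnames(SX) <- labs
  new("HarmonizedPairs", snp = sprintf("s%02d", seq_len(nrow(X))),
      betaX = X, seX = SX, betaY = by, seY = sy,
      exposures = labs, outcome = "Y", dropped = empty_drop())
}

# quick SumStats builder with sensible defaults
make_stats <- function(label, snp, beta, se, pval,
                       chrom = rep("1", length(snp)),
                       pos = seq_along(snp) * 1000L,
                       ea = rep("A", length(snp)),
                       oa = rep("G", length(snp)),
                       eaf = rep(0.3, length(snp)),
                       n = rep(1e5, length(snp))) {
  sumStats(label, data.frame(snp = snp, chrom = chrom, pos = pos, ea = ea,
                             oa = oa, eaf = eaf, beta = beta, se = se,
                             pval = pval, n = n, stringsAsFactors = FALSE))
}

random_pairs <- function(J, seed) {
  set.seed(seed)
  make_pairs(bx = rnorm(J, 0.08, 0.03),
             by = rnorm(J, 0.04, 0.03),
             sy = runif(J, 0.005, 0.05),
             sx = runif(J, 0.003, 0.02))
}

# --- independent oracles (definitional / stats::lm) -----------------------

ivw_oracle <- function(bx, by, sy) {
  unname(coef(lm(by ~ 0 + bx, weights = 1 / sy^2)))
}

egger_oracle <- function(bx, by, sy) {
  flip <- bx < 0
  bx[flip] <- -bx[flip]; by[flip] <- -by[flip]
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  unname(coef(fit))  # (intercept, slope)
}

# definitional weighted median: cumulative midpoint scores, explicit
# bracketing loop
wm_oracle <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  s <- numeric(length(w))
  acc <- 0
  for (i in seq_along(w)) {
    s[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (s[1] >= 0.5) return(r[1])
  for (i in 2:length(s)) {
    if (s[i] >= 0.5)
      return(r[i - 1] + (r[i] - r[i - 1]) * (0.5 - s[i - 1]) / (s[i] - s[i - 1]))
  }
  r[length(r)]
}

mvmr_oracle <- function(X, by, sy) {
  unname(coef(lm(by ~ 0 + X, weights = 1 / sy^2)))
}

cond_f_oracle <- function(X, SX, k) {
  target <- X[, k]
  v <- 1 / SX[, k]^2
  others <- X[, -k, drop = FALSE]
  fit <- lm(target ~ others, weights = v)
  sum(v * residuals(fit)^2) / (nrow(X) - ncol(X) + 1)
}

# definitional greedy clumping on a plain table (independent of the
# package implementation)
clump_oracle <- function(df, ld_pairs, r2_thr, window) {
  r2_of <- function(a, b) {
    hit <- (ld_pairs$snp_a == a & ld_pairs$snp_b == b) |
      (ld_pairs$snp_a == b & ld_pairs$snp_b == a)
    if (any(hit)) ld_pairs$r2[which(hit)[1]] else 0
  }
  df <- df[order(df$pval, df$chrom, df$pos, df$snp), ]
  keep <- character()
  removed <- character()
  for (i in seq_len(nrow(df))) {
    s <- df$snp[i]
    if (s %in% removed) next
    keep <- c(keep, s)
    for (j in seq_len(nrow(df))) {
      t <- df$snp[j]
      if (t == s || t %in% removed) next
      if (df$chrom[j] == df$chrom[i] &&
          abs(df$pos[j] - df$pos[i]) <= window &&
          r2_of(s, t) >= r2_thr)
        removed <- c(removed, t)
    }
    removed <- c(removed, s)
  }
  keep
}

# trait-to-mediator and reverse effects are kept at 0.06 so that
# trait-mediated per-SNP effects (0.06 * gamma) stay well below the
# genome-wide threshold in the mediator dataset: instrument sets then stay
# uncontaminated across traits while every screening leg keeps z > 4.5
panel_specs <- function() {
  list(
    list(label = "null_trait", effectOnMediator = 0, effectOnOutcome = 0,
         reverseEffect = 0),
    list(label = "med_only", effectOnMediator = 0.06, effectOnOutcome = 0,
         reverseEffect = 0),
    list(label = "out_only", effectOnMediator = 0, effectOnOutcome = 0.1,
         reverseEffect = 0),
    list(label = "both_ok", effectOnMediator = 0.06, effectOnOutcome = 0.1,
         reverseEffect = 0),
    list(label = "reversed", effectOnMediator = 0.06, effectOnOutcome = 0.1,
         reverseEffect = 0.06),
    list(label = "few_snps", effectOnMediator = 0.06, effectOnOutcome = 0.1,
         reverseEffect = 0, nSnp = 5))
}

panel_config <- function(seed) {
  simConfig(nSnpExposure = 60, nSnpMediator = 60, nNullSnps = 10,
            seed = seed)
}
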