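---
title: "Two-step Mendelian randomization mediation: models and methods"
author: "mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step Mendelian randomization mediation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The question this package answers

Two traits that co-occur — for example a metabolic disease and elevated
blood pressure — often share upstream risk factors. Two-step Mendelian
randomization (MR) asks, for each candidate risk factor, how much of its
causal effect on the outcome travels *through* a putative mediator. The
package takes GWAS summary statistics for an exposure trait, a mediator and
an outcome (three non-overlapping cohorts), selects genetic instruments,
screens traits for eligibility, and decomposes the total causal effect into
direct and indirect (mediated) components.

## The structural model and its estimands

All estimation is built on the linear structural model

* exposure $X$ with per-SNP instrument effects $\gamma_j$,
* mediator $M = \alpha X + \delta\text{-driven variation}$,
* outcome $Y = \tau' X + \beta_M M + \varepsilon$,

so that the estimands are

* **direct effect** $\tau'$ (effect of $X$ on $Y$ with $M$ held fixed),
* **indirect effect** $\alpha \beta_M$ (product of coefficients),
* **total effect** $\tau = \tau' + \alpha\beta_M$,
* **mediation proportion** $\alpha\beta_M / \tau$.

In the two-step design the total effect comes from univariable MR of the
trait on the outcome; $\alpha$ from univariable MR of the trait on the
mediator; and $\tau'$ and $\beta_M$ jointly from one multivariable MR fit
of the outcome on (trait, mediator). The indirect effect is the product
$\alpha\beta_M$ with the Sobel (delta-method) standard error
$\sqrt{\beta_M^2\,se_\alpha^2 + \alpha^2\,se_{\beta_M}^2}$. We take both
$\tau'$ and $\beta_M$ from a single joint fit rather than two separate
fits with swapped covariable roles: it is the simplest internally
consistent reading of the design, and it guarantees the two coefficients
are estimated under the same instrument set.

## Instrument selection and harmonization

Instruments must pass $P < 5\times 10^{-8}$, be biallelic single
nucleotides (indels are excluded), and be mutually independent after
greedy LD clumping at $r^2 < 0.001$ within a 10 Mb window. The window is
interpreted as distance to the index SNP (`|pos - pos_index| <= windowBp`),
and clumping ties are broken deterministically by (p-value, chromosome,
position, identifier), so the output is invariant to input row order. A
trait with fewer than 10 surviving variants is excluded from the study via
a catchable `insufficientInstruments` condition rather than an anonymous
error — exclusion is an analysis outcome, not a crash. LD always comes
from a precomputed pairwise table (absent pair = independent); the package
never derives LD from genotype panels.

Harmonization aligns every study to the exposure's effect allele. The four
unambiguous allele configurations (identity, swap, strand complement,
complement-plus-swap) are resolved mechanically; palindromic A/T and G/C
variants — whose swap is indistinguishable from a strand flip — are
resolved by allele frequency only when the minor-allele frequency is at
most 0.30 in every study, and dropped as ambiguous otherwise (a missing
frequency also drops the variant; conservative). The 0.30 limit is the
conventional practice in two-sample MR; the underlying studies this
workflow emulates do not state theirs.

## Univariable estimators and sensitivity suite

The primary estimator is inverse-variance weighted (IVW) regression of
SNP-outcome on SNP-exposure effects through the origin with weights
$1/se_{Y_j}^2$. Cochran's $Q$ on $J-1$ degrees of freedom summarises
heterogeneity; by default the standard error is the *multiplicative
random-effects* one, inflated by $\max(1, \sqrt{Q/df})$ — the fixed-effect
variant is exposed as an option since reference implementations differ and
the choice is rarely reported. MR-Egger adds a free intercept after
orienting all pairs to non-negative exposure effects (required for its
identifying assumption); a non-null intercept estimates directional
pleiotropy, with t-based inference on $J-2$ degrees of freedom and
variance inflation $\max(1, RSS/(J-2))$. The weighted median interpolates
the sorted per-SNP Wald ratios at cumulative midpoint weight 0.5; its
standard error is a seeded parametric bootstrap (default 1000 replicates),
since no closed form exists. Leave-one-out refits flag any single variant
whose omission flips the sign or exits the full-sample CI. MR-PRESSO
simulates the leave-one-out residual sum of squares under its parametric
null (default 1000 replicates, add-one Monte-Carlo p-value) and flags
outliers at a Bonferroni-adjusted empirical 0.05.

P-values are two-sided normal for IVW and the weighted median and
t-distributed for Egger and the multivariable fit — the conventional
pairings. All stochastic operations take an explicit seed and reports
record it.

## Multivariable MR and conditional instrument strength

The joint fit is weighted least squares of outcome effects on the $J\times
K$ matrix of exposure effects, no intercept, weights $1/se_Y^2$, standard
errors inflated by $\max(1, RSS/(J-K))$ on the variance scale. Instruments
are the union of each exposure's genome-wide-significant SNPs, restricted
to SNPs present in all datasets and clumped jointly on the minimum p-value
across exposures (deterministic and symmetric in the exposures). An
exposure whose instrument effects are all exactly zero is excluded from
the solve (coefficient 0, infinite SE) instead of being reported as
collinearity, so adding a no-signal exposure never perturbs the other
coefficients; genuinely collinear columns still raise an error.

Conditional F-statistics measure how much instrument signal one exposure
retains given the others: the target exposure's effects are regressed
(with intercept) on the other exposures' effects, weighted by the inverse
squared standard errors of the target, and $F = Q_x/(J-K+1)$ with $Q_x$
the weighted residual sum of squares. Published variants of this statistic
differ in whether cross-trait sampling covariance enters the weights; this
package uses the covariance-free form above — exact numerical agreement
with implementations that model the covariance is therefore not expected,
though the strong/weak classification at the conventional threshold of 10
agrees in practice.

## Screening and multiple-testing control

The first step screens every candidate trait with three IVW legs:
trait→mediator, trait→outcome, and the reverse leg mediator→trait (the
mediator's instruments, the trait as outcome), because a trait that the
mediator itself causes cannot serve as a mediation exposure.
Benjamini–Hochberg FDR at 5% is applied separately per leg across traits —
matching how screening funnels are usually reported; applying it jointly
across legs is the main alternative and would be slightly more
conservative. A trait is *eligible* exactly when both forward q-values are
significant and the reverse q-value is not. Each trait receives exactly
one status, with instrument insufficiency taking precedence, then the
mediator leg, the outcome leg, and the reverse leg.

## The synthetic-data generator

`simulateSummaryStats()` generates summary statistics directly at the
summary level: per-SNP true effects through the structural model, plus
independent Gaussian noise with the analytic standard error
$1/\sqrt{2p_j(1-p_j)N}$ for a unit-variance trait, independently in the
three cohorts (non-overlapping samples imply independent errors).
Generating at the summary level rather than from individual genotypes is
orders of magnitude faster and is exactly adequate for two-sample MR,
whose inputs are the summary statistics themselves. Defaults describe a
well-powered biobank-scale study: 150 exposure-causal SNPs and 100
mediator-only SNPs with effect SDs 0.05 (typical of quantitative-trait
GWAS hits), minor-allele frequencies uniform on (0.05, 0.5), cohorts of
200,000, $\tau' = 0.2$, $\alpha = 0.3$, $\beta_M = 0.5$ — hence total
0.35, indirect 0.15, proportion 42.9%. Extreme simulated z-scores are
clamped so p-values stay within machine range of (0, 1].

Three generator choices deserve explanation:

* **All simulated SNPs are mutually independent** (an empty LD table);
  clumping is exercised separately with hand-built LD tables. This keeps
  the generator honest about what it does and does not test.
* **Pleiotropic effects are sign-linked to the exposure-increasing
  allele** ($\eta_j \cdot \mathrm{sign}(\gamma_j)$). Directional
  pleiotropy is a statement about the exposure-raising allele; with
  arbitrary allele orientation a nonzero mean pleiotropic effect would
  cancel under Egger's orientation step and be undetectable by
  construction.
* **A palindrome-stress flag** injects A/T variants with small
  cross-cohort frequency jitter to exercise the frequency-based
  harmonization path.

What the generator does *not* emulate: LD structure, binary-trait
liability-scale effects (a disease mediator analysed on the log-odds scale
— all simulated traits are continuous, so the mediation proportion here is
exactly interpretable in a way it is not for a binary mediator),
cross-cohort frequency differences beyond the stress flag, and sample
overlap. Passing tests therefore demonstrate correctness of the estimators
under the linear model, not robustness to those real-data features.

## The screening test panel

Screening correctness is checked on a six-trait panel engineered to
realize one status per trait (plus a second null-leg trait), with
trait→mediator and reverse effects of 0.06 and 60 instruments per trait.
The effect size matters: per-SNP trait-mediated effects on the mediator
($0.06\gamma_j$, SD 0.003) stay more than four sigma below the
genome-wide selection threshold, so the mediator's instrument set is never
contaminated by another trait's variants — mirroring consortium-scale
mediator GWAS, whose own instruments dwarf trait-mediated signals — while
every truly non-null screening leg retains $|z| > 6$. With larger
mediated effects the contamination becomes common, inflates reverse-leg
heterogeneity, and the engineered statuses stop being identifiable; that
regime is a property of bidirectional MR itself (the package deliberately
does not implement directionality filtering, see Limitations).
Residual misclassification in the panel (~5% per null leg) is the designed
false-positive rate of FDR control at 5%, not an error.

## Numerical and degenerate-input conventions

* Wald ratios drop zero exposure-beta SNPs with a warning; an all-zero
  exposure errors.
* The weighted-median interpolation clamps to the extreme ratios when the
  midpoint score 0.5 falls outside the score range.
* Egger requires positive spread in oriented exposure effects; a constant
  column is a singular design and errors.
* MR-PRESSO's corrected estimate falls back to the full-sample IVW if
  outlier removal would leave fewer than two SNPs.
* The mediation proportion is undefined (flagged, never NaN) when the
  total effect is below machine tolerance; it is reported, with a caveat
  flag, when the indirect and total effects disagree in sign.
* Confidence bounds use normal quantiles for IVW/weighted median and t
  quantiles where inference is t-based.

## Problem sizes used by the test suite

The suite checks oracle equivalence against independent weighted-least-
squares fits on 100 random fixtures; parameter recovery and CI coverage
on 200 replicates of the default generator; Sobel type-I error on 500
replicates with the mediation path severed; MR-PRESSO size on 200
replicates of its null at 1000 simulations each; and screening status
assignment on 100 replicates of the six-trait panel. These sizes give
Monte-Carlo error comfortably inside the asserted bands while keeping the
whole suite around half a minute on one core.

## Limitations

* No Steiger/directionality filtering, no MR-RAPS, mode-based or
  contamination-mixture estimators, and no correlated-instrument
  (LD-aware) IVW: the univariable battery is IVW, Egger, weighted median,
  leave-one-out and MR-PRESSO.
* LD is consumed, never computed; proxy-SNP lookup is out of scope.
* The conditional-F convention is the covariance-free one described above.
* For a binary mediator analysed on the log-odds scale, the "proportion
  mediated" has no exact causal interpretation; the generator sidesteps
  this by simulating continuous traits, and results on real binary
  mediators should be read as approximate.

## A worked run

```{r example}
sim <- simulateSummaryStats(simConfig(seed = 7))
med <- twoStepMediation(sim$exposure, sim$mediator, sim$outcome)
med
c(total = sim$truth@total, indirect = sim$truth@indirect,
  proportion = sim$truth@proportion)
```
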