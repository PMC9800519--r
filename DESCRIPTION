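Package: mrmediate
Title: Two-Step Mendelian Randomization Causal Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) from GWAS summary
    statistics, organised around the two-step MR design for causal mediation:
    instrument selection (genome-wide significance filtering, biallelic-SNP
    rule, LD clumping), allele harmonization across studies, univariable MR
    estimators (inverse-variance weighted, MR-Egger, weighted median) with a
    full sensitivity suite (Cochran's Q, Egger intercept test, leave-one-out,
    MR-PRESSO), multivariable MR with conditional F-statistics, and the
    decomposition of a total effect into direct and indirect (mediated)
    components with the mediation proportion. Includes a generator of
    three-cohort synthetic GWAS summary statistics under a linear structural
    exposure-mediator-outcome model with a recorded ground truth, used for
    parameter-recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'sumstats-io.R'
    'clump.R'
    'harmonize.R'
    'mvmr.R'
    'uvmr.R'
    'mediation.R'
    'mrmediate-package.R'
    'presso.R'
    'uvmr-report.R'
    'pipeline.R'
    'simulate.R'
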