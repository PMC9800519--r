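#' @include mediation.R uvmr-report.R
NULL

.DEFAULT_RUN_PARAMS <- list(p_threshold = 5e-8, r2_threshold = 0.001,
                            window_bp = 1e7, min_variants = 10,
                            palindrome_maf_limit = 0.30,
                            fdr = 0.05, n_boot = 1000, n_sim = 1000,
                            seed = 1)

#' Build a full-study run configuration
#'
#' @param traits list of trait inputs; each a list with `path`, optional
#'   `label` and optional `column_map`.
#' @param mediator,outcome input lists with `path` (and optional `label`,
#'   `column_map`).
#' @param ld optional path to a pairwise LD TSV (`SNP_A SNP_B R2`); omitted
#'   means all variants are treated as independent.
#' @param params named list overriding the analysis defaults
#'   (`p_threshold` 5e-8, `r2_threshold` 0.001, `window_bp` 1e7,
#'   `min_variants` 10, `palindrome_maf_limit` 0.30, `fdr` 0.05, `n_boot`
#'   1000, `n_sim` 1000, `seed` 1).
#' @param outputDir directory the run writes into (created if needed).
#' @return a `RunConfig` (classed list).
#' @export
runConfig <- function(traits, mediator, outcome, ld = NULL,
                      params = list(), outputDir = tempfile("mr_run_")) {
  cfg <- list(traits = traits, mediator = mediator, outcome = outcome,
              ld = ld,
              params = utils::modifyList(.DEFAULT_RUN_PARAMS, params),
              output_dir = outputDir)
  errs <- .check_run_config(cfg)
  if (length(errs))
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = "RunConfig")
}

.check_run_config <- function(cfg) {
  errs <- character()
  chk_input <- function(x, what) {
    if (is.null(x$path)) return(paste0(what, ": no path given"))
    if (!file.exists(x$path))
      return(paste0(what, ": file not found: ", x$path))
    NULL
  }
  if (!length(cfg$traits)) errs <- c(errs, "no trait inputs given")
  for (i in seq_along(cfg$traits))
    errs <- c(errs, chk_input(cfg$traits[[i]], paste0("trait ", i)))
  errs <- c(errs, chk_input(cfg$mediator, "mediator"),
            chk_input(cfg$outcome, "outcome"))
  if (!is.null(cfg$ld) && !file.exists(cfg$ld))
    errs <- c(errs, paste0("ld: file not found: ", cfg$ld))
  p <- cfg$params
  in_range <- function(v, lo, hi) is.numeric(v) && length(v) == 1 &&
    is.finite(v) && v > lo && v <= hi
  if (!in_range(p$p_threshold, 0, 1))
    errs <- c(errs, "p_threshold must lie in (0, 1]")
  if (!in_range(p$r2_threshold, 0, 1))
    errs <- c(errs, "r2_threshold must lie in (0, 1]")
  if (!in_range(p$window_bp, 0, Inf))
    errs <- c(errs, "window_bp must be positive")
  if (!is.numeric(p$min_variants) || p$min_variants < 1)
    errs <- c(errs, "min_variants must be at least 1")
  if (!in_range(p$fdr, 0, 1) || p$fdr >= 1)
    errs <- c(errs, "fdr must lie in (0, 1)")
  if (!is.numeric(p$n_boot) || p$n_boot < 2)
    errs <- c(errs, "n_boot must be at least 2")
  if (!is.numeric(p$n_sim) || p$n_sim < 1)
    errs <- c(errs, "n_sim must be at least 1")
  errs[!vapply(errs, is.null, logical(1))]
}

#' Validate a run-configuration file
#'
#' Reads a YAML or JSON configuration (by file extension), applies defaults
#' and reports every violation at once (missing input paths, out-of-range
#' parameters) in a single error.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return a `RunConfig` on success; otherwise an error listing all
#'   violations.
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  inp <- raw$inputs
  if (is.null(inp)) inp <- raw
  runConfig(traits = inp$traits, mediator = inp$mediator,
            outcome = inp$outcome, ld = inp$ld,
            params = if (is.null(raw$params)) list() else raw$params,
            outputDir = if (is.null(raw$output_dir)) tempfile("mr_run_")
                        else raw$output_dir)
}

.read_input <- function(x, default_label) {
  readSumStats(x$path,
               traitLabel = if (is.null(x$label)) default_label else x$label,
               columnMap = x$column_map)
}

#' Run the full two-step MR mediation study
#'
#' End-to-end orchestration: reads every input, screens all candidate
#' traits ([screenTraits()]), runs the mediation decomposition
#' ([twoStepMediation()]) and the univariable sensitivity report
#' ([uvmrReport()]) for each eligible trait, and writes `screen.tsv`,
#' `mediation.tsv`, one `uvmr_<trait>.json` per eligible trait and a
#' `manifest.json` recording parameters, the seed, input content hashes
#' (md5) and every output file. A failure in one trait is logged and the
#' run continues (per-trait isolation); the function errors only if no
#' trait completes screening. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config a `RunConfig` from [runConfig()] or [validateConfig()].
#' @return (invisibly) list with `screen`, `mediation`, `reports`,
#'   `manifest`, `output_dir`.
#' @export
runFullStudy <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  p <- config$params
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) message("[mrmediate] ", ...)

  mediator <- .read_input(config$mediator, "mediator")
  outcome <- .read_input(config$outcome, "outcome")
  ld <- if (is.null(config$ld)) ldTable() else readLDTable(config$ld)
  traits <- list()
  for (i in seq_along(config$traits)) {
    lab <- sprintf("trait%02d", i)
    tr <- tryCatch(.read_input(config$traits[[i]], lab),
                   error = function(e) {
                     log_line("skipping input ", i, ": ", conditionMessage(e))
                     NULL
                   })
    if (!is.null(tr)) traits <- c(traits, list(tr))
  }
  if (!length(traits)) stop("no trait input could be read")

  sel <- list(pThreshold = p$p_threshold, r2Threshold = p$r2_threshold,
              windowBp = p$window_bp, minVariants = p$min_variants,
              palindromeMafLimit = p$palindrome_maf_limit)
  log_line("screening ", length(traits), " trait(s), seed ", p$seed)
  screen <- screenTraits(traits, mediator, outcome, ld, sel, fdrLevel = p$fdr)
  if (!nrow(screen)) stop("screening produced no results")
  .write_tsv(screen, file.path(config$output_dir, "screen.tsv"))

  eligible <- screen$trait[screen$status == "eligible"]
  results <- list()
  reports <- list()
  for (lab in eligible) {
    tr <- traits[[match(lab, vapply(traits, traitLabel, character(1)))]]
    res <- tryCatch({
      med <- twoStepMediation(tr, mediator, outcome, ld, sel)
      rep <- uvmrReport(tr, outcome, ld,
                        pThreshold = p$p_threshold,
                        r2Threshold = p$r2_threshold,
                        windowBp = p$window_bp,
                        minVariants = p$min_variants,
                        palindromeMafLimit = p$palindrome_maf_limit,
                        nBoot = p$n_boot, nSim = p$n_sim, seed = p$seed)
      log_line("trait ", lab, ": mediation complete (",
               med@total@nSnp, " instruments)")
      list(med = med, rep = rep)
    }, error = function(e) {
      log_line("trait ", lab, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      results[[lab]] <- res$med
      reports[[lab]] <- res$rep
      writeUvmrReport(res$rep,
                      file.path(config$output_dir,
                                paste0("uvmr_", lab, ".json")))
    }
  }
  med_tab <- mediationTable(unname(results))
  .write_tsv(med_tab, file.path(config$output_dir, "mediation.tsv"))

  input_paths <- c(vapply(config$traits, function(x) x$path, character(1)),
                   config$mediator$path, config$outcome$path, config$ld)
  manifest <- list(
    params = p,
    seed = p$seed,
    inputs = lapply(input_paths, function(pp)
      list(path = pp, md5 = unname(tools::md5sum(pp)))),
    screen_status_counts = as.list(table(screen$status)),
    outputs = c("screen.tsv", "mediation.tsv",
                if (length(results)) paste0("uvmr_", names(results), ".json")))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(screen = screen, mediation = med_tab, reports = reports,
                 manifest = manifest, output_dir = config$output_dir))
}
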