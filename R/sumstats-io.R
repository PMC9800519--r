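#' @include AllClasses.R
NULL

# canonical on-disk column names, in writing order
.CANONICAL <- c(snp = "SNP", chrom = "CHR", pos = "POS", ea = "EA",
                oa = "OA", eaf = "EAF", beta = "BETA", se = "SE",
                pval = "P", n = "N")

#' Construct a SumStats object from a data.frame
#'
#' @param traitLabel trait/cohort name.
#' @param records data.frame with columns `snp`, `chrom`, `pos`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `pval`, `n` (missing `eaf`/`n` allowed as `NA`).
#' @param source optional provenance string.
#' @return a validated [SumStats-class] object.
#' @export
#' @examples
#' rec <- data.frame(snp = "rs1", chrom = "1", pos = 1000L, ea = "A",
#'                   oa = "G", eaf = 0.3, beta = 0.02, se = 0.005,
#'                   pval = 6.3e-5, n = 50000L)
#' sumStats("height", rec)
sumStats <- function(traitLabel, records, source = "") {
  records <- as.data.frame(records)
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  if (!"n" %in% names(records)) records$n <- NA_real_
  records$chrom <- as.character(records$chrom)
  records$ea <- toupper(as.character(records$ea))
  records$oa <- toupper(as.character(records$oa))
  records <- records[, .SUMSTAT_COLS]
  rownames(records) <- NULL
  new("SumStats", traitLabel = traitLabel, records = records,
      source = source)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Parses a header-bearing delimited table into a [SumStats-class] object.
#' Rows with missing or invalid `beta`, `se` (must be > 0), alleles
#' (effect = other allele) or p-value (outside (0, 1]) are dropped and
#' counted in the parse report, available via `parseReport()`.
#'
#' @param path file path.
#' @param traitLabel trait name to attach; defaults to the file name.
#' @param columnMap named character vector mapping the standard fields
#'   (`snp`, `chrom`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `pval`, `n`)
#'   to the file's header names. Unmapped fields fall back to the canonical
#'   headers `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`. `eaf` and `n`
#'   may be absent from the file.
#' @param delimiter field delimiter, default tab.
#' @return a [SumStats-class] object with a populated `parseReport`.
#' @export
readSumStats <- function(path, traitLabel = basename(path),
                         columnMap = NULL, delimiter = "\t") {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  cmap <- .CANONICAL
  if (!is.null(columnMap)) cmap[names(columnMap)] <- unlist(columnMap)
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  required <- setdiff(names(cmap), c("eaf", "n"))
  missing_cols <- cmap[required][!cmap[required] %in% names(tab)]
  if (length(missing_cols))
    stop("mapped column(s) absent from header: ",
         paste(missing_cols, collapse = ", "))

  get_col <- function(field, as_num = FALSE) {
    col <- cmap[[field]]
    if (!col %in% names(tab)) return(rep(NA_real_, nrow(tab)))
    v <- tab[[col]]
    if (as_num) suppressWarnings(as.numeric(v)) else as.character(v)
  }
  rec <- data.frame(
    snp = get_col("snp"), chrom = get_col("chrom"),
    pos = suppressWarnings(as.integer(get_col("pos", TRUE))),
    ea = toupper(get_col("ea")), oa = toupper(get_col("oa")),
    eaf = get_col("eaf", TRUE), beta = get_col("beta", TRUE),
    se = get_col("se", TRUE), pval = get_col("pval", TRUE),
    n = get_col("n", TRUE), stringsAsFactors = FALSE)

  reasons <- c(
    "missing-beta"  = sum(!is.finite(rec$beta)),
    "invalid-se"    = sum(is.finite(rec$beta) &
                            (!is.finite(rec$se) | rec$se <= 0)),
    "invalid-alleles" = 0L, "invalid-pval" = 0L, "invalid-eaf" = 0L,
    "duplicate-snp" = 0L)
  ok <- is.finite(rec$beta) & is.finite(rec$se) & rec$se > 0
  bad_allele <- ok & (is.na(rec$ea) | is.na(rec$oa) |
                        !grepl("^[ACGT]+$", rec$ea) |
                        !grepl("^[ACGT]+$", rec$oa) | rec$ea == rec$oa)
  reasons["invalid-alleles"] <- sum(bad_allele)
  ok <- ok & !bad_allele
  bad_p <- ok & (!is.finite(rec$pval) | rec$pval <= 0 | rec$pval > 1)
  reasons["invalid-pval"] <- sum(bad_p)
  ok <- ok & !bad_p
  bad_eaf <- ok & !is.na(rec$eaf) & (rec$eaf < 0 | rec$eaf > 1)
  reasons["invalid-eaf"] <- sum(bad_eaf)
  ok <- ok & !bad_eaf
  dup <- ok & duplicated(rec$snp)
  reasons["duplicate-snp"] <- sum(dup)
  ok <- ok & !dup

  report <- list(nRows = nrow(rec), nValid = sum(ok),
                 nDropped = nrow(rec) - sum(ok),
                 reasons = reasons[reasons > 0])
  if (sum(ok) == 0L)
    stop("zero valid rows in ", path,
         " (", report$nRows, " rows read)")
  obj <- sumStats(traitLabel, rec[ok, , drop = FALSE], source = path)
  obj@parseReport <- report
  obj
}

#' @rdname readSumStats
#' @param x a [SumStats-class] object.
#' @return `parseReport` returns the parse report list.
#' @export
parseReport <- function(x) x@parseReport

#' Write summary statistics or harmonized pairs to disk
#'
#' Tab-separated, UTF-8, deterministic canonical column order
#' (`SNP CHR POS EA OA EAF BETA SE P N`); round-trip stable with
#' [readSumStats()] for valid rows.
#'
#' @param stats a [SumStats-class] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSumStats <- function(stats, path) {
  r <- records(stats)
  out <- r[, names(.CANONICAL)]
  names(out) <- unname(.CANONICAL)
  .write_tsv(out, path)
}

#' @rdname writeSumStats
#' @param pairs a [HarmonizedPairs-class] object. The retained table carries
#'   one `BETA_<exposure>`/`SE_<exposure>` column pair per exposure plus the
#'   outcome columns; the drop report is written alongside as
#'   `<path>.dropped.tsv` with one row per dropped SNP.
#' @export
writePairs <- function(pairs, path) {
  out <- data.frame(SNP = pairs@snp, stringsAsFactors = FALSE)
  for (k in seq_along(pairs@exposures)) {
    out[[paste0("BETA_", pairs@exposures[k])]] <- pairs@betaX[, k]
    out[[paste0("SE_", pairs@exposures[k])]] <- pairs@seX[, k]
  }
  out$BETA_OUTCOME <- pairs@betaY
  out$SE_OUTCOME <- pairs@seY
  .write_tsv(out, path)
  .write_tsv(pairs@dropped, paste0(path, ".dropped.tsv"))
  invisible(path)
}

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Construct or read a pairwise LD table
#'
#' @param pairs data.frame with columns `snp_a`, `snp_b`, `r2`. The table is
#'   treated as symmetric; pairs absent from it have r-squared 0.
#' @return an [LDTable-class] object.
#' @export
#' @examples
#' ldTable(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
ldTable <- function(pairs = data.frame(snp_a = character(),
                                       snp_b = character(), r2 = numeric())) {
  pairs <- as.data.frame(pairs)
  pairs$snp_a <- as.character(pairs$snp_a)
  pairs$snp_b <- as.character(pairs$snp_b)
  new("LDTable", pairs = pairs[, c("snp_a", "snp_b", "r2")])
}

#' @rdname ldTable
#' @param path TSV file with header columns `SNP_A`, `SNP_B`, `R2`.
#' @export
readLDTable <- function(path) {
  if (!file.exists(path)) stop("LD table file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("SNP_A", "SNP_B", "R2")
  if (!all(need %in% names(tab)))
    stop("LD table must have columns SNP_A, SNP_B, R2")
  ldTable(data.frame(snp_a = tab$SNP_A, snp_b = tab$SNP_B, r2 = tab$R2))
}

#' Pairwise r-squared lookup
#'
#' @param ld an [LDTable-class] object.
#' @param a,b SNP identifiers.
#' @return the stored r-squared, 1 for `a == b`, 0 for an absent pair.
#' @export
ldR2 <- function(ld, a, b) {
  if (a == b) return(1)
  p <- ld@pairs
  hit <- (p$snp_a == a & p$snp_b == b) | (p$snp_a == b & p$snp_b == a)
  if (any(hit)) p$r2[which(hit)[1]] else 0
}

#' Restrict a SumStats object to a set of SNPs
#'
#' @param stats a [SumStats-class] object.
#' @param ids SNP identifiers to keep (record order preserved).
#' @return a [SumStats-class] object.
#' @export
subsetSnps <- function(stats, ids) {
  r <- records(stats)
  out <- stats
  out@records <- r[r$snp %in% ids, , drop = FALSE]
  rownames(out@records) <- NULL
  out@parseReport <- list()
  out
}
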