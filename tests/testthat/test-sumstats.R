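# data model, readers/writers, harmonization, clumping, instrument selection

write_fixture_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

header <- "SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN"

test_that("well-formed rows parse to identical field values", {
  path <- write_fixture_tsv(c(
    header,
    "rs1\t1\t1000\tA\tG\t0.25\t0.1\t0.02\t5e-07\t10000",
    "rs2\t2\t5000\tT\tC\t0.4\t-0.05\t0.01\t0.001\t10000",
    "rs3\t10\t200\tG\tA\t0.1\t0\t0.03\t1\t9000"))
  ss <- readSumStats(path, traitLabel = "demo")
  r <- records(ss)
  expect_equal(nrow(r), 3L)
  expect_equal(r$snp, c("rs1", "rs2", "rs3"))
  expect_equal(r$beta, c(0.1, -0.05, 0))
  expect_equal(r$se, c(0.02, 0.01, 0.03))
  expect_equal(r$pval, c(5e-7, 1e-3, 1))
  expect_equal(r$chrom, c("1", "2", "10"))
  expect_equal(parseReport(ss)$nDropped, 0L)
})

test_that("a header-only table errors with zero valid rows", {
  expect_error(readSumStats(write_fixture_tsv(header)), "zero valid rows")
})

test_that("invalid rows are dropped and counted per reason", {
  path <- write_fixture_tsv(c(
    header,
    "rs1\t1\t1000\tA\tG\t0.25\t0.1\t0\t5e-07\t10000",    # se = 0
    "rs2\t1\t2000\tA\tA\t0.25\t0.1\t0.02\t5e-07\t10000", # ea == oa
    "rs3\t1\t3000\tA\tG\t0.25\t0.1\t0.02\t1.5\t10000",   # p > 1
    "rs4\t1\t4000\tA\tG\t0.25\t0.1\t0.02\t5e-07\t10000"))
  ss <- readSumStats(path)
  rep <- parseReport(ss)
  expect_equal(nVariants(ss), 1L)
  expect_equal(rep$nDropped, 3L)
  expect_equal(unname(rep$reasons[["invalid-se"]]), 1L)
  expect_equal(unname(rep$reasons[["invalid-alleles"]]), 1L)
  expect_equal(unname(rep$reasons[["invalid-pval"]]), 1L)
})

test_that("missing file and missing mapped column raise errors", {
  expect_error(readSumStats(tempfile()), "not found")
  path <- write_fixture_tsv(c("ID\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
                              "rs1\t1\t1\tA\tG\t0.2\t0.1\t0.02\t1e-5\t10"))
  expect_error(readSumStats(path), "absent from header")
  # a column map repairs it
  expect_s4_class(readSumStats(path, columnMap = c(snp = "ID")), "SumStats")
})

test_that("write -> read round-trips valid records", {
  ss <- make_stats("t", snp = c("rs1", "rs2", "rs3"),
                   beta = c(0.125, -0.5, 0.0625),
                   se = c(0.02, 0.01, 0.5),
                   pval = c(4e-10, 0.5, 0.25))
  path <- tempfile(fileext = ".tsv")
  writeSumStats(ss, path)
  back <- readSumStats(path, traitLabel = "t")
  expect_equal(records(back), records(ss))
  # writing what was read reproduces the file byte-for-byte
  path2 <- tempfile(fileext = ".tsv")
  writeSumStats(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("an empty collection writes a header-only file", {
  ss <- sumStats("empty", data.frame(snp = character(), chrom = character(),
                                     pos = integer(), ea = character(),
                                     oa = character(), eaf = numeric(),
                                     beta = numeric(), se = numeric(),
                                     pval = numeric(), n = numeric()))
  path <- tempfile(fileext = ".tsv")
  writeSumStats(ss, path)
  expect_equal(readLines(path), header)
})

test_that("writePairs emits the aligned table plus a drop report", {
  p <- make_pairs(bx = c(0.1, 0.2), by = c(0.05, 0.1), sy = c(0.01, 0.01))
  p@dropped <- data.frame(snp_id = c("rs9", "rs10"),
                          reason = c("palindromic-ambiguous",
                                     "allele-mismatch"),
                          stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  writePairs(p, path)
  main <- read.delim(path)
  expect_equal(nrow(main), 2L)
  expect_equal(main$BETA_X, c(0.1, 0.2))
  drops <- read.delim(paste0(path, ".dropped.tsv"))
  expect_equal(sort(drops$reason),
               c("allele-mismatch", "palindromic-ambiguous"))
})

# --- harmonization --------------------------------------------------------

two_study <- function(ea2, oa2, beta2 = 0.05, eaf1 = 0.2, eaf2 = 0.2,
                      ea1 = "A", oa1 = "G") {
  x <- make_stats("X", "rs1", beta = 0.1, se = 0.01, pval = 1e-9,
                  ea = ea1, oa = oa1, eaf = eaf1)
  y <- make_stats("Y", "rs1", beta = beta2, se = 0.02, pval = 0.01,
                  ea = ea2, oa = oa2, eaf = eaf2)
  harmonize(x, y)
}

test_that("harmonization aligns the four unambiguous configurations", {
  same <- two_study("A", "G")
  expect_equal(unname(same@betaY), 0.05)
  swapped <- two_study("G", "A", eaf2 = 0.8)
  expect_equal(unname(swapped@betaY), -0.05)
  strand <- two_study("T", "C")          # complement of A/G
  expect_equal(unname(strand@betaY), 0.05)
  strand_swap <- two_study("C", "T", eaf2 = 0.8)
  expect_equal(unname(strand_swap@betaY), -0.05)
  expect_equal(nrow(same@dropped), 0L)
})

test_that("non-matching allele pairs drop with reason allele-mismatch", {
  h <- two_study("A", "C")
  expect_equal(nSnp(h), 0L)
  expect_equal(h@dropped$reason, "allele-mismatch")
})

test_that("palindromic SNPs resolve by EAF or drop as ambiguous", {
  # maximal ambiguity: eaf = 0.5
  amb <- two_study("A", "T", ea1 = "A", oa1 = "T", eaf1 = 0.5, eaf2 = 0.5)
  expect_equal(amb@dropped$reason, "palindromic-ambiguous")
  # resolvable: both rare on the same side -> kept unflipped
  ok <- two_study("A", "T", ea1 = "A", oa1 = "T", eaf1 = 0.1, eaf2 = 0.12)
  expect_equal(unname(ok@betaY), 0.05)
  # opposite sides of 0.5 -> flipped
  fl <- two_study("A", "T", ea1 = "A", oa1 = "T", eaf1 = 0.1, eaf2 = 0.9)
  expect_equal(unname(fl@betaY), -0.05)
  # MAF above the limit in one study -> ambiguous
  hi <- two_study("G", "C", ea1 = "G", oa1 = "C", eaf1 = 0.45, eaf2 = 0.1)
  expect_equal(hi@dropped$reason, "palindromic-ambiguous")
  # missing EAF on a palindromic SNP -> drop (conservative)
  na <- two_study("A", "T", ea1 = "A", oa1 = "T", eaf1 = NA, eaf2 = 0.1)
  expect_equal(na@dropped$reason, "palindromic-ambiguous")
})

test_that("retained plus dropped partition the intersection", {
  set.seed(42)
  n <- 30
  eas <- c("A", "A", "T", "G")
  oas <- c("G", "T", "A", "C")
  pick <- sample.int(4, n, replace = TRUE)
  x <- make_stats("X", sprintf("rs%d", 1:n), beta = rnorm(n), se = runif(n, 0.01, 0.1),
                  pval = runif(n), ea = eas[pick], oa = oas[pick],
                  eaf = runif(n, 0.01, 0.99))
  pick2 <- sample.int(4, n, replace = TRUE)
  y <- make_stats("Y", sprintf("rs%d", 1:n), beta = rnorm(n), se = runif(n, 0.01, 0.1),
                  pval = runif(n), ea = eas[pick2], oa = oas[pick2],
                  eaf = runif(n, 0.01, 0.99))
  h <- harmonize(x, y)
  expect_equal(nSnp(h) + nrow(h@dropped), n)
  expect_true(all(snpIds(h) %in% intersect(snpIds(x), snpIds(y))))
})

test_that("the allele-swap transform is an involution", {
  set.seed(11)
  for (i in 1:20) {
    rec <- list(ea = sample(c("A", "C", "G", "T"), 1),
                oa = sample(c("A", "C", "G", "T"), 1),
                beta = rnorm(1), eaf = runif(1))
    once <- mrmediate:::.flip_record(rec$ea, rec$oa, rec$beta, rec$eaf)
    twice <- mrmediate:::.flip_record(once$ea, once$oa, once$beta, once$eaf)
    expect_equal(twice, rec)
  }
})

test_that("empty intersection errors", {
  x <- make_stats("X", "rs1", 0.1, 0.01, 1e-9)
  y <- make_stats("Y", "rs2", 0.1, 0.01, 1e-9)
  expect_error(harmonize(x, y), "empty SNP intersection")
})

# --- clumping and instrument selection ------------------------------------

test_that("independent SNPs all survive clumping", {
  ss <- make_stats("t", sprintf("rs%d", 1:5), beta = rep(0.1, 5),
                   se = rep(0.01, 5), pval = c(1e-10, 1e-9, 1e-8, 1e-7, 1e-6))
  expect_equal(clumpVariants(ss, ldTable()), sprintf("rs%d", 1:5))
})

test_that("the stronger SNP of a correlated pair wins", {
  ss <- make_stats("t", c("rs1", "rs2"), beta = c(0.1, 0.1),
                   se = c(0.01, 0.01), pval = c(1e-10, 1e-9),
                   pos = c(1000L, 2000L))
  ld <- ldTable(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5))
  expect_equal(clumpVariants(ss, ld, r2Threshold = 0.001), "rs1")
})

test_that("chained LD resolves greedily and matches the definitional oracle", {
  ss <- make_stats("t", sprintf("rs%d", 1:4), beta = rep(0.1, 4),
                   se = rep(0.01, 4),
                   pval = c(1e-12, 1e-11, 1e-10, 1e-9),
                   pos = c(1000L, 2000L, 3000L, 4000L))
  ld_df <- data.frame(snp_a = c("rs1", "rs2"), snp_b = c("rs2", "rs3"),
                      r2 = c(0.9, 0.9))
  got <- clumpVariants(ss, ldTable(ld_df), r2Threshold = 0.1)
  expect_equal(got, c("rs1", "rs3", "rs4"))
  expect_equal(got, clump_oracle(records(ss), ld_df, 0.1, 1e7))
})

test_that("clumping is invariant to input row order and honours the window", {
  ss <- make_stats("t", sprintf("rs%d", 1:6), beta = rep(0.1, 6),
                   se = rep(0.01, 6),
                   pval = c(1e-12, 1e-11, 1e-10, 1e-9, 1e-8, 1e-7),
                   chrom = c("1", "1", "1", "2", "2", "2"),
                   pos = c(1000L, 2000L, 50000L, 1000L, 2000L, 3000L))
  ld <- ldTable(data.frame(snp_a = c("rs1", "rs4"), snp_b = c("rs3", "rs5"),
                           r2 = c(0.8, 0.8)))
  base <- clumpVariants(ss, ld, r2Threshold = 0.1, windowBp = 10000)
  # rs3 is in LD with rs1 but beyond the 10 kb window -> kept
  expect_true("rs3" %in% base)
  expect_false("rs5" %in% base)
  set.seed(3)
  for (i in 1:5) {
    perm <- ss
    perm@records <- perm@records[sample.int(6), ]
    expect_equal(clumpVariants(perm, ld, r2Threshold = 0.1,
                               windowBp = 10000), base)
  }
})

test_that("instrument selection enforces the minimum-variant rule", {
  ss <- make_stats("t", sprintf("rs%d", 1:12), beta = rep(0.1, 12),
                   se = rep(0.01, 12),
                   pval = c(rep(1e-9, 9), 0.5, 0.5, 0.5))
  cond <- tryCatch(selectInstruments(ss, ldTable()),
                   insufficientInstruments = function(c) c)
  expect_s3_class(cond, "insufficientInstruments")
  expect_equal(cond$count, 9L)
  ok <- selectInstruments(make_stats("t", sprintf("rs%d", 1:12),
                                     beta = rep(0.1, 12), se = rep(0.01, 12),
                                     pval = rep(1e-9, 12)), ldTable())
  expect_length(snpIds(ok), 12L)
})

test_that("indels are excluded by the biallelic-SNP rule", {
  ss <- make_stats("t", sprintf("rs%d", 1:11),
                   beta = rep(0.1, 11), se = rep(0.01, 11),
                   pval = rep(1e-9, 11),
                   ea = c("AT", rep("A", 10)))
  cond <- tryCatch(selectInstruments(ss, ldTable(), minVariants = 11),
                   insufficientInstruments = function(c) c)
  expect_equal(cond$count, 10L)
})

test_that("no-op thresholds keep every biallelic SNP", {
  set.seed(5)
  ss <- make_stats("t", sprintf("rs%d", 1:20), beta = rnorm(20),
                   se = runif(20, 0.01, 0.1), pval = runif(20, 1e-10, 0.99),
                   ea = c(rep("A", 18), "AT", "A"),
                   oa = c(rep("G", 19), "GC"))
  inst <- selectInstruments(ss, ldTable(), pThreshold = 1, r2Threshold = 1,
                            minVariants = 1)
  expect_equal(sort(snpIds(inst)), sort(sprintf("rs%d", 1:18)))
})

test_that("per-SNP F follows its closed form", {
  expect_equal(perSnpF(0.1, 0.02), 25)
  expect_equal(perSnpF(0, 0.5), 0)
  expect_equal(perSnpF(0.03, 0.01), 9)
  expect_error(perSnpF(0.1, 0))
})
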