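#' @include AllClasses.R sumstats-io.R
NULL

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) {
  nchar(ea) == 1L & nchar(oa) == 1L & .complement(ea) == oa
}

# allele-swap transform: its own inverse (involution), used when a study
# reports the effect for the other allele
.flip_record <- function(ea, oa, beta, eaf) {
  list(ea = oa, oa = ea, beta = -beta,
       eaf = ifelse(is.na(eaf), NA_real_, 1 - eaf))
}

#' Harmonize allele coding across two or more GWAS studies
#'
#' Aligns every study's per-SNP effect to the effect allele of the first
#' (reference/exposure) study over the SNP intersection. Alignment handles
#' the four unambiguous configurations — identical allele pair, swapped
#' effect/other alleles (beta negated, EAF complemented), strand-complement
#' pair, and complement-plus-swap. Palindromic variants (A/T or G/C), whose
#' swap is indistinguishable from a strand flip, are resolved by effect-
#' allele frequency: when `min(eaf, 1-eaf) <= palindromeMafLimit` in every
#' study the coding is inferred from which side of 0.5 the frequencies fall;
#' otherwise (or when any EAF is missing) the SNP is dropped with reason
#' `"palindromic-ambiguous"`. Allele pairs matching none of the
#' configurations are dropped with reason `"allele-mismatch"`.
#'
#' With two studies the result feeds the univariable estimators; with three
#' or more, the last study is the outcome and all preceding ones become
#' exposure columns of a multivariable fit.
#'
#' @param exposure reference [SumStats-class]; its effect allele defines the
#'   orientation.
#' @param ... one or more further [SumStats-class] objects; the last one is
#'   treated as the outcome study.
#' @param palindromeMafLimit maximum minor-allele frequency at which a
#'   palindromic SNP is considered frequency-resolvable (default 0.30).
#' @return a [HarmonizedPairs-class]; retained plus dropped SNPs partition
#'   the study intersection.
#' @export
#' @examples
#' ex <- sumStats("X", data.frame(snp = "rs1", chrom = "1", pos = 1, ea = "A",
#'   oa = "G", eaf = 0.2, beta = 0.1, se = 0.01, pval = 1e-9, n = 1e5))
#' out <- sumStats("Y", data.frame(snp = "rs1", chrom = "1", pos = 1, ea = "G",
#'   oa = "A", eaf = 0.8, beta = 0.05, se = 0.01, pval = 1e-3, n = 1e5))
#' harmonize(ex, out)   # outcome beta becomes -0.05
harmonize <- function(exposure, ..., palindromeMafLimit = 0.30) {
  studies <- c(list(exposure), list(...))
  if (length(studies) < 2L)
    stop("harmonize needs at least an exposure and an outcome study")
  labels <- make.unique(vapply(studies, traitLabel, character(1)))

  shared <- Reduce(intersect, lapply(studies, snpIds))
  if (!length(shared)) stop("empty SNP intersection across studies")

  ref <- records(studies[[1]])
  ref <- ref[match(shared, ref$snp), , drop = FALSE]
  pal <- .is_palindromic(ref$ea, ref$oa)

  J <- length(shared)
  S <- length(studies)
  beta_al <- matrix(NA_real_, J, S)
  se_al <- matrix(NA_real_, J, S)
  drop_reason <- rep(NA_character_, J)
  beta_al[, 1] <- ref$beta
  se_al[, 1] <- ref$se

  # a palindromic SNP with unusable reference EAF can never be aligned
  ref_maf <- pmin(ref$eaf, 1 - ref$eaf)
  bad_ref_pal <- pal & (is.na(ref$eaf) | ref_maf > palindromeMafLimit)
  drop_reason[bad_ref_pal & is.na(drop_reason)] <- "palindromic-ambiguous"

  for (s in seq.int(2L, S)) {
    rs <- records(studies[[s]])
    rs <- rs[match(shared, rs$snp), , drop = FALSE]
    same  <- rs$ea == ref$ea & rs$oa == ref$oa
    swap  <- rs$ea == ref$oa & rs$oa == ref$ea
    csame <- .complement(rs$ea) == ref$ea & .complement(rs$oa) == ref$oa
    cswap <- .complement(rs$ea) == ref$oa & .complement(rs$oa) == ref$ea
    mism  <- !(same | swap | csame | cswap)

    flip <- rep(FALSE, J)
    flip[!pal & (swap | cswap) & !(same | csame)] <- TRUE

    # palindromic: resolve by EAF side, never by allele labels
    s_maf <- pmin(rs$eaf, 1 - rs$eaf)
    pal_bad <- pal & !mism & (is.na(rs$eaf) | s_maf > palindromeMafLimit)
    pal_ok <- pal & !mism & !pal_bad & !bad_ref_pal
    flip[pal_ok] <- (rs$eaf[pal_ok] > 0.5) != (ref$eaf[pal_ok] > 0.5)

    new_drop <- is.na(drop_reason) &
      (mism | (pal & !mism & (is.na(rs$eaf) | s_maf > palindromeMafLimit)))
    drop_reason[new_drop & mism] <- "allele-mismatch"
    drop_reason[new_drop & !mism] <- "palindromic-ambiguous"

    beta_al[, s] <- ifelse(flip, -rs$beta, rs$beta)
    se_al[, s] <- rs$se
  }

  keep <- is.na(drop_reason)
  dropped <- data.frame(snp_id = shared[!keep],
                        reason = drop_reason[!keep],
                        stringsAsFactors = FALSE)
  bx <- beta_al[keep, -S, drop = FALSE]
  sx <- se_al[keep, -S, drop = FALSE]
  colnames(bx) <- colnames(sx) <- labels[-S]
  new("HarmonizedPairs",
      snp = shared[keep],
      betaX = bx, seX = sx,
      betaY = beta_al[keep, S], seY = se_al[keep, S],
      exposures = labels[-S], outcome = labels[S],
      dropped = dropped)
}
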