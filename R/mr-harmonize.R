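# Harmonization of exposure and outcome summary statistics and instrument
# construction.

.complementAllele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

.isPalindromic <- function(ea, oa) {
  toupper(ea) == .complementAllele(oa)
}

.checkSumstats <- function(stats, label) {
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing <- setdiff(need, names(stats))
  if (length(missing))
    abortGD(label, " table misses columns: ", paste(missing, collapse = ", "))
  if (any(stats$se <= 0, na.rm = TRUE))
    abortGD(label, " table has non-positive SEs")
  stats
}

#' Harmonize exposure and outcome GWAS summary statistics
#'
#' Inner-joins two (or three, for multivariable MR) summary-statistic tables
#' on variant id and aligns outcome effects to the exposure's effect allele:
#' where effect/other alleles are swapped the outcome beta is sign-flipped;
#' strand flips (complementary allele labels) are resolved the same way;
#' strand-ambiguous (palindromic A/T, C/G) variants are dropped with a
#' message, as are variants whose alleles cannot be reconciled. Row order of
#' the inputs is immaterial: the result is canonically ordered by variant
#' id.
#'
#' @param exposure,outcome data.frames in the summary-statistics dialect
#'   (\code{snp_id}, \code{effect_allele}, \code{other_allele}, \code{beta},
#'   \code{se}, optionally \code{pval}, \code{n}).
#' @param exposure2 Optional second-exposure table (multivariable MR).
#' @return An \linkS4class{MRSummarySet}.
#' @export
harmonize <- function(exposure, outcome, exposure2 = NULL) {
  if (inherits(exposure, "SummaryScenario")) {
    scen <- exposure
    exposure <- scen$exposure
    outcome <- scen$outcome
    if (is.null(exposure2)) exposure2 <- scen$exposure2
  }
  .checkSumstats(exposure, "exposure")
  .checkSumstats(outcome, "outcome")
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!is.null(exposure2)) {
    .checkSumstats(exposure2, "second exposure")
    shared <- intersect(shared, exposure2$snp_id)
  }
  if (!length(shared)) abortGD("no overlapping SNPs to harmonize")
  shared <- sort(shared)  # canonical order: row order of inputs is immaterial
  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]

  eaX <- toupper(ex$effect_allele); oaX <- toupper(ex$other_allele)
  eaY <- toupper(ou$effect_allele); oaY <- toupper(ou$other_allele)
  pal <- .isPalindromic(eaX, oaX) | .isPalindromic(eaY, oaY)

  same <- eaY == eaX & oaY == oaX
  swapped <- eaY == oaX & oaY == eaX
  flipSame <- .complementAllele(eaY) == eaX & .complementAllele(oaY) == oaX
  flipSwap <- .complementAllele(eaY) == oaX & .complementAllele(oaY) == eaX
  align <- ifelse(same | flipSame, 1, ifelse(swapped | flipSwap, -1, NA))
  drop <- pal | is.na(align)
  if (any(drop))
    message(sum(drop), " SNP(s) dropped during harmonization (",
            sum(pal), " strand-ambiguous, ", sum(is.na(align) & !pal),
            " irreconcilable alleles)")
  if (all(drop)) abortGD("no SNPs left after harmonization")

  keep <- !drop
  ex <- ex[keep, ]; ou <- ou[keep, ]; align <- align[keep]
  bX2 <- se2 <- numeric()
  if (!is.null(exposure2)) {
    e2 <- exposure2[match(ex$snp_id, exposure2$snp_id), ]
    flip2 <- ifelse(toupper(e2$effect_allele) == toupper(ex$effect_allele) |
                      .complementAllele(e2$effect_allele) ==
                      toupper(ex$effect_allele), 1, -1)
    bX2 <- e2$beta * flip2
    se2 <- e2$se
  }
  MRSummarySet(snps = ex$snp_id, betaX = ex$beta, seX = ex$se,
               betaY = ou$beta * align, seY = ou$se,
               effectAllele = toupper(ex$effect_allele),
               otherAllele = toupper(ex$other_allele),
               pvalX = if ("pval" %in% names(ex)) ex$pval else numeric(),
               betaX2 = bX2, seX2 = se2)
}

#' Build a genetic instrument from harmonized statistics
#'
#' Retains SNPs with exposure p-value at or below \code{pThreshold} and id
#' not in \code{excludeIds}. The full instrument uses an empty exclusion
#' list; a restricted instrument excludes named variants (for example the
#' ADH1B variant rs1229984) while keeping everything else identical.
#'
#' @param set An \linkS4class{MRSummarySet} with exposure p-values (or a
#'   \code{pvalX} recomputable from betas and SEs).
#' @param pThreshold Significance threshold on the exposure association
#'   (default 1: keep all).
#' @param excludeIds Character vector of SNP ids to drop.
#' @return An \linkS4class{MRSummarySet}.
#' @export
buildInstrument <- function(set, pThreshold = 1, excludeIds = character()) {
  stopifnot(is(set, "MRSummarySet"))
  p <- if (length(set@pvalX)) set@pvalX else waldP(set@betaX, set@seX)
  keep <- p <= pThreshold & !(set@snps %in% excludeIds)
  if (!any(keep)) abortGD("empty instrument after filtering")
  set[keep]
}
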