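# Synthetic two-sample GWAS summary statistics under an explicit causal
# model with optional pleiotropy, planted outliers and an ADH1B-like
# large-effect variant.

#' Configuration of the summary-statistics generator
#'
#' Defaults emulate the main mGCIPL scenario: 80 independent instruments for
#' alcohol intake measured in an exposure GWAS of 941,280 samples, an
#' outcome GWAS of 31,434 samples with outcome SD 5.2 um, and a true causal
#' effect of -1.52 um per SD of genetically proxied exposure.
#'
#' @param nSNPs Number of independent instruments (>= 2 for multi-SNP
#'   methods).
#' @param trueEffect Causal effect, outcome units per SD of exposure.
#' @param exposureN,outcomeN GWAS sample sizes; per-SNP standard errors
#'   scale as \code{1/sqrt(n)} (times the outcome SD for the outcome side).
#' @param outcomeSD Phenotypic SD of the outcome (units of the outcome).
#' @param betaSD SD of the true per-allele exposure effects (SD units of
#'   exposure).
#' @param pleiotropyMode \code{"none"}, \code{"balanced"} (direct effects
#'   centred at zero) or \code{"directional"} (centred at
#'   \code{pleiotropySD}).
#' @param pleiotropySD Scale of the direct (pleiotropic) effects, outcome
#'   units.
#' @param nOutliers Number of planted outlier SNPs.
#' @param outlierShift Shift added to the outcome beta of each outlier,
#'   outcome units (e.g. \code{10 * outcomeSD / sqrt(outcomeN)} for a 10-SE
#'   outlier).
#' @param flaggedVariantPresent Include an ADH1B-like variant (id
#'   \code{rs1229984}) whose exposure effect magnitude is at least 5x the
#'   median.
#' @param secondExposureEffect Direct effect of a second exposure
#'   (smoking-initiation analogue) on the outcome; 0 disables the
#'   second-exposure block unless \code{withSecondExposure} is TRUE.
#' @param exposureCorrelation Correlation between the true per-allele
#'   effects of the two exposures (shared genetic architecture); nonzero
#'   values make the univariable IVW estimate biased and give multivariable
#'   MR something to correct.
#' @param withSecondExposure Emit second-exposure summary statistics.
#' @param noiseScale Multiplier on the realized sampling noise (reported SEs
#'   are unchanged); 0 gives the noiseless limit in which every Wald ratio
#'   equals \code{trueEffect} exactly.
#' @param seed Integer seed.
#' @return Validated list of class \code{"SummaryConfig"}.
#' @export
summaryConfig <- function(nSNPs = 80, trueEffect = -1.52,
                          exposureN = 941280, outcomeN = 31434,
                          outcomeSD = 5.2, betaSD = 0.01,
                          pleiotropyMode = c("none", "balanced",
                                             "directional"),
                          pleiotropySD = 0, nOutliers = 0,
                          outlierShift = 0,
                          flaggedVariantPresent = FALSE,
                          secondExposureEffect = 0,
                          exposureCorrelation = 0,
                          withSecondExposure = secondExposureEffect != 0,
                          noiseScale = 1, seed = 1) {
  pleiotropyMode <- match.arg(pleiotropyMode)
  cfg <- list(nSNPs = nSNPs, trueEffect = trueEffect,
              exposureN = exposureN, outcomeN = outcomeN,
              outcomeSD = outcomeSD, betaSD = betaSD,
              pleiotropyMode = pleiotropyMode, pleiotropySD = pleiotropySD,
              nOutliers = nOutliers, outlierShift = outlierShift,
              flaggedVariantPresent = isTRUE(flaggedVariantPresent),
              secondExposureEffect = secondExposureEffect,
              exposureCorrelation = exposureCorrelation,
              withSecondExposure = isTRUE(withSecondExposure),
              noiseScale = noiseScale, seed = seed)
  if (!isScalarCount(cfg$nSNPs)) abortGD("n_snps must be a count >= 1")
  nums <- c(cfg$trueEffect, cfg$exposureN, cfg$outcomeN, cfg$outcomeSD,
            cfg$betaSD, cfg$pleiotropySD, cfg$nOutliers, cfg$outlierShift,
            cfg$secondExposureEffect, cfg$noiseScale,
            cfg$exposureCorrelation)
  if (any(!is.finite(nums))) abortGD("non-finite configuration value")
  if (cfg$exposureN < 2 || cfg$outcomeN < 2)
    abortGD("sample sizes must give positive SEs")
  if (cfg$nOutliers > cfg$nSNPs) abortGD("more outliers than SNPs")
  if (cfg$noiseScale < 0) abortGD("noiseScale must be >= 0")
  if (abs(cfg$exposureCorrelation) > 1)
    abortGD("exposureCorrelation must lie in [-1, 1]")
  class(cfg) <- "SummaryConfig"
  cfg
}

.allelePairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                       ncol = 2, byrow = TRUE)

#' Generate synthetic two-sample GWAS summary statistics
#'
#' Per-SNP true exposure effects are drawn as \code{N(0, betaSD^2)};
#' estimated exposure betas add sampling noise with SE
#' \code{1/sqrt(exposureN)}. Outcome betas are \code{trueEffect} times the
#' true exposure beta, plus an optional pleiotropy term, plus the planted
#' outlier shift, plus sampling noise with SE
#' \code{outcomeSD/sqrt(outcomeN)}. The exposure and outcome tables use
#' disjoint sampling noise, emulating a two-sample design. When requested,
#' an ADH1B-like flagged variant (id \code{rs1229984}) receives a negative
#' exposure effect of 6x \code{betaSD} (well above 5x the median magnitude).
#' SNPs are independent by construction; alleles come from non-palindromic
#' pairs so harmonization is unambiguous.
#'
#' @param config A \code{\link{summaryConfig}}.
#' @return List of class \code{"SummaryScenario"}: \code{exposure},
#'   \code{outcome} and optionally \code{exposure2} tables in the summary
#'   statistics dialect (\code{snp_id}, \code{effect_allele},
#'   \code{other_allele}, \code{beta}, \code{se}, \code{pval}, \code{n}),
#'   plus \code{truth} (true betas, pleiotropy terms, outlier/flag masks).
#' @export
#' @examples
#' sc <- generateSummaryStats(summaryConfig(nSNPs = 10, seed = 3))
#' head(sc$exposure)
generateSummaryStats <- function(config = summaryConfig()) {
  stopifnot(inherits(config, "SummaryConfig"))
  withSeed(config$seed, {
    n <- config$nSNPs
    ids <- sprintf("rs%d", 100000 + seq_len(n))
    flagged <- rep(FALSE, n)
    if (config$flaggedVariantPresent) {
      ids[1] <- "rs1229984"
      flagged[1] <- TRUE
    }
    pair <- .allelePairs[sample(nrow(.allelePairs), n, TRUE), , drop = FALSE]
    swap <- stats::runif(n) < 0.5
    ea <- ifelse(swap, pair[, 2], pair[, 1])
    oa <- ifelse(swap, pair[, 1], pair[, 2])

    bTrue <- stats::rnorm(n, 0, config$betaSD)
    if (config$flaggedVariantPresent) bTrue[1] <- -6 * config$betaSD
    seX <- rep(1 / sqrt(config$exposureN), n)
    seY <- rep(config$outcomeSD / sqrt(config$outcomeN), n)

    alphaP <- switch(config$pleiotropyMode,
                     none = rep(0, n),
                     balanced = stats::rnorm(n, 0, config$pleiotropySD),
                     directional = stats::rnorm(n, config$pleiotropySD,
                                                config$pleiotropySD))
    outlier <- rep(FALSE, n)
    if (config$nOutliers > 0)
      outlier[seq(n, by = -1, length.out = config$nOutliers)] <- TRUE

    ns <- config$noiseScale
    bxHat <- bTrue + ns * stats::rnorm(n, 0, seX)
    byTrue <- config$trueEffect * bTrue + alphaP +
      ifelse(outlier, config$outlierShift, 0)

    out <- list()
    if (config$withSecondExposure) {
      rho <- config$exposureCorrelation
      sd2 <- config$betaSD / 2
      b2True <- rho * (sd2 / config$betaSD) * bTrue +
        sqrt(1 - rho^2) * stats::rnorm(n, 0, sd2)
      se2 <- rep(1 / sqrt(config$exposureN), n)
      b2Hat <- b2True + ns * stats::rnorm(n, 0, se2)
      byTrue <- byTrue + config$secondExposureEffect * b2True
      out$exposure2 <- data.frame(
        snp_id = ids, effect_allele = ea, other_allele = oa, beta = b2Hat,
        se = se2, pval = waldP(b2Hat, se2), n = config$exposureN)
    } else b2True <- NULL
    byHat <- byTrue + ns * stats::rnorm(n, 0, seY)

    out$exposure <- data.frame(
      snp_id = ids, effect_allele = ea, other_allele = oa, beta = bxHat,
      se = seX, pval = waldP(bxHat, seX), n = config$exposureN)
    out$outcome <- data.frame(
      snp_id = ids, effect_allele = ea, other_allele = oa, beta = byHat,
      se = seY, pval = waldP(byHat, seY), n = config$outcomeN)
    out$truth <- data.frame(snp_id = ids, betaTrue = bTrue,
                            pleiotropy = alphaP, outlierTruth = outlier,
                            flaggedVariant = flagged)
    if (!is.null(b2True)) out$truth$beta2True <- b2True
    out$config <- config
    structure(out[c("exposure", "outcome",
                    intersect("exposure2", names(out)), "truth", "config")],
              class = "SummaryScenario")
  })
}

#' @export
print.SummaryScenario <- function(x, ...) {
  cat("Synthetic two-sample GWAS scenario:", nrow(x$exposure), "SNPs,",
      "true effect", x$config$trueEffect, "\n")
  invisible(x)
}
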