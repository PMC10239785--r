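# MR-PRESSO: pleiotropy residual sum and outlier test.

#' MR-PRESSO global, outlier and distortion tests
#'
#' The observed statistic is the weighted residual sum of squares of the
#' outcome betas around their leave-one-out IVW predictions (weights
#' \code{1/seY^2}). Its null distribution is built from \code{nSim}
#' parametric simulations under the no-pleiotropy model: outcome betas
#' redrawn as \code{N(theta_(-j) * betaX_j, seY_j)}. The global p-value is
#' the exceedance fraction. Per-SNP outlier p-values compare each observed
#' weighted squared residual with its simulated distribution and are
#' Bonferroni-corrected; SNPs significant at \code{alpha} are outliers. When
#' outliers are found, an outlier-corrected IVW estimate on the retained
#' SNPs is reported, together with a distortion p-value obtained by
#' comparing the observed corrected-minus-original shift against the shifts
#' produced by removing equally many randomly chosen SNPs. When no outliers
#' are detected no corrected estimate is produced (the estimate slot is
#' \code{NA}), matching standard reporting practice for this method.
#'
#' @param set An \linkS4class{MRSummarySet} with at least 4 SNPs.
#' @param nSim Number of parametric simulations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level of the Bonferroni-corrected outlier test.
#' @param varianceModel Variance model of the corrected IVW estimate.
#' @return An \linkS4class{MREstimate} with diagnostics \code{global_rss},
#'   \code{global_p}, \code{outlier_ids}, \code{outlier_p} (Bonferroni
#'   corrected, capped at 1) and, when outliers exist, \code{distortion_p}
#'   and the \code{original} IVW estimate.
#' @export
mrPresso <- function(set, nSim = 1000, seed = 1, alpha = 0.05,
                     varianceModel = "multiplicative_random") {
  stopifnot(is(set, "MRSummarySet"))
  n <- nSNPs(set)
  if (n < 4) abortGD("MR-PRESSO needs at least 4 SNPs")
  if (nSim < 100) abortGD("nSim must be at least 100")
  bx <- set@betaX; by <- set@betaY; sey <- set@seY
  w <- 1 / sey^2

  # leave-one-out IVW estimates from totals (O(n))
  Sxy <- sum(w * bx * by); Sxx <- sum(w * bx^2)
  looTheta <- (Sxy - w * bx * by) / (Sxx - w * bx^2)
  resObs <- by - looTheta * bx
  rssObsPer <- w * resObs^2
  rssObs <- sum(rssObsPer)

  sim <- withSeed(seed, {
    rssSim <- numeric(nSim)
    exceedPer <- numeric(n)
    for (s in seq_len(nSim)) {
      bySim <- stats::rnorm(n, looTheta * bx, sey)
      SxyS <- sum(w * bx * bySim);
      looS <- (SxyS - w * bx * bySim) / (Sxx - w * bx^2)
      rPer <- w * (bySim - looS * bx)^2
      rssSim[s] <- sum(rPer)
      exceedPer <- exceedPer + (rPer >= rssObsPer)
    }
    list(rssSim = rssSim, exceedPer = exceedPer)
  })
  globalP <- (1 + sum(sim$rssSim >= rssObs)) / (1 + nSim)
  outlierPRaw <- (1 + sim$exceedPer) / (1 + nSim)
  outlierP <- pmin(1, outlierPRaw * n)  # Bonferroni
  isOutlier <- outlierP < alpha

  original <- mrIVW(set, varianceModel)
  diag <- list(global_rss = rssObs, global_p = globalP,
               outlier_ids = set@snps[isOutlier],
               outlier_p = stats::setNames(outlierP, set@snps),
               n_sim = nSim, original = original)

  if (!any(isOutlier)) {
    return(new("MREstimate", method = "MR-PRESSO", estimate = NA_real_,
               ciLow = NA_real_, ciHigh = NA_real_, p = NA_real_,
               nSNPs = as.integer(n), diagnostics = diag))
  }
  corrected <- mrIVW(set[!isOutlier], varianceModel)
  shiftObs <- estimate(corrected) - estimate(original)
  nOut <- sum(isOutlier)
  distortion <- withSeed(seed + 1, {
    shifts <- vapply(seq_len(nSim), function(s) {
      dropIdx <- sample(n, nOut)
      keep <- setdiff(seq_len(n), dropIdx)
      .ivwCore(bx[keep], by[keep], sey[keep])$theta - estimate(original)
    }, numeric(1))
    (1 + sum(abs(shifts) >= abs(shiftObs))) / (1 + nSim)
  })
  diag$distortion_p <- distortion
  diag$Q <- diagnostics(corrected)$Q
  diag$Q_p <- diagnostics(corrected)$Q_p
  MREstimate("MR-PRESSO", estimate(corrected), diagnostics(corrected)$se,
             n - nOut, diagnostics = diag)
}
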