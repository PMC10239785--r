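# Two-sample MR estimators: Wald ratio, IVW, MR-Egger, weighted median,
# weighted mode and multivariable MR. All operate on a harmonized
# MRSummarySet and return MREstimate objects with method-appropriate
# diagnostics.

#' Single-SNP Wald ratio
#'
#' The causal-effect estimate of one instrument: outcome beta divided by
#' exposure beta. The first-order delta-method SE is
#' \code{seY / |betaX|}; the optional second-order version adds the
#' contribution of the exposure beta's sampling error,
#' \code{sqrt(seY^2 / betaX^2 + betaY^2 * seX^2 / betaX^4)}.
#'
#' @param betaX,betaY,seX,seY Per-SNP statistics (vectorized).
#' @param secondOrder Use the second-order SE.
#' @return data.frame with columns \code{estimate} and \code{se}.
#' @export
#' @examples
#' waldRatio(0.2, 0.4, 0.01, 0.05)  # estimate 2
waldRatio <- function(betaX, betaY, seX, seY, secondOrder = FALSE) {
  if (any(betaX == 0)) abortGD("zero exposure beta: Wald ratio undefined")
  est <- betaY / betaX
  se <- if (secondOrder)
    sqrt(seY^2 / betaX^2 + betaY^2 * seX^2 / betaX^4)
  else seY / abs(betaX)
  data.frame(estimate = est, se = se)
}

# Internal: IVW point estimate and components from raw vectors.
.ivwCore <- function(bx, by, sey) {
  w <- 1 / sey^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  seFixed <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - theta * bx)^2)
  list(theta = theta, seFixed = seFixed, Q = Q)
}

#' Inverse-variance weighted estimate
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin, with weights \code{1/seY^2}. Under the multiplicative
#' random-effects model (the default) the SE is inflated by
#' \code{sqrt(max(1, Q/(n-1)))}, where Q is Cochran's heterogeneity
#' statistic; the fixed-effect model uses the unscaled SE. With a single
#' SNP the estimate falls back to the Wald ratio (with a message).
#'
#' @param set An \linkS4class{MRSummarySet}.
#' @param varianceModel \code{"multiplicative_random"} or \code{"fixed"}.
#' @return An \linkS4class{MREstimate} with \code{Q}, \code{Q_p} and
#'   \code{I2} diagnostics.
#' @export
mrIVW <- function(set, varianceModel = c("multiplicative_random", "fixed")) {
  stopifnot(is(set, "MRSummarySet"))
  varianceModel <- match.arg(varianceModel)
  n <- nSNPs(set)
  if (n < 1) abortGD("empty summary set")
  if (n == 1) {
    message("single SNP: falling back to the Wald ratio")
    wr <- waldRatio(set@betaX, set@betaY, set@seX, set@seY)
    return(MREstimate("Wald ratio", wr$estimate, wr$se, 1L))
  }
  core <- .ivwCore(set@betaX, set@betaY, set@seY)
  scale <- if (varianceModel == "multiplicative_random")
    sqrt(max(1, core$Q / (n - 1))) else 1
  se <- core$seFixed * scale
  Qp <- stats::pchisq(core$Q, df = n - 1, lower.tail = FALSE)
  I2 <- max(0, (core$Q - (n - 1)) / core$Q)
  MREstimate(paste0("IVW (", sub("_", " ", varianceModel), ")"),
             core$theta, se, n,
             diagnostics = list(Q = core$Q, Q_p = Qp, I2 = I2,
                                variance_model = varianceModel))
}

# Weighted least squares by explicit normal equations; returns coefficients
# and the unscaled covariance (X'WX)^{-1} plus the weighted RSS.
.wlsFit <- function(X, y, w) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  if (rcond(XtWX) < 1e-12) abortGD("collinear design in weighted regression")
  V <- solve(XtWX)
  beta <- as.numeric(V %*% (XtW %*% y))
  rss <- sum(w * (y - as.numeric(X %*% beta))^2)
  list(beta = beta, V = V, rss = rss)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an intercept
#' (weights \code{1/seY^2}), after orienting every SNP so its exposure beta
#' is positive. The slope estimates the causal effect under the InSIDE
#' assumption; the intercept and its p-value test for average directional
#' pleiotropy. SEs use the multiplicative random-effects inflation
#' \code{max(1, sigma)}. The regression-dilution statistic
#' \code{I2GX = (Q_GX - (n-1))/Q_GX} (floored at 0) quantifies exposure-beta
#' measurement error, with \code{Q_GX} the weighted heterogeneity of the
#' exposure betas.
#'
#' @param set An \linkS4class{MRSummarySet} with at least 3 SNPs.
#' @return An \linkS4class{MREstimate} with \code{egger_intercept},
#'   \code{intercept_p}, \code{intercept_se}, \code{Q}, \code{Q_p} and
#'   \code{I2GX} diagnostics.
#' @export
mrEgger <- function(set) {
  stopifnot(is(set, "MRSummarySet"))
  n <- nSNPs(set)
  if (n < 3) abortGD("MR-Egger needs at least 3 SNPs")
  flip <- sign(set@betaX)
  bx <- set@betaX * flip
  by <- set@betaY * flip
  w <- 1 / set@seY^2
  fit <- .wlsFit(cbind(1, bx), by, w)
  sigma2 <- fit$rss / (n - 2)
  infl <- max(1, sigma2)
  seInt <- sqrt(fit$V[1, 1] * infl)
  seSlope <- sqrt(fit$V[2, 2] * infl)
  QGX <- {
    wx <- 1 / set@seX^2
    mx <- sum(wx * bx) / sum(wx)
    sum(wx * (bx - mx)^2)
  }
  I2GX <- max(0, (QGX - (n - 1)) / QGX)
  Qp <- stats::pchisq(fit$rss, df = n - 2, lower.tail = FALSE)
  MREstimate("MR-Egger", fit$beta[2], seSlope, n,
             diagnostics = list(egger_intercept = fit$beta[1],
                                intercept_se = seInt,
                                intercept_p = waldP(fit$beta[1], seInt),
                                Q = fit$rss, Q_p = Qp, I2GX = I2GX))
}

# Weighted median of Wald ratios at probability 0.5 with the cumulative
# standardized weight interpolation s_j = (cumsum(w) - w/2)/sum(w).
.weightedMedianPoint <- function(ratios, weights) {
  weightedQuantile(ratios, weights, 0.5)
}

# Parametric bootstrap SE for ratio-based estimators: resample betas from
# their SEs and recompute the point estimate.
.bootstrapSE <- function(set, pointFun, nBoot, seed) {
  withSeed(seed, {
    n <- nSNPs(set)
    est <- vapply(seq_len(nBoot), function(b) {
      bx <- stats::rnorm(n, set@betaX, set@seX)
      by <- stats::rnorm(n, set@betaY, set@seY)
      pointFun(bx, by)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted median estimate
#'
#' Orders the per-SNP Wald ratios and takes the inverse-variance weighted
#' median: linear interpolation of the cumulative standardized weights at
#' probability one half. Consistent as long as at least half the weight
#' comes from valid instruments. The SE is a parametric bootstrap
#' (resampling betas from their SEs).
#'
#' @param set An \linkS4class{MRSummarySet} with at least 3 SNPs.
#' @param nBoot Bootstrap draws (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An \linkS4class{MREstimate}.
#' @export
mrMedian <- function(set, nBoot = 1000, seed = 1) {
  stopifnot(is(set, "MRSummarySet"))
  n <- nSNPs(set)
  if (n < 3) abortGD("weighted median needs at least 3 SNPs")
  ratio <- waldRatio(set@betaX, set@betaY, set@seX, set@seY)
  wts <- 1 / ratio$se^2
  est <- .weightedMedianPoint(ratio$estimate, wts)
  se <- .bootstrapSE(set, function(bx, by) {
    r <- by / bx
    .weightedMedianPoint(r, wts)
  }, nBoot, seed)
  MREstimate("Weighted median", est, se, n,
             diagnostics = list(n_boot = nBoot))
}

# Mode of the weighted, normal-kernel-smoothed density of ratios on a fixed
# grid. Bandwidth: phi x modified Silverman rule using the median absolute
# deviation, h = phi * 0.9 * min(sd, mad) * n^(-1/5).
.modePoint <- function(ratios, weights, phi, gridSize = 512) {
  s <- 0.9 * min(stats::sd(ratios), stats::mad(ratios)) *
    length(ratios)^(-1 / 5)
  if (!is.finite(s) || s <= 0) return(ratios[1])  # degenerate: all equal
  h <- phi * s
  # the ratio values join the regular grid so that narrow-bandwidth density
  # spikes cannot fall between grid points
  grid <- sort(c(seq(min(ratios) - 3 * h, max(ratios) + 3 * h,
                     length.out = gridSize), ratios))
  dens <- vapply(grid, function(g)
    sum(weights * stats::dnorm((g - ratios) / h)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimate
#'
#' Estimates the causal effect as the mode of the inverse-variance weighted,
#' normal-kernel-smoothed empirical density of the per-SNP Wald ratios,
#' evaluated on a 512-point grid spanning the ratios plus/minus three
#' bandwidths. Consistent when the largest group of SNPs sharing a ratio
#' value are valid instruments. SE by parametric bootstrap.
#'
#' @param set An \linkS4class{MRSummarySet} with at least 3 SNPs.
#' @param phi Bandwidth multiplier (> 0, default 1).
#' @param nBoot Bootstrap draws (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An \linkS4class{MREstimate}.
#' @export
mrMode <- function(set, phi = 1, nBoot = 1000, seed = 1) {
  stopifnot(is(set, "MRSummarySet"))
  n <- nSNPs(set)
  if (n < 3) abortGD("weighted mode needs at least 3 SNPs")
  if (!is.numeric(phi) || phi <= 0) abortGD("phi must be > 0")
  ratio <- waldRatio(set@betaX, set@betaY, set@seX, set@seY)
  wts <- 1 / ratio$se^2
  est <- .modePoint(ratio$estimate, wts, phi)
  se <- .bootstrapSE(set, function(bx, by) {
    r <- by / bx
    .modePoint(r, 1 / (set@seY / abs(bx))^2, phi)
  }, nBoot, seed)
  MREstimate("Weighted mode", est, se, n,
             diagnostics = list(phi = phi, n_boot = nBoot))
}

#' Multivariable MR
#'
#' Weighted regression of the outcome betas jointly on both exposures' betas
#' with no intercept and weights \code{1/seY^2}; reports the primary
#' (alcohol) exposure coefficient adjusted for the genetically proxied
#' second exposure. SE uses the multiplicative random-effects inflation.
#'
#' @param set An \linkS4class{MRSummarySet} carrying second-exposure betas.
#' @return An \linkS4class{MREstimate}; diagnostics include the
#'   second-exposure coefficient.
#' @export
mrMVMR <- function(set) {
  stopifnot(is(set, "MRSummarySet"))
  n <- nSNPs(set)
  if (n < 3) abortGD("multivariable MR needs at least 3 SNPs")
  if (!length(set@betaX2)) abortGD("no second-exposure betas in the set")
  w <- 1 / set@seY^2
  X <- cbind(set@betaX, set@betaX2)
  fit <- .wlsFit(X, set@betaY, w)
  sigma2 <- fit$rss / (n - 2)
  infl <- max(1, sigma2)
  se <- sqrt(fit$V[1, 1] * infl)
  MREstimate("Multivariable MR", fit$beta[1], se, n,
             diagnostics = list(beta_exposure2 = fit$beta[2],
                                se_exposure2 = sqrt(fit$V[2, 2] * infl),
                                Q = fit$rss))
}

#' Run the full MR estimator battery
#'
#' Convenience wrapper running IVW, MR-Egger, weighted median, weighted
#' mode, MR-PRESSO and (when second-exposure betas are present)
#' multivariable MR on one harmonized set.
#'
#' @param set An \linkS4class{MRSummarySet}.
#' @param methods Character vector choosing the estimators.
#' @param nBoot,nSim,seed Simulation controls passed through.
#' @return Named list of \linkS4class{MREstimate} objects.
#' @export
mrAll <- function(set, methods = c("ivw", "egger", "median", "mode",
                                   "presso", "mvmr"),
                  nBoot = 1000, nSim = 1000, seed = 1) {
  if (!length(set@betaX2)) methods <- setdiff(methods, "mvmr")
  out <- list()
  for (m in methods)
    out[[m]] <- switch(m,
                       ivw = mrIVW(set),
                       egger = mrEgger(set),
                       median = mrMedian(set, nBoot, seed),
                       mode = mrMode(set, 1, nBoot, seed),
                       presso = mrPresso(set, nSim, seed),
                       mvmr = mrMVMR(set),
                       abortGD("unknown MR method: ", m))
  out
}

#' Tabulate MR estimates
#'
#' @param estimates A list of \linkS4class{MREstimate} objects (e.g. from
#'   \code{\link{mrAll}}).
#' @return data.frame with one row per method.
#' @export
mrTable <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(method = e@method, estimate = e@estimate, ciLow = e@ciLow,
               ciHigh = e@ciHigh, p = e@p, nSNPs = e@nSNPs)))
}
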