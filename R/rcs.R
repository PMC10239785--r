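# Restricted cubic splines: truncated-power basis with linear tails, fixed
# heuristic knot percentiles, AIC model selection over 3-7 knots.

# Fixed heuristic knot percentiles (in %) for k = 3..7 knots.
.rcsKnotPercentiles <- list(
  `3` = c(10, 50, 90),
  `4` = c(5, 35, 65, 95),
  `5` = c(5, 27.5, 50, 72.5, 95),
  `6` = c(5, 23, 41, 59, 77, 95),
  `7` = c(2.5, 18.33, 34.17, 50, 65.83, 81.67, 97.5))

#' Restricted cubic spline basis
#'
#' Truncated-power parameterization of a restricted cubic spline: for knots
#' \code{t1 < ... < tk} the basis is the linear term plus \code{k - 2}
#' nonlinear terms
#' \deqn{X_j = [(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k -
#'   t_{k-1}) + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k -
#'   t_1)^2,}
#' which is continuous with continuous first and second derivatives and
#' exactly linear beyond the boundary knots. Below the first knot every
#' nonlinear column is zero.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing numeric vector of at least 3 knots.
#' @return Matrix with \code{length(knots) - 1} columns, the first being
#'   \code{x} itself.
#' @export
#' @examples
#' b <- rcsBasis(seq(0, 10, 0.5), knots = c(2, 5, 8))
rcsBasis <- function(x, knots) {
  if (length(knots) < 3) abortGD("need at least 3 knots")
  if (is.unsorted(knots, strictly = TRUE))
    abortGD("knots must be strictly increasing (no duplicates)")
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm <- (tk - t1)^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (pos3(x - tj) -
                       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("x", paste0("x", seq_len(k - 2), "p"))
  out
}

#' Fit restricted-cubic-spline dose-response models with AIC selection
#'
#' For each candidate number of knots (3 to 7) places knots at the fixed
#' heuristic percentiles of the natural-log intake distribution of the
#' retained regular drinkers, fits the maximally adjusted model (linear for
#' continuous outcomes, logistic for glaucoma) and selects the fit
#' minimizing the Akaike Information Criterion. The returned curve is the
#' partial dose-response effect over an intake grid, expressed relative to
#' the reference intake (the sample median), with pointwise Wald 95\%
#' intervals; for glaucoma it is on the odds-ratio scale. Guideline
#' positions (UK; US women/men) are attached for plotting.
#'
#' @param data Analysis cohort (regular drinkers with positive trimmed
#'   intake are selected internally).
#' @param outcome One of \code{iop}, \code{mrnfl}, \code{mgcipl},
#'   \code{glaucoma}.
#' @param kRange Candidate numbers of knots (subset of 3:7).
#' @param covariates Covariate specification.
#' @param gridLength Number of grid points of the returned curve.
#' @param referenceGrams Intake the curve is measured against; default the
#'   median retained intake.
#' @return A \linkS4class{SplineFit}.
#' @export
fitRCS <- function(data, outcome, kRange = 3:7,
                   covariates = covariateSpec(), gridLength = 200,
                   referenceGrams = NULL) {
  if (any(kRange < 3 | kRange > 7)) abortGD("kRange must lie within 3..7")
  dat <- data[!is.na(data$category) & data$category == "regular" &
                !is.na(data$includedAfterTrim) & data$includedAfterTrim &
                !is.na(data$gramsWeek) & data$gramsWeek > 0, ]
  dat$logIntake <- log(dat$gramsWeek)
  if (is.null(referenceGrams)) referenceGrams <- stats::median(dat$gramsWeek)

  isGlaucoma <- outcome == "glaucoma"
  if (isGlaucoma) {
    dat$glaucomaCase <- .glaucomaBinary(dat)
    dat <- dat[!is.na(dat$glaucomaCase), ]
    yname <- "glaucomaCase"
  } else yname <- outcome
  vars <- c(yname, "logIntake", covariates$name)
  dat <- dat[stats::complete.cases(dat[, vars]), ]

  fits <- lapply(kRange, function(k) {
    kn <- stats::quantile(dat$logIntake,
                          .rcsKnotPercentiles[[as.character(k)]] / 100,
                          names = FALSE)
    if (any(diff(kn) <= 0)) return(NULL)  # degenerate percentile ties
    basis <- rcsBasis(dat$logIntake, kn)
    colnames(basis) <- paste0("rcs", seq_len(ncol(basis)))
    df <- cbind(dat[, c(yname, covariates$name), drop = FALSE],
                as.data.frame(basis))
    f <- .modelFormula(yname, paste(colnames(basis), collapse = " + "),
                       covariates)
    fit <- if (isGlaucoma)
      stats::glm(f, data = df, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100))
    else stats::lm(f, data = df)
    list(k = k, knots = kn, fit = fit, aic = stats::AIC(fit),
         nbasis = ncol(basis))
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) abortGD("no fittable knot configuration")
  aicTable <- data.frame(nKnots = vapply(fits, `[[`, 0, "k"),
                         aic = vapply(fits, `[[`, 0, "aic"))
  best <- fits[[which.min(aicTable$aic)]]

  # partial-effect curve: spline block difference to the reference intake
  grid <- exp(seq(min(dat$logIntake), max(dat$logIntake),
                  length.out = gridLength))
  B <- rcsBasis(log(grid), best$knots)
  B0 <- rcsBasis(log(referenceGrams), best$knots)
  D <- B - matrix(B0, nrow(B), ncol(B), byrow = TRUE)
  cf <- stats::coef(best$fit)
  V <- stats::vcov(best$fit)
  idx <- paste0("rcs", seq_len(best$nbasis))
  eff <- as.numeric(D %*% cf[idx])
  se <- sqrt(rowSums((D %*% V[idx, idx]) * D))
  curve <- data.frame(grams = grid, logGrams = log(grid), estimate = eff,
                      ciLow = eff - 1.96 * se, ciHigh = eff + 1.96 * se)
  scale <- "identity"
  if (isGlaucoma) {
    curve$estimate <- exp(curve$estimate)
    curve$ciLow <- exp(curve$ciLow)
    curve$ciHigh <- exp(curve$ciHigh)
    scale <- "odds-ratio"
  }
  new("SplineFit", nKnots = as.integer(best$k), knots = best$knots,
      coefficients = cf, aic = best$aic, aicTable = aicTable,
      curve = curve, scale = scale,
      guidelines = c(UK = guidelineGrams("UK", "women"),
                     US_women = guidelineGrams("US", "women"),
                     US_men = guidelineGrams("US", "men")))
}

#' Plot a fitted dose-response spline
#'
#' Base-graphics rendering of the \linkS4class{SplineFit} curve with its
#' pointwise confidence band and the UK/US guideline verticals.
#'
#' @param x A \linkS4class{SplineFit}.
#' @param y Ignored.
#' @param xlab,ylab,main Usual graphical labels.
#' @param ... Passed to \code{plot}.
#' @export
setMethod("plot", signature(x = "SplineFit", y = "missing"),
          function(x, y, xlab = "Alcohol intake (g/week)",
                   ylab = "Effect vs reference intake", main = NULL, ...) {
  cv <- x@curve
  plot(cv$grams, cv$estimate, type = "n", log = "x", xlab = xlab,
       ylab = ylab, main = main,
       ylim = range(cv$ciLow, cv$ciHigh, finite = TRUE), ...)
  graphics::polygon(c(cv$grams, rev(cv$grams)),
                    c(cv$ciLow, rev(cv$ciHigh)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(cv$grams, cv$estimate, lwd = 2, col = "steelblue4")
  graphics::abline(v = x@guidelines, lty = 2, col = "grey40")
  graphics::abline(h = if (x@scale == "odds-ratio") 1 else 0, lty = 3)
  invisible(x)
})
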