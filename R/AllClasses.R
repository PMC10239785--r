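#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Tidy regression results
#'
#' \code{ModelResult} is a thin extension of \code{S4Vectors::DataFrame}
#' holding one row per fitted contrast with the columns \code{term},
#' \code{estimate}, \code{ciLow}, \code{ciHigh}, \code{p}, \code{n} and
#' \code{scale} (\code{"identity"} for linear-model coefficients,
#' \code{"odds-ratio"} for exponentiated logistic coefficients).
#'
#' @aliases ModelResult-class
#' @exportClass ModelResult
setClass("ModelResult", contains = "DFrame")

.modelResultCols <- c("term", "estimate", "ciLow", "ciHigh", "p", "n", "scale")

setValidity("ModelResult", function(object) {
  msg <- character()
  missing <- setdiff(.modelResultCols, colnames(object))
  if (length(missing))
    msg <- c(msg, paste("missing columns:", paste(missing, collapse = ", ")))
  if (!length(msg) && nrow(object)) {
    ok <- stats::complete.cases(as.data.frame(object)[, c("estimate", "ciLow", "ciHigh")])
    bad <- ok & (object$ciLow > object$estimate | object$estimate > object$ciHigh)
    if (any(bad)) msg <- c(msg, "ciLow <= estimate <= ciHigh violated")
    p <- object$p[!is.na(object$p)]
    if (any(p <= 0 | p > 1)) msg <- c(msg, "p-values must lie in (0, 1]")
    if (!all(object$scale %in% c("identity", "odds-ratio")))
      msg <- c(msg, "scale must be 'identity' or 'odds-ratio'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ModelResult table
#'
#' @param term Character vector of contrast names.
#' @param estimate Numeric estimates (beta coefficients or odds ratios).
#' @param ciLow,ciHigh 95\% confidence bounds.
#' @param p Two-sided p-values.
#' @param n Number of observations used for the fit.
#' @param scale \code{"identity"} or \code{"odds-ratio"}.
#' @param ... Further columns carried along (e.g. \code{outcome}).
#' @return A \linkS4class{ModelResult}.
#' @export
ModelResult <- function(term, estimate, ciLow, ciHigh, p, n,
                        scale = "identity", ...) {
  new("ModelResult", DataFrame(term = term, estimate = estimate,
                               ciLow = ciLow, ciHigh = ciHigh, p = p,
                               n = n, scale = scale, ...))
}

#' Harmonized two-sample MR summary set
#'
#' Per-SNP exposure and outcome association statistics after allele
#' harmonization, the input object of every MR estimator in the package.
#' Optional second-exposure betas support multivariable MR; the \code{flags}
#' DataFrame carries bookkeeping columns such as \code{flaggedVariant} (an
#' ADH1B-like large-effect variant) and, for synthetic data,
#' \code{outlierTruth}.
#'
#' @slot snps Character vector of variant identifiers.
#' @slot effectAllele,otherAllele Harmonized allele labels.
#' @slot betaX,seX Exposure association estimates and standard errors.
#' @slot betaY,seY Outcome association estimates and standard errors.
#' @slot pvalX Exposure association p-values (may be length 0).
#' @slot betaX2,seX2 Second-exposure statistics (length 0 when absent).
#' @slot flags A \code{DataFrame} of per-SNP logical/metadata columns.
#'
#' @aliases MRSummarySet-class
#' @exportClass MRSummarySet
setClass("MRSummarySet",
         representation(snps = "character",
                        effectAllele = "character",
                        otherAllele = "character",
                        betaX = "numeric", seX = "numeric",
                        betaY = "numeric", seY = "numeric",
                        pvalX = "numeric",
                        betaX2 = "numeric", seX2 = "numeric",
                        flags = "DataFrame"))

setValidity("MRSummarySet", function(object) {
  n <- length(object@snps)
  msg <- character()
  for (sl in c("effectAllele", "otherAllele", "betaX", "seX", "betaY", "seY"))
    if (length(slot(object, sl)) != n)
      msg <- c(msg, paste0("slot '", sl, "' must have length ", n))
  if (length(object@pvalX) && length(object@pvalX) != n)
    msg <- c(msg, "pvalX must be empty or match the number of SNPs")
  if (length(object@betaX2) && (length(object@betaX2) != n ||
                                length(object@seX2) != n))
    msg <- c(msg, "second-exposure betas/SEs must match the number of SNPs")
  if (anyDuplicated(object@snps)) msg <- c(msg, "duplicated SNP ids")
  if (!length(msg)) {
    if (any(!is.finite(object@seX)) || any(object@seX <= 0) ||
        any(!is.finite(object@seY)) || any(object@seY <= 0))
      msg <- c(msg, "standard errors must be finite and > 0")
    if (length(object@seX2) && any(object@seX2 <= 0))
      msg <- c(msg, "second-exposure SEs must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an MRSummarySet
#'
#' @param snps Variant ids.
#' @param betaX,seX,betaY,seY Exposure/outcome betas and SEs.
#' @param effectAllele,otherAllele Allele labels (default placeholders).
#' @param pvalX Optional exposure p-values.
#' @param betaX2,seX2 Optional second-exposure statistics.
#' @param flags Optional \code{DataFrame} of per-SNP metadata.
#' @return An \linkS4class{MRSummarySet}.
#' @export
MRSummarySet <- function(snps, betaX, seX, betaY, seY,
                         effectAllele = rep("A", length(snps)),
                         otherAllele = rep("G", length(snps)),
                         pvalX = numeric(), betaX2 = numeric(),
                         seX2 = numeric(), flags = NULL) {
  if (is.null(flags)) flags <- DataFrame(matrix(nrow = length(snps), ncol = 0))
  n <- length(snps)
  rec <- function(v) if (length(v) == 1L && n > 1L) rep(v, n) else v
  new("MRSummarySet", snps = as.character(snps),
      effectAllele = toupper(rec(effectAllele)),
      otherAllele = toupper(rec(otherAllele)),
      betaX = as.numeric(rec(betaX)), seX = as.numeric(rec(seX)),
      betaY = as.numeric(rec(betaY)), seY = as.numeric(rec(seY)),
      pvalX = as.numeric(pvalX), betaX2 = as.numeric(rec(betaX2)),
      seX2 = as.numeric(rec(seX2)), flags = flags)
}

#' A fitted Mendelian randomization estimate
#'
#' Holds the causal-effect estimate of one MR method together with its 95\%
#' confidence interval, p-value, the number of instruments used and
#' method-specific diagnostics (Cochran's Q and its p, I-squared, the Egger
#' intercept and its p, the regression-dilution statistic I2GX, MR-PRESSO
#' global/outlier/distortion results), stored in a named list.
#'
#' @slot method Method label, e.g. \code{"IVW (random)"}.
#' @slot estimate,ciLow,ciHigh,p Estimate, Wald 95\% bounds and p-value.
#' @slot nSNPs Number of SNPs contributing.
#' @slot diagnostics Named list of method-dependent diagnostics.
#'
#' @aliases MREstimate-class
#' @exportClass MREstimate
setClass("MREstimate",
         representation(method = "character", estimate = "numeric",
                        ciLow = "numeric", ciHigh = "numeric", p = "numeric",
                        nSNPs = "integer", diagnostics = "list"))

setValidity("MREstimate", function(object) {
  e <- object@estimate
  if (length(e) == 1 && is.finite(e) &&
      (object@ciLow > e || e > object@ciHigh))
    return("ciLow <= estimate <= ciHigh violated")
  TRUE
})

MREstimate <- function(method, estimate, se, nSNPs, p = waldP(estimate, se),
                       ci = waldCI(estimate, se), diagnostics = list()) {
  diagnostics$se <- se
  new("MREstimate", method = method, estimate = estimate,
      ciLow = ci[1], ciHigh = ci[2], p = p, nSNPs = as.integer(nSNPs),
      diagnostics = diagnostics)
}

#' A selected restricted-cubic-spline dose-response fit
#'
#' @slot nKnots Number of knots of the AIC-selected model (3-7).
#' @slot knots Knot positions on the log-intake scale.
#' @slot coefficients Coefficients of the selected fit (intercept, spline
#'   basis and covariates).
#' @slot aic AIC of the selected model.
#' @slot aicTable data.frame of candidate knot counts and their AICs.
#' @slot curve data.frame with columns \code{grams}, \code{logGrams},
#'   \code{estimate}, \code{ciLow}, \code{ciHigh}: the fitted dose-response
#'   curve relative to the reference intake, with pointwise 95\% CIs.
#' @slot scale \code{"identity"} or \code{"odds-ratio"} for the curve.
#' @slot guidelines Named numeric vector of guideline overlay positions
#'   (g/week) for plotting.
#'
#' @aliases SplineFit-class
#' @exportClass SplineFit
setClass("SplineFit",
         representation(nKnots = "integer", knots = "numeric",
                        coefficients = "numeric", aic = "numeric",
                        aicTable = "data.frame", curve = "data.frame",
                        scale = "character", guidelines = "numeric"))

setValidity("SplineFit", function(object) {
  if (object@nKnots < 3L || object@nKnots > 7L)
    return("nKnots must be between 3 and 7")
  if (is.unsorted(object@knots, strictly = TRUE))
    return("knots must be strictly increasing")
  TRUE
})
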