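# Observational association models: maximally adjusted linear and logistic
# fits, categorical contrasts, quintile dose-response with trend tests.

#' The default adjustment covariate set
#'
#' The 13 covariates of the maximally adjusted models: age (years), sex,
#' ethnicity (White/Black/Other), Townsend deprivation index, assessment
#' season, body mass index, height, systolic blood pressure, spherical
#' equivalent, diabetes, smoking status (never/previous/current), smoking
#' intensity (cigarettes/day) and physical activity (MET-minutes/week).
#'
#' @return data.frame with columns \code{name}, \code{type} and
#'   \code{reference} (reference level for categorical covariates).
#' @export
covariateSpec <- function() {
  data.frame(
    name = c("age", "sex", "ethnicity", "townsend", "season", "bmi",
             "height", "sbp", "sphericalEquivalent", "diabetes",
             "smokingStatus", "smokingIntensity", "physicalActivity"),
    type = c("continuous", "categorical", "categorical", "continuous",
             "categorical", "continuous", "continuous", "continuous",
             "continuous", "categorical", "categorical", "continuous",
             "continuous"),
    reference = c(NA, "Women", "White", NA, "Summer", NA, NA, NA, NA,
                  "FALSE", "never", NA, NA),
    stringsAsFactors = FALSE)
}

# Build the model formula outcome ~ exposure + covariates.
.modelFormula <- function(outcome, exposure, covariates) {
  stats::as.formula(paste(outcome, "~", exposure,
                          if (nrow(covariates))
                            paste("+", paste(covariates$name,
                                             collapse = " + "))
                          else ""))
}

.checkCovariates <- function(data, covariates) {
  missing <- setdiff(covariates$name, names(data))
  if (length(missing))
    abortGD("data misses covariate columns: ",
            paste(missing, collapse = ", "))
}

# Extract the exposure rows from a fitted lm/glm into a ModelResult.
.resultFromFit <- function(fit, termPrefix, scale, outcome) {
  sm <- summary(fit)$coefficients
  keep <- grepl(termPrefix, rownames(sm), fixed = TRUE)
  est <- sm[keep, 1]; se <- sm[keep, 2]
  nm <- rownames(sm)[keep]
  n <- length(stats::residuals(fit))
  if (scale == "odds-ratio") {
    ModelResult(term = nm, estimate = exp(est),
                ciLow = exp(est - 1.96 * se), ciHigh = exp(est + 1.96 * se),
                p = waldP(est, se), n = n, scale = scale, outcome = outcome)
  } else {
    ModelResult(term = nm, estimate = est,
                ciLow = est - 1.96 * se, ciHigh = est + 1.96 * se,
                p = waldP(est, se), n = n, scale = scale, outcome = outcome)
  }
}

#' Multivariable linear regression
#'
#' Ordinary least squares of a continuous outcome on an exposure (continuous
#' or factor) plus the adjustment covariates, on complete cases, with Wald
#' 95\% confidence intervals. Rank deficiency is reported with the collinear
#' terms.
#'
#' @param data data.frame of analysis rows.
#' @param outcome Name of the outcome column.
#' @param exposure Name of the exposure column.
#' @param covariates Covariate specification (default
#'   \code{\link{covariateSpec}}); use a zero-row data.frame for an
#'   unadjusted fit.
#' @return A \linkS4class{ModelResult} with one row per exposure term.
#' @export
fitLinear <- function(data, outcome, exposure,
                      covariates = covariateSpec()) {
  .checkCovariates(data, covariates)
  f <- .modelFormula(outcome, exposure, covariates)
  dat <- data[stats::complete.cases(data[, all.vars(f)]), ]
  if (nrow(dat) <= nrow(covariates) + 2)
    abortGD("too few complete cases for the requested model")
  fit <- stats::lm(f, data = dat)
  if (any(is.na(stats::coef(fit))))
    abortGD("rank-deficient design; collinear terms: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  .resultFromFit(fit, exposure, "identity", outcome)
}

#' Multivariable logistic regression
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' \code{stats::glm}, convergence at relative deviance change below 1e-10,
#' at most 100 iterations) of a binary outcome on the exposure plus
#' covariates. Exposure estimates are reported as odds ratios with Wald
#' intervals. Perfect separation is detected and reported.
#'
#' @inheritParams fitLinear
#' @return A \linkS4class{ModelResult} on the odds-ratio scale.
#' @export
fitLogistic <- function(data, outcome, exposure,
                        covariates = covariateSpec()) {
  .checkCovariates(data, covariates)
  f <- .modelFormula(outcome, exposure, covariates)
  dat <- data[stats::complete.cases(data[, all.vars(f)]), ]
  y <- dat[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2)
    abortGD("both outcome classes must be present")
  fit <- stats::glm(f, data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged) abortGD("logistic fit did not converge")
  if (any(abs(stats::coef(fit)) > 15, na.rm = TRUE))
    warning("very large coefficients: possible (quasi-)separation")
  if (any(is.na(stats::coef(fit))))
    abortGD("rank-deficient design; collinear terms: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  .resultFromFit(fit, exposure, "odds-ratio", outcome)
}

# Glaucoma analyses model case vs control; 'excluded' rows never enter.
.glaucomaBinary <- function(data) {
  status <- data$glaucomaStatus
  out <- rep(NA, nrow(data))
  out[status == "case"] <- 1L
  out[status == "control"] <- 0L
  out
}

# Route an outcome name to the right fitter, handling the glaucoma
# case/control coding.
.fitOutcome <- function(data, outcome, exposure, covariates) {
  if (outcome == "glaucoma") {
    data$glaucomaCase <- .glaucomaBinary(data)
    fitLogistic(data[!is.na(data$glaucomaCase), ], "glaucomaCase", exposure,
                covariates)
  } else {
    fitLinear(data, outcome, exposure, covariates)
  }
}

#' Categorical drinking-status analysis
#'
#' Contrasts each non-reference drinking category against the reference
#' (infrequent drinkers by default, the preferred low-volume reference
#' group; optionally a pooled never+infrequent reference) for each requested
#' outcome, maximally adjusted.
#'
#' @param data Analysis cohort with \code{category} and outcome columns.
#' @param outcomes Outcomes to fit (subset of \code{iop}, \code{mrnfl},
#'   \code{mgcipl}, \code{glaucoma}).
#' @param reference Reference category (default \code{"infrequent"}).
#' @param pooledReference Pool never and infrequent drinkers as the
#'   reference.
#' @param covariates Covariate specification.
#' @return A \linkS4class{ModelResult} with rows
#'   \code{category<level>} per outcome.
#' @export
categoricalAnalysis <- function(data,
                                outcomes = c("iop", "mrnfl", "mgcipl",
                                             "glaucoma"),
                                reference = "infrequent",
                                pooledReference = FALSE,
                                covariates = covariateSpec()) {
  dat <- data[!is.na(data$category), ]
  if (pooledReference) {
    dat$category[dat$category %in% c("never", "infrequent")] <- reference
  }
  lev <- intersect(c(reference, "never", "infrequent", "regular", "former"),
                   unique(dat$category))
  if (!reference %in% dat$category) abortGD("empty reference category")
  if (length(lev) < 2) abortGD("need at least 2 populated categories")
  dat$category <- factor(dat$category, levels = lev)
  res <- lapply(outcomes, function(o)
    .fitOutcome(dat, o, "category", covariates))
  do.call(rbind, res)
}

#' Quintile dose-response analysis with trend test
#'
#' Restricted to regular drinkers retained after trimming. Quintile cut
#' points come from the empirical intake distribution (type-7 interpolated
#' percentiles); boundaries are lower-closed so ties go to the lower
#' quintile. Q2-Q5 are contrasted against Q1, and the trend p-value comes
#' from refitting with each participant assigned their quintile's median
#' intake as a continuous term (Wald test).
#'
#' @param data Analysis cohort carrying \code{category}, \code{gramsWeek},
#'   \code{includedAfterTrim} and the outcome.
#' @param outcome One of \code{iop}, \code{mrnfl}, \code{mgcipl},
#'   \code{glaucoma}.
#' @param covariates Covariate specification.
#' @return List with \code{results} (\linkS4class{ModelResult}, quintile
#'   contrasts), \code{trendP}, \code{quintileMedians} and
#'   \code{cutPoints}.
#' @export
quintileAnalysis <- function(data, outcome, covariates = covariateSpec()) {
  dat <- data[!is.na(data$category) & data$category == "regular" &
                !is.na(data$includedAfterTrim) & data$includedAfterTrim, ]
  g <- dat$gramsWeek
  if (length(unique(g)) < 5)
    abortGD("too few distinct intake values to form quintiles")
  cuts <- stats::quantile(g, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  # lower-closed intervals: value equal to a cut point stays in the lower
  # quintile
  q <- findInterval(g, cuts, left.open = TRUE) + 1L
  dat$intakeQuintile <- factor(paste0("Q", q), levels = paste0("Q", 1:5))
  med <- tapply(g, dat$intakeQuintile, stats::median)
  res <- .fitOutcome(dat, outcome, "intakeQuintile", covariates)
  dat$quintileMedian <- med[as.character(dat$intakeQuintile)]
  trendFit <- .fitOutcome(dat, outcome, "quintileMedian", covariates)
  list(results = res, trendP = trendFit$p[1],
       quintileMedians = med, cutPoints = cuts)
}

#' Per-SD continuous dose-response analysis
#'
#' The headline quantitative contrast: outcome regressed on the
#' trim-standardized weekly intake among regular drinkers, maximally
#' adjusted. One SD corresponds to the trimmed regular-drinker intake SD
#' (about 111 g/week at the default generator calibration).
#'
#' @inheritParams quintileAnalysis
#' @return A \linkS4class{ModelResult} with the per-SD row.
#' @export
perSDAnalysis <- function(data, outcome, covariates = covariateSpec()) {
  dat <- data[!is.na(data$category) & data$category == "regular" &
                !is.na(data$intakeStd), ]
  .fitOutcome(dat, outcome, "intakeStd", covariates)
}
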