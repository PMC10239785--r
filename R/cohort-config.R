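# Configuration for the synthetic cohort generator. Defaults encode the
# study conditions the analyses assume: covariate marginals and category mix
# of a large UK population cohort, per-SD outcome effects, the
# former-drinker glaucoma odds ratio, and the PRS x alcohol interaction
# gradient on IOP.

# Covariate marginal parameters (means/SDs or category probabilities) used
# by the generator; only marginal summaries are emulated.
.covariateMarginals <- list(
  age = c(mean = 56.6, sd = 8.1),
  sexWomen = 0.531,
  ethnicity = c(White = 0.906, Black = 0.032, Other = 0.062),
  townsend = c(mean = -1.1, sd = 2.9),
  bmi = c(mean = 27.3, sd = 4.7),
  height = c(mean = 168.9, sd = 9.3),
  sbp = c(mean = 137.0, sd = 18.3),
  sphericalEquivalent = c(mean = -0.4, sd = 2.7),
  diabetes = 0.055,
  smoking = c(never = 0.575, previous = 0.360, current = 0.065),
  smokingIntensityCurrent = c(mean = 14.5, sd = 8.2),
  physicalActivity = c(mean = 2669, sd = 2678))

#' Configuration of the synthetic cohort generator
#'
#' Bundles every tunable of \code{\link{generateCohort}}. The defaults
#' reproduce the statistical structure of the analysis cohorts: category mix
#' (never/infrequent/regular/former = 4.8/11.9/79.7/3.6\%), a right-skewed
#' (log-normal) weekly intake among regular drinkers with median 91.3 and SD
#' 111 g/week, per-SD outcome effects of +0.08 mmHg (IOP), -0.17 um (mRNFL),
#' -0.34 um (mGCIPL) and OR 1.11 (glaucoma), a former-vs-infrequent glaucoma
#' odds ratio of 1.53, a baseline glaucoma prevalence of 1.8\%, and an
#' intake x PRS interaction on IOP of 0.05 mmHg per SD intake per SD PRS
#' (which yields a top-PRS-quintile per-SD effect of about 0.15 mmHg).
#'
#' @param n Number of participants.
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @param effectIOPPerSD,effectMRNFLPerSD,effectMGCIPLPerSD Continuous
#'   per-SD intake effects on IOP (mmHg), mRNFL (um), mGCIPL (um).
#' @param logORGlaucomaPerSD Log odds of glaucoma per SD intake.
#' @param logORFormerDrinker Former-vs-infrequent log odds of glaucoma.
#' @param interactionIOP Intake x PRS interaction on IOP, mmHg per SD intake
#'   per SD PRS.
#' @param baselinePrevalence Marginal glaucoma prevalence.
#' @param categoryProbabilities Probabilities of (never, infrequent, regular,
#'   former); must sum to 1.
#' @param categoryEffects Named list of per-outcome category contrasts
#'   relative to infrequent drinkers (vectors with elements \code{never},
#'   \code{regular}, \code{former}; glaucoma on the log-odds scale, the
#'   \code{former} element there is taken from \code{logORFormerDrinker}).
#' @param confounderWeight Standardized weight of the shared linear
#'   dependence of intake and every outcome on the confounding covariates
#'   (age, sex, BMI, systolic blood pressure, current smoking).
#' @param noiseSDs Residual SDs of the continuous outcomes (mmHg / um).
#' @param outcomeBaselines Outcome values at reference category and mean
#'   covariates.
#' @param intakeMedian,intakeSD Median and SD (g/week) calibrating the
#'   log-normal intake of regular drinkers.
#' @param iopTrimPercentiles Lower/upper percentile trim the IOP derivation
#'   stage applies (the generator pre-compensates the latent IOP effects
#'   for the resulting outcome-tail truncation so the trimmed analysis
#'   recovers the configured contrasts).
#' @param treatedFraction Probability that a non-case uses ocular
#'   hypotensive medication.
#' @param treatedCaseFraction Same, for cases.
#' @param beverages Beverage table used to translate intake into portion
#'   counts (and back).
#' @return A validated list of class \code{"CohortConfig"}.
#' @export
#' @examples
#' cfg <- cohortConfig(n = 500, seed = 1)
cohortConfig <- function(n = 10000, seed = 1,
                         effectIOPPerSD = 0.08,
                         effectMRNFLPerSD = -0.17,
                         effectMGCIPLPerSD = -0.34,
                         logORGlaucomaPerSD = log(1.11),
                         logORFormerDrinker = log(1.53),
                         interactionIOP = 0.05,
                         baselinePrevalence = 0.018,
                         categoryProbabilities = c(never = 0.048,
                                                   infrequent = 0.119,
                                                   regular = 0.797,
                                                   former = 0.036),
                         categoryEffects = list(
                           iop = c(never = 0.09, regular = 0.17,
                                   former = -0.15),
                           mrnfl = c(never = -0.08, regular = -0.10,
                                     former = -0.21),
                           mgcipl = c(never = -0.08, regular = -0.17,
                                      former = -0.06),
                           glaucoma = c(never = log(1.23),
                                        regular = log(1.13),
                                        former = NA)),
                         confounderWeight = 0.05,
                         noiseSDs = c(iop = 3.4, mrnfl = 3.8, mgcipl = 5.2),
                         outcomeBaselines = c(iop = 16.1, mrnfl = 28.9,
                                              mgcipl = 75.2),
                         intakeMedian = 91.3, intakeSD = 111,
                         iopTrimPercentiles = c(0.5, 0.5),
                         treatedFraction = 0.01,
                         treatedCaseFraction = 0.5,
                         beverages = defaultBeverageTable()) {
  cfg <- list(n = n, seed = seed,
              effectIOPPerSD = effectIOPPerSD,
              effectMRNFLPerSD = effectMRNFLPerSD,
              effectMGCIPLPerSD = effectMGCIPLPerSD,
              logORGlaucomaPerSD = logORGlaucomaPerSD,
              logORFormerDrinker = logORFormerDrinker,
              interactionIOP = interactionIOP,
              baselinePrevalence = baselinePrevalence,
              categoryProbabilities = categoryProbabilities,
              categoryEffects = categoryEffects,
              confounderWeight = confounderWeight,
              noiseSDs = noiseSDs,
              outcomeBaselines = outcomeBaselines,
              intakeMedian = intakeMedian, intakeSD = intakeSD,
              iopTrimPercentiles = iopTrimPercentiles,
              treatedFraction = treatedFraction,
              treatedCaseFraction = treatedCaseFraction,
              beverages = beverages,
              covariates = .covariateMarginals)
  cfg$categoryEffects$glaucoma["former"] <- logORFormerDrinker
  validateCohortConfig(cfg)
  class(cfg) <- "CohortConfig"
  cfg
}

validateCohortConfig <- function(cfg) {
  if (!isScalarCount(cfg$n)) abortGD("n_participants must be a count >= 1")
  nums <- c(cfg$effectIOPPerSD, cfg$effectMRNFLPerSD, cfg$effectMGCIPLPerSD,
            cfg$logORGlaucomaPerSD, cfg$logORFormerDrinker,
            cfg$interactionIOP, cfg$baselinePrevalence,
            cfg$categoryProbabilities, cfg$noiseSDs, cfg$outcomeBaselines,
            cfg$intakeMedian, cfg$intakeSD, cfg$confounderWeight,
            cfg$treatedFraction, cfg$treatedCaseFraction)
  if (any(!is.finite(nums))) abortGD("non-finite configuration value")
  p <- cfg$categoryProbabilities
  if (length(p) != 4 || any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-8)
    abortGD("category_probabilities must be a 4-vector in [0,1] summing to 1")
  if (cfg$baselinePrevalence < 0 || cfg$baselinePrevalence > 1 ||
      cfg$treatedFraction < 0 || cfg$treatedFraction > 1 ||
      cfg$treatedCaseFraction < 0 || cfg$treatedCaseFraction > 1)
    abortGD("probabilities must lie in [0, 1]")
  if (any(cfg$noiseSDs < 0)) abortGD("noise SDs must be >= 0")
  if (cfg$intakeMedian <= 0 || cfg$intakeSD <= 0)
    abortGD("intake median/SD must be > 0")
  if (length(cfg$iopTrimPercentiles) != 2 ||
      any(!is.finite(cfg$iopTrimPercentiles)) ||
      any(cfg$iopTrimPercentiles < 0) || sum(cfg$iopTrimPercentiles) >= 50)
    abortGD("iopTrimPercentiles must be two percentages in [0, 50)")
  invisible(cfg)
}

# Log-normal (mu, sigma) from a target median m and SD s:
# median = exp(mu); s^2/m^2 = (e^{sigma^2} - 1) e^{sigma^2}.
lognormalFromMedianSD <- function(m, s) {
  v <- (s / m)^2
  u <- (1 + sqrt(1 + 4 * v)) / 2   # u = exp(sigma^2)
  list(mu = log(m), sigma = sqrt(log(u)))
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat("Synthetic cohort configuration:", x$n, "participants, seed", x$seed,
      "\n")
  cat(sprintf("  per-SD effects: IOP %+0.2f mmHg, mRNFL %+0.2f um, mGCIPL %+0.2f um, glaucoma OR %.2f\n",
              x$effectIOPPerSD, x$effectMRNFLPerSD, x$effectMGCIPLPerSD,
              exp(x$logORGlaucomaPerSD)))
  cat(sprintf("  former-drinker glaucoma OR %.2f; IOP interaction %+0.3f mmHg/SD/SD\n",
              exp(x$logORFormerDrinker), x$interactionIOP))
  cat("  category mix:", paste(sprintf("%s %.1f%%",
                                       names(x$categoryProbabilities),
                                       100 * x$categoryProbabilities),
                               collapse = ", "), "\n")
  invisible(x)
}
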