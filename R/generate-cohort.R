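# Synthetic cohort generation. Covariates are drawn from the configured
# marginals, drinking category and intake from the configured mix and
# log-normal calibration, and outcomes from explicit linear / logistic
# generative models so that every downstream analysis has a known truth.

# Draw the covariate block (13 adjustment covariates + PRS).
.drawCovariates <- function(n, cv) {
  sex <- factor(ifelse(stats::runif(n) < cv$sexWomen, "Women", "Men"),
                levels = c("Women", "Men"))
  eth <- cv$ethnicity / sum(cv$ethnicity)
  smk <- cv$smoking / sum(cv$smoking)
  smokingStatus <- factor(sample(names(smk), n, TRUE, smk),
                          levels = c("never", "previous", "current"))
  intens <- numeric(n)
  cur <- smokingStatus == "current"
  intens[cur] <- pmax(0, stats::rnorm(sum(cur),
                                      cv$smokingIntensityCurrent["mean"],
                                      cv$smokingIntensityCurrent["sd"]))
  pa <- cv$physicalActivity
  shape <- (pa["mean"] / pa["sd"])^2
  data.frame(
    age = stats::rnorm(n, cv$age["mean"], cv$age["sd"]),
    sex = sex,
    ethnicity = factor(sample(names(eth), n, TRUE, eth),
                       levels = c("White", "Black", "Other")),
    townsend = stats::rnorm(n, cv$townsend["mean"], cv$townsend["sd"]),
    bmi = stats::rnorm(n, cv$bmi["mean"], cv$bmi["sd"]),
    height = stats::rnorm(n, cv$height["mean"], cv$height["sd"]),
    sbp = stats::rnorm(n, cv$sbp["mean"], cv$sbp["sd"]),
    sphericalEquivalent = stats::rnorm(n, cv$sphericalEquivalent["mean"],
                                       cv$sphericalEquivalent["sd"]),
    diabetes = stats::runif(n) < cv$diabetes,
    smokingStatus = smokingStatus,
    smokingIntensity = intens,
    physicalActivity = stats::rgamma(n, shape = shape,
                                     scale = pa["sd"]^2 / pa["mean"]),
    season = factor(sample(c("Summer", "Autumn", "Winter", "Spring"), n,
                           TRUE),
                    levels = c("Summer", "Autumn", "Winter", "Spring")),
    prs = stats::rnorm(n))
}

# Standardized confounder scores shared by intake and outcomes.
.confounderScores <- function(cov, cv) {
  cbind(age = (cov$age - cv$age["mean"]) / cv$age["sd"],
        sexMen = ((cov$sex == "Men") - (1 - cv$sexWomen)) /
          sqrt(cv$sexWomen * (1 - cv$sexWomen)),
        bmi = (cov$bmi - cv$bmi["mean"]) / cv$bmi["sd"],
        sbp = (cov$sbp - cv$sbp["mean"]) / cv$sbp["sd"],
        smokingCurrent = ((cov$smokingStatus == "current") -
                            cv$smoking["current"]) /
          sqrt(cv$smoking["current"] * (1 - cv$smoking["current"])))
}

# Questionnaire block: frequency, reporting period and integer portion
# counts consistent with a target weekly intake. Returns the questionnaire
# columns plus the exact grams implied by the emitted portions.
.buildQuestionnaire <- function(category, gramsTarget, beverages) {
  n <- length(category)
  freq <- rep(NA_character_, n)
  ever <- rep(NA, n)
  period <- rep(NA_character_, n)
  withMeals <- rep(NA, n)
  portions <- matrix(NA_real_, n, 6,
                     dimnames = list(NULL, paste0("portions_",
                                                  beverageNames())))
  gpp <- beverages$portion_ml[match(beverageNames(), beverages$beverage)] *
    beverages$concentration_g_ml[match(beverageNames(), beverages$beverage)]

  freq[category == "never"] <- "Never"
  ever[category == "never"] <- FALSE
  freq[category == "former"] <- "Never"
  ever[category == "former"] <- TRUE

  quant <- which(category %in% c("infrequent", "regular"))
  if (length(quant)) {
    ever[quant] <- TRUE
    withMeals[quant] <- stats::runif(length(quant)) < 0.55
    reg <- quant[category[quant] == "regular"]
    if (length(reg)) {
      # frequency increases with intake: quartiles of the target grams
      q <- stats::quantile(gramsTarget[reg], c(0.25, 0.5, 0.75))
      lab <- c("1-3 times a month", "1-2 times a week", "3-4 times a week",
               "Daily/almost daily")
      freq[reg] <- lab[findInterval(gramsTarget[reg], q) + 1]
    }
    inf <- quant[category[quant] == "infrequent"]
    freq[inf] <- "Special occasions only"
    period[quant] <- ifelse(freq[quant] %in% c("Special occasions only",
                                               "1-3 times a month"),
                            "monthly", "weekly")
    # split the target over beverages with random per-person preferences,
    # then round to integer portion counts
    w <- matrix(stats::rexp(length(quant) * 6), ncol = 6)
    w <- w / rowSums(w)
    k <- ifelse(period[quant] == "weekly", 1, kMonthly())
    target <- gramsTarget[quant] * w
    portions[quant, ] <- round(sweep(target, 2, gpp, "/") / k)
  }
  grams <- rep(NA_real_, n)
  if (length(quant)) {
    k <- ifelse(period[quant] == "weekly", 1, kMonthly())
    grams[quant] <- as.numeric(portions[quant, , drop = FALSE] %*% gpp) * k
  }
  list(table = data.frame(frequency = freq, everDrank = ever,
                          reportingPeriod = period, withMeals = withMeals,
                          portions),
       grams = grams)
}

#' Generate a synthetic analysis cohort
#'
#' Draws covariates from the configured marginals, assigns drinking
#' categories and a right-skewed weekly intake (expressed as integer
#' questionnaire portion counts, so quantification downstream reproduces the
#' generator's grams exactly), and generates outcomes from the configured
#' linear models (continuous outcomes) and logistic model (glaucoma):
#' baseline + category contrast + confounder terms + per-SD effect x
#' trim-standardized intake (+ intake x PRS interaction for IOP) + noise.
#' Intake and all outcomes share a linear dependence on age, sex, BMI,
#' systolic blood pressure and current smoking, inducing confounding that
#' the adjusted models must remove. Latent glaucoma cases are expressed as
#' self-report flags and/or ICD records; treatment and surgery flags and
#' per-eye measurements (mean-preserving left/right splits of the
#' individual-level value, with the measured IOP scaled by 0.7 for treated
#' participants) complete the raw phenotype surface.
#'
#' @param config A \code{\link{cohortConfig}}.
#' @return A list of class \code{"CohortData"} with elements
#'   \code{participants} (one row per participant: questionnaire fields, 13
#'   covariates, PRS, flags, per-eye measurements), \code{diagnoses}
#'   (long-format ICD records), \code{truth} (latent generative quantities,
#'   synthetic bookkeeping only) and \code{config}.
#' @export
#' @examples
#' cd <- generateCohort(cohortConfig(n = 200, seed = 42))
#' head(cd$participants)
generateCohort <- function(config = cohortConfig()) {
  validateCohortConfig(config)
  withSeed(config$seed, .generateCohortImpl(config))
}

.generateCohortImpl <- function(cfg) {
  n <- cfg$n
  cv <- cfg$covariates
  cov <- .drawCovariates(n, cv)
  z <- .confounderScores(cov, cv)
  d <- rep(cfg$confounderWeight, ncol(z))

  catP <- cfg$categoryProbabilities / sum(cfg$categoryProbabilities)
  category <- sample(names(catP), n, TRUE, catP)

  # weekly intake: log-normal among regular drinkers, confounded through the
  # shared covariate scores; infrequent drinkers report small quantities
  ln <- lognormalFromMedianSD(cfg$intakeMedian, cfg$intakeSD)
  L <- as.numeric(z %*% d) +
    sqrt(max(0, 1 - sum(d^2))) * stats::rnorm(n)
  gramsTarget <- rep(NA_real_, n)
  reg <- category == "regular"
  gramsTarget[reg] <- exp(ln$mu + ln$sigma * L[reg])
  inf <- category == "infrequent"
  gramsTarget[inf] <- exp(log(2.8) + 1.2 * stats::rnorm(sum(inf)))

  qn <- .buildQuestionnaire(category, gramsTarget, cfg$beverages)
  grams <- qn$grams

  # exposure scale actually analyzed: trim regular drinkers at 1/1
  # percentiles (zero-gram reports fall out with the bottom percentile or
  # the positivity rule) and standardize the retained subset
  x <- rep(0, n)
  regQ <- reg & !is.na(grams)
  keep <- rep(FALSE, n)
  if (sum(regQ) > 2) {
    mask <- trimPercentiles(grams[regQ], 1, 1) & grams[regQ] > 0
    keep[regQ][mask] <- TRUE
    m <- mean(grams[keep]); s <- stats::sd(grams[keep])
    x[regQ] <- (grams[regQ] - m) / s  # same affine map for trimmed-out rows
  }
  xReg <- ifelse(reg, x, 0)

  catEffect <- function(outcome) {
    eff <- cfg$categoryEffects[[outcome]]
    out <- rep(0, n)
    for (lv in names(eff)) out[category == lv] <- eff[[lv]]
    out
  }
  confTerm <- as.numeric(z %*% rep(cfg$confounderWeight, ncol(z)))

  # Derived IOP is trimmed at the extreme percentiles before modeling.
  # Truncating the outcome tails attenuates every regression contrast on
  # the trimmed sample by the analytic factor
  #   gamma = 1 - [|z_lo| phi(z_lo) + z_hi phi(z_hi)] / (1 - p_lo - p_hi)
  # (normal residuals), so the latent IOP effects are pre-compensated by
  # 1/gamma: the configured values are the estimands of the trimmed
  # analysis, which is what the study reports.
  pTrim <- cfg$iopTrimPercentiles / 100
  gamma <- if (cfg$noiseSDs["iop"] <= 0 || sum(pTrim) <= 0) 1 else {
    zlo <- stats::qnorm(pTrim[1]); zhi <- stats::qnorm(1 - pTrim[2])
    1 - (abs(zlo) * stats::dnorm(zlo) + zhi * stats::dnorm(zhi)) /
      (1 - sum(pTrim))
  }

  yIOP <- cfg$outcomeBaselines["iop"] + catEffect("iop") / gamma +
    cfg$noiseSDs["iop"] * confTerm +
    (cfg$effectIOPPerSD / gamma) * xReg +
    (cfg$interactionIOP / gamma) * xReg * cov$prs +
    stats::rnorm(n, 0, cfg$noiseSDs["iop"])
  yRNFL <- cfg$outcomeBaselines["mrnfl"] + catEffect("mrnfl") +
    cfg$noiseSDs["mrnfl"] * confTerm +
    cfg$effectMRNFLPerSD * xReg + stats::rnorm(n, 0, cfg$noiseSDs["mrnfl"])
  yGCIPL <- cfg$outcomeBaselines["mgcipl"] + catEffect("mgcipl") +
    cfg$noiseSDs["mgcipl"] * confTerm +
    cfg$effectMGCIPLPerSD * xReg + stats::rnorm(n, 0, cfg$noiseSDs["mgcipl"])

  catG <- catEffect("glaucoma")
  catEffG <- c(never = unname(cfg$categoryEffects$glaucoma["never"]),
               infrequent = 0,
               regular = unname(cfg$categoryEffects$glaucoma["regular"]),
               former = unname(cfg$categoryEffects$glaucoma["former"]))
  alpha <- stats::qlogis(cfg$baselinePrevalence) -
    sum(catP * catEffG[names(catP)])
  eta <- alpha + catG + confTerm + cfg$logORGlaucomaPerSD * xReg
  case <- stats::runif(n) < stats::plogis(eta)

  treated <- ifelse(case, stats::runif(n) < cfg$treatedCaseFraction,
                    stats::runif(n) < cfg$treatedFraction)

  # express phenotypes -----------------------------------------------------
  measuredIOP <- pmax(0.1, ifelse(treated, yIOP * 0.7, yIOP))
  split2 <- function(value, spread, pOneMissing, pBothMissing) {
    dlt <- stats::rnorm(n, 0, spread)
    # floor keeps physically impossible negative readings out of the far
    # lower tail
    right <- pmax(0.05, value + dlt); left <- pmax(0.05, value - dlt)
    u <- stats::runif(n)
    oneLost <- u < pOneMissing
    side <- stats::runif(n) < 0.5
    right[oneLost & side] <- NA
    left[oneLost & !side] <- NA
    both <- u >= pOneMissing & u < pOneMissing + pBothMissing
    right[both] <- NA; left[both] <- NA
    list(right = right, left = left)
  }
  iopEyes <- split2(measuredIOP, 0.8, 0.02, 0.005)
  rnflEyes <- split2(pmax(0.1, yRNFL), 1.0, 0.03, 0.01)
  gciplEyes <- split2(pmax(0.1, yGCIPL), 1.2, 0.03, 0.01)

  glaucomaSurgery <- case & stats::runif(n) < 0.10
  refractiveSurgery <- stats::runif(n) < 0.02
  cornealGraft <- stats::runif(n) < 0.002
  ocularTrauma <- stats::runif(n) < 0.003

  # case evidence mix: both self-report and codes / self-report only /
  # codes only
  u <- stats::runif(n)
  selfReport <- case & (u < 0.8)             # 60% both + 20% self-only
  hasCode <- case & (u < 0.6 | u >= 0.8)     # 60% both + 20% code-only
  selfReport <- selfReport | glaucomaSurgery # surgery implies self-report

  id <- seq_len(n)
  dxList <- list()
  caseIdx <- which(hasCode)
  if (length(caseIdx)) {
    codes <- sample(c("H40.1", "H40.11", "H40.2", "H42", "365.1", "365.11"),
                    length(caseIdx), TRUE,
                    prob = c(0.45, 0.15, 0.1, 0.05, 0.15, 0.1))
    days <- round(stats::runif(length(caseIdx), -3650, 365))
    ageAtDx <- pmax(30.5, cov$age[caseIdx] + days / 365)
    young <- stats::runif(length(caseIdx)) < 0.01  # exercise the age-30 rule
    ageAtDx[young] <- 25
    dxList$cases <- data.frame(participant_id = id[caseIdx], code = codes,
                               days_from_baseline = days,
                               age_at_diagnosis = ageAtDx)
  }
  suspectIdx <- which(!case & stats::runif(n) < 0.005)
  if (length(suspectIdx))
    dxList$suspects <- data.frame(
      participant_id = id[suspectIdx],
      code = sample(c("H40.0", "365.0"), length(suspectIdx), TRUE),
      days_from_baseline = round(stats::runif(length(suspectIdx), -2000,
                                              200)),
      age_at_diagnosis = NA_real_)
  irrIdx <- which(stats::runif(n) < 0.01)
  if (length(irrIdx))
    dxList$irrelevant <- data.frame(
      participant_id = id[irrIdx],
      code = sample(c("H26.9", "H25.1", "250.0", "I10"), length(irrIdx),
                    TRUE),
      days_from_baseline = round(stats::runif(length(irrIdx), -3650, 365)),
      age_at_diagnosis = NA_real_)
  diagnoses <- do.call(rbind, dxList)
  if (is.null(diagnoses))
    diagnoses <- data.frame(participant_id = integer(), code = character(),
                            days_from_baseline = integer(),
                            age_at_diagnosis = numeric())
  rownames(diagnoses) <- NULL

  participants <- cbind(
    data.frame(participant_id = id), cov, qn$table,
    data.frame(onHypotensives = treated,
               glaucomaSurgery = glaucomaSurgery,
               cornealGraft = cornealGraft,
               refractiveSurgery = refractiveSurgery,
               ocularTrauma = ocularTrauma,
               selfReportGlaucoma = selfReport,
               iopRight = iopEyes$right, iopLeft = iopEyes$left,
               mrnflRight = rnflEyes$right, mrnflLeft = rnflEyes$left,
               mgciplRight = gciplEyes$right, mgciplLeft = gciplEyes$left))

  truth <- data.frame(participant_id = id, category = category,
                      gramsTarget = gramsTarget, grams = grams,
                      includedAfterTrim = keep, intakeStd = xReg,
                      iopTrue = yIOP, mrnflTrue = yRNFL,
                      mgciplTrue = yGCIPL, etaGlaucoma = eta,
                      caseLatent = case)

  structure(list(participants = participants, diagnoses = diagnoses,
                 truth = truth, config = cfg),
            class = "CohortData")
}

#' @export
print.CohortData <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$participants), "participants,",
      nrow(x$diagnoses), "diagnosis records (seed", x$config$seed, ")\n")
  print(table(x$truth$category))
  invisible(x)
}

#' Generate questionnaire records only
#'
#' Draws drinking categories and questionnaire responses (frequency,
#' ever-drank follow-up, reporting period, portion counts) without the
#' covariate and outcome machinery of \code{\link{generateCohort}}. Never
#' drinkers carry no quantity fields; regular drinkers at weekly frequency
#' or above report weekly counts, the rest monthly counts; former drinkers
#' answer frequency "Never" with ever-drank yes.
#'
#' @param config A \code{\link{cohortConfig}}.
#' @return data.frame of questionnaire records.
#' @export
generateQuestionnaire <- function(config = cohortConfig()) {
  validateCohortConfig(config)
  withSeed(config$seed, {
    n <- config$n
    catP <- config$categoryProbabilities / sum(config$categoryProbabilities)
    category <- sample(names(catP), n, TRUE, catP)
    ln <- lognormalFromMedianSD(config$intakeMedian, config$intakeSD)
    gramsTarget <- rep(NA_real_, n)
    reg <- category == "regular"
    gramsTarget[reg] <- exp(ln$mu + ln$sigma * stats::rnorm(sum(reg)))
    inf <- category == "infrequent"
    gramsTarget[inf] <- exp(log(2.8) + 1.2 * stats::rnorm(sum(inf)))
    qn <- .buildQuestionnaire(category, gramsTarget, config$beverages)
    cbind(data.frame(participant_id = seq_len(n)), qn$table)
  })
}
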