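# Cohort generator: seed contract, marginal calibration, generative-model
# oracle, null-effect behaviour and questionnaire structure.

test_that("the seed contract gives bit-identical reruns and differing seeds", {
  a <- generateCohort(cohortConfig(n = 400, seed = 33))
  b <- generateCohort(cohortConfig(n = 400, seed = 33))
  c <- generateCohort(cohortConfig(n = 400, seed = 34))
  expect_identical(a$participants, b$participants)
  expect_identical(a$diagnoses, b$diagnoses)
  expect_false(identical(a$participants$age, c$participants$age))
  # the generator leaves the global RNG stream untouched
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generateCohort(cohortConfig(n = 50, seed = 2)))
  expect_identical(runif(3), before)
})

test_that("category mix, covariate marginals and prevalence match configuration", {
  fx <- derivedCohort(20000, 77)
  d <- fx$data; cfg <- fx$cohort$config
  n <- nrow(d)
  # category proportions within 3 binomial SEs
  for (cat in names(cfg$categoryProbabilities)) {
    p <- cfg$categoryProbabilities[[cat]]
    expect_lt(abs(mean(d$category == cat) - p), 3 * sqrt(p * (1 - p) / n))
  }
  # continuous covariate means within 3 Monte-Carlo SEs
  marg <- cfg$covariates
  for (v in c("age", "townsend", "bmi", "height", "sbp")) {
    expect_lt(abs(mean(d[[v]]) - marg[[v]]["mean"]),
              3 * marg[[v]]["sd"] / sqrt(n))
    expect_lt(abs(sd(d[[v]]) / marg[[v]]["sd"] - 1), 0.05)
  }
  expect_lt(abs(mean(d$sex == "Women") - marg$sexWomen),
            3 * sqrt(marg$sexWomen * (1 - marg$sexWomen) / n))
  # glaucoma prevalence ~ 1.8% within binomial error (latent model)
  prev <- cfg$baselinePrevalence
  expect_lt(abs(mean(fx$cohort$truth$caseLatent) - prev),
            3.5 * sqrt(prev * (1 - prev) / n))
  # outcome means match the analytic expectation of the generative
  # equation: baseline + category mix + realised exposure/interaction terms
  tr <- fx$cohort$truth
  expCat <- with(cfg, sapply(c("never", "infrequent", "regular", "former"),
    function(cc) if (cc == "infrequent") 0 else categoryEffects$iop[[cc]]))
  expIOP <- cfg$outcomeBaselines[["iop"]] +
    mean(expCat[tr$category]) +
    cfg$effectIOPPerSD * mean(tr$intakeStd) +
    cfg$interactionIOP * mean(tr$intakeStd * d$prs)
  expect_lt(abs(mean(tr$iopTrue) - expIOP),
            3.5 * cfg$noiseSDs[["iop"]] / sqrt(n))
  # regular-drinker intake calibration: median near the configured value
  med <- median(d$gramsWeek[d$category == "regular"], na.rm = TRUE)
  expect_lt(abs(med - cfg$intakeMedian) / cfg$intakeMedian, 0.08)
})

test_that("zero-noise, zero-confounding cohorts reproduce the generative expectation exactly", {
  cfg <- cohortConfig(n = 1500, seed = 19,
                      noiseSDs = c(iop = 0, mrnfl = 0, mgcipl = 0),
                      confounderWeight = 0)
  cd <- generateCohort(cfg)
  tr <- cd$truth
  catEff <- sapply(tr$category, function(cc)
    if (cc == "infrequent") 0 else cfg$categoryEffects$iop[[cc]])
  oracle <- cfg$outcomeBaselines[["iop"]] + catEff +
    cfg$effectIOPPerSD * tr$intakeStd +
    cfg$interactionIOP * tr$intakeStd * cd$participants$prs
  expect_equal(tr$iopTrue, unname(oracle), tolerance = 1e-12)
  expect_equal(mean(tr$iopTrue), mean(oracle), tolerance = 1e-12)
  # with zero noise and zero confounding, regression on the generated data
  # returns the configured effect to machine precision
  d <- deriveExposure(cd$participants)
  reg <- d$category == "regular" & d$includedAfterTrim %in% TRUE
  fit <- lm(tr$iopTrue[reg] ~ d$intakeStd[reg] + cd$participants$prs[reg] +
              d$intakeStd[reg]:cd$participants$prs[reg])
  expect_equal(unname(coef(fit)[2]), cfg$effectIOPPerSD, tolerance = 1e-8)
})

test_that("a null-effect configuration yields per-SD coefficients near zero", {
  cfg <- cohortConfig(n = 2000, seed = 8, effectIOPPerSD = 0,
                      effectMRNFLPerSD = 0, effectMGCIPLPerSD = 0,
                      logORGlaucomaPerSD = 0, interactionIOP = 0)
  fx <- derivedCohort(config = cfg, label = "null")
  r <- perSDAnalysis(fx$data, "iop")
  se <- (r$ciHigh[1] - r$ciLow[1]) / (2 * 1.96)
  expect_lt(abs(r$estimate[1]), 4 * se)
})

test_that("questionnaire records follow the reporting rules", {
  cfg <- cohortConfig(n = 4000, seed = 13)
  qn <- generateQuestionnaire(cfg)
  cat <- classifyDrinker(qn$frequency, qn$everDrank)
  portCols <- paste0("portions_", beverageNames())
  # never drinkers carry no quantity fields
  expect_true(all(is.na(qn[cat == "never", portCols])))
  expect_true(all(is.na(qn[cat == "former", portCols])))
  # weekly-or-more frequencies report weekly counts, the rest monthly
  weeklyFreqs <- c("1-2 times a week", "3-4 times a week",
                   "Daily/almost daily")
  expect_true(all(qn$reportingPeriod[qn$frequency %in% weeklyFreqs] ==
                    "weekly"))
  expect_true(all(qn$reportingPeriod[qn$frequency %in%
                    c("1-3 times a month", "Special occasions only")] ==
                    "monthly"))
  expect_true(all(qn[cat %in% c("regular", "infrequent"), portCols] >= 0))
  # seeded batch: category frequencies match the configured probabilities
  # within binomial error (direct counting oracle)
  for (cc in names(cfg$categoryProbabilities)) {
    p <- cfg$categoryProbabilities[[cc]]
    expect_lt(abs(mean(cat == cc) - p), 3.5 * sqrt(p * (1 - p) / nrow(qn)))
  }
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohortConfig(n = 0), "count")
  expect_error(cohortConfig(baselinePrevalence = 1.4), "\\[0, 1\\]")
  expect_error(cohortConfig(categoryProbabilities = c(0.5, 0.2, 0.2, 0.2)),
               "summing to 1")
  expect_error(cohortConfig(effectIOPPerSD = Inf), "non-finite")
  expect_error(cohortConfig(intakeSD = -3), "> 0")
})
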