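# Shared fixtures: small derived cohorts and brute-force oracle utilities.
# Cohorts are cached per (n, seed, label) within a test run.

.fixtureCache <- new.env(parent = emptyenv())

derivedCohort <- function(n = 4000, seed = 11, config = NULL, label = "") {
  key <- paste(n, seed, label, sep = "_")
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  if (is.null(config)) config <- cohortConfig(n = n, seed = seed)
  cd <- generateCohort(config)
  d <- deriveExposure(cd$participants)
  d <- deriveOutcomes(d, cd$diagnoses)
  out <- list(data = d, cohort = cd)
  .fixtureCache[[key]] <- out
  out
}

# Brute-force six-term gram summation for one questionnaire record.
bruteGrams <- function(portions, period, beverages = defaultBeverageTable()) {
  k <- if (period == "weekly") 1 else 12 * 7 / 365
  total <- 0
  for (i in seq_along(beverageNames())) {
    b <- beverages[beverages$beverage == beverageNames()[i], ]
    total <- total + portions[i] * b$portion_ml * (b$abv_percent / 100 * 0.789) * k
  }
  total
}

# Independent normal-equations OLS solve.
bruteOLS <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

# Independent weighted normal-equations solve.
bruteWLS <- function(X, y, w) {
  as.numeric(solve(t(X * w) %*% X, t(X * w) %*% y))
}

# Logistic log-likelihood for numeric maximization.
logisticNegLL <- function(beta, X, y) {
  eta <- as.numeric(X %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}
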