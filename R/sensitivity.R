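# Sensitivity-analysis harness re-running the primary analyses under named
# variants.

#' Run a named sensitivity analysis
#'
#' Re-runs the per-SD (or categorical) primary analysis under one of the
#' documented variants:
#' \describe{
#'   \item{sex-stratified}{Separate fits for women and men plus the
#'     sex x intake product-term p-value.}
#'   \item{subgroup}{Restriction to rows satisfying \code{subset} (e.g.
#'     European descent, no hypertension).}
#'   \item{beverage-type}{Per-SD fits of beverage-specific weekly grams
#'     (requires the portion columns).}
#'   \item{extra-covariates}{Adds the columns in \code{extra} to the
#'     adjustment set.}
#'   \item{exclude-glaucoma}{Drops ascertained cases before fitting
#'     IOP/OCT outcomes.}
#'   \item{meal-interaction}{Intake x with-meals product-term p-value.}
#' }
#'
#' @param data Analysis cohort.
#' @param variant Variant name (see above).
#' @param outcome Outcome to fit.
#' @param covariates Covariate specification.
#' @param subset Logical vector for the \code{subgroup} variant.
#' @param extra Character vector of extra covariate columns.
#' @param beverages Beverage table for \code{beverage-type}.
#' @return A list with \code{results} (a \linkS4class{ModelResult} or a
#'   named list of them) and, for interaction variants,
#'   \code{interactionP}.
#' @export
runSensitivity <- function(data, variant, outcome = "iop",
                           covariates = covariateSpec(), subset = NULL,
                           extra = character(),
                           beverages = defaultBeverageTable()) {
  regMask <- !is.na(data$category) & data$category == "regular" &
    !is.na(data$intakeStd)
  reg <- data[regMask, ]
  switch(variant,
    "sex-stratified" = {
      res <- lapply(c(Women = "Women", Men = "Men"), function(s) {
        cov2 <- covariates[covariates$name != "sex", ]
        .fitOutcome(reg[reg$sex == s, ], outcome, "intakeStd", cov2)
      })
      intFit <- .interactionProductFit(reg, outcome, "sex", covariates)
      list(results = res, interactionP = intFit)
    },
    "subgroup" = {
      if (is.null(subset)) abortGD("subgroup variant needs a subset mask")
      list(results = .fitOutcome(data[regMask & subset, ], outcome,
                                 "intakeStd", covariates))
    },
    "beverage-type" = {
      gpp <- beverages$portion_ml * beverages$concentration_g_ml
      names(gpp) <- beverages$beverage
      res <- lapply(beverageNames(), function(b) {
        col <- paste0("portions_", b)
        k <- ifelse(reg$reportingPeriod == "weekly", 1, kMonthly())
        reg$bevGrams <- reg[[col]] * gpp[[b]] * k
        reg$bevGramsStd <- as.numeric(scale(reg$bevGrams))
        .fitOutcome(reg, outcome, "bevGramsStd", covariates)
      })
      names(res) <- beverageNames()
      list(results = res)
    },
    "extra-covariates" = {
      missing <- setdiff(extra, names(data))
      if (length(missing))
        abortGD("extra covariate columns absent: ",
                paste(missing, collapse = ", "))
      cov2 <- rbind(covariates,
                    data.frame(name = extra, type = "continuous",
                               reference = NA))
      list(results = .fitOutcome(reg, outcome, "intakeStd", cov2))
    },
    "exclude-glaucoma" = {
      if (outcome == "glaucoma")
        abortGD("exclude-glaucoma applies to IOP/OCT outcomes")
      keep <- reg$glaucomaStatus != "case"
      list(results = .fitOutcome(reg[keep, ], outcome, "intakeStd",
                                 covariates),
           nExcluded = sum(!keep))
    },
    "meal-interaction" = {
      list(interactionP = .interactionProductFit(reg, outcome, "withMeals",
                                                 covariates))
    },
    abortGD("unknown sensitivity variant: ", variant))
}

# Product-term p-value of intakeStd x modifier in the maximally adjusted
# model.
.interactionProductFit <- function(dat, outcome, modifier, covariates) {
  if (outcome == "glaucoma") {
    dat$glaucomaCase <- .glaucomaBinary(dat)
    yname <- "glaucomaCase"
    dat <- dat[!is.na(dat$glaucomaCase), ]
  } else yname <- outcome
  covNames <- unique(c(covariates$name, modifier))
  f <- stats::as.formula(paste(yname, "~ intakeStd *", modifier, "+",
                               paste(setdiff(covNames, modifier),
                                     collapse = " + ")))
  dat <- dat[stats::complete.cases(dat[, c(yname, "intakeStd", covNames)]), ]
  fit <- if (yname == "glaucomaCase")
    stats::glm(f, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  else stats::lm(f, data = dat)
  sm <- summary(fit)$coefficients
  row <- grep("^intakeStd:", rownames(sm))
  waldP(sm[row, 1], sm[row, 2])[1]
}
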