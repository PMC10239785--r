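# Association models: oracle equivalences for the fitters, categorical and
# quintile analyses, spline basis exactness and AIC selection.

noCov <- covariateSpec()[0, ]

test_that("linear fits agree with an independent normal-equations solve", {
  set.seed(14)
  n <- 50
  toy <- data.frame(y = rnorm(n), x = rnorm(n), z1 = rnorm(n),
                    z2 = rnorm(n))
  cov2 <- data.frame(name = c("z1", "z2"), type = "continuous",
                     reference = NA)
  res <- fitLinear(toy, "y", "x", cov2)
  X <- cbind(1, toy$x, toy$z1, toy$z2)
  expect_equal(res$estimate[1], bruteOLS(X, toy$y)[2], tolerance = 1e-8)
  # single continuous exposure, no covariates: slope = cov(x,y)/var(x)
  res0 <- fitLinear(toy, "y", "x", noCov)
  expect_equal(res0$estimate[1], cov(toy$x, toy$y) / var(toy$x),
               tolerance = 1e-10)
  # rank deficiency is reported with the collinear term
  toy$x2 <- toy$x
  cov3 <- data.frame(name = "x2", type = "continuous", reference = NA)
  expect_error(fitLinear(toy, "y", "x", cov3), "rank-deficient")
})

test_that("logistic fits agree with the saturated closed form and a likelihood search", {
  # 2x2 table: OR equals the cross-product ratio ad/bc
  tab <- data.frame(y = rep(c(1, 0, 1, 0), c(30, 70, 55, 45)),
                    g = rep(c(0, 0, 1, 1), c(30, 70, 55, 45)))
  res <- fitLogistic(tab, "y", "g", noCov)
  expect_equal(res$estimate[1], (55 * 70) / (45 * 30), tolerance = 1e-6)

  # n = 200 toy against direct numeric likelihood maximization
  set.seed(5)
  n <- 200
  toy <- data.frame(x = rnorm(n), z1 = rnorm(n))
  eta <- -0.3 + 0.8 * toy$x - 0.4 * toy$z1
  toy$y <- rbinom(n, 1, plogis(eta))
  cov1 <- data.frame(name = "z1", type = "continuous", reference = NA)
  res <- fitLogistic(toy, "y", "x", cov1)
  X <- cbind(1, toy$x, toy$z1)
  opt <- optim(c(0, 0, 0), logisticNegLL, X = X, y = toy$y,
               method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(log(res$estimate[1]), opt$par[2], tolerance = 1e-6)
  expect_error(fitLogistic(data.frame(y = c(1, 1), x = 1:2), "y", "x",
                           noCov), "both outcome classes")
})

test_that("categorical analysis honors the reference and relabeling symmetry", {
  fx <- derivedCohort(3000, 21)
  d <- fx$data
  res <- categoricalAnalysis(d, outcomes = "iop")
  expect_s4_class(res, "ModelResult")
  expect_identical(sort(res$term),
                   sort(paste0("category", c("never", "regular", "former"))))
  # relabeling: using 'regular' as reference flips the regular contrast
  res2 <- categoricalAnalysis(d, outcomes = "iop", reference = "regular")
  iopRegular <- res$estimate[res$term == "categoryregular"]
  iopInfreq <- res2$estimate[res2$term == "categoryinfrequent"]
  expect_equal(unname(iopInfreq), unname(-iopRegular), tolerance = 1e-8)
  # pooled never+infrequent reference keeps only two contrasts
  resP <- categoricalAnalysis(d, outcomes = "iop", pooledReference = TRUE)
  expect_identical(sort(resP$term),
                   sort(paste0("category", c("regular", "former"))))
  d2 <- d[d$category != "infrequent", ]
  expect_error(categoricalAnalysis(d2, outcomes = "iop"),
               "empty reference")
})

test_that("quintile analysis reproduces sort-based medians and the trend construction", {
  d <- derivedCohort(3000, 21)$data
  # sort-based oracle on a deterministic intake ladder
  toy <- d[rep(1, 100), ]
  toy$gramsWeek <- 1:100
  toy$includedAfterTrim <- TRUE
  toy$category <- "regular"
  toy$iop <- rnorm(100)
  q <- quintileAnalysis(toy, "iop", noCov)
  expect_equal(as.numeric(q$quintileMedians),
               c(10.5, 30.5, 50.5, 70.5, 90.5))
  expect_identical(names(q$quintileMedians), paste0("Q", 1:5))
  # quintile contrasts Q2..Q5 vs Q1 and a Wald trend p in (0, 1]
  expect_identical(sort(q$results$term),
                   sort(paste0("intakeQuintile", paste0("Q", 2:5))))
  expect_true(q$trendP > 0 && q$trendP <= 1)
  expect_error(quintileAnalysis(toy[1:4, ], "iop", noCov),
               "too few distinct")
  # monotone truth: top-quintile contrast exceeds the second's
  qq <- quintileAnalysis(d, "mgcipl")
  est <- qq$results$estimate
  expect_lt(est[4], est[1])  # Q5 more negative than Q2 under a negative slope
})

test_that("the per-SD fit is scale equivariant", {
  d <- derivedCohort(3000, 21)$data
  reg <- d[d$category == "regular" & d$includedAfterTrim %in% TRUE, ]
  s <- sd(reg$gramsWeek)
  perSD <- fitLinear(reg, "iop", "intakeStd", noCov)$estimate[1]
  perGram <- fitLinear(reg, "iop", "gramsWeek", noCov)$estimate[1]
  expect_equal(perSD, perGram * s, tolerance = 1e-10)
})

test_that("the spline basis matches the truncated-power formula and is linear in the tails", {
  kn <- c(1.2, 2.5, 3.1, 4.8)
  x <- seq(0, 6, length.out = 400)
  B <- rcsBasis(x, kn)
  # direct evaluation of the truncated-power formula
  k <- length(kn); tk <- kn[k]; tk1 <- kn[k - 1]
  pos3 <- function(u) pmax(u, 0)^3
  for (j in 1:(k - 2)) {
    direct <- (pos3(x - kn[j]) -
                 pos3(x - tk1) * (tk - kn[j]) / (tk - tk1) +
                 pos3(x - tk) * (tk1 - kn[j]) / (tk - tk1)) / (tk - kn[1])^2
    expect_equal(B[, j + 1], direct, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # below the first knot every nonlinear column is exactly zero
  expect_true(all(B[x < kn[1], -1] == 0))
  # beyond the last knot the represented function is linear: second
  # differences of every basis column vanish
  xr <- seq(5, 8, by = 0.01)
  Br <- rcsBasis(xr, kn)
  d2 <- diff(Br, differences = 2)
  expect_lt(max(abs(d2)), 1e-8)
  expect_error(rcsBasis(x, c(3, 2, 1)), "strictly increasing")
  expect_error(rcsBasis(x, c(1, 1, 2)), "strictly increasing")
  expect_error(rcsBasis(x, c(1, 2)), "at least 3")
})

test_that("spline fits select by AIC, match the AIC identity and collapse to linear truth", {
  d <- derivedCohort(6000, 29)$data
  sf <- fitRCS(d, "iop", kRange = 3:5)
  expect_s4_class(sf, "SplineFit")
  expect_true(sf@nKnots %in% 3:5)
  expect_equal(sf@aic, min(sf@aicTable$aic))
  expect_error(fitRCS(d, "iop", kRange = 2:4), "3..7")

  # AIC identity 2p - 2 logLik against a direct refit
  reg <- d[d$category == "regular" & d$includedAfterTrim %in% TRUE &
             !is.na(d$gramsWeek) & d$gramsWeek > 0 & !is.na(d$iop), ]
  kn <- quantile(log(reg$gramsWeek), c(0.1, 0.5, 0.9), names = FALSE)
  B <- rcsBasis(log(reg$gramsWeek), kn)
  fit <- lm(reg$iop ~ B)
  expect_equal(AIC(fit),
               2 * (length(coef(fit)) + 1) - 2 * as.numeric(logLik(fit)),
               tolerance = 1e-10)

  # under a linear (in log intake) truth the selected nonlinear
  # coefficients stay within 3 SEs of zero
  set.seed(31)
  toy <- reg
  toy$iop <- 16 + 0.4 * log(toy$gramsWeek) + rnorm(nrow(toy), 0, 1)
  sfLin <- fitRCS(toy, "iop", kRange = 3:4, covariates = noCov)
  cf <- sfLin@coefficients
  nl <- grep("^rcs[2-9]", names(cf))
  expect_true(length(nl) >= 1)
  # refit to obtain SEs for the nonlinear block
  B2 <- rcsBasis(log(toy$gramsWeek), sfLin@knots)
  colnames(B2) <- paste0("rcs", seq_len(ncol(B2)))
  refit <- lm(toy$iop ~ ., data = as.data.frame(cbind(B2)))
  sm <- summary(refit)$coefficients
  for (term in names(cf)[nl])
    expect_lt(abs(sm[term, 1] / sm[term, 2]), 3.5)
})

test_that("spline curves are invariant to recentering and carry guideline overlays", {
  d <- derivedCohort(3000, 21)$data
  sf1 <- fitRCS(d, "iop", kRange = 3, referenceGrams = 50)
  sf2 <- fitRCS(d, "iop", kRange = 3, referenceGrams = 150)
  # recentering the reference shifts the curve by a constant only
  shift <- sf1@curve$estimate - sf2@curve$estimate
  expect_lt(diff(range(shift)), 1e-8)
  expect_equal(unname(sf1@guidelines),
               c(112, 98, 196))
})

test_that("sensitivity variants re-run the primary analyses coherently", {
  fx <- derivedCohort(3000, 21)
  d <- fx$data
  # exclude-glaucoma bookkeeping: n drops by exactly the case count among
  # the analysis rows
  full <- perSDAnalysis(d, "iop")
  sens <- runSensitivity(d, "exclude-glaucoma", outcome = "iop")
  reg <- d[d$category == "regular" & !is.na(d$intakeStd), ]
  usable <- complete.cases(reg[, c("iop", "intakeStd",
                                   covariateSpec()$name)])
  casesInModel <- sum(reg$glaucomaStatus[usable] == "case")
  expect_equal(full$n[1] - sens$results$n[1], casesInModel)

  # stratification by sex: stratum estimates within 4 joint SEs
  strat <- runSensitivity(d, "sex-stratified", outcome = "iop")
  e <- vapply(strat$results, function(r) r$estimate[1], 0)
  se <- vapply(strat$results,
               function(r) (r$ciHigh[1] - r$ciLow[1]) / (2 * 1.96), 0)
  expect_lt(abs(e[1] - e[2]), 4 * sqrt(sum(se^2)))
  expect_true(strat$interactionP > 0 && strat$interactionP <= 1)
  expect_error(runSensitivity(d, "not-a-variant"), "unknown sensitivity")
})
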