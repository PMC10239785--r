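# Two-sample MR: harmonization, instruments, and the estimator battery
# against independent oracles.

# small helper building a clean harmonized set with known truth
mkSet <- function(n = 20, theta = -1.5, seed = 1, noiseScale = 1, ...) {
  harmonize(generateSummaryStats(
    summaryConfig(nSNPs = n, trueEffect = theta, seed = seed,
                  noiseScale = noiseScale, ...)))
}

test_that("harmonization aligns alleles, drops ambiguity and ignores row order", {
  ex <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                   effect_allele = c("A", "A", "A", "A"),
                   other_allele = c("G", "G", "G", "T"),
                   beta = c(0.1, 0.2, 0.3, 0.4),
                   se = 0.01, pval = 1e-10, n = 1000)
  ou <- ex
  ou$beta <- c(1, 2, 3, 4)
  # rs2: swapped alleles must flip the outcome beta
  ou$effect_allele[2] <- "G"; ou$other_allele[2] <- "A"
  # rs3: strand-flipped labels (complement), same orientation
  ou$effect_allele[3] <- "T"; ou$other_allele[3] <- "C"
  set <- suppressMessages(harmonize(ex, ou))
  # rs4 is palindromic (A/T) and dropped
  expect_identical(snps(set), c("rs1", "rs2", "rs3"))
  expect_equal(betaY(set), c(1, -2, 3))
  expect_message(harmonize(ex, ou), "strand-ambiguous")
  # permuting input rows changes nothing
  set2 <- suppressMessages(harmonize(ex[c(3, 1, 4, 2), ], ou[c(2, 4, 3, 1), ]))
  expect_identical(as.data.frame(set), as.data.frame(set2))
  expect_error(harmonize(ex, transform(ou, snp_id = paste0("x", snp_id))),
               "no overlapping")
})

test_that("instrument construction filters on p-value and exclusion list", {
  sc <- generateSummaryStats(summaryConfig(nSNPs = 30,
                                           flaggedVariantPresent = TRUE,
                                           seed = 9))
  set <- harmonize(sc)
  full <- buildInstrument(set)
  expect_identical(nSNPs(full), 30L)
  restricted <- buildInstrument(set, excludeIds = "rs1229984")
  expect_identical(nSNPs(restricted), 29L)
  expect_false("rs1229984" %in% snps(restricted))
  # full and restricted agree SNP-by-SNP on the retained variants
  expect_identical(as.data.frame(full[snps(restricted)]),
                   as.data.frame(restricted))
  expect_identical(nSNPs(buildInstrument(set, pThreshold = 1)), 30L)
  expect_error(buildInstrument(set, excludeIds = snps(set)),
               "empty instrument")
})

test_that("Wald ratios follow the delta method", {
  expect_equal(waldRatio(0.2, 0.4, 0.01, 0.05)$estimate, 2)
  wr0 <- waldRatio(0.2, 0, 0.01, 0.05)
  expect_equal(wr0$estimate, 0)
  expect_equal(wr0$se, 0.05 / 0.2)
  expect_error(waldRatio(0, 0.3, 0.01, 0.05), "zero exposure")
  # second-order SE against a parametric simulation of the ratio at
  # se/beta <= 0.1
  bx <- 0.5; by <- 1.0; sx <- 0.05; sy <- 0.08
  se2 <- waldRatio(bx, by, sx, sy, secondOrder = TRUE)$se
  set.seed(10)
  sim <- rnorm(200000, by, sy) / rnorm(200000, bx, sx)
  expect_lt(abs(se2 / sd(sim) - 1), 0.1)
})

test_that("IVW matches its closed form, the noiseless limit and the single-SNP fallback", {
  set <- mkSet(15, theta = -1.52, seed = 2, noiseScale = 0)
  est <- mrIVW(set)
  expect_equal(estimate(est), -1.52, tolerance = 1e-10)
  expect_lt(diagnostics(est)$Q, 1e-16)
  # weighted through-origin regression oracle
  setN <- mkSet(25, theta = -1.5, seed = 3)
  w <- 1 / seY(setN)^2
  oracle <- sum(w * betaX(setN) * betaY(setN)) / sum(w * betaX(setN)^2)
  expect_equal(estimate(mrIVW(setN)), oracle, tolerance = 1e-12)
  # fixed vs multiplicative-random SEs differ by sqrt(max(1, Q/(n-1)))
  fx <- mrIVW(setN, "fixed"); rd <- mrIVW(setN)
  Q <- diagnostics(rd)$Q
  expect_equal(diagnostics(rd)$se,
               diagnostics(fx)$se * sqrt(max(1, Q / (nSNPs(setN) - 1))),
               tolerance = 1e-12)
  # single SNP reduces to the Wald ratio
  one <- setN[1]
  expect_message(e1 <- mrIVW(one), "Wald ratio")
  expect_equal(estimate(e1),
               waldRatio(betaX(one), betaY(one), seX(one), seY(one))$estimate,
               tolerance = 1e-12)
})

test_that("MR-Egger recovers exact intercept/slope pairs and matches a WLS oracle", {
  # data constructed exactly as by = a + theta * bx (bx > 0)
  bx <- seq(0.05, 0.5, length.out = 10)
  a <- 0.03; theta <- -1.2
  set <- MRSummarySet(paste0("s", 1:10), betaX = bx, seX = 0.01,
                      betaY = a + theta * bx, seY = seq(0.02, 0.06,
                                                        length.out = 10))
  e <- mrEgger(set)
  expect_equal(estimate(e), theta, tolerance = 1e-10)
  expect_equal(diagnostics(e)$egger_intercept, a, tolerance = 1e-10)
  # independent weighted-normal-equations oracle on noisy data
  setN <- mkSet(30, theta = -1.5, seed = 6)
  flip <- sign(betaX(setN))
  X <- cbind(1, betaX(setN) * flip)
  cf <- bruteWLS(X, betaY(setN) * flip, 1 / seY(setN)^2)
  eN <- mrEgger(setN)
  expect_equal(diagnostics(eN)$egger_intercept, cf[1], tolerance = 1e-10)
  expect_equal(estimate(eN), cf[2], tolerance = 1e-10)
  expect_true(diagnostics(eN)$I2GX >= 0 && diagnostics(eN)$I2GX <= 1)
  expect_error(mrEgger(setN[1:2]), "at least 3")
})

test_that("the weighted median interpolates the weighted-quantile definition", {
  # equal weights, odd n: plain median of the ratios
  bx <- rep(0.2, 5)
  by <- c(0.1, 0.3, 0.2, 0.5, 0.4)
  set <- MRSummarySet(paste0("s", 1:5), betaX = bx, seX = 0.01,
                      betaY = by, seY = 0.05)
  m <- mrMedian(set, nBoot = 200, seed = 1)
  expect_equal(estimate(m), median(by / bx), tolerance = 1e-10)
  # exhaustive evaluation of the cumulative-weight definition
  setN <- mkSet(19, theta = -1.5, seed = 8)
  r <- betaY(setN) / betaX(setN)
  w <- 1 / (seY(setN) / abs(betaX(setN)))^2
  o <- order(r); r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  j <- max(which(s < 0.5))
  oracle <- r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
  expect_equal(estimate(mrMedian(setN, nBoot = 200, seed = 1)), oracle,
               tolerance = 1e-10)
  expect_error(mrMedian(setN[1:2]), "at least 3")
})

test_that("the weighted median resists minority outliers", {
  # <= 49% of the weight on planted outliers leaves the estimate near theta
  reps <- vapply(1:20, function(s) {
    sc <- summaryConfig(nSNPs = 21, trueEffect = -1.5, nOutliers = 9,
                        outlierShift = 0.5, seed = 300 + s)
    estimate(mrMedian(harmonize(generateSummaryStats(sc)), nBoot = 100,
                      seed = s))
  }, numeric(1))
  expect_lt(abs(mean(reps) - (-1.5)), 0.25)
})

test_that("the weighted mode maximizes the smoothed ratio density", {
  # all ratios identical: the mode is that value for any bandwidth
  set <- MRSummarySet(paste0("s", 1:5), betaX = rep(0.2, 5), seX = 0.01,
                      betaY = rep(-0.3, 5), seY = 0.05)
  for (phi in c(0.5, 1, 2))
    expect_equal(estimate(mrMode(set, phi = phi, nBoot = 100, seed = 1)),
                 -1.5, tolerance = 1e-10)
  expect_error(mrMode(set, phi = 0), "phi")
  # fine brute-force grid search of the same density
  setN <- mkSet(25, theta = -1.5, seed = 12)
  r <- betaY(setN) / betaX(setN)
  w <- 1 / (seY(setN) / abs(betaX(setN)))^2
  h <- 0.9 * min(sd(r), mad(r)) * length(r)^(-1 / 5)
  fine <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 20001)
  dens <- vapply(fine, function(g) sum(w * dnorm((g - r) / h)), 0)
  oracle <- fine[which.max(dens)]
  got <- estimate(mrMode(setN, nBoot = 100, seed = 1))
  gridStep <- (max(r) - min(r) + 6 * h) / 511
  expect_lt(abs(got - oracle), gridStep)
  # majority cluster wins over a pooled mean
  set.seed(77)
  bx <- rep(0.2, 15)
  by <- c(rep(0.2 * -1.5, 10), rep(0.2 * 2, 5)) + rnorm(15, 0, 1e-4)
  two <- MRSummarySet(paste0("s", 1:15), betaX = bx, seX = 0.01,
                      betaY = by, seY = 0.05)
  est <- estimate(mrMode(two, nBoot = 100, seed = 2))
  expect_lt(abs(est - (-1.5)), 0.3)
  pooled <- mean(by / bx)
  expect_gt(abs(pooled - (-1.5)), abs(est - (-1.5)))
})

test_that("MR-PRESSO separates tight nulls from planted outliers deterministically", {
  # tight, noiseless set: global p ~ 1, no outliers, no corrected estimate
  tight <- mkSet(12, theta = -1.5, seed = 3, noiseScale = 0.01)
  pres <- mrPresso(tight, nSim = 300, seed = 5)
  expect_gt(diagnostics(pres)$global_p, 0.5)
  expect_identical(diagnostics(pres)$outlier_ids, character(0))
  expect_true(is.na(estimate(pres)))
  # planted 10-SE outlier among 50 SNPs is flagged
  seY1 <- 5.2 / sqrt(31434)
  sc <- summaryConfig(nSNPs = 50, trueEffect = -1.5, nOutliers = 1,
                      outlierShift = 10 * seY1, seed = 21)
  set <- harmonize(generateSummaryStats(sc))
  outlierId <- sc$nSNPs  # planted at the tail by construction
  pres2 <- mrPresso(set, nSim = 1000, seed = 6)
  truthIds <- generateSummaryStats(sc)$truth
  planted <- truthIds$snp_id[truthIds$outlierTruth]
  expect_true(planted %in% diagnostics(pres2)$outlier_ids)
  expect_lt(diagnostics(pres2)$global_p, 0.05)
  expect_false(is.na(estimate(pres2)))
  expect_true(!is.null(diagnostics(pres2)$distortion_p))
  # simulation oracle: the same seed reproduces the same global p
  pres3 <- mrPresso(set, nSim = 1000, seed = 6)
  expect_identical(diagnostics(pres2)$global_p,
                   diagnostics(pres3)$global_p)
  expect_error(mrPresso(set[1:3]), "at least 4")
  expect_error(mrPresso(set, nSim = 50), "at least 100")
})

test_that("multivariable MR matches a WLS oracle and nests univariable IVW", {
  sc <- summaryConfig(nSNPs = 40, trueEffect = -1.5,
                      secondExposureEffect = 1.2, seed = 14)
  set <- harmonize(generateSummaryStats(sc))
  mv <- mrMVMR(set)
  X <- cbind(set@betaX, set@betaX2)
  cf <- bruteWLS(X, betaY(set), 1 / seY(set)^2)
  expect_equal(estimate(mv), cf[1], tolerance = 1e-10)
  expect_equal(diagnostics(mv)$beta_exposure2, cf[2], tolerance = 1e-10)

  # nested limit: a second-exposure column orthogonal (under the IVW
  # weights) to the first leaves the primary coefficient exactly at IVW
  base <- mkSet(20, theta = -1.5, seed = 15)
  ivw <- estimate(mrIVW(base))
  w <- 1 / seY(base)^2
  set.seed(1)
  z <- rnorm(20)
  zo <- z - betaX(base) * sum(w * betaX(base) * z) /
    sum(w * betaX(base)^2)
  for (eps in c(1e-3, 1e-6)) {
    jit <- MRSummarySet(snps(base), betaX = betaX(base), seX = seX(base),
                        betaY = betaY(base), seY = seY(base),
                        betaX2 = eps * zo, seX2 = rep(1e-3, 20))
    expect_equal(estimate(mrMVMR(jit)), ivw, tolerance = 1e-8)
  }
  # correlated second-exposure pathway: univariable IVW is biased by the
  # shared architecture, the adjusted estimate recovers the truth
  errs <- sapply(1:20, function(s) {
    scB <- summaryConfig(nSNPs = 60, trueEffect = -1.5,
                         secondExposureEffect = 3,
                         exposureCorrelation = 0.6, seed = 500 + s)
    st <- harmonize(generateSummaryStats(scB))
    c(mvmr = abs(estimate(mrMVMR(st)) + 1.5),
      ivw = abs(estimate(mrIVW(st)) + 1.5))
  })
  expect_lt(mean(errs["mvmr", ]), mean(errs["ivw", ]))
})

test_that("estimators are invariant to SNP order and joint sign flips", {
  set <- mkSet(24, theta = -1.5, seed = 18)
  perm <- sample(24)
  flip <- sample(c(-1, 1), 24, TRUE)
  flipped <- MRSummarySet(snps(set), betaX = betaX(set) * flip,
                          seX = seX(set), betaY = betaY(set) * flip,
                          seY = seY(set))
  permuted <- set[perm]
  for (f in list(mrIVW, mrEgger)) {
    expect_equal(estimate(f(permuted)), estimate(f(set)), tolerance = 1e-12)
    expect_equal(estimate(f(flipped)), estimate(f(set)), tolerance = 1e-12)
  }
  expect_equal(estimate(mrMedian(flipped, nBoot = 100, seed = 3)),
               estimate(mrMedian(set, nBoot = 100, seed = 3)),
               tolerance = 1e-10)
  expect_equal(estimate(mrMode(flipped, nBoot = 100, seed = 3)),
               estimate(mrMode(set, nBoot = 100, seed = 3)),
               tolerance = 1e-10)
  # leave-one-out identity: dropping one SNP reproduces the restricted set
  expect_equal(estimate(mrIVW(set[-5])),
               estimate(mrIVW(buildInstrument(set,
                                              excludeIds = snps(set)[5]))),
               tolerance = 1e-12)
})
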