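# Exposure quantification: classification, gram conversion, trimming and
# guideline arithmetic.

test_that("drinker classification maps the questionnaire grid onto four categories", {
  expect_identical(classifyDrinker("Never", FALSE), "never")
  expect_identical(classifyDrinker("Never", TRUE), "former")
  expect_identical(classifyDrinker("Special occasions only"), "infrequent")
  for (f in c("1-3 times a month", "1-2 times a week", "3-4 times a week",
              "Daily/almost daily"))
    expect_identical(classifyDrinker(f), "regular")
  # frequency Never with unknown history is an explicit missing signal
  expect_true(is.na(classifyDrinker("Never", NA)))
  expect_error(classifyDrinker("sometimes"), "unknown frequency")

  # totality/partition property on a generated questionnaire batch
  qn <- generateQuestionnaire(cohortConfig(n = 800, seed = 5))
  cat <- classifyDrinker(qn$frequency, qn$everDrank)
  expect_false(anyNA(cat))
  expect_true(all(cat %in% c("never", "infrequent", "regular", "former")))
})

test_that("weekly gram quantification matches a brute-force six-term summation", {
  set.seed(42)
  for (i in 1:25) {
    portions <- rpois(6, 3)
    period <- sample(c("weekly", "monthly"), 1)
    expect_equal(weeklyGrams(portions, period),
                 bruteGrams(portions, period), tolerance = 1e-12)
  }
  expect_identical(weeklyGrams(rep(0, 6), "weekly"), 0)
  # monthly reporting scales the weekly-equivalent sum by k = 12*7/365
  p <- c(2, 1, 4, 0, 1, 0)
  expect_equal(weeklyGrams(p, "monthly"),
               weeklyGrams(p, "weekly") * 12 * 7 / 365, tolerance = 1e-12)
  expect_equal(round(12 * 7 / 365, 2), 0.23)
  expect_error(weeklyGrams(c(-1, 0, 0, 0, 0, 0), "weekly"), "negative")
  expect_error(weeklyGrams(rep(1, 6), "weekly",
                           defaultBeverageTable()[-1, ]), "misses entries")
})

test_that("quantification is linear and monotone in every portion count", {
  base <- c(1, 2, 0, 3, 1, 2)
  g0 <- weeklyGrams(base, "weekly")
  for (i in 1:6) {
    e <- replace(rep(0, 6), i, 1)
    g1 <- weeklyGrams(base + e, "weekly")
    g2 <- weeklyGrams(base + 2 * e, "weekly")
    expect_gt(g1, g0)
    expect_equal(g2 - g1, g1 - g0, tolerance = 1e-12)  # linearity
  }
})

test_that("percentile trimming retains ties and excludes strict tails", {
  mask <- trimPercentiles(1:100, 1, 1)
  expect_identical(which(!mask), c(1L, 100L))
  expect_true(all(trimPercentiles(1:50, 0, 0)))
  expect_true(all(trimPercentiles(rep(7, 30), 1, 1)))
  expect_error(trimPercentiles(rep(NA_real_, 5)), "missing")

  # sort-based oracle on random draws: excluded values are exactly those
  # strictly outside the interpolated percentile thresholds
  set.seed(9)
  for (i in 1:10) {
    x <- rlnorm(237)
    mask <- trimPercentiles(x, 1, 1)
    lo <- quantile(x, 0.01); hi <- quantile(x, 0.99)
    expect_identical(mask, x >= lo & x <= hi)
  }
})

test_that("guideline thresholds and unit conversions are mutually consistent", {
  expect_equal(guidelineGrams("UK", "women"), 112)
  expect_equal(guidelineGrams("UK", "men"), 112)
  expect_equal(guidelineGrams("US", "women"), 98)
  expect_equal(guidelineGrams("US", "men"), 196)
  expect_equal(guidelineGrams("US", "men"), 2 * guidelineGrams("US", "women"))
  expect_error(guidelineGrams("EU", "women"))

  expect_equal(gramsToUnits(0, "UK"), 0)
  expect_equal(gramsToUnits(50, "UK"), 6.25)
  expect_equal(gramsToUnits(112, "UK"), 14)  # inverse of the UK guideline
  expect_equal(gramsToUnits(guidelineGrams("US", "men"), "US"), 14)
  expect_error(gramsToUnits(-1, "UK"), "negative")
  # round trip units -> grams -> units
  for (u in c(0.5, 3, 14))
    expect_equal(gramsToUnits(u * 8, "UK"), u, tolerance = 1e-12)
})

test_that("derived exposure is standardized on the trimmed regular drinkers", {
  d <- derivedCohort(3000, 21)$data
  reg <- d$category == "regular" & d$includedAfterTrim %in% TRUE
  expect_equal(mean(d$intakeStd[reg]), 0, tolerance = 1e-10)
  expect_equal(sd(d$intakeStd[reg]), 1, tolerance = 1e-10)
  # never/former drinkers carry no quantity
  expect_true(all(is.na(d$gramsWeek[d$category %in% c("never", "former")])))
  expect_true(all(is.na(d$intakeStd[d$category != "regular"])))
  # grams equal an independent per-row recomputation
  idx <- sample(which(d$category %in% c("regular", "infrequent")), 40)
  for (i in idx) {
    p <- as.numeric(d[i, paste0("portions_", beverageNames())])
    expect_equal(d$gramsWeek[i], bruteGrams(p, d$reportingPeriod[i]),
                 tolerance = 1e-10)
  }
})
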