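# Alcohol exposure: drinker classification, gram quantification, trimming and
# unit conversions.

#' Questionnaire frequency categories
#'
#' The six drinking-frequency response options of the baseline touchscreen
#' questionnaire, from most to least frequent.
#' @export
drinkingFrequencies <- function() {
  c("Daily/almost daily", "3-4 times a week", "1-2 times a week",
    "1-3 times a month", "Special occasions only", "Never")
}

#' Beverage categories
#' @export
beverageNames <- function() {
  c("red_wine", "white_wine", "beer_cider", "spirits", "fortified_wine",
    "other")
}

# Weekly-to-monthly conversion factor, full precision: 12 months / 365 days
# x 7 days. Printed elsewhere rounded to 0.23.
kMonthly <- function() 12 * 7 / 365

#' Default beverage portion sizes and alcohol concentrations
#'
#' Stand-in portion volumes and alcohol-by-volume values for the six beverage
#' categories (the food-composition values used for the original derivation
#' are not publicly deposited): 175 mL glasses of wine at 12\% ABV, 568 mL
#' (one pint) of beer/cider at 4\%, 25 mL spirit measures at 40\%, 50 mL
#' fortified wine at 17.5\% and 250 mL "other" drinks at 4\%. Alcohol
#' concentration in g/mL is ABV x 0.789 (the density of ethanol).
#'
#' @return data.frame with columns \code{beverage}, \code{portion_ml},
#'   \code{abv_percent} and the derived \code{concentration_g_ml}.
#' @export
#' @examples
#' defaultBeverageTable()
defaultBeverageTable <- function() {
  tab <- data.frame(
    beverage = beverageNames(),
    portion_ml = c(175, 175, 568, 25, 50, 250),
    abv_percent = c(12, 12, 4, 40, 17.5, 4),
    stringsAsFactors = FALSE)
  tab$concentration_g_ml <- tab$abv_percent / 100 * 0.789
  tab
}

#' Read a beverage table from a delimited file
#'
#' Expects the 3 columns \code{beverage}, \code{portion_ml},
#' \code{abv_percent}; the g/mL concentration is derived.
#'
#' @param path Path to a tab- or comma-delimited file.
#' @return data.frame in the layout of \code{\link{defaultBeverageTable}}.
#' @export
readBeverageTable <- function(path) {
  tab <- utils::read.delim(path, sep = "", stringsAsFactors = FALSE)
  need <- c("beverage", "portion_ml", "abv_percent")
  if (!all(need %in% names(tab)))
    abortGD("beverage table must contain columns: ",
            paste(need, collapse = ", "))
  validateBeverageTable(tab)
  tab$concentration_g_ml <- tab$abv_percent / 100 * 0.789
  tab
}

validateBeverageTable <- function(tab) {
  missing <- setdiff(beverageNames(), tab$beverage)
  if (length(missing))
    abortGD("beverage table misses entries for: ",
            paste(missing, collapse = ", "))
  if (any(tab$portion_ml <= 0)) abortGD("portion volumes must be > 0")
  conc <- tab$abv_percent / 100 * 0.789
  if (any(conc <= 0 | conc > 0.789))
    abortGD("alcohol concentrations must lie in (0, 0.789] g/mL")
  invisible(tab)
}

#' Classify drinking behaviour
#'
#' Maps questionnaire frequency and the ever-drank follow-up onto the four
#' drinker categories: never drinkers (frequency "Never", never drank),
#' infrequent drinkers ("Special occasions only"), regular drinkers
#' ("1-3 times a month" or more often) and former drinkers (frequency
#' "Never" but previously drank).
#'
#' @param frequency Character vector of frequency responses (see
#'   \code{\link{drinkingFrequencies}}).
#' @param everDrank Logical vector; only consulted where frequency is
#'   "Never". \code{NA} there yields an \code{NA} category.
#' @return Character vector with values \code{"never"}, \code{"infrequent"},
#'   \code{"regular"}, \code{"former"} (or \code{NA}).
#' @export
#' @examples
#' classifyDrinker("Never", FALSE)            # "never"
#' classifyDrinker("Daily/almost daily", NA)  # "regular"
#' classifyDrinker("Never", TRUE)             # "former"
classifyDrinker <- function(frequency, everDrank = NA) {
  freqs <- drinkingFrequencies()
  bad <- !is.na(frequency) & !(frequency %in% freqs)
  if (any(bad))
    abortGD("unknown frequency value(s): ",
            paste(unique(frequency[bad]), collapse = ", "))
  everDrank <- rep_len(everDrank, length(frequency))
  out <- rep(NA_character_, length(frequency))
  regular <- frequency %in% freqs[1:4]
  out[regular] <- "regular"
  out[frequency == "Special occasions only"] <- "infrequent"
  nev <- !is.na(frequency) & frequency == "Never"
  out[nev & !is.na(everDrank) & !everDrank] <- "never"
  out[nev & !is.na(everDrank) & everDrank] <- "former"
  # frequency "Never" with unknown drinking history stays NA (explicit
  # missing-category signal)
  out
}

#' Quantify weekly ethanol intake in grams
#'
#' Computes \code{sum_i portions_i x volume_i x concentration_i x k} over the
#' six beverage categories, with \code{k = 1} for weekly reporters and
#' \code{k = 12 * 7 / 365} (printed as 0.23) for monthly reporters.
#'
#' @param portions Numeric vector (one record) or matrix/data.frame (records
#'   x 6 beverages) of portion counts, columns ordered or named as
#'   \code{\link{beverageNames}}.
#' @param reportingPeriod \code{"weekly"} or \code{"monthly"}, recycled.
#' @param beverages Beverage table (see \code{\link{defaultBeverageTable}}).
#' @return Numeric vector of grams of ethanol per week.
#' @export
#' @examples
#' weeklyGrams(c(2, 0, 3, 1, 0, 0), "weekly")
weeklyGrams <- function(portions, reportingPeriod = "weekly",
                        beverages = defaultBeverageTable()) {
  validateBeverageTable(beverages)
  if (is.null(dim(portions))) portions <- matrix(portions, nrow = 1)
  portions <- as.matrix(portions)
  if (ncol(portions) != length(beverageNames()))
    abortGD("portions must have one column per beverage category")
  if (!is.null(colnames(portions)))
    portions <- portions[, beverageNames(), drop = FALSE]
  if (any(portions < 0, na.rm = TRUE)) abortGD("negative portion counts")
  if (!all(reportingPeriod %in% c("weekly", "monthly")))
    abortGD("reportingPeriod must be 'weekly' or 'monthly'")
  gramsPerPortion <- beverages$portion_ml[match(beverageNames(),
                                                beverages$beverage)] *
    beverages$concentration_g_ml[match(beverageNames(), beverages$beverage)]
  k <- ifelse(rep_len(reportingPeriod, nrow(portions)) == "weekly",
              1, kMonthly())
  as.numeric(portions %*% gramsPerPortion) * k
}

#' Percentile-based trimming mask
#'
#' Flags values for inclusion after removing the extreme tails: values
#' strictly below the \code{lowerPct}-th percentile or strictly above the
#' \code{(100 - upperPct)}-th percentile are excluded. Percentiles use linear
#' interpolation between closest ranks (\code{stats::quantile} type 7); ties
#' at the thresholds are retained, so trimming is conservative.
#'
#' @param values Numeric vector; \code{NA}s are passed through as \code{NA}.
#' @param lowerPct,upperPct Percentages in \code{[0, 50)}.
#' @return Logical inclusion mask of the same length.
#' @export
#' @examples
#' trimPercentiles(1:100, 1, 1)  # excludes exactly 1 and 100
trimPercentiles <- function(values, lowerPct = 1, upperPct = 1) {
  if (!length(values)) abortGD("empty input")
  if (all(is.na(values))) abortGD("all values missing")
  stopifnot(lowerPct >= 0, lowerPct < 50, upperPct >= 0, upperPct < 50)
  lo <- stats::quantile(values, lowerPct / 100, na.rm = TRUE, names = FALSE)
  hi <- stats::quantile(values, 1 - upperPct / 100, na.rm = TRUE,
                        names = FALSE)
  mask <- values >= lo & values <= hi
  mask
}

#' Weekly guideline thresholds in grams of ethanol
#'
#' UK guidance is 14 units/week for both sexes at 8 g of ethanol per unit
#' (112 g/week); US guidance is 7 standard drinks/week for women and 14 for
#' men at 14 g per drink (98 and 196 g/week).
#'
#' @param jurisdiction \code{"UK"} or \code{"US"}.
#' @param sex \code{"women"} or \code{"men"}.
#' @return Grams of ethanol per week.
#' @export
#' @examples
#' guidelineGrams("UK", "women")  # 112
#' guidelineGrams("US", "men")    # 196
guidelineGrams <- function(jurisdiction = c("UK", "US"),
                           sex = c("women", "men")) {
  jurisdiction <- match.arg(jurisdiction)
  sex <- match.arg(sex)
  if (jurisdiction == "UK") 14 * 8
  else if (sex == "women") 7 * 14
  else 14 * 14
}

#' Convert grams of ethanol per week into alcoholic units
#'
#' @param grams Non-negative grams/week.
#' @param system \code{"UK"} (8 g/unit) or \code{"US"} (14 g/standard drink).
#' @return Units (or standard drinks) per week.
#' @export
#' @examples
#' gramsToUnits(50, "UK")  # 6.25
gramsToUnits <- function(grams, system = c("UK", "US")) {
  system <- match.arg(system)
  if (any(grams < 0, na.rm = TRUE)) abortGD("negative gram input")
  grams / if (system == "UK") 8 else 14
}

#' Derive the analysis-ready exposure columns for a cohort
#'
#' Classifies every participant, quantifies grams/week for quantifiable
#' (infrequent and regular) drinkers, trims regular drinkers' quantities at
#' the configured percentiles and standardizes the retained regular-drinker
#' intake to mean 0, SD 1. Never and former drinkers carry missing grams;
#' standardized intake is defined only for regular drinkers (the quantitative
#' analysis population), using the trimmed-subset mean and SD.
#'
#' @param cohort data.frame with columns \code{frequency}, \code{everDrank},
#'   and the six portion-count columns \code{portions_<beverage>}.
#' @param beverages Beverage table.
#' @param trim Length-2 numeric: lower and upper trim percentages (default
#'   \code{c(1, 1)}).
#' @return The cohort with columns \code{category}, \code{gramsWeek},
#'   \code{includedAfterTrim}, \code{intakeStd} appended.
#' @export
deriveExposure <- function(cohort, beverages = defaultBeverageTable(),
                           trim = c(1, 1)) {
  portCols <- paste0("portions_", beverageNames())
  if (!all(portCols %in% names(cohort)))
    abortGD("cohort misses portion columns: ",
            paste(setdiff(portCols, names(cohort)), collapse = ", "))
  category <- classifyDrinker(cohort$frequency, cohort$everDrank)
  grams <- rep(NA_real_, nrow(cohort))
  quantifiable <- !is.na(category) & category %in% c("infrequent", "regular")
  if (any(quantifiable)) {
    pm <- as.matrix(cohort[quantifiable, portCols])
    colnames(pm) <- beverageNames()
    grams[quantifiable] <- weeklyGrams(
      pm, cohort$reportingPeriod[quantifiable], beverages)
  }
  included <- rep(NA, nrow(cohort))
  reg <- !is.na(category) & category == "regular" & !is.na(grams)
  if (any(reg))
    included[reg] <- trimPercentiles(grams[reg], trim[1], trim[2]) &
      grams[reg] > 0  # log-intake models need positive intake
  intakeStd <- rep(NA_real_, nrow(cohort))
  keep <- reg & !is.na(included) & included
  if (sum(keep) > 1) {
    m <- mean(grams[keep]); s <- stats::sd(grams[keep])
    intakeStd[keep] <- (grams[keep] - m) / s
  }
  cohort$category <- category
  cohort$gramsWeek <- grams
  cohort$includedAfterTrim <- included
  cohort$intakeStd <- intakeStd
  cohort
}
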