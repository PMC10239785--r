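# Polygenic score construction and gene-environment interaction analysis.

#' Compute a weighted-sum polygenic score
#'
#' The raw score of participant \code{i} is \code{sum_v w_v * d_iv}, the
#' standard weighted sum of risk-allele dosages over the weight panel.
#' Dosage columns are matched to weights by variant id; where the dosage
#' file counts the opposite allele the dosage is flipped to \code{2 - d}.
#' Missing dosages are mean-imputed per variant (configurable). The score
#' is standardized to mean 0, SD 1 within the scoring cohort, and quintile
#' labels are attached.
#'
#' @param dosages Numeric matrix (participants x variants) with values in
#'   \code{[0, 2]}, column names = variant ids.
#' @param weights data.frame with columns \code{snp_id},
#'   \code{effect_allele}, \code{weight}.
#' @param dosageAlleles Named character vector giving the allele counted by
#'   each dosage column; defaults to the weights' effect alleles (no
#'   flipping).
#' @param imputeMissing Mean-impute missing dosages per variant (default
#'   TRUE).
#' @return data.frame with columns \code{raw}, \code{standardized} and
#'   \code{quintile}.
#' @export
#' @examples
#' d <- matrix(c(2, 1, 0, 1), 2, dimnames = list(NULL, c("rs1", "rs2")))
#' w <- data.frame(snp_id = c("rs1", "rs2"), effect_allele = "A",
#'                 weight = c(0.1, -0.2))
#' computePRS(d, w)$raw  # 0.0, -0.1
computePRS <- function(dosages, weights, dosageAlleles = NULL,
                       imputeMissing = TRUE) {
  if (!all(c("snp_id", "weight") %in% names(weights)))
    abortGD("weights need columns snp_id and weight")
  if (anyDuplicated(weights$snp_id)) abortGD("duplicated weight ids")
  if (!all(is.finite(weights$weight))) abortGD("non-finite weights")
  miss <- setdiff(weights$snp_id, colnames(dosages))
  if (length(miss))
    abortGD("dosage matrix misses variants: ", paste(miss, collapse = ", "))
  D <- as.matrix(dosages[, weights$snp_id, drop = FALSE])
  if (any(D < 0 | D > 2, na.rm = TRUE))
    abortGD("dosages must lie in [0, 2]")
  if (!is.null(dosageAlleles)) {
    flip <- toupper(dosageAlleles[weights$snp_id]) !=
      toupper(weights$effect_allele)
    flip[is.na(flip)] <- FALSE
    if (any(flip)) D[, flip] <- 2 - D[, flip]
  }
  if (anyNA(D)) {
    if (!imputeMissing) abortGD("missing dosages and imputeMissing = FALSE")
    mu <- colMeans(D, na.rm = TRUE)
    for (j in which(colSums(is.na(D)) > 0))
      D[is.na(D[, j]), j] <- mu[j]
  }
  raw <- as.numeric(D %*% weights$weight)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    abortGD("degenerate polygenic score: zero variance")
  z <- (raw - mean(raw)) / s
  cuts <- stats::quantile(z, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  q <- findInterval(z, cuts, left.open = TRUE) + 1L
  data.frame(raw = raw, standardized = z,
             quintile = factor(paste0("Q", q), levels = paste0("Q", 1:5)))
}

#' Read a 3-column PRS weight file
#'
#' @param path Delimited file with columns \code{snp_id},
#'   \code{effect_allele}, \code{weight}.
#' @return data.frame of weights.
#' @export
readPRSWeights <- function(path) {
  w <- utils::read.delim(path, sep = "", stringsAsFactors = FALSE)
  if (!all(c("snp_id", "effect_allele", "weight") %in% names(w)))
    abortGD("weight file needs columns snp_id, effect_allele, weight")
  w
}

#' Gene-environment interaction analysis
#'
#' Fits the maximally adjusted model with a multiplicative interaction term
#' between standardized intake and the continuous standardized polygenic
#' score (restricted to regular drinkers in the quantitative analysis
#' population) and reports the product-term estimate and p-value. The
#' cohort is then split into polygenic-score quintiles, computed on the
#' analysis subset actually modeled, and the per-SD intake effect is
#' refitted within each quintile (descriptive stratified effects).
#'
#' @param data Analysis cohort carrying \code{intakeStd} and the outcome.
#' @param prs Numeric vector: the standardized polygenic score, aligned
#'   with \code{data} rows (defaults to \code{data$prs}).
#' @param outcome Outcome name (default \code{"iop"}).
#' @param covariates Covariate specification.
#' @param quintileEffects Also refit the per-SD effect within each PRS
#'   quintile (default TRUE; the product-term test alone is cheaper and
#'   robust to sparse strata).
#' @return List with \code{interaction} (\linkS4class{ModelResult} row for
#'   the product term), \code{interactionP}, and \code{byQuintile}
#'   (\linkS4class{ModelResult} of per-SD effects in PRS quintiles 1-5).
#' @export
interactionAnalysis <- function(data, prs = data$prs, outcome = "iop",
                                covariates = covariateSpec(),
                                quintileEffects = TRUE) {
  dat <- data
  dat$prsScore <- prs
  dat <- dat[!is.na(dat$category) & dat$category == "regular" &
               !is.na(dat$intakeStd) & !is.na(dat$prsScore), ]
  if (outcome == "glaucoma") {
    dat$glaucomaCase <- .glaucomaBinary(dat)
    dat <- dat[!is.na(dat$glaucomaCase), ]
    yname <- "glaucomaCase"
  } else yname <- outcome
  vars <- c(yname, "intakeStd", "prsScore", covariates$name)
  dat <- dat[stats::complete.cases(dat[, vars]), ]

  f <- stats::as.formula(paste(yname, "~ intakeStd * prsScore +",
                               paste(covariates$name, collapse = " + ")))
  fit <- if (yname == "glaucomaCase")
    stats::glm(f, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  else stats::lm(f, data = dat)
  sm <- summary(fit)$coefficients
  row <- grep("^intakeStd:prsScore$", rownames(sm))
  scale <- if (yname == "glaucomaCase") "odds-ratio" else "identity"
  est <- sm[row, 1]; se <- sm[row, 2]
  interaction <- if (scale == "odds-ratio")
    ModelResult("intakeStd:prsScore", exp(est), exp(est - 1.96 * se),
                exp(est + 1.96 * se), waldP(est, se), nrow(dat), scale,
                outcome = outcome)
  else
    ModelResult("intakeStd:prsScore", est, est - 1.96 * se,
                est + 1.96 * se, waldP(est, se), nrow(dat), scale,
                outcome = outcome)

  if (!quintileEffects)
    return(list(interaction = interaction,
                interactionP = interaction$p[1], byQuintile = NULL))

  # quintiles on the analysis subset actually modeled
  cuts <- stats::quantile(dat$prsScore, c(0.2, 0.4, 0.6, 0.8),
                          names = FALSE)
  ql <- findInterval(dat$prsScore, cuts, left.open = TRUE) + 1L
  byQ <- lapply(1:5, function(q)
    .fitOutcome(dat[ql == q, ], outcome, "intakeStd", covariates))
  bq <- as.data.frame(do.call(rbind, byQ))
  byQuintile <- ModelResult(term = paste0("intakeStd|PRS Q", 1:5),
                            estimate = bq$estimate, ciLow = bq$ciLow,
                            ciHigh = bq$ciHigh, p = bq$p, n = bq$n,
                            scale = bq$scale, outcome = bq$outcome)
  list(interaction = interaction, interactionP = interaction$p[1],
       byQuintile = byQuintile)
}
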