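# Phenotype derivation: intraocular pressure, macular OCT thicknesses and
# glaucoma case/control ascertainment.

#' Derive individual-level intraocular pressure
#'
#' The per-participant IOP is the mean of the available right and left
#' corneal-compensated values. For participants on ocular hypotensive
#' medication the pretreatment value is imputed by dividing the measured IOP
#' by 0.7. Participants with a history of glaucoma surgery or laser therapy,
#' corneal graft, refractive surgery or significant ocular trauma, or with
#' both eyes missing, get a missing value. Population-level trimming of the
#' extreme percentiles (default top and bottom 0.5) is the caller's job via
#' \code{\link{trimPercentiles}} (see \code{\link{deriveOutcomes}}).
#'
#' @param right,left Per-eye measured IOP in mmHg (may be \code{NA}).
#' @param treated Logical: on ocular hypotensives.
#' @param excluded Logical: any IOP exclusion flag set.
#' @return Numeric vector of derived IOP in mmHg.
#' @export
#' @examples
#' deriveIOP(15, 17, treated = FALSE)        # 16
#' deriveIOP(14, NA, treated = TRUE)         # 20
deriveIOP <- function(right, left, treated = FALSE, excluded = FALSE) {
  if (any(c(right, left) < 0, na.rm = TRUE)) abortGD("negative IOP input")
  n <- max(length(right), length(left))
  right <- rep_len(right, n); left <- rep_len(left, n)
  treated <- rep_len(treated, n); excluded <- rep_len(excluded, n)
  iop <- rowMeans(cbind(right, left), na.rm = TRUE)
  iop[is.nan(iop)] <- NA_real_
  iop[treated %in% TRUE] <- iop[treated %in% TRUE] / 0.7
  iop[excluded %in% TRUE] <- NA_real_
  iop
}

#' Derive individual-level OCT layer thicknesses
#'
#' Per-layer mean of all available right and left eye measurements; missing
#' when neither eye was measured.
#'
#' @param rightRNFL,leftRNFL Macular RNFL thickness per eye (um).
#' @param rightGCIPL,leftGCIPL Macular GCIPL thickness per eye (um).
#' @return data.frame with columns \code{mrnfl} and \code{mgcipl}.
#' @export
#' @examples
#' deriveOCT(28, 30, 74, 76)  # mrnfl 29, mgcipl 75
deriveOCT <- function(rightRNFL, leftRNFL, rightGCIPL, leftGCIPL) {
  if (any(c(rightRNFL, leftRNFL, rightGCIPL, leftGCIPL) < 0, na.rm = TRUE))
    abortGD("negative thickness input")
  mrnfl <- rowMeans(cbind(rightRNFL, leftRNFL), na.rm = TRUE)
  mgcipl <- rowMeans(cbind(rightGCIPL, leftGCIPL), na.rm = TRUE)
  mrnfl[is.nan(mrnfl)] <- NA_real_
  mgcipl[is.nan(mgcipl)] <- NA_real_
  data.frame(mrnfl = mrnfl, mgcipl = mgcipl)
}

# Normalized prefix matching of diagnosis codes. ICD-10 glaucoma: H40.*
# except the H40.0 (suspect) block, plus any H42.*; ICD-9: 365.* except
# 365.0. Codes outside both families never change status.
normalizeCode <- function(code) toupper(trimws(code))

isQualifyingCode <- function(code) {
  code <- normalizeCode(code)
  icd10 <- (startsWith(code, "H40") & !startsWith(code, "H40.0")) |
    startsWith(code, "H42")
  icd9 <- startsWith(code, "365") & !startsWith(code, "365.0")
  icd10 | icd9
}

isSuspectCode <- function(code) {
  code <- normalizeCode(code)
  startsWith(code, "H40.0") | startsWith(code, "365.0")
}

#' Ascertain glaucoma case/control status for one participant
#'
#' A participant is a case on self-reported glaucoma (or glaucoma
#' surgery/laser) or on carrying a qualifying diagnosis code (ICD-10 H40.*
#' excluding H40.0, any H42.*; ICD-9 365.* excluding 365.0) at any point
#' before and up to one year (365 days, inclusive) after baseline. Cases
#' diagnosed before 30 years of age are excluded. Non-cases are excluded as
#' controls when on ocular hypotensive medication or carrying a glaucoma
#' suspect code (H40.0 / 365.0); everyone else is a control.
#'
#' @param selfReport Logical: self-reported glaucoma or glaucoma surgery.
#' @param records data.frame of diagnosis records with columns \code{code},
#'   \code{days_from_baseline} and optionally \code{age_at_diagnosis}
#'   (NULL or zero rows for none).
#' @param onHypotensives Logical: using ocular hypotensive medication.
#' @param windowDays Ascertainment window after baseline (default 365).
#' @return \code{"case"}, \code{"control"} or \code{"excluded"}.
#' @export
#' @examples
#' rec <- data.frame(code = "H40.1", days_from_baseline = -100)
#' ascertainGlaucoma(FALSE, rec, FALSE)  # "case"
ascertainGlaucoma <- function(selfReport, records = NULL,
                              onHypotensives = FALSE, windowDays = 365) {
  qual <- suspect <- FALSE
  ageMin <- NA_real_
  if (!is.null(records) && nrow(records)) {
    code <- as.character(records$code)
    if (any(is.na(code) | !nzchar(trimws(code))))
      abortGD("malformed diagnosis code: ",
              paste(utils::head(code[is.na(code) | !nzchar(trimws(code))]),
                    collapse = ", "))
    inWindow <- records$days_from_baseline <= windowDays
    q <- isQualifyingCode(code) & inWindow
    qual <- any(q)
    suspect <- any(isSuspectCode(code))
    if (qual && "age_at_diagnosis" %in% names(records)) {
      ages <- records$age_at_diagnosis[q]
      if (any(!is.na(ages))) ageMin <- min(ages, na.rm = TRUE)
    }
  }
  if (isTRUE(selfReport) || qual) {
    if (!is.na(ageMin) && ageMin < 30) "excluded" else "case"
  } else if (isTRUE(onHypotensives) || suspect) {
    "excluded"
  } else "control"
}

#' Derive all analysis-ready phenotypes for a cohort
#'
#' Applies \code{\link{deriveIOP}} (with the treatment imputation, exclusion
#' flags and population-level 0.5/0.5 percentile trimming),
#' \code{\link{deriveOCT}} and \code{\link{ascertainGlaucoma}} across a
#' participant table plus its long-format diagnosis table.
#'
#' @param cohort Participant data.frame carrying \code{participant_id},
#'   per-eye measurement columns (\code{iopRight}, \code{iopLeft},
#'   \code{mrnflRight}, \code{mrnflLeft}, \code{mgciplRight},
#'   \code{mgciplLeft}), treatment flag \code{onHypotensives}, the IOP
#'   exclusion flags (\code{glaucomaSurgery}, \code{cornealGraft},
#'   \code{refractiveSurgery}, \code{ocularTrauma}) and
#'   \code{selfReportGlaucoma}.
#' @param diagnoses Long-format data.frame (\code{participant_id},
#'   \code{code}, \code{days_from_baseline}, \code{age_at_diagnosis}); may be
#'   \code{NULL} or empty.
#' @param iopTrim Length-2 percentile trim for derived IOP (default 0.5/0.5).
#' @param windowDays Ascertainment window (default 365).
#' @return The cohort with \code{iop}, \code{mrnfl}, \code{mgcipl} and
#'   \code{glaucomaStatus} appended.
#' @export
deriveOutcomes <- function(cohort, diagnoses = NULL, iopTrim = c(0.5, 0.5),
                           windowDays = 365) {
  excl <- with(cohort, glaucomaSurgery | cornealGraft | refractiveSurgery |
                 ocularTrauma)
  iop <- deriveIOP(cohort$iopRight, cohort$iopLeft, cohort$onHypotensives,
                   excl)
  if (any(!is.na(iop))) {
    keep <- trimPercentiles(iop, iopTrim[1], iopTrim[2])
    iop[!is.na(keep) & !keep] <- NA_real_
  }
  oct <- deriveOCT(cohort$mrnflRight, cohort$mrnflLeft,
                   cohort$mgciplRight, cohort$mgciplLeft)
# participants without any diagnosis record reduce to the self-report /
  # medication rules; only record carriers need the full per-record pass
  status <- ifelse(cohort$selfReportGlaucoma %in% TRUE, "case",
                   ifelse(cohort$onHypotensives %in% TRUE, "excluded",
                          "control"))
  if (!is.null(diagnoses) && nrow(diagnoses)) {
    split_dx <- split(diagnoses, factor(diagnoses$participant_id))
    idx <- match(names(split_dx), as.character(cohort$participant_id))
    for (j in seq_along(split_dx)) {
      i <- idx[j]
      if (is.na(i)) next
      status[i] <- ascertainGlaucoma(cohort$selfReportGlaucoma[i],
                                     split_dx[[j]],
                                     cohort$onHypotensives[i], windowDays)
    }
  }
  cohort$iop <- iop
  cohort$mrnfl <- oct$mrnfl
  cohort$mgcipl <- oct$mgcipl
  cohort$glaucomaStatus <- status
  cohort
}
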