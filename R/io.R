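# Delimited readers/writers for the package's table dialects. All outputs
# are tab-delimited with a documented header; header comment lines carry
# provenance (config hash) when written by the pipeline.

#' Write a participant table
#'
#' Tab-delimited, one row per participant, \code{NA} as empty field.
#'
#' @param participants data.frame (e.g. \code{generateCohort()$participants}).
#' @param path Output path.
#' @param comments Optional character vector written as leading
#'   \code{#}-comment lines.
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(participants, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(participants, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a participant table written by \code{\link{writeCohort}}
#' @param path Input path.
#' @return data.frame.
#' @export
readCohort <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

#' Write GWAS summary statistics
#'
#' Columns \code{snp_id}, \code{effect_allele}, \code{other_allele},
#' \code{beta}, \code{se}, \code{pval}, \code{n}, tab-delimited.
#'
#' @param stats Summary-statistic data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSummaryStats <- function(stats, path) {
  need <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  if (!all(need %in% names(stats)))
    abortGD("summary statistics need columns: ", paste(need, collapse = ", "))
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics in the package dialect
#'
#' Accepts externally supplied summary files with the columns
#' \code{snp_id}, \code{effect_allele}, \code{other_allele}, \code{beta},
#' \code{se} and optionally \code{pval}, \code{n} (tab- or
#' whitespace-delimited).
#'
#' @param path Input path.
#' @return data.frame validated for the required columns.
#' @export
readSummaryStats <- function(path) {
  .checkSumstats(utils::read.delim(path, stringsAsFactors = FALSE),
                 basename(path))
}

#' Write a long-format diagnosis table
#' @param diagnoses data.frame (\code{participant_id}, \code{code},
#'   \code{days_from_baseline}, \code{age_at_diagnosis}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDiagnoses <- function(diagnoses, path) {
  utils::write.table(diagnoses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format diagnosis table
#' @param path Input path.
#' @return data.frame.
#' @export
readDiagnoses <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}
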