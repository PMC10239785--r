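# Accessor generics and methods for the package's S4 value classes.

#' @rdname MREstimate-class
#' @param object An object.
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))
#' @rdname MREstimate-class
#' @export
setGeneric("ciLower", function(object) standardGeneric("ciLower"))
#' @rdname MREstimate-class
#' @export
setGeneric("ciUpper", function(object) standardGeneric("ciUpper"))
#' @rdname MREstimate-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname MREstimate-class
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))
#' @rdname MRSummarySet-class
#' @param object An object.
#' @export
setGeneric("nSNPs", function(object) standardGeneric("nSNPs"))

setMethod("estimate", "MREstimate", function(object) object@estimate)
setMethod("ciLower", "MREstimate", function(object) object@ciLow)
setMethod("ciUpper", "MREstimate", function(object) object@ciHigh)
setMethod("pValue", "MREstimate", function(object) object@p)
setMethod("diagnostics", "MREstimate", function(object) object@diagnostics)
setMethod("nSNPs", "MREstimate", function(object) object@nSNPs)
setMethod("nSNPs", "MRSummarySet", function(object) length(object@snps))

#' @rdname MRSummarySet-class
#' @export
setGeneric("betaX", function(object) standardGeneric("betaX"))
#' @rdname MRSummarySet-class
#' @export
setGeneric("betaY", function(object) standardGeneric("betaY"))
#' @rdname MRSummarySet-class
#' @export
setGeneric("seX", function(object) standardGeneric("seX"))
#' @rdname MRSummarySet-class
#' @export
setGeneric("seY", function(object) standardGeneric("seY"))
#' @rdname MRSummarySet-class
#' @export
setGeneric("snps", function(object) standardGeneric("snps"))

setMethod("betaX", "MRSummarySet", function(object) object@betaX)
setMethod("betaY", "MRSummarySet", function(object) object@betaY)
setMethod("seX", "MRSummarySet", function(object) object@seX)
setMethod("seY", "MRSummarySet", function(object) object@seY)
setMethod("snps", "MRSummarySet", function(object) object@snps)

#' Subset an MRSummarySet by SNP
#'
#' @param x An \linkS4class{MRSummarySet}.
#' @param i Logical, integer or character (SNP id) index.
#' @param j,drop,... Ignored.
#' @return An \linkS4class{MRSummarySet}.
#' @export
setMethod("[", "MRSummarySet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@snps)
  sub <- function(v) if (length(v)) v[i] else v
  new("MRSummarySet", snps = x@snps[i],
      effectAllele = x@effectAllele[i], otherAllele = x@otherAllele[i],
      betaX = x@betaX[i], seX = x@seX[i],
      betaY = x@betaY[i], seY = x@seY[i],
      pvalX = sub(x@pvalX), betaX2 = sub(x@betaX2), seX2 = sub(x@seX2),
      flags = x@flags[i, , drop = FALSE])
})

#' Coerce an MRSummarySet to a data.frame
#'
#' @param x An \linkS4class{MRSummarySet}.
#' @param ... Ignored.
#' @export
setMethod("as.data.frame", "MRSummarySet", function(x, ...) {
  df <- data.frame(snp_id = x@snps, effect_allele = x@effectAllele,
                   other_allele = x@otherAllele, beta_x = x@betaX,
                   se_x = x@seX, beta_y = x@betaY, se_y = x@seY,
                   stringsAsFactors = FALSE)
  if (length(x@pvalX)) df$pval_x <- x@pvalX
  if (length(x@betaX2)) { df$beta_x2 <- x@betaX2; df$se_x2 <- x@seX2 }
  cbind(df, as.data.frame(x@flags))
})

setMethod("show", "MRSummarySet", function(object) {
  cat("MRSummarySet with", nSNPs(object), "harmonized SNPs",
      if (length(object@betaX2)) "(two exposures)" else "", "\n")
  df <- as.data.frame(object)
  print(utils::head(df, 5))
  if (nrow(df) > 5) cat("...", nrow(df) - 5, "more SNPs\n")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s estimate over %d SNPs\n", object@method, object@nSNPs))
  cat(sprintf("  estimate %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
              object@estimate, object@ciLow, object@ciHigh, object@p))
  d <- object@diagnostics
  if (!is.null(d[["Q"]]) && !is.null(d[["I2"]]))
    cat(sprintf("  Cochran's Q = %.2f (p = %.3g), I2 = %.1f%%\n",
                d[["Q"]], d[["Q_p"]], 100 * d[["I2"]]))
  if (!is.null(d[["egger_intercept"]]))
    cat(sprintf("  Egger intercept = %.4g (p = %.3g), I2GX = %.2f\n",
                d[["egger_intercept"]], d[["intercept_p"]], d[["I2GX"]]))
  if (!is.null(d[["global_p"]]))
    cat(sprintf("  MR-PRESSO global p = %.3g; outliers: %s\n",
                d[["global_p"]],
                if (length(d[["outlier_ids"]]))
                  paste(d[["outlier_ids"]], collapse = ", ") else "none"))
  invisible(object)
})

setMethod("show", "SplineFit", function(object) {
  cat(sprintf("Restricted cubic spline fit: %d knots selected by AIC (%.2f)\n",
              object@nKnots, object@aic))
  cat("  knots (log g/week):", paste(sprintf("%.3f", object@knots),
                                     collapse = ", "), "\n")
  cat("  candidates:\n")
  print(object@aicTable, row.names = FALSE)
  invisible(object)
})
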