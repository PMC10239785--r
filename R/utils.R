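# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs \code{expr} with \code{set.seed(seed)} in effect and restores the
#' caller's \code{.Random.seed} afterwards, so seeded generators never disturb
#' the global random stream.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Scalar finite check used by config validators.
isScalarFinite <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

isScalarCount <- function(x) isScalarFinite(x) && x >= 1 && x == floor(x)

# Stop with a consistent prefix.
abortGD <- function(...) stop(..., call. = FALSE)

# Weighted sample quantile of ratio-type statistics: linear interpolation on
# the cumulative standardized weight s_j = (sum_{i<=j} w_i - w_j/2) / sum(w).
weightedQuantile <- function(x, w, probs = 0.5) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(s, x, xout = probs, rule = 2, ties = "ordered")$y
}

# Wald-style two-sided p-value from an estimate and SE.
waldP <- function(est, se) 2 * stats::pnorm(-abs(est / se))

# 95% Wald interval.
waldCI <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(est - z * se, est + z * se)
}
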