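# Multiple-comparison thresholds and per-PheCode significance classes.

#' Bonferroni familywise threshold
#'
#' @param alpha significance level
#' @param m number of tests (>= 1)
#' @return `alpha / m`
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (m < 1) phewasStop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) phewasStop("alpha must lie in (0, 1)")
  alpha / m
}

#' Benjamini-Hochberg step-up threshold
#'
#' Sorts the p-values ascending and finds the largest rank `k` with
#' `p(k) <= (k/m) * alpha`; the threshold is that `p(k)`, or 0 when no rank
#' qualifies. Exactly the p-values at or below the returned threshold are
#' BH discoveries (equivalently, those with `p.adjust(p, "BH") <= alpha`).
#'
#' @param pValues numeric vector of p-values in [0, 1]
#' @param alpha significance level
#' @return the step-up threshold (0 when nothing passes)
#' @examples
#' fdrThreshold(c(0.001, 0.02, 0.03, 0.9), 0.05)  # 0.03
#' @export
fdrThreshold <- function(pValues, alpha = 0.05) {
  if (length(pValues) == 0L) phewasStop("empty p-value set")
  if (any(is.na(pValues) | pValues < 0 | pValues > 1)) {
    phewasStop("p-values must lie in [0, 1]")
  }
  m <- length(pValues)
  ps <- sort(pValues)
  ok <- which(ps <= seq_len(m) / m * alpha)
  if (length(ok) == 0L) 0 else ps[max(ok)]
}

#' Classify fitted PheCodes against the correction thresholds
#'
#' Each converged PheCode gets the class `"bonferroni"` when
#' `p <= alpha/m`, else `"fdr"` when `p <= ` the BH step-up threshold, else
#' `"insignificant"`. The boundary counts as passing (`<=`, not `<`) — an
#' explicit convention. Non-converged PheCodes are always classed
#' insignificant. By default `m` is the number of fitted PheCodes (the
#' post-filter count), not the full mapping-table size; `mPolicy = "table"`
#' with `mTable` uses the table size for the Bonferroni denominator
#' instead, and both values are logged.
#'
#' @param results a [PhewasResults]
#' @param alpha significance level (defaults to the model's)
#' @param mPolicy `"fitted"` or `"table"`
#' @param mTable total PheCode count of the mapping table (required when
#'   `mPolicy = "table"`)
#' @return a [PhewasThresholds]
#' @export
classifySignificance <- function(results, alpha = NULL,
                                 mPolicy = c("fitted", "table"),
                                 mTable = NULL) {
  stopifnot(is(results, "PhewasResults"))
  mPolicy <- match.arg(mPolicy)
  alpha <- alpha %||% results@model@alpha
  r <- resultsTable(results)
  mFitted <- nrow(r)
  m <- if (mPolicy == "table") {
    if (is.null(mTable)) phewasStop("mTable required when mPolicy = 'table'")
    mTable
  } else {
    mFitted
  }
  phewasLog(sprintf("significance over m = %d tests (fitted: %d, policy: %s)",
                    m, mFitted, mPolicy))
  bon <- bonferroniThreshold(alpha, m)
  conv <- r$converged & !is.na(r$p_value)
  fdr <- if (any(conv)) {
    # BH over the fitted, converged p-values; with mPolicy = "table" the
    # step-up denominator also uses the table size.
    p <- r$p_value[conv]
    ps <- sort(p)
    ok <- which(ps <= seq_along(ps) / m * alpha)
    if (length(ok)) ps[max(ok)] else 0
  } else 0
  cls <- rep("insignificant", nrow(r))
  cls[conv & r$p_value <= bon] <- "bonferroni"
  cls[conv & r$p_value <= fdr & cls == "insignificant"] <- "fdr"
  new("PhewasThresholds", alpha = alpha, m = as.numeric(m),
      bonferroni = bon, fdr = fdr,
      classes = stats::setNames(cls, r$phecode))
}
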