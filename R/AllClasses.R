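#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' PhewasExperiment: patients-by-PheCode feature matrices
#'
#' A container for the three per-patient PheCode aggregation schemes derived
#' from a longitudinal EHR, built on [SummarizedExperiment::SummarizedExperiment].
#' Rows are PheCodes (with `phecode`, `description` and `category` in
#' `rowData`), columns are patients, and the three assays hold one feature
#' matrix each:
#'
#' * `binary` — 1 if the PheCode appears at least once in the patient's
#'   record, else 0;
#' * `count` — total number of records of the PheCode for the patient;
#' * `duration` — years between the first and last occurrence of the
#'   PheCode for the patient (0 when absent or occurring exactly once).
#'
#' Group demographics (the candidate target variables and covariates) live in
#' `colData`, so a single object carries everything a PheWAS model needs.
#'
#' The validity method enforces the cross-scheme invariants: binary values
#' are exactly 0/1, counts are non-negative integers, durations are
#' non-negative, `count >= 1` exactly where `binary == 1`, and a positive
#' duration implies at least two records.
#'
#' @seealso [buildPhewasExperiment()], [runPhewas()],
#'   [cacheFeatureMatrices()]
#' @export
setClass("PhewasExperiment", contains = "SummarizedExperiment")

setValidity("PhewasExperiment", function(object) {
  msgs <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  need <- c("binary", "count", "duration")
  if (!all(need %in% an)) {
    return(sprintf("assays must include %s", paste(need, collapse = ", ")))
  }
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("phecode", "description", "category")) {
    if (!col %in% colnames(rd)) msgs <- c(msgs, sprintf("rowData lacks '%s'", col))
  }
  b <- SummarizedExperiment::assay(object, "binary")
  k <- SummarizedExperiment::assay(object, "count")
  d <- SummarizedExperiment::assay(object, "duration")
  if (!all(b %in% c(0, 1))) msgs <- c(msgs, "binary assay must contain only 0/1")
  if (any(k < 0) || any(k != round(k))) {
    msgs <- c(msgs, "count assay must contain non-negative integers")
  }
  if (any(d < 0)) msgs <- c(msgs, "duration assay must be non-negative")
  if (!all((k >= 1) == (b == 1))) {
    msgs <- c(msgs, "count >= 1 must hold exactly where binary == 1")
  }
  if (any(d > 0 & k < 2)) {
    msgs <- c(msgs, "positive duration requires count >= 2")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PhewasModelSpec: a PheWAS model definition
#'
#' Captures what `runPhewas()` fits for every PheCode: the binary target
#' variable, optional covariates, which aggregation scheme supplies the
#' PheCode values, whether the target is the dependent variable or an
#' independent predictor, the significance level, and the minimum-subject
#' filter. Build instances with [phewasModel()].
#'
#' @slot target name of the binary target variable in the group data
#' @slot covariates covariate names (may be empty)
#' @slot aggregation one of "binary", "count", "duration"
#' @slot targetRole "dependent" (target is the outcome; logistic) or
#'   "predictor" (the PheCode value is the outcome; logistic for binary
#'   aggregation, linear otherwise)
#' @slot alpha significance level in (0, 1)
#' @slot minSubjects PheCodes carried by fewer patients are skipped
#'   (0 disables the filter)
#' @export
setClass("PhewasModelSpec",
  representation(target = "character", covariates = "character",
                 aggregation = "character", targetRole = "character",
                 alpha = "numeric", minSubjects = "numeric"))

setValidity("PhewasModelSpec", function(object) {
  msgs <- character(0)
  if (length(object@target) != 1L || !nzchar(object@target)) {
    msgs <- c(msgs, "target must be a single non-empty name")
  }
  if (object@target %in% object@covariates) {
    msgs <- c(msgs, "covariates must exclude the target")
  }
  if (!object@aggregation %in% c("binary", "count", "duration")) {
    msgs <- c(msgs, "aggregation must be binary, count or duration")
  }
  if (!object@targetRole %in% c("dependent", "predictor")) {
    msgs <- c(msgs, "targetRole must be dependent or predictor")
  }
  if (object@alpha <= 0 || object@alpha >= 1) {
    msgs <- c(msgs, "alpha must lie in (0, 1)")
  }
  if (object@minSubjects < 0) msgs <- c(msgs, "minSubjects must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PhewasResults: per-PheCode mass univariate regression results
#'
#' One row per fitted PheCode with the coefficient of interest (log-odds for
#' logistic fits), its standard error, 95% Wald interval, two-sided Wald
#' p-value, the number of subjects carrying the PheCode, and a convergence
#' flag. PheCodes excluded before fitting (e.g. by the minimum-subject
#' filter) are listed in the skip log, never silently dropped.
#'
#' @slot results a [S4Vectors::DataFrame] with columns `phecode`,
#'   `description`, `category`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `n_subjects`, `converged`, `model_family`
#' @slot model the [PhewasModelSpec] that produced the results
#' @slot skipLog a [S4Vectors::DataFrame] with columns `phecode`, `reason`
#' @seealso [runPhewas()], [classifySignificance()], [writeResultTable()]
#' @export
setClass("PhewasResults",
  representation(results = "DataFrame", model = "PhewasModelSpec",
                 skipLog = "DataFrame"))

setValidity("PhewasResults", function(object) {
  msgs <- character(0)
  need <- c("phecode", "description", "category", "beta", "se", "ci_low",
            "ci_high", "p_value", "n_subjects", "converged", "model_family")
  miss <- setdiff(need, colnames(object@results))
  if (length(miss)) msgs <- c(msgs, sprintf("results lack columns: %s",
                                            paste(miss, collapse = ", ")))
  if (!all(c("phecode", "reason") %in% colnames(object@skipLog))) {
    msgs <- c(msgs, "skipLog must have columns phecode, reason")
  }
  if (length(msgs) == 0) {
    r <- object@results
    if (anyDuplicated(r$phecode)) msgs <- c(msgs, "duplicate phecodes in results")
    if (length(intersect(r$phecode, object@skipLog$phecode))) {
      msgs <- c(msgs, "skip log must be disjoint from results")
    }
    conv <- which(r$converged)
    if (length(conv)) {
      ok <- r$ci_low[conv] <= r$beta[conv] + 1e-12 &
        r$beta[conv] <= r$ci_high[conv] + 1e-12
      if (!all(ok)) msgs <- c(msgs, "ci_low <= beta <= ci_high violated")
      p <- r$p_value[conv]
      if (any(!is.na(p) & (p < 0 | p > 1))) msgs <- c(msgs, "p_value outside [0,1]")
    }
    if (any(r$n_subjects < 0)) msgs <- c(msgs, "n_subjects must be >= 0")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PhewasThresholds: multiple-comparison thresholds and classes
#'
#' Holds the Bonferroni threshold `alpha/m`, the Benjamini-Hochberg step-up
#' threshold (0 when nothing passes), and the per-PheCode significance class
#' (`"bonferroni"`, `"fdr"` or `"insignificant"`). Classes partition the
#' fitted PheCodes; boundary p-values count as passing (`<=`).
#'
#' @slot alpha the significance level used
#' @slot m number of tests entering the correction
#' @slot bonferroni alpha/m
#' @slot fdr the BH step-up cut, 0 when no p-value qualifies
#' @slot classes named character vector, names are phecodes
#' @seealso [classifySignificance()], [fdrThreshold()]
#' @export
setClass("PhewasThresholds",
  representation(alpha = "numeric", m = "numeric", bonferroni = "numeric",
                 fdr = "numeric", classes = "character"))

setValidity("PhewasThresholds", function(object) {
  msgs <- character(0)
  if (!all(object@classes %in% c("bonferroni", "fdr", "insignificant"))) {
    msgs <- c(msgs, "classes must be bonferroni, fdr or insignificant")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
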