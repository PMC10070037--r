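# Accessors and show() methods for the S4 classes.

#' Accessors for PhewasExperiment
#'
#' `binaryAssay()`, `countAssay()` and `durationAssay()` return the three
#' feature matrices (PheCodes in rows, patients in columns); `phecodes()` and
#' `patients()` return the axis identities. Group demographics are available
#' through `SummarizedExperiment::colData()`.
#'
#' @param x a [PhewasExperiment]
#' @return a matrix or character vector
#' @name PhewasExperiment-accessors
NULL

#' @rdname PhewasExperiment-accessors
#' @export
setMethod("binaryAssay", "PhewasExperiment", function(x)
  SummarizedExperiment::assay(x, "binary"))

#' @rdname PhewasExperiment-accessors
#' @export
setMethod("countAssay", "PhewasExperiment", function(x)
  SummarizedExperiment::assay(x, "count"))

#' @rdname PhewasExperiment-accessors
#' @export
setMethod("durationAssay", "PhewasExperiment", function(x)
  SummarizedExperiment::assay(x, "duration"))

#' @rdname PhewasExperiment-accessors
#' @export
setMethod("phecodes", "PhewasExperiment", function(x)
  as.character(SummarizedExperiment::rowData(x)$phecode))

#' @rdname PhewasExperiment-accessors
#' @export
setMethod("patients", "PhewasExperiment", function(x) colnames(x))

#' Accessors for PhewasResults
#'
#' `resultsTable()` returns the per-PheCode result table as a `data.frame`,
#' `nTests()` the number of fitted PheCodes (the `m` that enters the
#' multiple-comparison correction), `skipLog()` the table of PheCodes that
#' were not fitted with the reason, and `modelSpec()` the model definition.
#'
#' @param x a [PhewasResults]
#' @name PhewasResults-accessors
NULL

#' @rdname PhewasResults-accessors
#' @export
setMethod("resultsTable", "PhewasResults", function(x)
  as.data.frame(x@results))

#' @rdname PhewasResults-accessors
#' @export
setMethod("nTests", "PhewasResults", function(x) nrow(x@results))

#' @rdname PhewasResults-accessors
#' @export
setMethod("skipLog", "PhewasResults", function(x) as.data.frame(x@skipLog))

#' @rdname PhewasResults-accessors
#' @export
setMethod("modelSpec", "PhewasResults", function(x) x@model)

#' Accessors for PhewasThresholds
#'
#' `significanceClasses()` returns the named per-PheCode class vector,
#' `bonferroniCut()` and `fdrCut()` the two thresholds.
#'
#' @param x a [PhewasThresholds]
#' @name PhewasThresholds-accessors
NULL

#' @rdname PhewasThresholds-accessors
#' @export
setMethod("significanceClasses", "PhewasThresholds", function(x) x@classes)

#' @rdname PhewasThresholds-accessors
#' @export
setMethod("bonferroniCut", "PhewasThresholds", function(x) x@bonferroni)

#' @rdname PhewasThresholds-accessors
#' @export
setMethod("fdrCut", "PhewasThresholds", function(x) x@fdr)

setMethod("show", "PhewasExperiment", function(object) {
  cat(sprintf("PhewasExperiment: %d PheCodes x %d patients\n",
              nrow(object), ncol(object)))
  cat("assays: ", paste(SummarizedExperiment::assayNames(object),
                        collapse = ", "), "\n", sep = "")
  cats <- unique(SummarizedExperiment::rowData(object)$category)
  cat(sprintf("PheCode categories: %d\n", length(cats)))
  gv <- colnames(SummarizedExperiment::colData(object))
  if (length(gv)) {
    cat("group variables: ", paste(utils::head(gv, 8), collapse = ", "),
        if (length(gv) > 8) ", ..." else "", "\n", sep = "")
  }
  invisible(NULL)
})

setMethod("show", "PhewasModelSpec", function(object) {
  cat(sprintf("PheWAS model: target '%s' as %s, %s aggregation, alpha %g\n",
              object@target, object@targetRole, object@aggregation,
              object@alpha))
  if (length(object@covariates)) {
    cat("covariates: ", paste(object@covariates, collapse = ", "), "\n",
        sep = "")
  } else {
    cat("covariates: none\n")
  }
  invisible(NULL)
})

setMethod("show", "PhewasResults", function(object) {
  cat(sprintf("PhewasResults: %d PheCodes fitted (%d skipped)\n",
              nrow(object@results), nrow(object@skipLog)))
  show(object@model)
  r <- as.data.frame(object@results)
  if (nrow(r)) {
    top <- r[order(r$p_value), c("phecode", "beta", "p_value", "n_subjects")]
    cat("smallest p-values:\n")
    print(utils::head(top, 5), row.names = FALSE)
  }
  invisible(NULL)
})

setMethod("show", "PhewasThresholds", function(object) {
  tab <- table(factor(object@classes,
                      levels = c("bonferroni", "fdr", "insignificant")))
  cat(sprintf(
    "PhewasThresholds: alpha %g over m = %d tests\n  bonferroni <= %.3g | fdr <= %.3g\n",
    object@alpha, object@m, object@bonferroni, object@fdr))
  cat(sprintf("  classes: %d bonferroni, %d fdr, %d insignificant\n",
              tab[["bonferroni"]], tab[["fdr"]], tab[["insignificant"]]))
  invisible(NULL)
})
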