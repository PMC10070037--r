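#' @rdname PhewasExperiment-accessors
#' @export
setGeneric("binaryAssay", function(x) standardGeneric("binaryAssay"))

#' @rdname PhewasExperiment-accessors
#' @export
setGeneric("countAssay", function(x) standardGeneric("countAssay"))

#' @rdname PhewasExperiment-accessors
#' @export
setGeneric("durationAssay", function(x) standardGeneric("durationAssay"))

#' @rdname PhewasExperiment-accessors
#' @export
setGeneric("phecodes", function(x) standardGeneric("phecodes"))

#' @rdname PhewasExperiment-accessors
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))

#' @rdname PhewasResults-accessors
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname PhewasResults-accessors
#' @export
setGeneric("nTests", function(x) standardGeneric("nTests"))

#' @rdname PhewasResults-accessors
#' @export
setGeneric("skipLog", function(x) standardGeneric("skipLog"))

#' @rdname PhewasResults-accessors
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))

#' @rdname PhewasThresholds-accessors
#' @export
setGeneric("significanceClasses", function(x) standardGeneric("significanceClasses"))

#' @rdname PhewasThresholds-accessors
#' @export
setGeneric("bonferroniCut", function(x) standardGeneric("bonferroniCut"))

#' @rdname PhewasThresholds-accessors
#' @export
setGeneric("fdrCut", function(x) standardGeneric("fdrCut"))

#' Run the per-PheCode mass univariate regression
#'
#' @param x a [PhewasExperiment] (or a plain feature matrix; see the method
#'   documentation)
#' @param model a [PhewasModelSpec] from [phewasModel()]
#' @param ... passed to methods
#' @return a [PhewasResults]
#' @export
setGeneric("runPhewas", function(x, model, ...) standardGeneric("runPhewas"))
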