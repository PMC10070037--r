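# The three linked result views as serializable payloads: volcano plot,
# threshold-filtered effect-size plot, and the sorted data table.

NEGLOG10P_CAP <- 300

#' Volcano-plot payload
#'
#' One point per converged fitted PheCode: effect size on x, significance
#' `-log10(p)` on y, coloured by the multiple-comparison class. A p-value
#' that underflows to 0 is capped at `y = 300` and flagged.
#'
#' @param results a [PhewasResults]
#' @param thresholds the matching [PhewasThresholds]
#' @return data.frame with columns `phecode`, `beta`, `neg_log10_p`,
#'   `class`, `capped`
#' @export
volcanoPayload <- function(results, thresholds) {
  r <- resultsTable(results)
  r <- r[r$converged & !is.na(r$p_value), , drop = FALSE]
  y <- -log10(r$p_value)
  capped <- !is.finite(y) | y > NEGLOG10P_CAP
  y[capped] <- NEGLOG10P_CAP
  cls <- significanceClasses(thresholds)[r$phecode]
  out <- data.frame(phecode = r$phecode, beta = r$beta, neg_log10_p = y,
                    class = unname(cls), capped = capped,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Effect-size plot payload
#'
#' Keeps only PheCodes passing the selected correction: `"bonferroni"`
#' keeps the bonferroni class, `"fdr"` keeps bonferroni and fdr classes
#' (the FDR view is a superset by construction). Entries carry the 95%
#' interval, category and subject count, ordered by category then effect
#' size; category indices are assigned deterministically by sorting the
#' category names. An empty payload is valid when nothing passes.
#'
#' @param results a [PhewasResults]
#' @param thresholds the matching [PhewasThresholds]
#' @param selected `"bonferroni"` or `"fdr"`
#' @return data.frame with columns `phecode`, `description`, `category`,
#'   `category_index`, `beta`, `ci_low`, `ci_high`, `n_subjects`, `class`
#' @export
effectPlotPayload <- function(results, thresholds,
                              selected = c("fdr", "bonferroni")) {
  selected <- match.arg(selected)
  r <- resultsTable(results)
  cls <- significanceClasses(thresholds)[r$phecode]
  keepClasses <- if (selected == "bonferroni") "bonferroni"
                 else c("bonferroni", "fdr")
  keep <- r$converged & unname(cls) %in% keepClasses
  r <- r[keep, , drop = FALSE]
  cls <- cls[keep]
  catLevels <- sort(unique(resultsTable(results)$category))
  out <- data.frame(phecode = r$phecode, description = r$description,
                    category = r$category,
                    category_index = match(r$category, catLevels) - 1L,
                    beta = r$beta, ci_low = r$ci_low, ci_high = r$ci_high,
                    n_subjects = r$n_subjects, class = unname(cls),
                    stringsAsFactors = FALSE)
  out <- out[order(out$category, out$beta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sorted data-table payload
#'
#' The full fitted result table sorted ascending by p-value (most
#' significant first; non-converged last), with the significance class
#' attached — the in-memory form of the saved table written by
#' [writeResultTable()].
#'
#' @param results a [PhewasResults]
#' @param thresholds the matching [PhewasThresholds]
#' @return data.frame
#' @export
tablePayload <- function(results, thresholds) {
  r <- resultsTable(results)
  r$class <- unname(significanceClasses(thresholds)[r$phecode])
  r <- r[order(r$p_value, r$phecode, na.last = TRUE), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Locate one PheCode across the three linked views
#'
#' Returns the row position (or absence) of a PheCode in the table, volcano
#' and effect-size payloads, so a front-end can highlight the same datum in
#' every view. An insignificant PheCode is present in the volcano and
#' table but absent from the effect plot.
#'
#' @param phecode single PheCode string
#' @param payloads list with elements `table`, `volcano`, `effects` (as
#'   returned by the payload functions)
#' @return list of locators: each is `list(present = , row = )`
#' @export
linkedSelection <- function(phecode, payloads) {
  stopifnot(is.list(payloads),
            all(c("table", "volcano", "effects") %in% names(payloads)))
  loc <- lapply(payloads[c("table", "volcano", "effects")], function(p) {
    row <- match(phecode, p$phecode)
    list(present = !is.na(row), row = if (is.na(row)) NULL else row)
  })
  if (!any(vapply(loc, `[[`, logical(1), "present"))) {
    phewasStop(sprintf("phecode '%s' not present in any view", phecode),
               class = "not_found")
  }
  loc
}

#' Write the report payloads as versioned JSON
#'
#' Emits `volcano.json` and `effects.json` (schema-versioned,
#' plot-library-agnostic) plus the result CSV into `dir`.
#'
#' @param results a [PhewasResults]
#' @param thresholds a [PhewasThresholds]
#' @param dir output directory
#' @param selected threshold selection for the effect plot
#' @return invisible named list of written paths
#' @export
writeReportPayloads <- function(results, thresholds, dir,
                                selected = c("fdr", "bonferroni")) {
  selected <- match.arg(selected)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(table = file.path(dir, "results.csv"),
                volcano = file.path(dir, "volcano.json"),
                effects = file.path(dir, "effects.json"))
  writeResultTable(results, paths$table)
  meta <- list(schema_version = 1, alpha = thresholds@alpha,
               m = thresholds@m,
               bonferroni_threshold = thresholds@bonferroni,
               fdr_threshold = thresholds@fdr)
  jsonlite::write_json(c(meta, list(points = volcanoPayload(results, thresholds))),
                       paths$volcano, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(c(meta, list(selected = selected,
                                    entries = effectPlotPayload(results, thresholds, selected))),
                       paths$effects, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}

#' Static convenience plots
#'
#' Thin ggplot2 renderers over the payloads; all logic lives in the payload
#' functions. Requires ggplot2.
#'
#' @param results a [PhewasResults]
#' @param thresholds a [PhewasThresholds]
#' @return a ggplot object
#' @export
plotVolcano <- function(results, thresholds) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    phewasStop("ggplot2 is required for plotting", class = "io")
  }
  v <- volcanoPayload(results, thresholds)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$beta, y = .data$neg_log10_p,
                                  colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "effect size (beta)",
                  y = expression(-log[10](p)), colour = "threshold") +
    ggplot2::theme_minimal()
}

#' @rdname plotVolcano
#' @param selected threshold selection for the effect plot
#' @export
plotEffects <- function(results, thresholds,
                        selected = c("fdr", "bonferroni")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    phewasStop("ggplot2 is required for plotting", class = "io")
  }
  e <- effectPlotPayload(results, thresholds, selected)
  e$phecode <- factor(e$phecode, levels = rev(e$phecode))
  ggplot2::ggplot(e, ggplot2::aes(x = .data$beta, y = .data$phecode,
                                  colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::labs(x = "effect size (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
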