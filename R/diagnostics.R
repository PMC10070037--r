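# Per-variable and pairwise covariate diagnostics: group-stratified
# histograms, joint distribution grids, correlation with the target, and
# the multicollinearity test backing covariate selection.

# Shared bin edges over the pooled (both-group) range so the two groups are
# directly comparable. Binary variables get exactly two bins centred on 0
# and 1; a constant variable gets a unit-width bin around its value.
sharedEdges <- function(values, bins) {
  v <- values[!is.na(values)]
  if (length(v) && all(v %in% c(0, 1))) return(c(-0.5, 0.5, 1.5))
  lo <- min(v)
  hi <- max(v)
  if (lo == hi) return(c(lo - 0.5, lo + 0.5))
  seq(lo, hi, length.out = bins + 1)
}

binCounts <- function(values, edges) {
  v <- values[!is.na(values)]
  h <- graphics::hist(v[v >= edges[1] & v <= edges[length(edges)]],
                      breaks = edges, plot = FALSE)
  h$counts
}

#' Summarize one group variable against the target
#'
#' Produces the per-target-group histograms on shared bin edges plus the
#' Pearson correlation between the variable and the 0/1 target (the
#' point-biserial correlation for a continuous variable, the phi
#' coefficient when both are binary), with its two-sided p-value. Matched
#' case/control designs show up as near-identical group histograms.
#'
#' @param values numeric vector of the variable
#' @param target 0/1 vector, same length
#' @param bins number of equal-width bins over the pooled range (binary
#'   variables always use 2)
#' @param name optional variable name carried into the summary
#' @return a `VariableSummary` list: `name`, `edges`, `counts1`/`counts0`
#'   (target = 1 / 0), `r`, `p`, `constant` flag
#' @export
variableSummary <- function(values, target, bins = 20, name = NULL) {
  checkTarget(target)
  if (length(values) != length(target)) {
    phewasStop("values and target lengths differ")
  }
  if (sum(!is.na(values)) < 2) phewasStop("need at least 2 non-missing values")
  edges <- sharedEdges(values, bins)
  c1 <- binCounts(values[!is.na(target) & target == 1], edges)
  c0 <- binCounts(values[!is.na(target) & target == 0], edges)
  ok <- !is.na(values) & !is.na(target)
  constant <- stats::sd(values[ok]) == 0 || stats::sd(target[ok]) == 0
  if (constant) {
    r <- NA_real_
    p <- NA_real_
  } else {
    ct <- stats::cor.test(values[ok], target[ok], method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(name = name, edges = edges, counts1 = c1, counts0 = c0,
                 r = r, p = p, constant = constant),
            class = "VariableSummary")
}

checkTarget <- function(target) {
  if (!all(target[!is.na(target)] %in% c(0, 1))) {
    phewasStop("target must be binary 0/1")
  }
}

#' Joint distribution grid for a variable pair
#'
#' Bins the two variables on shared 2-D edges (pooled over both target
#' groups) and counts patients per cell, separately for target = 1 and
#' target = 0. Summing a grid over either axis reproduces the 1-D marginal
#' histogram on the same edges, which is also returned.
#'
#' @param v1,v2 numeric vectors
#' @param target 0/1 vector
#' @param bins bins per axis (default 10)
#' @return list with `edges1`, `edges2`, `grid1`, `grid0` (matrices,
#'   `v1` bins in rows), and marginals `m1_v1`, `m1_v2`, `m0_v1`, `m0_v2`
#' @export
jointDistribution <- function(v1, v2, target, bins = 10) {
  checkTarget(target)
  e1 <- sharedEdges(v1, bins)
  e2 <- sharedEdges(v2, bins)
  gridFor <- function(g) {
    sel <- !is.na(target) & target == g & !is.na(v1) & !is.na(v2)
    b1 <- cut(v1[sel], e1, include.lowest = TRUE)
    b2 <- cut(v2[sel], e2, include.lowest = TRUE)
    unclass(table(b1, b2))
  }
  g1 <- gridFor(1)
  g0 <- gridFor(0)
  list(edges1 = e1, edges2 = e2, grid1 = g1, grid0 = g0,
       m1_v1 = rowSums(g1), m1_v2 = colSums(g1),
       m0_v1 = rowSums(g0), m0_v2 = colSums(g0))
}

#' Multicollinearity test for a covariate pair
#'
#' Regresses the binary target on each variable individually and on both
#' together (three logistic fits through the same fitting layer as the mass
#' regression) and reports every slope with its p-value, plus the absolute
#' coefficient drift between the individual and joint fits. Small drift
#' together with low pair correlation supports including both covariates:
#' the independence assumption holds when the coefficients stay constant
#' across the individual and combined models. A perfectly collinear pair
#' makes the joint fit non-identifiable, which is flagged rather than
#' silently resolved.
#'
#' @param target 0/1 vector
#' @param v1,v2 numeric covariate vectors
#' @return list with `beta1`, `p1`, `beta2`, `p2` (individual fits),
#'   `beta1_joint`, `p1_joint`, `beta2_joint`, `p2_joint`, `drift1`,
#'   `drift2`, and flags `converged` (per fit) and `nonIdentifiable`
#' @export
multicollinearityTest <- function(target, v1, v2) {
  checkTarget(target)
  ok <- !is.na(target) & !is.na(v1) & !is.na(v2)
  t <- target[ok]
  f1 <- fitGlmCore(t, data.frame(v1 = v1[ok]), "logistic")
  f2 <- fitGlmCore(t, data.frame(v2 = v2[ok]), "logistic")
  fj <- fitGlmCore(t, data.frame(v1 = v1[ok], v2 = v2[ok]), "logistic")
  nonIdent <- length(fj$aliased) > 0
  list(beta1 = unname(f1$beta["v1"]), p1 = unname(f1$p["v1"]),
       beta2 = unname(f2$beta["v2"]), p2 = unname(f2$p["v2"]),
       beta1_joint = unname(fj$beta["v1"]), p1_joint = unname(fj$p["v1"]),
       beta2_joint = unname(fj$beta["v2"]), p2_joint = unname(fj$p["v2"]),
       drift1 = abs(unname(f1$beta["v1"]) - unname(fj$beta["v1"])),
       drift2 = abs(unname(f2$beta["v2"]) - unname(fj$beta["v2"])),
       converged = c(v1 = f1$converged, v2 = f2$converged,
                     joint = fj$converged),
       nonIdentifiable = nonIdent)
}

#' Full pairwise comparison report
#'
#' Bundles, for one variable pair, the joint distribution grids, the pair's
#' Pearson correlation with p-value, and the multicollinearity
#' coefficients — the quantitative content of a variable-comparison view.
#'
#' @param group group data.frame
#' @param target name of the binary target variable
#' @param pair character vector of two variable names
#' @param bins grid bins per axis
#' @return a `ComparisonReport` list
#' @export
comparisonReport <- function(group, target, pair, bins = 10) {
  stopifnot(length(pair) == 2)
  miss <- setdiff(c(target, pair), colnames(group))
  if (length(miss)) {
    phewasStop(sprintf("variable(s) absent from group data: %s",
                       paste(miss, collapse = ", ")))
  }
  t <- group[[target]]
  v1 <- group[[pair[1]]]
  v2 <- group[[pair[2]]]
  ok <- !is.na(v1) & !is.na(v2)
  ct <- if (stats::sd(v1[ok]) > 0 && stats::sd(v2[ok]) > 0) {
    stats::cor.test(v1[ok], v2[ok], method = "pearson")
  } else NULL
  structure(list(
    pair = pair,
    joint = jointDistribution(v1, v2, t, bins = bins),
    r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
    p = if (is.null(ct)) NA_real_ else ct$p.value,
    multicollinearity = multicollinearityTest(t, v1, v2)
  ), class = "ComparisonReport")
}

#' Diagnostics report across all group variables
#'
#' Runs [variableSummary()] for every non-id group variable against the
#' target and [comparisonReport()] for each requested pair; the result
#' serializes directly to JSON for any front-end. Significance colouring of
#' the blocks uses p < 0.05 ("significant") and p < 0.1 ("borderline") by
#' default.
#'
#' @param group group data.frame (column `id`)
#' @param target name of the binary target
#' @param pairs list of 2-element character vectors to compare (optional)
#' @param bins histogram bins; `gridBins` for the 2-D grids
#' @param gridBins bins per joint-grid axis
#' @param levels named numeric vector of significance colour levels
#' @return list with `target`, `correlation_method`, `levels`, `summaries`,
#'   `comparisons`
#' @export
diagnosticsReport <- function(group, target, pairs = NULL, bins = 20,
                              gridBins = 10,
                              levels = c(significant = 0.05,
                                         borderline = 0.1)) {
  vars <- setdiff(colnames(group), c("id", target))
  t <- group[[target]]
  summaries <- lapply(vars, function(v) {
    s <- variableSummary(group[[v]], t, bins = bins, name = v)
    s$significance <- significanceLevel(s$p, levels)
    unclass(s)
  })
  names(summaries) <- vars
  comparisons <- lapply(pairs, function(p) {
    unclass(comparisonReport(group, target, p, bins = gridBins))
  })
  list(target = target, correlation_method = "pearson",
       levels = as.list(levels), summaries = summaries,
       comparisons = comparisons)
}

significanceLevel <- function(p, levels = c(significant = 0.05,
                                            borderline = 0.1)) {
  if (is.na(p)) return("undefined")
  lv <- sort(levels)
  for (i in seq_along(lv)) if (p < lv[i]) return(names(lv)[i])
  "none"
}
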