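# Mass univariate per-PheCode regression: model-pair construction, single
# fits with Wald inference, and the whole-matrix driver.

#' Define a PheWAS model
#'
#' @param target name of the binary target variable (case status)
#' @param covariates covariate names included in every per-PheCode fit
#' @param aggregation which feature matrix supplies the PheCode values:
#'   `"binary"`, `"count"` or `"duration"`
#' @param targetRole `"dependent"` regresses the target on the PheCode value
#'   plus covariates (always logistic); `"predictor"` regresses the PheCode
#'   value on the target plus covariates — logistic when the aggregation is
#'   binary, linear otherwise (count and duration outcomes are nonbinary)
#' @param alpha significance level used downstream for the thresholds
#' @param minSubjects PheCodes carried by fewer than this many patients are
#'   skipped (0 disables); degenerate fits on one or two carriers are
#'   uninformative and numerically unstable
#' @return a [PhewasModelSpec]
#' @examples
#' phewasModel("target", covariates = c("sex"), aggregation = "binary")
#' @export
phewasModel <- function(target, covariates = character(0),
                        aggregation = c("binary", "count", "duration"),
                        targetRole = c("dependent", "predictor"),
                        alpha = 0.05, minSubjects = 5) {
  new("PhewasModelSpec", target = target,
      covariates = as.character(covariates),
      aggregation = match.arg(aggregation),
      targetRole = match.arg(targetRole),
      alpha = alpha, minSubjects = minSubjects)
}

# One fit, shared by the mass regression and the covariate diagnostics so
# every coefficient in the package comes from the same code path.
# y: response; X: data.frame of predictors (intercept added here);
# returns per-term beta/se/p plus a convergence flag. Any glm warning
# (non-convergence, fitted probabilities of 0 or 1 under separation) marks
# the fit non-converged; there is no silent penalized fallback, which would
# change the meaning of the coefficient mid-table.
fitGlmCore <- function(y, X, family = c("logistic", "linear")) {
  family <- match.arg(family)
  df <- data.frame(.y = y, X, check.names = FALSE)
  warned <- FALSE
  sm <- NULL
  fit <- withCallingHandlers({
    f <- if (family == "logistic") {
      stats::glm(.y ~ ., data = df, family = stats::binomial(),
                 model = FALSE, y = FALSE)
    } else {
      stats::lm(.y ~ ., data = df, model = FALSE)
    }
    # a degenerate (zero-residual) summary also warns; keep it in scope
    sm <- summary(f)$coefficients
    f
  },
  warning = function(w) {
    warned <<- TRUE
    invokeRestart("muffleWarning")
  })
  co <- stats::coef(fit)
  terms <- setdiff(names(co), "(Intercept)")
  aliased <- terms[is.na(co[terms])]
  beta <- se <- p <- stats::setNames(rep(NA_real_, length(terms)), terms)
  est <- intersect(rownames(sm), terms)
  beta[est] <- sm[est, 1]
  se[est] <- sm[est, 2]
  z <- beta[est] / se[est]
  p[est] <- 2 * stats::pnorm(-abs(z))
  # glm's own convergence flag misses complete separation (the deviance
  # criterion is met while the MLE diverges), so treat essentially infinite
  # log-odds or exploded standard errors as non-convergence too.
  separated <- family == "logistic" &&
    any(!is.na(beta) & (abs(beta) > 15 | se > 100))
  # linear least squares always "converges"; its only warning of note is
  # the harmless zero-residual perfect fit, which stays a valid result
  converged <- !separated && length(aliased) == 0L &&
    (family == "linear" || (!warned && isTRUE(fit$converged)))
  list(beta = beta, se = se, p = p, converged = converged,
       aliased = aliased, family = family)
}

#' Assemble the dependent vector and predictor design for one PheCode
#'
#' Encodes the model-selection rule: with the target as dependent variable
#' the fit is logistic with predictors `[phecode value, covariates...]`;
#' with the target as an independent predictor the PheCode value is the
#' outcome, the predictors are `[target, covariates...]`, and the family is
#' logistic exactly when the aggregation is binary (count and duration
#' outcomes are nonbinary, hence linear). An intercept is always included
#' by the fitting layer. Patients with a missing value in any involved
#' variable are excluded for this fit only, with the exclusion count
#' returned.
#'
#' @param model a [PhewasModelSpec]
#' @param phecodeValues numeric vector of the PheCode's aggregated values,
#'   aligned to the group rows
#' @param group group data.frame (must contain the target and covariates)
#' @return list with `y`, `X` (data.frame), `family`, `term` (the design
#'   column whose coefficient is the reported effect size), `nExcluded`,
#'   and `used` (logical row mask)
#' @export
buildModelPair <- function(model, phecodeValues, group) {
  vars <- c(model@target, model@covariates)
  miss <- setdiff(vars, colnames(group))
  if (length(miss)) {
    phewasStop(sprintf("variable(s) absent from group data: %s",
                       paste(miss, collapse = ", ")))
  }
  tgt <- group[[model@target]]
  if (!all(tgt[!is.na(tgt)] %in% c(0, 1))) {
    phewasStop(sprintf("target '%s' must be binary 0/1", model@target))
  }
  covs <- group[model@covariates]
  used <- !is.na(phecodeValues) & !is.na(tgt)
  for (cv in model@covariates) used <- used & !is.na(covs[[cv]])
  nExcluded <- sum(!used)
  if (!any(used)) {
    phewasStop("no usable patients after missing-value exclusion")
  }
  if (model@targetRole == "dependent") {
    y <- tgt[used]
    X <- data.frame(phecode = phecodeValues[used], check.names = FALSE)
    family <- "logistic"
    term <- "phecode"
  } else {
    y <- phecodeValues[used]
    X <- stats::setNames(data.frame(tgt[used], check.names = FALSE),
                         model@target)
    family <- if (model@aggregation == "binary") "logistic" else "linear"
    term <- model@target
  }
  for (cv in model@covariates) X[[cv]] <- covs[[cv]][used]
  list(y = y, X = X, family = family, term = term,
       nExcluded = nExcluded, used = used)
}

#' Fit a single PheCode model
#'
#' Maximum-likelihood logistic or least-squares linear fit with an
#' intercept. The reported effect size is the coefficient of the PheCode
#' term (target as dependent) or of the target term (target as predictor);
#' the 95% interval is Wald, `beta +/- 1.959964 * se`, with a two-sided
#' Wald p-value. Separation or non-convergence yields `converged = FALSE`
#' with the statistics unavailable — never a silently regularized fit.
#'
#' @param pair a model pair from [buildModelPair()]
#' @return list with `beta`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `converged`, `model_family`
#' @export
fitSingle <- function(pair) {
  fit <- fitGlmCore(pair$y, pair$X, pair$family)
  beta <- unname(fit$beta[pair$term])
  se <- unname(fit$se[pair$term])
  p <- unname(fit$p[pair$term])
  if (!fit$converged) {
    return(list(beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p_value = NA_real_, converged = FALSE,
                model_family = pair$family))
  }
  list(beta = beta, se = se,
       ci_low = beta - Z975 * se, ci_high = beta + Z975 * se,
       p_value = p, converged = TRUE, model_family = pair$family)
}

phewasCore <- function(values, binaryView, group, model, phecodeMeta) {
  miss <- setdiff(c(model@target, model@covariates), colnames(group))
  if (length(miss)) {
    phewasStop(sprintf(
      "variable(s) absent from group data: %s (available: %s)",
      paste(miss, collapse = ", "),
      paste(setdiff(colnames(group), "id"), collapse = ", ")))
  }
  codes <- rownames(values)
  nSubjects <- as.integer(rowSums(binaryView >= 1))
  fitIdx <- which(nSubjects >= model@minSubjects)
  skipped <- codes[nSubjects < model@minSubjects]
  skip <- data.frame(phecode = skipped,
                     reason = rep(sprintf("n_subjects < %d",
                                          model@minSubjects),
                                  length(skipped)),
                     stringsAsFactors = FALSE)
  if (length(fitIdx) == 0L) {
    phewasStop("no PheCode passes the minimum-subject filter")
  }
  rows <- vector("list", length(fitIdx))
  for (k in seq_along(fitIdx)) {
    i <- fitIdx[k]
    res <- tryCatch({
      pair <- buildModelPair(model, values[i, ], group)
      fitSingle(pair)
    }, phewas_error = function(e) e)
    if (inherits(res, "phewas_error")) {
      skip <- rbind(skip, data.frame(phecode = codes[i],
                                     reason = conditionMessage(res),
                                     stringsAsFactors = FALSE))
      rows[k] <- list(NULL)
      next
    }
    rows[[k]] <- data.frame(
      phecode = codes[i], beta = res$beta, se = res$se,
      ci_low = res$ci_low, ci_high = res$ci_high, p_value = res$p_value,
      n_subjects = nSubjects[i], converged = res$converged,
      model_family = res$model_family, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) phewasStop("no PheCode could be fitted")
  out <- do.call(rbind, rows)
  meta <- phecodeMeta[match(out$phecode, phecodeMeta$phecode), ]
  out$description <- as.character(meta$description)
  out$category <- as.character(meta$category)
  out <- out[c("phecode", "description", "category", "beta", "se", "ci_low",
               "ci_high", "p_value", "n_subjects", "converged",
               "model_family")]
  rownames(out) <- NULL
  new("PhewasResults", results = S4Vectors::DataFrame(out), model = model,
      skipLog = S4Vectors::DataFrame(skip))
}

#' @describeIn runPhewas Fit one regression per PheCode of a
#'   [PhewasExperiment]. PheCode values come from the assay selected by the
#'   model's aggregation; the number of subjects per PheCode is always the
#'   row sum of the binary assay; group variables come from `colData`.
#'   Results are returned in the input PheCode order (sorting happens at
#'   report time) and are fully deterministic.
#' @export
setMethod("runPhewas", "PhewasExperiment", function(x, model, ...) {
  stopifnot(is(model, "PhewasModelSpec"))
  values <- SummarizedExperiment::assay(x, model@aggregation)
  group <- as.data.frame(SummarizedExperiment::colData(x))
  meta <- as.data.frame(SummarizedExperiment::rowData(x))
  phewasCore(values, binaryAssay(x), group, model, meta)
})

#' @describeIn runPhewas Fit from a plain PheCodes x patients matrix whose
#'   aggregation matches the model; `group` must be supplied with one row
#'   per matrix column. Subject counts use non-zero cells, which equals the
#'   binary view for binary and count matrices (for duration matrices a
#'   single-occurrence carrier is invisible, so prefer the
#'   `PhewasExperiment` method there).
#' @param group group data.frame (matrix method only)
#' @param phecodeMeta optional data.frame (`phecode`, `description`,
#'   `category`); defaults to empty annotations
#' @export
setMethod("runPhewas", "matrix", function(x, model, group,
                                          phecodeMeta = NULL, ...) {
  stopifnot(is(model, "PhewasModelSpec"))
  if (is.null(phecodeMeta)) {
    phecodeMeta <- data.frame(phecode = rownames(x),
                              description = rownames(x),
                              category = "unassigned",
                              stringsAsFactors = FALSE)
  }
  phewasCore(x, x != 0, group, model, phecodeMeta)
})
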