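# Case definition from ICD record-count thresholds and one-to-one
# matched-control selection.

#' Define a matching specification
#'
#' Describes how controls must resemble their case: `exactKeys` are group
#' variables matched exactly (e.g. biological sex), `toleranceKeys` are
#' numeric variables matched within an absolute tolerance in the variable's
#' own units (e.g. minimum age at visit within 0.1 years).
#'
#' @param exactKeys character vector of variable names matched exactly
#' @param toleranceKeys named numeric vector: names are variable names,
#'   values the (positive) tolerances
#' @return a `MatchSpec` object
#' @examples
#' matchSpec(exactKeys = "sex", toleranceKeys = c(MinAgeAtVisit = 0.1))
#' @export
matchSpec <- function(exactKeys = character(0), toleranceKeys = numeric(0)) {
  if (length(toleranceKeys)) {
    if (is.null(names(toleranceKeys)) || any(!nzchar(names(toleranceKeys)))) {
      phewasStop("toleranceKeys must be a named numeric vector")
    }
    if (any(toleranceKeys <= 0)) phewasStop("tolerances must be > 0")
  }
  structure(list(exactKeys = exactKeys, toleranceKeys = toleranceKeys),
            class = "MatchSpec")
}

#' Select cases by a minimum ICD record count
#'
#' A patient is a case when its total number of EHR records across the
#' given ICD code set reaches `minRecords`. Counts are pooled across the
#' set's codes by default (two records of one code plus one of another
#' reach a threshold of 3); `perCode = TRUE` switches to the strict reading
#' requiring `minRecords` records of a single code.
#'
#' @param records data.frame of ICD records from [readEhrFile()]
#' @param codeSet data.frame with columns `icd_version`, `icd_code`
#'   defining the case codes (codes are normalized before comparison)
#' @param minRecords minimum record count, >= 1
#' @param perCode require the threshold within a single code
#' @return character vector of case patient ids
#' @export
selectCases <- function(records, codeSet, minRecords = 1L, perCode = FALSE) {
  if (minRecords < 1) phewasStop("minRecords must be >= 1")
  if (!is.data.frame(codeSet) || nrow(codeSet) == 0L) {
    phewasStop("codeSet must be a non-empty data.frame of (icd_version, icd_code)")
  }
  key <- paste(records$icd_version, records$icd_code, sep = "|")
  setKey <- paste(codeSet$icd_version,
                  normalizeIcd(codeSet$icd_code, codeSet$icd_version),
                  sep = "|")
  hit <- key %in% setKey
  if (!any(hit)) return(character(0))
  if (perCode) {
    cnt <- table(records$id[hit], key[hit])
    ids <- rownames(cnt)[apply(cnt, 1, max) >= minRecords]
  } else {
    cnt <- table(records$id[hit])
    ids <- names(cnt)[cnt >= minRecords]
  }
  sort(as.character(ids))
}

# Eligible controls for one case: exact keys equal, every tolerance key
# within its band. Returns ids.
eligibleControls <- function(caseId, poolIds, group, spec) {
  gi <- group[match(caseId, group$id), , drop = FALSE]
  keep <- rep(TRUE, length(poolIds))
  pi <- match(poolIds, group$id)
  for (k in spec$exactKeys) {
    keep <- keep & !is.na(group[[k]][pi]) & group[[k]][pi] == gi[[k]]
  }
  for (k in names(spec$toleranceKeys)) {
    dv <- abs(group[[k]][pi] - gi[[k]])
    keep <- keep & !is.na(dv) & dv <= spec$toleranceKeys[[k]]
  }
  poolIds[keep]
}

toleranceDistance <- function(caseId, controlIds, group, spec) {
  if (!length(names(spec$toleranceKeys))) return(numeric(length(controlIds)))
  gi <- match(caseId, group$id)
  ci <- match(controlIds, group$id)
  d <- 0
  for (k in names(spec$toleranceKeys)) {
    d <- d + abs(group[[k]][ci] - group[[k]][gi]) / spec$toleranceKeys[[k]]
  }
  d
}

#' One-to-one matched-control selection
#'
#' Pairs each case with a distinct control from the pool so that every pair
#' satisfies the [matchSpec()] predicates. The core is greedy: cases are
#' visited in a seed-shuffled order and each takes the eligible control at
#' the smallest tolerance-key distance (ties broken by control id). Greedy
#' alone can strand a case whose nearest control was taken by another case,
#' so any case left unmatched triggers an augmenting-path repair over the
#' eligibility graph; together these find a complete matching whenever one
#' exists. With full success the combined cohort has `2 * length(cases)`
#' patients.
#'
#' @param cases character vector of case ids (disjoint from the pool)
#' @param pool character vector of candidate control ids
#' @param group group data.frame carrying the match variables
#' @param spec a [matchSpec()]
#' @param seed integer seed for the case ordering
#' @param unmatched `"drop"` (default) logs and drops cases with no
#'   admissible control; `"error"` fails instead
#' @return data.frame with columns `case`, `control`, one row per matched
#'   pair, plus attribute `unmatched` listing dropped case ids
#' @export
matchControls <- function(cases, pool, group, spec, seed = 1L,
                          unmatched = c("drop", "error")) {
  unmatched <- match.arg(unmatched)
  if (length(pool) == 0L) phewasStop("control pool is empty")
  if (length(intersect(cases, pool))) {
    phewasStop("cases and pool must be disjoint")
  }
  miss <- setdiff(c(spec$exactKeys, names(spec$toleranceKeys)),
                  colnames(group))
  if (length(miss)) {
    phewasStop(sprintf("match variable(s) absent from group data: %s",
                       paste(miss, collapse = ", ")))
  }
  order <- withr::with_seed(seed, sample(length(cases)))
  cases <- cases[order]
  matchOf <- character(0)    # control id -> case id
  eligCache <- new.env(parent = emptyenv())
  elig <- function(cs) {
    if (is.null(eligCache[[cs]])) {
      e <- eligibleControls(cs, pool, group, spec)
      d <- toleranceDistance(cs, e, group, spec)
      o <- base::order(d, e)
      eligCache[[cs]] <- e[o]
    }
    eligCache[[cs]]
  }
  # Greedy pass
  stranded <- character(0)
  for (cs in cases) {
    e <- elig(cs)
    free <- e[!e %in% names(matchOf)]
    if (length(free)) {
      matchOf[free[1]] <- cs
    } else {
      stranded <- c(stranded, cs)
    }
  }
  # Augmenting-path repair (Kuhn): reassigns taken controls along an
  # alternating path so a feasible case is never left unmatched. Iterative
  # depth-first search — paths can be thousands of cases long.
  stillUnmatched <- character(0)
  for (cs in stranded) {
    visited <- new.env(parent = emptyenv())
    fCase <- cs
    fElig <- list(elig(cs))
    fIdx <- 0L
    fCtrl <- NA_character_
    success <- FALSE
    while (length(fCase) > 0L) {
      d <- length(fCase)
      e <- fElig[[d]]
      i <- fIdx[d] + 1L
      while (i <= length(e) && !is.null(visited[[e[i]]])) i <- i + 1L
      fIdx[d] <- i
      if (i > length(e)) {          # branch exhausted: backtrack
        fCase <- fCase[-d]
        fElig[[d]] <- NULL
        fIdx <- fIdx[-d]
        fCtrl <- fCtrl[-d]
        next
      }
      ctrl <- e[i]
      visited[[ctrl]] <- TRUE
      fCtrl[d] <- ctrl
      owner <- matchOf[ctrl]
      if (is.na(owner)) {           # free control: flip the whole path
        for (k in seq_len(d)) matchOf[fCtrl[k]] <- fCase[k]
        success <- TRUE
        break
      }
      fCase <- c(fCase, unname(owner))
      fElig[[d + 1L]] <- elig(unname(owner))
      fIdx <- c(fIdx, 0L)
      fCtrl <- c(fCtrl, NA_character_)
    }
    if (!success) stillUnmatched <- c(stillUnmatched, cs)
  }
  if (length(stillUnmatched)) {
    msg <- sprintf("%d case(s) have no admissible control: %s",
                   length(stillUnmatched),
                   paste(utils::head(stillUnmatched, 5), collapse = ", "))
    if (unmatched == "error") phewasStop(msg)
    phewasLog(msg, level = "WARN")
  }
  out <- data.frame(case = unname(matchOf), control = names(matchOf),
                    stringsAsFactors = FALSE)
  out <- out[base::order(match(out$case, cases)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmatched") <- stillUnmatched
  out
}
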