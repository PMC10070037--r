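# Collapse per-event PheCode records into per-patient feature matrices
# under the three aggregation schemes, and assemble the PhewasExperiment.

checkRecordPatients <- function(records, patients) {
  unknown <- setdiff(unique(records$id), patients)
  if (length(unknown)) {
    phewasStop(sprintf("record(s) for unknown patient(s): %s",
                       paste(utils::head(unknown, 5), collapse = ", ")))
  }
}

# Shared indexing: linear cell index per record into the phecodes x patients
# matrix. Records whose phecode is outside the requested axis are ignored
# (the axis is the caller's contract, e.g. a post-filter subset).
cellIndex <- function(records, patients, phecodes) {
  checkRecordPatients(records, patients)
  keep <- records$phecode %in% phecodes
  i <- match(records$phecode[keep], phecodes)
  j <- match(records$id[keep], patients)
  list(idx = (j - 1L) * length(phecodes) + i, keep = keep)
}

emptyFeatureMatrix <- function(patients, phecodes, storage = 0) {
  matrix(storage, nrow = length(phecodes), ncol = length(patients),
         dimnames = list(phecodes, patients))
}

#' Aggregate PheCode records into per-patient feature matrices
#'
#' The three schemes summarize the presence of each PheCode across each
#' patient's record:
#'
#' * `aggregateBinary()` — cell is 1 iff the patient has at least one record
#'   of the PheCode, else 0;
#' * `aggregateCount()` — cell is the total number of records of the
#'   PheCode for the patient (every row counts, including rows at identical
#'   ages, which represent repeat billing);
#' * `aggregateDuration()` — cell is the time in years between the first
#'   and last occurrence, `max(age) - min(age)`; exactly 0 when the PheCode
#'   is absent or occurs once.
#'
#' Matrices are PheCodes x patients, with dimnames carrying the axis
#' identities. Record order never affects any result.
#'
#' @param records data.frame of PheCode records (`id`, `phecode`, `age`),
#'   e.g. from [mapRecords()]
#' @param patients ordered character vector of patient ids (the matrix
#'   column axis); a record for a patient outside this set is an error
#' @param phecodes ordered character vector of PheCodes (the row axis)
#' @return a numeric matrix `length(phecodes)` x `length(patients)`
#' @examples
#' rec <- data.frame(id = c("P1", "P1", "P2"), phecode = "313.1",
#'                   age = c(10, 12.5, 8))
#' aggregateCount(rec, c("P1", "P2"), "313.1")
#' aggregateDuration(rec, c("P1", "P2"), "313.1")
#' @export
aggregateBinary <- function(records, patients, phecodes) {
  m <- aggregateCount(records, patients, phecodes)
  m[] <- as.numeric(m >= 1)
  m
}

#' @rdname aggregateBinary
#' @export
aggregateCount <- function(records, patients, phecodes) {
  ci <- cellIndex(records, patients, phecodes)
  n <- length(phecodes) * length(patients)
  m <- emptyFeatureMatrix(patients, phecodes)
  if (length(ci$idx)) m[] <- tabulate(ci$idx, nbins = n)
  m
}

#' @rdname aggregateBinary
#' @export
aggregateDuration <- function(records, patients, phecodes) {
  ci <- cellIndex(records, patients, phecodes)
  m <- emptyFeatureMatrix(patients, phecodes)
  if (length(ci$idx)) {
    age <- records$age[ci$keep]
    hi <- tapply(age, ci$idx, max)
    lo <- tapply(age, ci$idx, min)
    at <- as.integer(names(hi))
    m[at] <- unname(hi - lo)
  }
  m
}

#' Construct a PhewasExperiment
#'
#' Low-level constructor from the three pre-built feature matrices; most
#' users will call [buildPhewasExperiment()] instead.
#'
#' @param binary,count,duration PheCodes x patients matrices with identical
#'   dimnames
#' @param phecodeData data.frame with columns `phecode`, `description`,
#'   `category`, one row per matrix row
#' @param groupData data.frame of group demographics; rownames (or an `id`
#'   column) must equal the matrix column names
#' @return a validated [PhewasExperiment]
#' @export
PhewasExperiment <- function(binary, count, duration, phecodeData,
                             groupData = NULL) {
  if (!identical(dimnames(binary), dimnames(count)) ||
      !identical(dimnames(binary), dimnames(duration))) {
    phewasStop("the three matrices must share identical patient and PheCode axes")
  }
  if (is.null(groupData)) {
    groupData <- data.frame(row.names = colnames(binary))
  } else if ("id" %in% colnames(groupData) &&
             !identical(rownames(groupData), as.character(groupData$id))) {
    rownames(groupData) <- as.character(groupData$id)
    groupData$id <- NULL
  }
  groupData <- groupData[colnames(binary), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(binary = binary, count = count, duration = duration),
    rowData = S4Vectors::DataFrame(phecodeData, row.names = rownames(binary)),
    colData = S4Vectors::DataFrame(groupData, row.names = colnames(binary))
  )
  new("PhewasExperiment", se)
}

#' Build all three feature matrices in one preprocessing pass
#'
#' Maps nothing itself: takes already-mapped PheCode records (see
#' [mapRecords()]) plus the group table and the map, builds binary, count
#' and duration matrices over a common axis, attaches PheCode descriptions
#' and categories as `rowData` and the group demographics as `colData`.
#'
#' @param records data.frame of PheCode records (`id`, `phecode`, `age`)
#' @param group group data.frame from [readGroupFile()] (column `id`)
#' @param map PheCode map supplying description and category
#' @param phecodeSet `"observed"` (default) restricts the PheCode axis to
#'   codes present in the records — all-zero columns are untestable in
#'   regression anyway; `"table"` uses the map's full PheCode set
#' @return a [PhewasExperiment]
#' @export
buildPhewasExperiment <- function(records, group, map,
                                  phecodeSet = c("observed", "table")) {
  phecodeSet <- match.arg(phecodeSet)
  patients <- as.character(group$id)
  codes <- if (phecodeSet == "observed") {
    sort(unique(records$phecode))
  } else {
    sort(unique(map$phecode))
  }
  k <- aggregateCount(records, patients, codes)
  b <- k
  b[] <- as.numeric(k >= 1)
  d <- aggregateDuration(records, patients, codes)
  PhewasExperiment(binary = b, count = k, duration = d,
                   phecodeData = phecodeInfo(map, codes),
                   groupData = group)
}
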