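# Readers and writers for the three CSV inputs (group demographics, EHR,
# PheCode map), the saved result table, and the feature-matrix cache.
#
# All files are comma-separated UTF-8 with a header row. Empty cells and
# "NA" read as missing; missing values never silently become zero.

#' Read the group demographics file
#'
#' One row per patient: a unique identifier plus binary candidate target
#' variables and numeric or binary covariates. Variable kinds are inferred
#' with the rule implemented by [variableKinds()]: a variable whose
#' non-missing values all lie in \{0, 1\} is binary, anything else
#' continuous. At least one binary variable must exist, since the PheWAS
#' target must be binary.
#'
#' @param path CSV file path
#' @param idColumn name of the patient identifier column (default `"id"`)
#' @return a data.frame with one row per patient, the id column coerced to
#'   character
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("P1", "P2"), target = c(0, 1)), f,
#'           row.names = FALSE)
#' readGroupFile(f)
#' @export
readGroupFile <- function(path, idColumn = "id") {
  df <- readCsvStrict(path)
  if (!idColumn %in% colnames(df)) {
    phewasStop(sprintf("group file lacks id column '%s'", idColumn),
               class = "format")
  }
  df[[idColumn]] <- as.character(df[[idColumn]])
  dup <- df[[idColumn]][duplicated(df[[idColumn]])]
  if (length(dup)) {
    phewasStop(sprintf("duplicate patient id(s): %s",
                       paste(unique(dup), collapse = ", ")))
  }
  kinds <- variableKinds(df, idColumn = idColumn)
  if (!any(kinds == "binary")) {
    phewasStop("group file has no binary variable; no candidate target exists")
  }
  if (idColumn != "id") {
    names(df)[names(df) == idColumn] <- "id"
  }
  df
}

#' Infer variable kinds in a group table
#'
#' A variable is binary when its non-missing values form a subset of
#' \{0, 1\} (missing cells are ignored, so `c(0, 1, 1, NA)` is binary);
#' every other variable is continuous.
#'
#' @param group a group data.frame
#' @param idColumn identifier column to exclude
#' @return named character vector with values "binary" or "continuous"
#' @export
variableKinds <- function(group, idColumn = "id") {
  vars <- setdiff(colnames(group), idColumn)
  kinds <- vapply(vars, function(v) {
    x <- group[[v]]
    x <- x[!is.na(x)]
    if (is.numeric(x) && length(x) && all(x %in% c(0, 1))) "binary"
    else "continuous"
  }, character(1))
  kinds
}

#' Read the EHR file
#'
#' One row per coded clinical event: patient identifier, ICD code, ICD
#' version (9 or 10) and age at the event in years. Codes are normalized
#' with [normalizeIcd()]; row order is preserved. Duplicate exact rows are
#' kept — they plausibly represent repeat billing and therefore count toward
#' the count aggregation — with the duplicate tally logged.
#'
#' @param path CSV file path
#' @param columns named character vector mapping the canonical roles `id`,
#'   `code`, `version`, `age` to the file's column names; defaults follow
#'   the common convention `id`, `ICD_CODE`, `ICD_TYPE`, `AgeAtICD`
#' @return a data.frame with columns `id`, `icd_code`, `icd_version`, `age`
#' @export
readEhrFile <- function(path,
                        columns = c(id = "id", code = "ICD_CODE",
                                    version = "ICD_TYPE", age = "AgeAtICD")) {
  df <- readCsvStrict(path)
  need <- columns[c("id", "code", "version", "age")]
  miss <- setdiff(unname(need), colnames(df))
  if (length(miss)) {
    phewasStop(sprintf("EHR file lacks column(s): %s",
                       paste(miss, collapse = ", ")), class = "format")
  }
  out <- data.frame(id = as.character(df[[need[["id"]]]]),
                    icd_code = as.character(df[[need[["code"]]]]),
                    icd_version = df[[need[["version"]]]],
                    age = as.numeric(df[[need[["age"]]]]),
                    stringsAsFactors = FALSE)
  badVer <- which(!out$icd_version %in% c(9, 10))
  if (length(badVer)) {
    phewasStop(sprintf("ICD version not in {9, 10} at row(s): %s",
                       paste(utils::head(badVer, 10), collapse = ", ")))
  }
  badAge <- which(is.na(out$age) | out$age < 0)
  if (length(badAge)) {
    phewasStop(sprintf("negative or missing age at row(s): %s",
                       paste(utils::head(badAge, 10), collapse = ", ")))
  }
  out$icd_code <- normalizeIcd(out$icd_code, out$icd_version)
  nDup <- sum(duplicated(out))
  if (nDup > 0) {
    phewasLog(sprintf("%d duplicate EHR row(s) kept (repeat billing)", nDup))
  }
  out
}

#' Read an ICD-to-PheCode mapping table
#'
#' Columns `icd_version`, `icd_code`, `phecode`, `description`, `category`.
#' Codes are normalized on read. Several ICD codes may share one PheCode
#' (many-to-one), but a single (version, code) key mapping to two PheCodes
#' is rejected, as is a PheCode carrying two different descriptions or
#' categories. Exact duplicate rows are collapsed.
#'
#' @param path CSV file path
#' @return a data.frame keyed by (icd_version, icd_code) with the PheCode,
#'   description and category of each entry
#' @export
readPhecodeMap <- function(path) {
  df <- readCsvStrict(path)
  need <- c("icd_version", "icd_code", "phecode", "description", "category")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    phewasStop(sprintf("phecode map lacks column(s): %s",
                       paste(miss, collapse = ", ")), class = "format")
  }
  df <- df[need]
  df$icd_code <- normalizeIcd(df$icd_code, df$icd_version)
  df$phecode <- as.character(df$phecode)
  df <- unique(df)
  key <- paste(df$icd_version, df$icd_code, sep = "|")
  if (anyDuplicated(key)) {
    bad <- unique(key[duplicated(key)])
    phewasStop(sprintf("conflicting map entries for key(s): %s",
                       paste(utils::head(bad, 5), collapse = ", ")))
  }
  meta <- unique(df[c("phecode", "description", "category")])
  if (anyDuplicated(meta$phecode)) {
    bad <- unique(meta$phecode[duplicated(meta$phecode)])
    phewasStop(sprintf(
      "phecode(s) with conflicting description/category: %s",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  rownames(df) <- NULL
  df
}

#' Look up PheCode metadata in a map table
#'
#' @param map a PheCode map data.frame
#' @param phecode character vector of PheCodes
#' @return data.frame with one row per requested PheCode: `phecode`,
#'   `description`, `category`
#' @export
phecodeInfo <- function(map, phecode) {
  meta <- unique(map[c("phecode", "description", "category")])
  idx <- match(as.character(phecode), meta$phecode)
  out <- meta[idx, , drop = FALSE]
  out$phecode <- as.character(phecode)
  rownames(out) <- NULL
  out
}

#' Write the saved PheWAS result table
#'
#' Writes the per-PheCode results as CSV with columns `phecode`,
#' `description`, `category`, `coefficient`, `ci_low`, `ci_high`,
#' `p_value`, `n_subjects`, `converged`, sorted ascending by p-value so the
#' most significant associations are at the top (non-converged fits, which
#' have no p-value, sort last). Numeric columns are written at full
#' precision so a read-back reproduces the coefficients exactly.
#'
#' @param results a [PhewasResults]
#' @param path output CSV path
#' @return the path, invisibly
#' @seealso [readResultTable()]
#' @export
writeResultTable <- function(results, path) {
  stopifnot(is(results, "PhewasResults"))
  r <- resultsTable(results)
  if (nrow(r) == 0L) {
    phewasStop("result set is empty; nothing to write")
  }
  r <- r[order(r$p_value, r$phecode, na.last = TRUE), ]
  out <- data.frame(phecode = r$phecode,
                    description = r$description,
                    category = r$category,
                    coefficient = formatFull(r$beta),
                    ci_low = formatFull(r$ci_low),
                    ci_high = formatFull(r$ci_high),
                    p_value = formatFull(r$p_value),
                    n_subjects = r$n_subjects,
                    converged = r$converged,
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) phewasStop(sprintf("cannot write result table to %s", path),
                      class = "io")
  invisible(path)
}

#' Read back a saved result table
#'
#' @param path CSV written by [writeResultTable()]
#' @return data.frame with numeric columns restored at full precision
#' @export
readResultTable <- function(path) {
  if (!file.exists(path)) {
    phewasStop(sprintf("file not found: %s", path), class = "io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"),
                        colClasses = c(phecode = "character"))
  for (col in c("coefficient", "ci_low", "ci_high", "p_value")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$converged <- as.logical(df$converged)
  df
}

CACHE_SCHEMA_VERSION <- 1L

#' Cache and reload feature matrices
#'
#' The three aggregation matrices are built once per dataset and saved for
#' faster startup in later sessions. The cache is a directory of plain CSV
#' files plus a self-describing `meta.json` carrying the schema version and
#' an MD5 checksum of every input file the matrices were built from. On
#' load, a schema-version mismatch or an input-file checksum change raises a
#' stale-cache error (condition class `phewas_stale_cache_error`) so a stale
#' cache is rebuilt, never silently reused. Values round-trip bit-exactly.
#'
#' @param pe a [PhewasExperiment]
#' @param dir cache directory (created if absent)
#' @param inputs character vector of input file paths whose checksums guard
#'   staleness (typically the group file, EHR file and map table)
#' @return `cacheFeatureMatrices()` returns `dir` invisibly;
#'   `loadFeatureMatrices()` returns the reconstructed [PhewasExperiment]
#' @export
cacheFeatureMatrices <- function(pe, dir, inputs = character(0)) {
  stopifnot(is(pe, "PhewasExperiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sums <- if (length(inputs)) unname(tools::md5sum(inputs)) else character(0)
  rd <- as.data.frame(SummarizedExperiment::rowData(pe))
  cd <- as.data.frame(SummarizedExperiment::colData(pe))
  meta <- list(
    schema_version = CACHE_SCHEMA_VERSION,
    input_checksums = sums,
    n_phecodes = nrow(pe),
    n_patients = ncol(pe),
    coldata_classes = vapply(cd, function(x) class(x)[1], character(1))
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  writeMatrixCsv <- function(m, path) {
    cols <- lapply(seq_len(ncol(m)), function(j) formatFull(m[, j]))
    names(cols) <- colnames(m)
    df <- data.frame(phecode = rownames(m), cols, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  writeMatrixCsv(binaryAssay(pe), file.path(dir, "binary.csv"))
  writeMatrixCsv(countAssay(pe), file.path(dir, "count.csv"))
  writeMatrixCsv(durationAssay(pe), file.path(dir, "duration.csv"))
  utils::write.csv(rd, file.path(dir, "rowdata.csv"), row.names = FALSE)
  utils::write.csv(cbind(id = rownames(cd), cd),
                   file.path(dir, "coldata.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname cacheFeatureMatrices
#' @export
loadFeatureMatrices <- function(dir, inputs = character(0)) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) {
    phewasStop(sprintf("no cache at %s", dir), class = "stale_cache")
  }
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (is.null(meta$schema_version) ||
      meta$schema_version != CACHE_SCHEMA_VERSION) {
    phewasStop(sprintf("cache schema version %s != current %d; rebuild",
                       meta$schema_version %||% "<absent>",
                       CACHE_SCHEMA_VERSION),
               class = "stale_cache")
  }
  if (length(inputs)) {
    sums <- unname(tools::md5sum(inputs))
    stored <- as.character(meta$input_checksums %||% character(0))
    if (length(stored) != length(sums) || !all(stored == sums)) {
      phewasStop("input files changed since the cache was written; rebuild",
                 class = "stale_cache")
    }
  }
  readMatrixCsv <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
    rn <- df$phecode
    df$phecode <- NULL
    m <- vapply(df, as.numeric, numeric(nrow(df)))
    if (nrow(df) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(df)))
    rownames(m) <- rn
    m
  }
  b <- readMatrixCsv(file.path(dir, "binary.csv"))
  k <- readMatrixCsv(file.path(dir, "count.csv"))
  d <- readMatrixCsv(file.path(dir, "duration.csv"))
  rd <- utils::read.csv(file.path(dir, "rowdata.csv"),
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  cd <- utils::read.csv(file.path(dir, "coldata.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  rownames(cd) <- as.character(cd$id)
  cd$id <- NULL
  cls <- meta$coldata_classes
  for (nm in names(cls)) {
    if (!nm %in% colnames(cd)) next
    cd[[nm]] <- switch(cls[[nm]],
                       character = as.character(cd[[nm]]),
                       integer = as.integer(cd[[nm]]),
                       logical = as.logical(cd[[nm]]),
                       as.numeric(cd[[nm]]))
  }
  PhewasExperiment(binary = b, count = k, duration = d,
                   phecodeData = rd, groupData = cd)
}
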