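# ICD code normalization and ICD -> PheCode record mapping.

#' Normalize an ICD code string
#'
#' Trims surrounding whitespace and upper-cases the code. The internal
#' decimal point is preserved and no truncation or parent-code fallback is
#' applied: `"f90"` stays `"F90"` and is never expanded to its children.
#' Lookup into the PheCode map is exact-match on the normalized code, so an
#' unmapped child code is dropped rather than rolled up (rolling up would
#' silently change record counts).
#'
#' @param rawCode character vector of ICD code strings
#' @param version ICD version, 9 or 10 (kept for interface symmetry; the
#'   normalization rule is version-independent)
#' @return character vector of normalized codes
#' @examples
#' normalizeIcd(" f90.0 ", 10)  # "F90.0"
#' @export
normalizeIcd <- function(rawCode, version = 9) {
  if (!all(version %in% c(9, 10))) {
    phewasStop("icd_version must be 9 or 10")
  }
  out <- toupper(trimws(as.character(rawCode)))
  if (any(is.na(out) | !nzchar(out))) {
    phewasStop("ICD code empty after normalization")
  }
  out
}

#' Map ICD records to PheCode records
#'
#' Joins each ICD record against the PheCode map on the exact
#' (version, normalized code) key. Records whose key is absent from the map
#' are removed from the study and tallied; mapping tables are known to be
#' incomplete, so the per-code drop tally is logged for visibility. The
#' conservation identity `nrow(records) == nrow(mapped) + droppedCount`
#' always holds.
#'
#' @param records a data.frame of ICD records as returned by [readEhrFile()]
#'   (columns `id`, `icd_code`, `icd_version`, `age`)
#' @param map a PheCode map from [readPhecodeMap()] or
#'   [generateMapFixture()]
#' @return a list with `records` (data.frame of PheCode records: `id`,
#'   `phecode`, `age`, in input row order) and `droppedCount`
#' @examples
#' map <- generateMapFixture(simSpec(nPhecodes = 3, seed = 1))
#' ehr <- data.frame(id = "P1", icd_code = map$icd_code[1],
#'                   icd_version = map$icd_version[1], age = 10)
#' mapRecords(ehr, map)
#' @export
mapRecords <- function(records, map) {
  stopifnot(is.data.frame(records), is.data.frame(map))
  if (nrow(records) == 0L) {
    return(list(records = data.frame(id = character(0),
                                     phecode = character(0),
                                     age = numeric(0)),
                droppedCount = 0L))
  }
  recKey <- paste(records$icd_version, records$icd_code, sep = "|")
  mapKey <- paste(map$icd_version, map$icd_code, sep = "|")
  idx <- match(recKey, mapKey)
  hit <- !is.na(idx)
  dropped <- sum(!hit)
  if (dropped > 0) {
    tally <- sort(table(records$icd_code[!hit]), decreasing = TRUE)
    phewasLog(sprintf("dropped %d unmapped record(s) over %d code(s): %s",
                      dropped, length(tally),
                      paste(utils::head(names(tally), 5), collapse = ", ")))
  }
  list(
    records = data.frame(id = records$id[hit],
                         phecode = map$phecode[idx[hit]],
                         age = records$age[hit],
                         stringsAsFactors = FALSE),
    droppedCount = as.integer(dropped)
  )
}
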