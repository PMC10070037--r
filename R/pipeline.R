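# End-to-end drivers: preprocessing with cache reuse, and the full
# regress-plus-report run with reproducibility metadata.

#' Preprocess a study into cached feature matrices
#'
#' Reads the three inputs, maps ICD records to PheCodes, builds the three
#' aggregation matrices in one pass and (optionally) caches them guarded by
#' the input-file checksums. A fresh cache is reused; a stale or corrupt
#' cache triggers a rebuild with a notice, never a silent reuse.
#'
#' @param groupPath,ehrPath,mapPath input CSV paths
#' @param cacheDir optional cache directory
#' @param idColumn id column name of the group file
#' @param ehrColumns column mapping passed to [readEhrFile()]
#' @param phecodeSet passed to [buildPhewasExperiment()]
#' @return list with `pe` (the [PhewasExperiment]), `nRecords`, `nMapped`,
#'   `nDropped`, and `fromCache`
#' @export
preprocessStudy <- function(groupPath, ehrPath, mapPath, cacheDir = NULL,
                            idColumn = "id",
                            ehrColumns = c(id = "id", code = "ICD_CODE",
                                           version = "ICD_TYPE",
                                           age = "AgeAtICD"),
                            phecodeSet = "observed") {
  inputs <- c(groupPath, ehrPath, mapPath)
  for (p in inputs) {
    if (!file.exists(p)) phewasStop(sprintf("input file not found: %s", p),
                                    class = "io")
  }
  if (!is.null(cacheDir)) {
    loaded <- tryCatch(
      loadFeatureMatrices(cacheDir, inputs = inputs),
      phewas_stale_cache_error = function(e) {
        phewasLog(sprintf("cache not reusable (%s); rebuilding",
                          conditionMessage(e)))
        NULL
      })
    if (!is.null(loaded)) {
      rep <- file.path(cacheDir, "preprocess_report.json")
      counts <- if (file.exists(rep)) jsonlite::read_json(rep) else list()
      phewasLog("feature matrices loaded from cache")
      return(list(pe = loaded,
                  nRecords = counts$n_records %||% NA_integer_,
                  nMapped = counts$n_mapped %||% NA_integer_,
                  nDropped = counts$n_dropped %||% NA_integer_,
                  fromCache = TRUE))
    }
  }
  group <- readGroupFile(groupPath, idColumn = idColumn)
  ehr <- readEhrFile(ehrPath, columns = ehrColumns)
  map <- readPhecodeMap(mapPath)
  mapped <- mapRecords(ehr, map)
  phewasLog(sprintf("%d EHR records: %d mapped, %d dropped (unmapped codes)",
                    nrow(ehr), nrow(mapped$records), mapped$droppedCount))
  pe <- buildPhewasExperiment(mapped$records, group, map,
                              phecodeSet = phecodeSet)
  phewasLog(sprintf("feature matrices: %d PheCodes x %d patients",
                    nrow(pe), ncol(pe)))
  if (!is.null(cacheDir)) {
    cacheFeatureMatrices(pe, cacheDir, inputs = inputs)
    jsonlite::write_json(list(n_records = nrow(ehr),
                              n_mapped = nrow(mapped$records),
                              n_dropped = mapped$droppedCount),
                         file.path(cacheDir, "preprocess_report.json"),
                         auto_unbox = TRUE)
  }
  list(pe = pe, nRecords = nrow(ehr), nMapped = nrow(mapped$records),
       nDropped = mapped$droppedCount, fromCache = FALSE)
}

#' Run a PheWAS model and write every result artifact
#'
#' Fits the mass univariate regression, classifies significance, and writes
#' the sorted result CSV, the volcano and effect-size JSON payloads, and a
#' machine-readable `run_meta.json` (package version, model configuration
#' and its hash, m, thresholds, skip counts) sufficient to reproduce the
#' run. Identical inputs and configuration give byte-identical result
#' artifacts.
#'
#' @param pe a [PhewasExperiment]
#' @param model a [PhewasModelSpec]
#' @param outDir output directory
#' @param selected effect-plot threshold selection
#' @param mPolicy,mTable passed to [classifySignificance()]
#' @return invisible list with `results`, `thresholds`, `paths`
#' @export
runStudy <- function(pe, model, outDir, selected = "fdr",
                     mPolicy = "fitted", mTable = NULL) {
  results <- runPhewas(pe, model)
  thresholds <- classifySignificance(results, mPolicy = mPolicy,
                                     mTable = mTable)
  paths <- writeReportPayloads(results, thresholds, outDir,
                               selected = selected)
  cfg <- list(target = model@target, covariates = model@covariates,
              aggregation = model@aggregation, target_role = model@targetRole,
              alpha = model@alpha, min_subjects = model@minSubjects,
              m_policy = mPolicy, selected = selected)
  cfgJson <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  tf <- tempfile()
  writeLines(cfgJson, tf)
  meta <- list(package = "phewasKit",
               version = as.character(utils::packageVersion("phewasKit")),
               config = cfg,
               config_md5 = unname(tools::md5sum(tf)),
               m = thresholds@m,
               bonferroni_threshold = thresholds@bonferroni,
               fdr_threshold = thresholds@fdr,
               n_fitted = nTests(results),
               n_skipped = nrow(skipLog(results)))
  unlink(tf)
  jsonlite::write_json(meta, file.path(outDir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$meta <- file.path(outDir, "run_meta.json")
  invisible(list(results = results, thresholds = thresholds, paths = paths))
}
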