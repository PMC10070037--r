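# Readers, writers and the feature-matrix cache.

test_that("group file parses with inferred variable kinds", {
  f <- writeTempCsv(data.frame(id = c("P1", "P2", "P3"),
                               sex = c(0, 1, 1), target = c(0, 1, 0)))
  g <- readGroupFile(f)
  expect_equal(nrow(g), 3)
  expect_equal(variableKinds(g)[["target"]], "binary")
})

test_that("a {0,1,missing} column is still flagged binary", {
  df <- data.frame(id = c("P1", "P2", "P3", "P4"),
                   target = c(0, 1, 1, NA),
                   bmi = c(21.2, NA, 30.1, 25))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, na = "")
  g <- readGroupFile(f)
  kinds <- variableKinds(g)
  expect_equal(kinds[["target"]], "binary")
  expect_equal(kinds[["bmi"]], "continuous")
  expect_true(is.na(g$target[4]))  # missing stays missing, never zero
})

test_that("group file validation: duplicate id and missing id column", {
  f <- writeTempCsv(data.frame(id = c("P1", "P1"), target = c(0, 1)))
  expect_error(readGroupFile(f), "P1", class = "phewas_validation_error")
  f2 <- writeTempCsv(data.frame(subject = c("P1"), target = 1))
  expect_error(readGroupFile(f2), class = "phewas_format_error")
})

test_that("EHR file parses row-per-record with validation", {
  f <- writeTempCsv(data.frame(id = c("P1", "P2", "P1", "P3", "P2"),
                               ICD_CODE = c("314.01", "f90.0", "314.01",
                                            "008.45", "F90.0"),
                               ICD_TYPE = c(9, 10, 9, 9, 10),
                               AgeAtICD = c(8.3, 9, 8.5, 40, 10)))
  rec <- readEhrFile(f)
  expect_equal(nrow(rec), 5)  # cardinality preserved
  expect_equal(rec$icd_code[1], "314.01")
  expect_equal(rec$icd_code[2], "F90.0")  # normalized on read
  expect_equal(rec$age[1], 8.3)

  bad <- writeTempCsv(data.frame(id = "P1", ICD_CODE = "314.01",
                                 ICD_TYPE = 9, AgeAtICD = -1))
  expect_error(readEhrFile(bad), "row", class = "phewas_validation_error")
  badv <- writeTempCsv(data.frame(id = "P1", ICD_CODE = "314.01",
                                  ICD_TYPE = 8, AgeAtICD = 1))
  expect_error(readEhrFile(badv), "9", class = "phewas_validation_error")
})

test_that("phecode map reads, rejects conflicts, and answers lookups", {
  f <- writeTempCsv(tinyMap()[1:2, ])
  m <- readPhecodeMap(f)
  expect_equal(nrow(m), 2)
  expect_equal(length(unique(m$phecode)), 1)

  conflict <- tinyMap()
  conflict$phecode[2] <- "999.0"
  conflict$icd_version[2] <- 9
  conflict$icd_code[2] <- "314.01"  # same key as row 1, other phecode
  f2 <- writeTempCsv(conflict)
  expect_error(readPhecodeMap(f2), class = "phewas_validation_error")

  info <- phecodeInfo(readPhecodeMap(writeTempCsv(tinyMap())), "313.1")
  expect_equal(info$category, "mental disorders")
})

makeResults <- function(p = c(0.5, 0.001, 0.02)) {
  n <- length(p)
  beta <- seq(0.1, by = 0.1, length.out = n) * 3.1459
  df <- S4Vectors::DataFrame(
    phecode = sprintf("%03d.1", seq_len(n)), description = "d",
    category = "c", beta = beta, se = 0.1, ci_low = beta - 0.196,
    ci_high = beta + 0.196, p_value = p, n_subjects = 10L,
    converged = TRUE, model_family = "logistic")
  new("PhewasResults", results = df,
      model = phewasModel("t"),
      skipLog = S4Vectors::DataFrame(phecode = character(0),
                                     reason = character(0)))
}

test_that("result table is written sorted by p and round-trips exactly", {
  r <- makeResults(c(0.5, 0.001, 0.02))
  f <- withr::local_tempfile(fileext = ".csv")
  writeResultTable(r, f)
  back <- readResultTable(f)
  expect_equal(back$p_value, c(0.001, 0.02, 0.5))
  orig <- resultsTable(r)
  m <- match(back$phecode, orig$phecode)
  expect_true(all(abs(back$coefficient - orig$beta[m]) <=
                    1e-12 * abs(orig$beta[m])))
  expect_identical(back$coefficient, orig$beta[m])  # bit-exact round trip
})

test_that("empty result set refuses to write", {
  empty <- new("PhewasResults",
               results = S4Vectors::DataFrame(
                 phecode = character(0), description = character(0),
                 category = character(0), beta = numeric(0),
                 se = numeric(0), ci_low = numeric(0),
                 ci_high = numeric(0), p_value = numeric(0),
                 n_subjects = integer(0), converged = logical(0),
                 model_family = character(0)),
               model = phewasModel("t"),
               skipLog = S4Vectors::DataFrame(phecode = character(0),
                                              reason = character(0)))
  f <- withr::local_tempfile(fileext = ".csv")
  expect_error(writeResultTable(empty, f), class = "phewas_validation_error")
})

test_that("cache round-trips bit-exactly and detects staleness", {
  st <- smallStudy(n = 40, nPhecodes = 5, logOR = 0, seed = 9)
  dir <- withr::local_tempdir()
  input <- writeTempCsv(data.frame(id = "P1", x = 1))
  cacheFeatureMatrices(st$pe, dir, inputs = input)
  back <- loadFeatureMatrices(dir, inputs = input)
  expect_identical(binaryAssay(back), binaryAssay(st$pe))
  expect_identical(countAssay(back), countAssay(st$pe))
  expect_identical(durationAssay(back), durationAssay(st$pe))
  expect_identical(phecodes(back), phecodes(st$pe))
  expect_identical(patients(back), patients(st$pe))
  expect_equal(as.data.frame(SummarizedExperiment::colData(back)),
               as.data.frame(SummarizedExperiment::colData(st$pe)))

  # schema version bump -> stale-cache error, never silent reuse
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  meta$schema_version <- 0
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  expect_error(loadFeatureMatrices(dir, inputs = input),
               class = "phewas_stale_cache_error")

  # restore version, then change an input file -> checksum mismatch
  meta$schema_version <- 1
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  expect_silent(invisible(loadFeatureMatrices(dir, inputs = input)))
  cat("tweak\n", file = input, append = TRUE)
  expect_error(loadFeatureMatrices(dir, inputs = input),
               class = "phewas_stale_cache_error")
})

test_that("cache round-trip is an identity on random small experiments", {
  for (seed in c(2, 3)) {
    st <- smallStudy(n = 25, nPhecodes = 3, logOR = 0, seed = seed)
    dir <- withr::local_tempdir()
    cacheFeatureMatrices(st$pe, dir)
    back <- loadFeatureMatrices(dir)
    expect_identical(durationAssay(back), durationAssay(st$pe))
    expect_identical(countAssay(back), countAssay(st$pe))
  }
})
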