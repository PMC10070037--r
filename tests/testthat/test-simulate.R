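# The seeded synthetic-study generator.

test_that("the map fixture has the requested phecodes and categories", {
  m <- generateMapFixture(simSpec(nPhecodes = 10, nCategories = 3))
  expect_equal(length(unique(m$phecode)), 10)
  expect_equal(length(unique(m$category)), 3)
  # every phecode has both an ICD-9 and an ICD-10 synonym
  byPhe <- split(m$icd_version, m$phecode)
  expect_true(all(vapply(byPhe, function(v) all(c(9, 10) %in% v),
                         logical(1))))
  # many-to-one entries exist and keys are unique
  expect_true(any(vapply(byPhe, length, integer(1)) > 2))
  expect_equal(anyDuplicated(paste(m$icd_version, m$icd_code)), 0)
})

test_that("generation is deterministic: byte-identical files per seed", {
  spec <- simSpec(nPatients = 60, nPhecodes = 5, seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulatePhewasStudy(spec, d1)
  simulatePhewasStudy(spec, d2)
  for (f in c("group.csv", "ehr.csv", "phecode_map.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  d3 <- withr::local_tempdir()
  simulatePhewasStudy(simSpec(nPatients = 60, nPhecodes = 5, seed = 78), d3)
  expect_false(identical(readLines(file.path(d1, "ehr.csv")),
                         readLines(file.path(d3, "ehr.csv"))))
})

test_that("generated files parse cleanly with zero drops at orphan 0", {
  spec <- simSpec(nPatients = 50, nPhecodes = 6, seed = 19)
  dir <- withr::local_tempdir()
  out <- simulatePhewasStudy(spec, dir)
  group <- readGroupFile(out$paths$group)
  ehr <- readEhrFile(out$paths$ehr)
  map <- readPhecodeMap(out$paths$map)
  expect_equal(nrow(group), 50)
  mapped <- mapRecords(ehr, map)
  expect_equal(mapped$droppedCount, 0)
  expect_equal(nrow(mapped$records), nrow(ehr))
})

test_that("orphan records are dropped in the ground-truth quantity", {
  spec <- simSpec(nPatients = 80, nPhecodes = 5, orphanFraction = 0.15,
                  seed = 20)
  map <- generateMapFixture(spec)
  group <- generateCohort(spec)
  ehr <- generateEhr(group, map, spec)
  expect_gt(attr(ehr, "nOrphan"), 0)
  mapped <- mapRecords(ehr, map)
  expect_equal(mapped$droppedCount, attr(ehr, "nOrphan"))
  expect_equal(nrow(mapped$records) + mapped$droppedCount, nrow(ehr))
})

test_that("matched mode clones sex and jitters age within tolerance", {
  spec <- simSpec(nPatients = 200, matchedDesign = TRUE,
                  matchTolerance = 0.1, seed = 21)
  g <- generateCohort(spec)
  expect_equal(sum(g$target), 100)
  s <- variableSummary(g$sex, g$target)
  expect_identical(s$counts1, s$counts0)  # identical per-group histograms
  # every control's minimum visit age is within tolerance of its case twin
  caseAge <- g$MinAgeAtVisit[g$target == 1]
  ctrlAge <- g$MinAgeAtVisit[g$target == 0]
  expect_true(all(abs(ctrlAge - caseAge) <= 0.1 + 1e-12))
})

test_that("a target-shifted demographic moves the group mean as specified", {
  shift <- 0.8
  spec <- simSpec(nPatients = 1500, seed = 25,
                  demographics = list(
                    sex = list(type = "binary", p = 0.5),
                    deprivation_index = list(type = "normal", mean = 0,
                                             sd = 1, targetShift = shift)))
  g <- generateCohort(spec)
  d1 <- g$deprivation_index[g$target == 1]
  d0 <- g$deprivation_index[g$target == 0]
  se <- sqrt(1 / length(d1) + 1 / length(d0))
  expect_lt(abs((mean(d1) - mean(d0)) - shift), 3 * se)
})

test_that("synonym choice never changes the binary matrix", {
  spec <- simSpec(nPatients = 60, nPhecodes = 6, seed = 33)
  map <- generateMapFixture(spec)
  group <- generateCohort(spec)
  ehr <- generateEhr(group, map, spec)
  mapped <- mapRecords(ehr, map)
  b1 <- aggregateBinary(mapped$records, group$id, sort(unique(map$phecode)))
  # rewrite every record to the first synonym of its phecode: the phecode
  # identity, hence the binary matrix, is unchanged
  firstSyn <- map[!duplicated(map$phecode), ]
  idx <- match(mapped$records$phecode, firstSyn$phecode)
  ehr2 <- data.frame(id = mapped$records$id,
                     icd_code = firstSyn$icd_code[idx],
                     icd_version = firstSyn$icd_version[idx],
                     age = mapped$records$age)
  mapped2 <- mapRecords(ehr2, map)
  b2 <- aggregateBinary(mapped2$records, group$id, sort(unique(map$phecode)))
  expect_identical(b1, b2)
})

test_that("single-record cells give an all-zero duration matrix", {
  spec <- simSpec(nPatients = 40, nPhecodes = 4, countIntensity = 0,
                  seed = 27)
  map <- generateMapFixture(spec)
  group <- generateCohort(spec)
  ehr <- generateEhr(group, map, spec)
  mapped <- mapRecords(ehr, map)
  pe <- buildPhewasExperiment(mapped$records, group, map)
  expect_true(all(countAssay(pe) <= 1))
  expect_true(all(durationAssay(pe) == 0))
})
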