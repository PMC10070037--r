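# Shared fixtures built in code; nothing on disk.

options(phewasKit.verbose = FALSE)

writeTempCsv <- function(df, env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

# Minimal two-entry map: one ICD-9 and one ICD-10 code for the same
# ADHD-style phecode plus an unrelated code.
tinyMap <- function() {
  data.frame(
    icd_version = c(9, 10, 9),
    icd_code = c("314.01", "F90.0", "008.45"),
    phecode = c("313.1", "313.1", "008.5"),
    description = c("Attention deficit disorder",
                    "Attention deficit disorder",
                    "Intestinal infection"),
    category = c("mental disorders", "mental disorders",
                 "infectious diseases"),
    stringsAsFactors = FALSE)
}

# Random phecode-record set plus axes, for brute-force aggregation oracles.
randomPheRecords <- function(nPatients = 12, nPhecodes = 4, nRecords = 60,
                             seed = 1) {
  withr::with_seed(seed, {
    patients <- sprintf("P%02d", seq_len(nPatients))
    codes <- sprintf("%05.1f", seq_len(nPhecodes) + 100)
    list(records = data.frame(
           id = sample(patients, nRecords, replace = TRUE),
           phecode = sample(codes, nRecords, replace = TRUE),
           age = round(runif(nRecords, 1, 60), 2),
           stringsAsFactors = FALSE),
         patients = patients, phecodes = codes)
  })
}

# Independent per-cell brute-force scan of the three aggregation rules.
bruteAggregate <- function(records, patients, phecodes, scheme) {
  m <- matrix(0, length(phecodes), length(patients),
              dimnames = list(phecodes, patients))
  for (i in seq_along(phecodes)) {
    for (j in seq_along(patients)) {
      ages <- records$age[records$id == patients[j] &
                            records$phecode == phecodes[i]]
      m[i, j] <- switch(scheme,
        binary = as.numeric(length(ages) >= 1),
        count = length(ages),
        duration = if (length(ages) >= 1) max(ages) - min(ages) else 0)
    }
  }
  m
}

# A small experiment with one injected presence effect, used across the
# regression and reporting tests.
smallStudy <- function(n = 300, nPhecodes = 6, logOR = c(1.2, rep(0, 5)),
                       seed = 42) {
  spec <- simSpec(nPatients = n, nPhecodes = nPhecodes, logOR = logOR,
                  seed = seed)
  map <- generateMapFixture(spec)
  group <- generateCohort(spec)
  ehr <- generateEhr(group, map, spec)
  mapped <- mapRecords(ehr, map)
  list(spec = spec, map = map, group = group, ehr = ehr,
       pe = buildPhewasExperiment(mapped$records, group, map))
}
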