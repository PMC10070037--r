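# Seeded synthetic-EHR generator: group demographics, ICD event records and
# a fixture PheCode map with known injected statistical structure, so every
# pipeline stage is testable without access to restricted clinical data.

PHECODE_CATEGORIES <- c(
  "circulatory system", "congenital anomalies", "dermatologic", "digestive",
  "endocrine/metabolic", "genitourinary", "hematopoietic",
  "infectious diseases", "injuries & poisonings", "mental disorders",
  "musculoskeletal", "neoplasms", "neurological", "pregnancy complications",
  "respiratory", "sense organs", "symptoms", "other")

#' Specify a synthetic PheWAS study
#'
#' Collects every knob of the generator; the defaults describe a matched
#' case-control paediatric cohort of 2000 patients and 50 PheCodes with no
#' injected effects (a global null). All randomness is fixed by `seed`.
#'
#' @param nPatients number of patients
#' @param caseFraction fraction with target = 1
#' @param nPhecodes number of distinct PheCodes in the fixture map
#' @param nCategories number of PheCode categories cycled over the codes
#'   (default 18, the size of the standard category set)
#' @param baselinePrev per-PheCode baseline presence probability among
#'   controls (scalar recycled)
#' @param logOR per-PheCode injected log-odds of presence for target = 1
#'   versus target = 0 (scalar recycled; 0 = null)
#' @param countIntensity Poisson mean of extra records per positive
#'   patient-PheCode cell (records per positive cell = 1 + Poisson)
#' @param countMultiplier multiplies the count intensity for cases, to
#'   inject count-channel effects
#' @param durationMultiplier scales the fraction of the visit window over
#'   which a case's records are spread (capped at the full window), to
#'   inject duration-channel effects
#' @param orphanFraction fraction of EHR records rewritten to an ICD code
#'   absent from the map, exercising the unmapped-record drop path
#' @param ageRange range (years) of the minimum age at visit
#' @param visitSpan range (years) of the visit-window length
#' @param demographics named list of extra group-variable specs; each is
#'   `list(type = "binary", p = ...)` or
#'   `list(type = "normal", mean = ..., sd = ..., targetShift = ...)`
#' @param matchedDesign clone each control from a case (same sex, minimum
#'   visit age jittered within `matchTolerance`), emulating a 1:1 matched
#'   cohort; requires `caseFraction = 0.5`
#' @param matchTolerance jitter half-width (years) in matched mode
#' @param seed integer fixing all randomness
#' @return a `SimSpec` list
#' @export
simSpec <- function(nPatients = 2000, caseFraction = 0.5, nPhecodes = 50,
                    nCategories = 18, baselinePrev = 0.2, logOR = 0,
                    countIntensity = 2, countMultiplier = 1,
                    durationMultiplier = 1, orphanFraction = 0,
                    ageRange = c(4, 12), visitSpan = c(2, 8),
                    demographics = list(
                      sex = list(type = "binary", p = 0.5),
                      deprivation_index = list(type = "normal", mean = 0,
                                               sd = 1, targetShift = 0)),
                    matchedDesign = FALSE, matchTolerance = 0.1, seed = 1L) {
  stopifnot(nPhecodes >= 1, nCategories <= max(nPhecodes, 18))
  spec <- list(nPatients = nPatients, caseFraction = caseFraction,
               nPhecodes = nPhecodes, nCategories = nCategories,
               baselinePrev = rep_len(baselinePrev, nPhecodes),
               logOR = rep_len(logOR, nPhecodes),
               countIntensity = rep_len(countIntensity, nPhecodes),
               countMultiplier = countMultiplier,
               durationMultiplier = durationMultiplier,
               orphanFraction = orphanFraction, ageRange = ageRange,
               visitSpan = visitSpan, demographics = demographics,
               matchedDesign = matchedDesign,
               matchTolerance = matchTolerance, seed = as.integer(seed))
  if (any(spec$baselinePrev <= 0 | spec$baselinePrev >= 1)) {
    phewasStop("baselinePrev must lie in (0, 1)")
  }
  if (caseFraction <= 0 || caseFraction >= 1) {
    phewasStop("caseFraction must lie in (0, 1)")
  }
  if (orphanFraction < 0 || orphanFraction > 1) {
    phewasStop("orphanFraction must lie in [0, 1]")
  }
  structure(spec, class = "SimSpec")
}

#' Generate a fixture ICD-to-PheCode map
#'
#' Deterministically constructs `nPhecodes` synthetic PheCodes, each with
#' one ICD-9 and one ICD-10 synonym (every third PheCode gets a second
#' ICD-9 code, exercising many-to-one mapping), descriptions, and
#' categories cycled over the first `nCategories` standard category names.
#' The orphan ICD code used by [generateEhr()] (version 9, code `999.99`)
#' is deliberately absent from the table.
#'
#' @param spec a [simSpec()]
#' @return a PheCode map data.frame as from [readPhecodeMap()]
#' @export
generateMapFixture <- function(spec) {
  i <- seq_len(spec$nPhecodes)
  phe <- sprintf("%03d.1", 100 + i)
  desc <- sprintf("synthetic phenotype %d", i)
  cats <- rep_len(PHECODE_CATEGORIES[seq_len(min(spec$nCategories,
                                                 length(PHECODE_CATEGORIES)))],
                  spec$nPhecodes)
  icd9 <- sprintf("%03d.01", 100 + i)
  icd10 <- sprintf("%s%02d.0", LETTERS[(i - 1L) %% 26L + 1L],
                   (i - 1L) %/% 26L + 10L)
  rows <- list(
    data.frame(icd_version = 9, icd_code = icd9, phecode = phe,
               description = desc, category = cats,
               stringsAsFactors = FALSE),
    data.frame(icd_version = 10, icd_code = icd10, phecode = phe,
               description = desc, category = cats,
               stringsAsFactors = FALSE))
  syn <- which(i %% 3L == 0L)
  if (length(syn)) {
    rows[[3]] <- data.frame(icd_version = 9,
                            icd_code = sprintf("%03d.02", 100 + syn),
                            phecode = phe[syn], description = desc[syn],
                            category = cats[syn], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

drawDemographic <- function(d, n, target) {
  switch(d$type,
    binary = stats::rbinom(n, 1, d$p),
    normal = stats::rnorm(n, d$mean + (d$targetShift %||% 0) * target, d$sd),
    phewasStop(sprintf("unknown demographic type '%s'", d$type)))
}

#' Generate a synthetic group demographics table
#'
#' Draws the binary target at `caseFraction`, the visit-age window
#' (`MinAgeAtVisit`, `MaxAgeAtVisit`) and the configured demographic
#' variables. In matched-design mode each control is cloned from a case:
#' identical sex, minimum visit age jittered uniformly within
#' `matchTolerance` — so a feasible 1:1 control always exists and the group
#' emulates a matched cohort.
#'
#' @param spec a [simSpec()]
#' @return group data.frame (`id`, `target`, demographics,
#'   `MinAgeAtVisit`, `MaxAgeAtVisit`)
#' @export
generateCohort <- function(spec) {
  withr::with_seed(spec$seed + 1L, {
    n <- spec$nPatients
    if (spec$matchedDesign) {
      if (abs(spec$caseFraction - 0.5) > 1e-9) {
        phewasStop("matchedDesign requires caseFraction = 0.5")
      }
      nCase <- floor(n / 2)
      nCtrl <- n - nCase
      sexCase <- stats::rbinom(nCase, 1, spec$demographics$sex$p %||% 0.5)
      minACase <- stats::runif(nCase, spec$ageRange[1], spec$ageRange[2])
      jit <- stats::runif(nCtrl, -spec$matchTolerance, spec$matchTolerance)
      target <- c(rep(1, nCase), rep(0, nCtrl))
      sex <- c(sexCase, rep_len(sexCase, nCtrl))
      minA <- c(minACase, rep_len(minACase, nCtrl) + jit)
      minA <- pmax(minA, 0)
    } else {
      target <- stats::rbinom(n, 1, spec$caseFraction)
      sex <- stats::rbinom(n, 1, spec$demographics$sex$p %||% 0.5)
      minA <- stats::runif(n, spec$ageRange[1], spec$ageRange[2])
    }
    span <- stats::runif(n, spec$visitSpan[1], spec$visitSpan[2])
    out <- data.frame(id = sprintf("P%05d", seq_len(n)), target = target,
                      sex = sex, MinAgeAtVisit = minA,
                      MaxAgeAtVisit = minA + span,
                      stringsAsFactors = FALSE)
    for (nm in setdiff(names(spec$demographics), "sex")) {
      out[[nm]] <- drawDemographic(spec$demographics[[nm]], n, target)
    }
    out
  })
}

#' Generate synthetic EHR records
#'
#' For every patient x PheCode cell, presence is drawn with probability
#' `plogis(qlogis(baselinePrev) + logOR * target)` — the injected effect
#' lives on the presence (binary) channel, so a covariate-free logistic
#' PheWAS recovers `logOR` directly. Present cells receive
#' `1 + Poisson(countIntensity * countMultiplier^target)` records with ages
#' uniform over the patient's visit window (scaled by `durationMultiplier`
#' for cases, capped at the full window); each record's ICD code is drawn
#' among the PheCode's synonym codes. With probability `orphanFraction` a
#' record's code is rewritten to the unmapped orphan code `999.99` (ICD-9);
#' the number of such records — the ground truth for the drop count — is
#' attached as attribute `nOrphan`.
#'
#' @param group group table from [generateCohort()]
#' @param map fixture map from [generateMapFixture()]
#' @param spec a [simSpec()]
#' @return data.frame of ICD records (`id`, `icd_code`, `icd_version`,
#'   `age`) with attribute `nOrphan`
#' @export
generateEhr <- function(group, map, spec) {
  withr::with_seed(spec$seed + 2L, {
    n <- nrow(group)
    phe <- unique(map$phecode)
    stopifnot(length(phe) == spec$nPhecodes)
    target <- group$target
    # durationMultiplier > 1 widens the case window relative to controls by
    # shrinking the control window; < 1 shrinks the case window. Either way
    # no record leaves the patient's visit window.
    dm <- spec$durationMultiplier
    wFrac <- ifelse(target == 1, min(1, dm), min(1, 1 / dm))
    lo <- group$MinAgeAtVisit
    w <- (group$MaxAgeAtVisit - lo) * wFrac
    parts <- vector("list", length(phe))
    for (j in seq_along(phe)) {
      p <- stats::plogis(stats::qlogis(spec$baselinePrev[j]) +
                           spec$logOR[j] * target)
      pos <- which(stats::rbinom(n, 1, p) == 1L)
      if (!length(pos)) next
      lam <- spec$countIntensity[j] * spec$countMultiplier^target[pos]
      k <- 1L + stats::rpois(length(pos), lam)
      pi <- rep(pos, k)
      ages <- lo[pi] + stats::runif(length(pi)) * w[pi]
      syn <- map[map$phecode == phe[j], c("icd_version", "icd_code")]
      pick <- sample.int(nrow(syn), length(pi), replace = TRUE)
      parts[[j]] <- data.frame(id = group$id[pi],
                               icd_code = syn$icd_code[pick],
                               icd_version = syn$icd_version[pick],
                               age = ages, stringsAsFactors = FALSE)
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    out <- if (length(parts)) do.call(rbind, parts) else {
      data.frame(id = character(0), icd_code = character(0),
                 icd_version = numeric(0), age = numeric(0))
    }
    nOrphan <- 0L
    if (spec$orphanFraction > 0 && nrow(out)) {
      orphan <- stats::runif(nrow(out)) < spec$orphanFraction
      out$icd_code[orphan] <- "999.99"
      out$icd_version[orphan] <- 9
      nOrphan <- sum(orphan)
    }
    rownames(out) <- NULL
    attr(out, "nOrphan") <- as.integer(nOrphan)
    out
  })
}

#' Generate and write a complete synthetic study
#'
#' Runs the three generators and writes `group.csv`, `ehr.csv` (file
#' dialect columns `id`, `ICD_CODE`, `ICD_TYPE`, `AgeAtICD`) and
#' `phecode_map.csv` into `dir`, plus `sim_meta.json` recording the ground
#' truth (injected effects, orphan record count). Byte-identical across
#' runs for a fixed spec.
#'
#' @param spec a [simSpec()]
#' @param dir output directory (created if needed)
#' @return invisible list with the three file paths, the in-memory objects
#'   and `nOrphan`
#' @export
simulatePhewasStudy <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  map <- generateMapFixture(spec)
  group <- generateCohort(spec)
  ehr <- generateEhr(group, map, spec)
  paths <- list(group = file.path(dir, "group.csv"),
                ehr = file.path(dir, "ehr.csv"),
                map = file.path(dir, "phecode_map.csv"))
  gOut <- group
  for (col in names(gOut)) {
    if (is.double(gOut[[col]])) gOut[[col]] <- formatFull(gOut[[col]])
  }
  utils::write.csv(gOut, paths$group, row.names = FALSE, quote = FALSE)
  eOut <- data.frame(id = ehr$id, ICD_CODE = ehr$icd_code,
                     ICD_TYPE = ehr$icd_version,
                     AgeAtICD = formatFull(ehr$age),
                     stringsAsFactors = FALSE)
  utils::write.csv(eOut, paths$ehr, row.names = FALSE, quote = FALSE)
  utils::write.csv(map, paths$map, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = spec$seed, n_patients = spec$nPatients,
         n_phecodes = spec$nPhecodes, log_or = spec$logOR,
         baseline_prev = spec$baselinePrev,
         orphan_records = attr(ehr, "nOrphan")),
    file.path(dir, "sim_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, map = map, group = group, ehr = ehr,
                 nOrphan = attr(ehr, "nOrphan")))
}
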