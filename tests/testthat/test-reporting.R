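# Volcano, effect-size and table payloads plus cross-view linking.

reportFixture <- function() {
  st <- smallStudy(n = 400, nPhecodes = 8,
                   logOR = c(1.5, 1.0, rep(0, 6)), seed = 47)
  r <- runPhewas(st$pe, phewasModel("target"))
  list(results = r, thresholds = classifySignificance(r))
}

resultsFromPReporting <- function(p) {
  n <- length(p)
  df <- S4Vectors::DataFrame(
    phecode = sprintf("%03d.1", 100 + seq_len(n)), description = "d",
    category = rep_len(c("mental disorders", "respiratory"), n),
    beta = 0.5, se = 0.1, ci_low = 0.3, ci_high = 0.7, p_value = p,
    n_subjects = 10L, converged = TRUE, model_family = "logistic")
  new("PhewasResults", results = df, model = phewasModel("t"),
      skipLog = S4Vectors::DataFrame(phecode = character(0),
                                     reason = character(0)))
}

test_that("volcano y is -log10(p) with class pass-through and capping", {
  fx <- reportFixture()
  v <- volcanoPayload(fx$results, fx$thresholds)
  r <- resultsTable(fx$results)
  m <- match(v$phecode, r$phecode)
  expect_equal(v$neg_log10_p, -log10(r$p_value[m]))
  expect_identical(v$class,
                   unname(significanceClasses(fx$thresholds)[v$phecode]))

  # hand values and the underflow cap
  p1 <- resultsFromPReporting(c(0.001, 1, 1e-320))
  th <- classifySignificance(p1)
  v2 <- volcanoPayload(p1, th)
  expect_equal(v2$neg_log10_p[1], 3.0)
  expect_equal(v2$neg_log10_p[2], 0)
  expect_equal(v2$neg_log10_p[3], 300)
  expect_true(v2$capped[3])
  expect_false(any(v2$capped[1:2]))
})

test_that("effect payload filters by the selected threshold", {
  # p chosen so classes are {bonferroni, fdr, insignificant} at alpha 0.05
  r <- resultsFromPReporting(c(0.001, 0.03, 0.9))
  th <- classifySignificance(r, alpha = 0.05)
  expect_equal(unname(significanceClasses(th)),
               c("bonferroni", "fdr", "insignificant"))
  eFdr <- effectPlotPayload(r, th, "fdr")
  eBon <- effectPlotPayload(r, th, "bonferroni")
  expect_equal(nrow(eFdr), 2)
  expect_equal(nrow(eBon), 1)
  expect_true(all(eBon$phecode %in% eFdr$phecode))
})

test_that("the fdr payload always contains the bonferroni payload", {
  withr::with_seed(83, {
    for (i in 1:25) {
      r <- resultsFromPReporting(runif(12)^3)
      th <- classifySignificance(r)
      eF <- effectPlotPayload(r, th, "fdr")
      eB <- effectPlotPayload(r, th, "bonferroni")
      expect_true(all(eB$phecode %in% eF$phecode))
    }
  })
})

test_that("effect entries are ordered by category then effect size", {
  fx <- reportFixture()
  e <- effectPlotPayload(fx$results, fx$thresholds, "fdr")
  if (nrow(e) > 1) {
    expect_true(!is.unsorted(e$category))
    for (ct in unique(e$category)) {
      expect_true(!is.unsorted(e$beta[e$category == ct]))
    }
  }
  # deterministic category indices follow the sorted category names
  cats <- sort(unique(resultsTable(fx$results)$category))
  expect_equal(e$category_index, match(e$category, cats) - 1L)
})

test_that("the three views are consistent projections of one result set", {
  fx <- reportFixture()
  tab <- tablePayload(fx$results, fx$thresholds)
  v <- volcanoPayload(fx$results, fx$thresholds)
  e <- effectPlotPayload(fx$results, fx$thresholds, "fdr")
  expect_true(!is.unsorted(tab$p_value, na.rm = TRUE))  # sorted table
  shared <- intersect(tab$phecode, v$phecode)
  expect_equal(tab$beta[match(shared, tab$phecode)],
               v$beta[match(shared, v$phecode)])
  for (ph in e$phecode) {
    expect_equal(e$beta[e$phecode == ph], tab$beta[tab$phecode == ph])
  }
})

test_that("linked selection locates a phecode across views", {
  fx <- reportFixture()
  payloads <- list(table = tablePayload(fx$results, fx$thresholds),
                   volcano = volcanoPayload(fx$results, fx$thresholds),
                   effects = effectPlotPayload(fx$results, fx$thresholds,
                                               "fdr"))
  sig <- payloads$effects$phecode[1]
  loc <- linkedSelection(sig, payloads)
  expect_true(all(vapply(loc, `[[`, logical(1), "present")))

  insig <- setdiff(payloads$volcano$phecode, payloads$effects$phecode)[1]
  loc2 <- linkedSelection(insig, payloads)
  expect_true(loc2$table$present && loc2$volcano$present)
  expect_false(loc2$effects$present)

  expect_error(linkedSelection("nope", payloads),
               class = "phewas_not_found_error")
})

test_that("report payload files are valid, versioned JSON", {
  fx <- reportFixture()
  dir <- withr::local_tempdir()
  paths <- writeReportPayloads(fx$results, fx$thresholds, dir)
  expect_true(all(file.exists(unlist(paths))))
  vol <- jsonlite::read_json(paths$volcano)
  expect_equal(vol$schema_version, 1)
  expect_equal(length(vol$points), nrow(resultsTable(fx$results)))
  eff <- jsonlite::read_json(paths$effects)
  expect_equal(eff$selected, "fdr")
})
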