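---
title: "Methods: the phewasKit PheWAS engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the phewasKit PheWAS engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phewasKit)
options(phewasKit.verbose = FALSE)
```

## The model

A phenome-wide association study inverts the usual association design: one
binary target variable is tested against every phenotype derivable from a
cohort's EHR. phewasKit implements the four-stage procedure — map ICD
events to PheCodes, aggregate per patient, run one regression per PheCode,
correct and visualize — as composable functions around a
`SummarizedExperiment`-derived container, the `PhewasExperiment`, whose
three assays hold the binary, count and duration feature matrices and
whose `colData` carries the group demographics.

Per PheCode $j$ with aggregated value $x_j$ and covariates $c$, the engine
fits, depending on the model specification:

* target as **dependent** variable (always logistic):
  $\mathrm{logit}\,P(y=1) = \beta_0 + \beta x_j + \gamma^\top c$;
* target as **predictor**: $x_j = \beta_0 + \beta y + \gamma^\top c$,
  logistic when the aggregation is binary (the outcome is 0/1) and
  ordinary least squares otherwise, since count and duration outcomes are
  nonbinary.

The reported effect size is always the coefficient linking the PheCode to
the target: the $x_j$ coefficient in the dependent form, the $y$
coefficient in the predictor form (the latter convention is stated in the
run metadata, since "the" effect size is ambiguous when the target sits on
the right-hand side). Inference is Wald throughout: a 95% interval
$\hat\beta \pm 1.959964\,\widehat{se}$ and a two-sided normal p-value, for
the linear family as well — at the sample sizes where a PheWAS is
meaningful the $t$ vs normal distinction is negligible, and one inferential
convention across thousands of fits keeps the result table homogeneous.
Wald rather than profile-likelihood intervals is the standard PheWAS
trade-off: at $10^3$–$10^4$ fits per run, profile intervals cost far more
and change little for the moderate effects of interest.

The per-PheCode fits assume independent subjects, no separation, and —
for the linear family — homoscedastic residuals; none of these is checked
per fit, which is why the covariate diagnostics exist upstream and why
non-convergence is flagged rather than repaired (see below).

## Assumptions encoded in preprocessing

ICD codes are normalized by trimming and upper-casing only; lookup into
the mapping table is exact-match. An unmapped child code (say `F90.1`
missing from a table that has `F90`) is **dropped, not rolled up** to its
parent: rollup would silently inflate counts, and dropping matches how
incomplete mapping tables are handled in practice. Drops are tallied
per code and logged; the conservation identity (records in = mapped +
dropped) is enforced by construction and tested.

Duplicate EHR rows — same patient, code and age — are kept. They plausibly
represent repeat billing, they are real signal for the count aggregation,
and removing them would be an irreversible judgement the data do not
support. The duplicate tally is logged so users can audit it.

A patient whose PheCode occurs exactly once has duration 0, the unambiguous
degenerate value of "time between first and last occurrence". A
consequence worth knowing: duration-aggregation effect estimates for rare
codes shrink toward zero, because most carriers contribute 0.

The PheCode axis of the feature matrices defaults to the codes actually
observed in the mapped records; an all-zero column cannot be fitted anyway.
`phecodeSet = "table"` restores the full table axis when a fixed phenome
is wanted.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.05 | — | conventional level; enters both corrections |
| `minSubjects` | 5 | patients | fits on 1–4 carriers are unstable and uninformative; 0 disables |
| `bins` (histograms) | 20 | bins | equal-width over the pooled range so both target groups share edges; binary variables always get 2 |
| joint grid | 10×10 | bins | coarse enough to read, fine enough to show overlap |
| match tolerance | user-set | variable units | e.g. minimum visit age ±0.1 years |
| `mPolicy` | `"fitted"` | — | the correction denominator is the number of fitted PheCodes; `"table"` substitutes the full table size (e.g. 1866) for a stricter familywise guarantee; both values are logged |
| significance colours | p<0.05, p<0.1 | — | diagnostic blocks only; configurable |

Boundary p-values count as passing (`<=`, not `<`) for both thresholds —
an explicit, tested convention so that a p-value exactly equal to
$\alpha/m$ is classed Bonferroni.

Correlation in the diagnostics is Pearson everywhere (point-biserial
against the binary target, phi when both variables are binary), with the
choice recorded in the report metadata: the diagnostic is a screening
device, and Pearson's interpretation as the regression-relevant linear
association is what the multicollinearity test needs.

## Numerical choices

* **Separation.** `glm`'s own convergence flag passes under complete
  separation (the IRLS deviance stabilizes while the MLE diverges), so a
  logistic fit is additionally declared non-converged when any coefficient
  exceeds 15 in absolute value or any standard error exceeds 100 — log-odds
  beyond ±15 are indistinguishable from infinity at EHR scale. Such fits
  keep their row in the saved table with empty statistics and are excluded
  from plots; there is deliberately no penalized fallback, which would
  change the meaning of $\beta$ mid-table.
* **Aliased designs** (e.g. a duplicated covariate) are flagged
  non-identifiable, never silently dropped to a sub-model.
* **Underflow.** $-\log_{10} p$ is capped at 300 with a flag.
* **Full-precision text.** All numeric output (result table, cache) is
  written with `%.17g`, which round-trips IEEE-754 doubles exactly; the
  write-then-read identity is tested bit-for-bit.
* **Determinism.** Fitting has no randomness; identical inputs and
  configuration produce byte-identical artifacts. The only seeded
  components are the generator and the case-shuffling step of matching.

## Cohort construction

Cases are patients whose record count over a set of qualifying ICD codes
reaches a threshold. The threshold **pools counts across the code set** by
default (two records of one code plus one of a synonym qualify at
threshold 3): the code set exists precisely because the codes are
clinically synonymous, and versions of the same diagnosis split across
ICD-9/ICD-10 eras would otherwise be missed. `perCode = TRUE` provides the
strict single-code reading.

Matching is greedy: cases in a seed-shuffled order each take the eligible
control (exact keys equal, tolerance keys within band) at the smallest
tolerance distance, ties broken by control id. Greedy alone can strand a
feasible case — a neighbour may take the only admissible control — so any
stranded case triggers an iterative augmenting-path search over the
eligibility graph, which reassigns controls along an alternating path.
Greedy-plus-augmenting returns a complete matching whenever one exists
(it is Kuhn's maximum bipartite matching seeded with the greedy solution)
while keeping the greedy solution's nearest-neighbour character for the
bulk of cases. Globally distance-optimal assignment is a non-goal; the
matched sets it produces differ only in which of several admissible
controls is used.

## What the generator emulates — and what it does not

`simSpec()` describes a paediatric matched case-control study: by default
2000 patients, half cases, visit windows of 2–8 years starting at ages
4–12, a sex covariate, a continuous deprivation-index-like covariate with
an optional target-dependent shift, and 50 PheCodes cycled over the 18
standard category names with ICD-9 and ICD-10 synonyms (some many-to-one).
Presence of PheCode $j$ in patient $i$ is drawn with probability
$\mathrm{logit}^{-1}(\mathrm{logit}(\pi_j) + \beta_j y_i)$, so the injected
$\beta_j$ **is** the population log-odds ratio that a covariate-free
logistic PheWAS estimates — parameter recovery is exact in expectation, not
approximate. Count effects enter as a multiplicative intensity on the
records-per-positive Poisson rate, duration effects as a target-dependent
scaling of the within-window age spread; keeping the three channels
separate is what makes the three aggregation models separately testable.
Orphan ICD codes (present in the EHR, absent from the map) are injected at
a configurable rate, with the exact count returned as ground truth for the
drop-accounting tests.

The generator is deliberately simple where real EHR is not: code
frequencies are homogeneous rather than Zipf-like, events are exchangeable
within a patient's window rather than clustered into encounters, there is
no temporal disease progression, no inter-PheCode correlation beyond the
shared target, and no informative missingness. Passing tests therefore
demonstrate that the engine's arithmetic, accounting and calibration are
correct under known structure — not that any clinical conclusion drawn
from real data is valid.

## Problem sizes in the test and acceptance suites

The statistical checks run at sizes chosen to make their expectations
sharp while staying desk-fast: null calibration uses 50 replicates of
$n = 2000$, $m = 50$ (2500 null p-values; the fraction below 0.05 is
compared against binomial 99% bounds), parameter recovery uses 100
replicates of $n = 2000$ with $\log\mathrm{OR} = 1$ injected on one of 5
PheCodes (coverage compared against 95% ± 3 points), the brute-force
aggregation oracle uses 200 random record sets, the BH oracle 1000 random
p-vectors, and the matched-cohort identity runs at the full 3487-case
scale. Unit tests reuse the same oracles at smaller sizes.

## Known limitations

* Wald inference is first-order; for PheCodes carried by very few subjects
  the intervals are approximate (mitigated, not solved, by `minSubjects`).
* The duration model ignores censoring by the observation window; its
  coefficient measures recorded span, not disease duration.
* No mixed-effects, survival or dosage-coded genotype models.
* The multicollinearity test diagnoses pairwise instability only; it is a
  human-in-the-loop screening aid, not automated covariate selection.
* One process, one machine: at phenome scale (~$10^3$–$10^4$ PheCodes) a
  run is minutes, which has not justified parallel execution.
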