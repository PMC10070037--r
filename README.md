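# phewasKit

A mass univariate PheWAS (phenome-wide association study) engine for
longitudinal electronic health records, written in R with
Bioconductor-style S4 classes.

## The problem

A PheWAS asks the reverse of a GWAS question: given one binary **target
variable** — a disease diagnosis, an exposure, a genotype — which of the
hundreds of phenotypes recorded in a patient cohort's EHR are associated
with it? The raw material is billing-level data: one row per coded clinical
event carrying a patient identifier, an ICD-9-CM or ICD-10-CM code, and the
patient's age at the event. ICD codes are too granular and too redundant to
test directly, so they are first mapped to **PheCodes** — curated phenotype
groups, each with a description and one of 18 clinical categories — and any
record whose code is absent from the mapping table is removed from the
study.

Each patient's PheCode history is then collapsed to a feature matrix under
one of three **aggregation** schemes:

| scheme   | cell value for patient *i*, PheCode *j* |
|----------|------------------------------------------|
| binary   | 1 if the PheCode appears at least once, else 0 |
| count    | total number of records of the PheCode |
| duration | years between first and last occurrence (0 if absent or single) |

The engine then fits one regression per PheCode. With the target *y* as
the dependent variable the model is logistic,

&nbsp;&nbsp;&nbsp;&nbsp;logit P(y = 1) = β₀ + β·x_j + γᵀc,

where x_j is the PheCode's aggregated value and c the covariates; with the
target as an independent predictor the PheCode value is the outcome and the
family is logistic when the aggregation is binary, linear otherwise. Each
fit reports the effect size β (log-odds for logistic fits), a 95% Wald
interval β ± 1.959964·se, a two-sided Wald p-value, and the number of
subjects carrying the PheCode. Across the m fitted PheCodes, significance
is classified against the Bonferroni threshold α/m and the
Benjamini–Hochberg step-up threshold (largest p(k) ≤ (k/m)·α), and the
results feed three linked views: a volcano plot (β vs −log₁₀ p), a
threshold-filtered effect-size plot with confidence intervals by category,
and the saved data table sorted by p-value.

The package also provides cohort construction (case definition by minimum
ICD record counts, e.g. "at least 3 records of ICD-9-CM 314.01 or ICD-10-CM
F90.x", and 1:1 control matching on exact keys plus numeric tolerances such
as minimum visit age ± 0.1 years), covariate diagnostics (group-stratified
histograms, joint distribution grids, a multicollinearity test comparing
individual and joint regression coefficients), and a fully seeded
synthetic-EHR generator with injectable PheCode–target effects so the whole
pipeline is testable without access to restricted clinical data.

## Worked example

```r
library(phewasKit)

# a synthetic study: 1000 patients, 20 PheCodes, log-OR 1.0 injected on
# the first PheCode, everything else null
spec <- simSpec(nPatients = 1000, nPhecodes = 20,
                logOR = c(1.0, rep(0, 19)), seed = 11)
sim <- simulatePhewasStudy(spec, "demo")

pp <- preprocessStudy(sim$paths$group, sim$paths$ehr, sim$paths$map)
#> [INFO] 12700 EHR records: 12700 mapped, 0 dropped (unmapped codes)
#> [INFO] feature matrices: 20 PheCodes x 1000 patients

results <- runPhewas(pp$pe, phewasModel("target", covariates = "sex"))
results
#> PhewasResults: 20 PheCodes fitted (0 skipped)
#> PheWAS model: target 'target' as dependent, binary aggregation, alpha 0.05
#> covariates: sex
#> smallest p-values:
#>  phecode       beta      p_value n_subjects
#>    101.1  0.7381230 2.460044e-07        289
#>    111.1 -0.3080141 4.817406e-02        212
#>    118.1 -0.2299393 1.378788e-01        214

classifySignificance(results)
#> PhewasThresholds: alpha 0.05 over m = 20 tests
#>   bonferroni <= 0.0025 | fdr <= 2.46e-07
#>   classes: 1 bonferroni, 0 fdr, 19 insignificant
```

The injected PheCode (101.1) is recovered with β̂ = 0.74 — within its 95%
interval [0.46, 1.02] of the true 1.0 — and is the only PheCode passing
the Bonferroni threshold 0.05/20 = 0.0025; the weakly negative runner-up
(p = 0.048) is a chance finding among the 19 nulls, which is exactly what
the multiple-comparison correction is for. `writeResultTable()`,
`volcanoPayload()` and `effectPlotPayload()` turn the same result set into
the saved table and the two plot payloads; `runStudy()` does all of it in
one call and records run metadata.

A command-line wrapper with subcommands `simulate`, `preprocess`,
`diagnose`, `match`, `regress`/`report`/`run` ships in
`inst/scripts/phewas-cli.R`:

```sh
Rscript inst/scripts/phewas-cli.R simulate --seed 5 --out sim
Rscript inst/scripts/phewas-cli.R run --group sim/group.csv \
    --ehr sim/ehr.csv --map sim/phecode_map.csv --cache cache \
    --target target --covariates sex --out out
```

## File formats

All inputs are UTF-8 CSV with a header. Group file: `id` plus free-form
variable columns (empty cell or `NA` = missing). EHR file: `id`,
`ICD_CODE`, `ICD_TYPE` (9 or 10), `AgeAtICD` (years); column names
configurable. Map table: `icd_version`, `icd_code`, `phecode`,
`description`, `category`. The saved result table has columns `phecode`,
`description`, `category`, `coefficient`, `ci_low`, `ci_high`, `p_value`,
`n_subjects`, `converged`, sorted ascending by p-value. The feature-matrix
cache is a directory of CSVs plus a schema-versioned `meta.json` carrying
input checksums; a mismatch forces a rebuild.

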