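# nutrilcm

Gold-standard-free comparison of malnutrition diagnostic criteria in
cancer cohorts.

Malnutrition in colorectal-cancer patients can be diagnosed by the PG-SGA
score, the ESPEN 2015 consensus criteria, or the GLIM criteria — and the
three disagree substantially. Because no gold-standard diagnosis of
malnutrition exists, their accuracy cannot be estimated by comparison with
a reference. `nutrilcm` is written for biostatisticians and clinical
nutrition researchers who face exactly this setting. It provides:

* **Criteria engines** — deterministic, literally-thresholded rule
  implementations of PG-SGA banding, ESPEN conditions C1–C3 and GLIM
  phenotypic/etiologic criteria with severity grading, plus mode
  imputation for masked baseline fields.
* **A Bayesian latent class model** — for K conditionally independent
  binary tests with no reference standard, the pattern probability is the
  two-class mixture

  P(y) = π ∏ₖ Seₖ^yₖ (1−Seₖ)^(1−yₖ) + (1−π) ∏ₖ (1−Spₖ)^yₖ Spₖ^(1−yₖ),

  fitted by a fully conjugate data-augmentation Gibbs sampler (latent
  diseased counts per pattern cell, then Beta full conditionals for the
  prevalence π and every sensitivity Seₖ / specificity Spₖ), with
  per-chain label-switching correction (orientation constraint
  Σₖ(Seₖ+Spₖ) > K), equal-tailed 95% credible intervals, and
  Gelman–Rubin R̂ / effective-sample-size diagnostics.
* **Discrepancy attribution** — each ESPEN-positive/GLIM-negative patient
  is assigned the rule feature GLIM cannot see (historical "> 10% at any
  time" weight loss, the BMI 18.5–20 kg/m² band, FFMI, low BMI), with
  chi-square / Fisher group comparisons.
* **Survival machinery from first principles** — Kaplan–Meier with median
  survival, multi-group log-rank, and Cox proportional hazards via the
  partial likelihood (Efron or Breslow ties, damped Newton–Raphson, Wald
  intervals), cross-validated against the `survival` package in the test
  suite.
* **A synthetic cohort simulator** — two modes (exact latent-class
  structure for model validation; mechanistic covariates for rule-engine
  and discrepancy testing) with proportional-hazards follow-up and MCAR
  missingness, so the entire pipeline is testable without access to any
  patient registry.

## Worked example

Simulate a cohort with the default study conditions (n = 3,182, latent
prevalence 0.25, Se = 0.80/0.84/0.57 and Sp = 0.99/0.43/0.81 for
PG-SGA/ESPEN/GLIM), then re-estimate the operating characteristics from
the diagnoses alone:

```r
library(nutrilcm)

spec   <- cohort_spec(n_patients = 3182, seed = 11)
cohort <- generate_latent_class_cohort(spec)
panel  <- apply_all(cohort$records)
tab    <- build_cross_class(panel[c("pgsga", "espen", "glim")])
fit    <- enforce_orientation(
  gibbs_fit(tab, chains = 3, iterations = 20000, burn_in = 5000, seeds = 1:3))
lcm_summarize(fit)
#>    parameter mean median lower upper
#> 1 prevalence 0.24   0.24  0.19  0.30
#> 2   se_pgsga 0.79   0.79  0.65  0.96
#> 3   se_espen 0.88   0.88  0.84  0.92
#> 4    se_glim 0.56   0.56  0.51  0.62
#> 5   sp_pgsga 0.98   0.98  0.95  1.00
#> 6   sp_espen 0.45   0.45  0.42  0.48
#> 7    sp_glim 0.81   0.81  0.78  0.84
gelman_rubin(fit)
#> Gelman-Rubin diagnostics (threshold 1.10): all parameters converged
```

Every parameter's posterior mean sits close to its generating truth and
the 95% credible intervals cover it: with three tests and one population
the model is just-identifiable, and the fit recovers each instrument's
sensitivity and specificity without ever observing the latent state. The
full pipeline (simulate → impute → diagnose → cross-classify → fit →
diagnostics → discrepancy → survival) runs through one call:

```r
report <- run_pipeline(run_config(
  simulation = cohort_spec(n_patients = 3182, seed = 11),
  chains = 3, iterations = 20000, burn_in = 5000, seeds = 1:3))
write_run_report(report, "report.json")
```

A thin command-line wrapper lives at `inst/scripts/run-pipeline.R`.

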