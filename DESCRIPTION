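Package: nutrilcm
Title: Gold-Standard-Free Comparison of Malnutrition Diagnostic Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing malnutrition diagnostic instruments
    (PG-SGA, ESPEN 2015, GLIM) in oncology cohorts when no gold standard
    exists. Provides deterministic rule engines for the three criteria
    sets, a Bayesian latent class model for conditionally independent
    binary tests fitted by data-augmentation Gibbs sampling with
    Gelman-Rubin convergence diagnostics, pathway attribution for
    discordant ESPEN/GLIM diagnoses, Kaplan-Meier, log-rank and Cox
    proportional-hazards machinery implemented from first principles,
    and a synthetic cohort simulator so that every stage is testable
    without access to patient-level registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
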