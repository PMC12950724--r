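# Synthetic cohort generators.
#
# Two modes share one cohort_spec:
#   * latent-class mode draws test results directly from the two-class
#     mixture (exact conditional independence, for validating the LCM);
#   * mechanistic mode draws covariates and lets the criteria engines
#     produce the test results (for exercising the rule engines and the
#     discrepancy analysis).

TEST_ORDER <- c("pgsga", "espen", "glim")

new_latent_cohort <- function(records, true_status, true_severity, spec,
                              mode) {
  stopifnot(nrow(records) == length(true_status),
            length(true_status) == length(true_severity),
            all(true_severity[true_status == 0L] == "well"),
            all(true_severity[true_status == 1L] != "well"))
  structure(
    list(records = records,
         true_status = as.integer(true_status),
         true_severity = true_severity,
         spec = spec,
         mode = mode),
    class = "latent_cohort")
}

#' @export
print.latent_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort (%s mode): %d patients, %d truly malnourished (%.1f%%)\n",
              x$mode, nrow(x$records), sum(x$true_status),
              100 * mean(x$true_status)))
  if ("followup_months" %in% names(x$records)) {
    cat(sprintf("  follow-up attached: %d events (%.1f%%)\n",
                sum(x$records$event), 100 * mean(x$records$event)))
  }
  invisible(x)
}

draw_severity <- function(status, severe_fraction) {
  sev <- rep("well", length(status))
  mal <- which(status == 1L)
  if (length(mal)) {
    sev[mal] <- ifelse(stats::runif(length(mal)) < severe_fraction,
                       "severe", "moderate")
  }
  sev
}

#' Generate a cohort directly from the latent class model
#'
#' Draws a latent binary malnutrition state with the specified prevalence
#' and, conditionally on it, K independent binary test results with the
#' specified sensitivities and specificities (result ~ Bernoulli(se_k) for
#' malnourished patients, Bernoulli(1 - sp_k) otherwise). This is exactly
#' the generative model that the latent class fitter assumes, so parameter
#' recovery experiments against it are well-posed.
#'
#' @param spec a [cohort_spec()].
#' @return a `latent_cohort`: records with `id` and one binary
#'   `test_<tool>` column per test, plus `true_status` (0/1) and
#'   `true_severity` ("well"/"moderate"/"severe") vectors.
#' @export
#' @examples
#' cohort <- generate_latent_class_cohort(cohort_spec(n_patients = 200, seed = 7))
#' colMeans(cohort$records[paste0("test_", c("pgsga", "espen", "glim"))])
generate_latent_class_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_patients
  K <- length(spec$se)
  status <- stats::rbinom(n, 1L, spec$prevalence)
  tests <- matrix(0L, n, K)
  for (k in seq_len(K)) {
    p_pos <- ifelse(status == 1L, spec$se[k], 1 - spec$sp[k])
    tests[, k] <- stats::rbinom(n, 1L, p_pos)
  }
  test_names <- if (K == length(TEST_ORDER)) TEST_ORDER else
    paste0("t", seq_len(K))
  colnames(tests) <- paste0("test_", test_names)
  records <- data.frame(id = sprintf("P%05d", seq_len(n)), tests,
                        stringsAsFactors = FALSE)
  severity <- draw_severity(status, spec$severe_fraction)
  new_latent_cohort(records, status, severity, spec, mode = "latent_class")
}

#' Generate a cohort with mechanistic covariates
#'
#' Draws demographics, anthropometrics and nutrition-interview fields whose
#' distributions depend on a latent malnutrition state, so that applying
#' the PG-SGA / ESPEN / GLIM rule engines to the records yields
#' non-degenerate cross-classifications. Internal consistency is enforced:
#' the anthropometric muscle flag agrees with the FFMI cutoff at the
#' configured agreement rate, weight-loss windows are nested
#' (`wl_any_time_pct >= max(wl_3mo_pct, wl_6mo_pct, wl_beyond_6mo_pct)`),
#' and GLIM-style severity is derived from the simulated weight loss.
#'
#' @param spec a [cohort_spec()]; `covariate_config` controls the
#'   distributions (see [default_covariate_config()]).
#' @return a `latent_cohort` whose records carry the full patient-record
#'   schema (see [cohort_schema()]), without follow-up until
#'   [attach_survival()] is called.
#' @export
generate_mechanistic_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_patients
  cc <- spec$covariate_config
  status <- stats::rbinom(n, 1L, spec$prevalence)
  mal <- status == 1L

  ge65 <- stats::runif(n) < cc$age$p_ge65
  age <- ifelse(ge65,
                stats::runif(n, 65, cc$age$max),
                stats::runif(n, cc$age$min, 65))
  sex <- ifelse(stats::runif(n) < cc$sex$p_male, "male", "female")

  wl <- cc$weight_loss
  recent <- stats::runif(n) < ifelse(mal, wl$p_recent_mal, wl$p_recent_well)
  wl_6mo <- ifelse(recent,
                   stats::rgamma(n, shape = 2,
                                 scale = ifelse(mal, wl$mean_recent_mal,
                                                wl$mean_recent_well) / 2),
                   0)
  frac <- stats::runif(n, wl$recent_3mo_frac[1], wl$recent_3mo_frac[2])
  wl_3mo <- wl_6mo * frac
  past <- stats::runif(n) < ifelse(mal, wl$p_past_mal, wl$p_past_well)
  wl_beyond <- ifelse(past,
                      stats::rgamma(n, shape = 2,
                                    scale = ifelse(mal, wl$mean_past_mal,
                                                   wl$mean_past_well) / 2),
                      0)
  # loss from the lifetime maximum weight, spread over time: visible only
  # to the "> 10% at any time" clause, not to any single interview window
  legacy <- stats::runif(n) < ifelse(mal, wl$p_legacy_mal, wl$p_legacy_well)
  wl_legacy <- ifelse(legacy,
                      stats::rgamma(n, shape = 2,
                                    scale = ifelse(mal, wl$mean_legacy_mal,
                                                   wl$mean_legacy_well) / 2),
                      0)
  wl_any <- pmax(wl_3mo, wl_6mo, wl_beyond, wl_legacy)

  # BMI reflects the cumulative loss: heavy losers sit lower
  bmi <- stats::rnorm(n,
                      ifelse(mal, cc$bmi$mean_mal, cc$bmi$mean_well),
                      ifelse(mal, cc$bmi$sd_mal, cc$bmi$sd_well)) -
    cc$bmi$loss_coupling * wl_any
  bmi <- pmin(pmax(bmi, cc$bmi$min), cc$bmi$max)

  ffmi_mean <- ifelse(sex == "male", cc$ffmi$mean_male, cc$ffmi$mean_female) +
    ifelse(mal, cc$ffmi$shift_mal, 0)
  ffmi <- stats::rnorm(n, ffmi_mean,
                       ifelse(sex == "male", cc$ffmi$sd_male,
                              cc$ffmi$sd_female)) -
    cc$ffmi$loss_coupling * wl_any
  ffmi_low <- ffmi < ifelse(sex == "male", 17, 15)
  agree <- stats::runif(n) < cc$muscle_agreement
  muscle_flag <- ifelse(agree, ffmi_low, !ffmi_low)

  # PG-SGA banding is driven by the spec's first test's Se/Sp: truly
  # malnourished patients score in the malnourished bands (>= 2) with
  # probability se[1], well-nourished ones with probability 1 - sp[1]
  pg_hit <- stats::runif(n) < ifelse(mal, spec$se[1], 1 - spec$sp[1])
  pgsga <- ifelse(pg_hit,
                  2L + stats::rpois(n, ifelse(mal, cc$pgsga$lambda_pos_mal,
                                              cc$pgsga$lambda_pos_well)),
                  stats::rpois(n, cc$pgsga$lambda_neg))
  nrs <- stats::runif(n) < ifelse(mal, cc$nrs$p_pos_mal, cc$nrs$p_pos_well)
  intake <- stats::runif(n) < ifelse(mal, cc$intake$p_reduced_mal,
                                     cc$intake$p_reduced_well)

  records <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age = round(age, 1),
    sex = sex,
    bmi = round(bmi, 2),
    wl_3mo_pct = round(wl_3mo, 2),
    wl_6mo_pct = round(wl_6mo, 2),
    wl_beyond_6mo_pct = round(wl_beyond, 2),
    wl_any_time_pct = round(wl_any, 2),
    ffmi = round(ffmi, 2),
    muscle_reduced_anthro = as.logical(muscle_flag),
    pgsga_score = as.integer(pgsga),
    nrs_positive = as.logical(nrs),
    reduced_intake = as.logical(intake),
    has_cancer = TRUE,
    stringsAsFactors = FALSE
  )

  # severity mirrors the GLIM weight-loss grading; a malnourished patient
  # without qualifying loss is graded moderate
  severity <- rep("well", n)
  severity[mal] <- ifelse(records$wl_6mo_pct[mal] >= 10 |
                            records$wl_beyond_6mo_pct[mal] >= 20,
                          "severe", "moderate")
  new_latent_cohort(records, status, severity, spec, mode = "mechanistic")
}

#' Attach survival follow-up to a cohort
#'
#' Event times are drawn from a Weibull (exponential by default) with rate
#' `hazard_scale * HR(severity)`, where HR is 1 for well-nourished patients
#' and `hr_moderate` / `hr_severe` otherwise; censoring times are
#' independent exponential with rate `censoring_rate`. The observed
#' follow-up is the minimum of the two, in months.
#'
#' @param cohort a `latent_cohort` with `true_severity`.
#' @param spec a [cohort_spec()] supplying the survival parameters
#'   (defaults to the cohort's own spec).
#' @param seed optional integer seed; defaults to `spec$seed + 1` so the
#'   survival draw does not re-use the covariate stream.
#' @return the cohort with `followup_months` (> 0) and `event` (0/1)
#'   columns added to its records.
#' @export
attach_survival <- function(cohort, spec = cohort$spec, seed = NULL) {
  stopifnot(inherits(cohort, "latent_cohort"))
  spec <- validate_cohort_spec(spec)
  if (is.null(seed)) {
    seed <- if (!is.null(spec$seed)) spec$seed + 1L else NULL
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort$records)
  hr <- c(well = 1, moderate = spec$hr_moderate, severe = spec$hr_severe)
  rate <- spec$hazard_scale * hr[cohort$true_severity]
  # scale b = rate^(-1/shape) makes the cumulative hazard rate * t^shape,
  # which is the exponential(rate) when shape = 1
  event_time <- stats::rweibull(n, shape = spec$weibull_shape,
                                scale = rate^(-1 / spec$weibull_shape))
  cens_time <- if (spec$censoring_rate > 0)
    stats::rexp(n, spec$censoring_rate) else rep(Inf, n)
  time <- pmin(event_time, cens_time)
  cohort$records$followup_months <- pmax(time, 1e-6)
  cohort$records$event <- as.integer(event_time <= cens_time)
  cohort
}

#' Mask baseline fields completely at random
#'
#' Masks eligible categorical baseline cells (sex, the anthropometric
#' muscle flag, the screening result, reduced intake, and any test-result
#' columns) independently with probability `missing_fraction`. Survival
#' follow-up is never masked, and no patient ever loses all three test
#' results at once; when the mask would do so, one of the three is retained
#' at random.
#'
#' @param cohort a `latent_cohort` or a plain records data frame.
#' @param missing_fraction probability a cell is masked, in \[0, 1).
#' @param seed optional integer seed.
#' @return the cohort with `NA`s injected into its records.
#' @export
inject_missingness <- function(cohort, missing_fraction, seed = NULL) {
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("'missing_fraction' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rec <- if (inherits(cohort, "latent_cohort")) cohort$records else cohort
  if (missing_fraction == 0) return(cohort)

  categorical <- intersect(
    c("sex", "muscle_reduced_anthro", "nrs_positive", "reduced_intake"),
    names(rec))
  test_cols <- grep("^test_", names(rec), value = TRUE)
  for (col in c(categorical, test_cols)) {
    mask <- stats::runif(nrow(rec)) < missing_fraction
    rec[[col]][mask] <- NA
  }
  if (length(test_cols) >= 2) {
    all_masked <- rowSums(is.na(rec[test_cols])) == length(test_cols)
    for (i in which(all_masked)) {
      keep <- sample(test_cols, 1L)
      orig <- if (inherits(cohort, "latent_cohort")) cohort$records else cohort
      rec[[keep]][i] <- orig[[keep]][i]
    }
  }
  if (inherits(cohort, "latent_cohort")) {
    cohort$records <- rec
    cohort
  } else {
    rec
  }
}

#' Cohort CSV schema
#'
#' The frozen column order of the cohort CSV written by [write_cohort()]:
#' one row per patient, missing values encoded as empty strings, logical
#' fields as TRUE/FALSE. Columns absent from a cohort (e.g. covariates in
#' latent-class mode) are simply omitted.
#'
#' @return character vector of column names in canonical order.
#' @export
cohort_schema <- function() {
  c("id", "age", "sex", "bmi",
    "wl_3mo_pct", "wl_6mo_pct", "wl_beyond_6mo_pct", "wl_any_time_pct",
    "ffmi", "muscle_reduced_anthro", "pgsga_score", "nrs_positive",
    "reduced_intake", "has_cancer",
    paste0("test_", TEST_ORDER),
    "followup_months", "event")
}

#' Write a cohort (and its truth sidecar) to CSV
#'
#' @param cohort a `latent_cohort`.
#' @param path output CSV path for the patient records.
#' @param truth_path optional path for the truth sidecar
#'   (`id`, `true_status`, `true_severity`), used by recovery tests.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  stopifnot(inherits(cohort, "latent_cohort"))
  cols <- intersect(cohort_schema(), names(cohort$records))
  utils::write.csv(cohort$records[cols], path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    utils::write.csv(
      data.frame(id = cohort$records$id,
                 true_status = cohort$true_status,
                 true_severity = cohort$true_severity,
                 stringsAsFactors = FALSE),
      truth_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @return records data frame with schema types restored.
#' @export
read_cohort <- function(path) {
  rec <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  for (col in intersect(c("muscle_reduced_anthro", "nrs_positive",
                          "reduced_intake", "has_cancer"), names(rec))) {
    rec[[col]] <- as.logical(rec[[col]])
  }
  for (col in intersect(c("pgsga_score", "event",
                          paste0("test_", TEST_ORDER)), names(rec))) {
    rec[[col]] <- as.integer(rec[[col]])
  }
  rec
}
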