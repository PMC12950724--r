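#' Specification of a synthetic colorectal-cancer cohort
#'
#' A `cohort_spec` collects every knob of the synthetic cohort generators:
#' the latent malnutrition structure (prevalence, per-test sensitivity and
#' specificity), the survival process (baseline hazard, severity hazard
#' ratios, censoring), covariate distributions, and missingness. The same
#' spec drives both generation modes (see [generate_latent_class_cohort()]
#' and [generate_mechanistic_cohort()]).
#'
#' Defaults describe a cohort of 3,182 colorectal-cancer patients: latent
#' malnutrition prevalence 0.25, test operating characteristics equal to the
#' posterior means reported for PG-SGA, ESPEN and GLIM in the study cohort
#' (Se 0.80/0.84/0.57, Sp 0.99/0.43/0.81), exponential survival in months
#' with hazard ratios 1.29 (moderate) and 1.50 (severe malnutrition), and an
#' age mix with 58.5% of patients aged 65 or older.
#'
#' @param n_patients number of patients (>= 1).
#' @param prevalence latent malnutrition prevalence, in \[0, 1\].
#' @param se,sp numeric vectors of per-test sensitivity / specificity in the
#'   fixed test order (PG-SGA, ESPEN, GLIM). Each pair must satisfy
#'   `se[k] + sp[k] > 1` so the tests are oriented (better than chance).
#' @param hazard_scale baseline event rate for well-nourished patients,
#'   events per month.
#' @param hr_moderate,hr_severe hazard ratios for moderately / severely
#'   malnourished patients relative to well-nourished.
#' @param censoring_rate rate of the independent exponential censoring
#'   process (per month); 0 means no random censoring.
#' @param weibull_shape shape of the Weibull event-time distribution;
#'   1 (default) gives the exponential baseline.
#' @param severe_fraction fraction of malnourished patients who are severely
#'   (rather than moderately) malnourished in latent-class mode; in
#'   mechanistic mode severity follows from simulated weight loss.
#' @param covariate_config nested list of covariate distribution settings;
#'   see [default_covariate_config()] for the fields and defaults. Partial
#'   lists are merged over the defaults.
#' @param missing_fraction probability that an eligible baseline cell is
#'   masked by [inject_missingness()], in \[0, 1).
#' @param seed integer seed used by the generators (NULL = leave RNG alone).
#'
#' @return an object of class `cohort_spec` (a validated list).
#' @export
#' @examples
#' spec <- cohort_spec(n_patients = 500, seed = 1)
#' cohort <- generate_latent_class_cohort(spec)
cohort_spec <- function(n_patients = 3182,
                        prevalence = 0.25,
                        se = c(pgsga = 0.80, espen = 0.84, glim = 0.57),
                        sp = c(pgsga = 0.99, espen = 0.43, glim = 0.81),
                        hazard_scale = 0.012,
                        hr_moderate = 1.29,
                        hr_severe = 1.50,
                        censoring_rate = 0.015,
                        weibull_shape = 1,
                        severe_fraction = 1 / 3,
                        covariate_config = list(),
                        missing_fraction = 0,
                        seed = NULL) {
  spec <- list(
    n_patients = as.integer(n_patients),
    prevalence = prevalence,
    se = unname(se), sp = unname(sp),
    hazard_scale = hazard_scale,
    hr_moderate = hr_moderate,
    hr_severe = hr_severe,
    censoring_rate = censoring_rate,
    weibull_shape = weibull_shape,
    severe_fraction = severe_fraction,
    covariate_config = utils::modifyList(default_covariate_config(),
                                         covariate_config),
    missing_fraction = missing_fraction,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' Default covariate distribution settings
#'
#' Values are chosen so the criteria rule engines fire with the structure
#' seen in colorectal-cancer cohorts: the age mix reproduces the reported
#' 58.5% aged >= 65; weight-loss histories are dominated by losses around
#' diagnosis and treatment that lie outside the 3/6-month interview
#' windows (the "legacy" component, which only the ESPEN "> 10% at any
#' time" clause can see); BMI is depressed by cumulative weight loss
#' (`loss_coupling`), which populates the 18.5--20 kg/m2 band separating
#' the ESPEN and GLIM low-BMI cutoffs; and low FFMI is largely specific to
#' the malnourished class. Under these defaults the ESPEN-positive rate
#' exceeds the GLIM-positive rate and the ESPEN-only group dominates the
#' GLIM-only group, as in the study cohort.
#'
#' Weight-loss components, all in percent of body weight: `recent` is the
#' loss within the past 6 months (its 3-month share drawn uniformly from
#' `recent_3mo_frac`), `past` the loss over a window beyond 6 months, and
#' `legacy` an additional loss from the lifetime maximum weight that is
#' spread over time and therefore raises only `wl_any_time_pct`.
#'
#' @return nested list of distribution settings.
#' @export
default_covariate_config <- function() {
  list(
    age = list(p_ge65 = 0.585, min = 30, max = 88),
    sex = list(p_male = 0.597),
    bmi = list(mean_well = 23.4, sd_well = 1.9,
               mean_mal = 20.4, sd_mal = 1.8,
               loss_coupling = 0.24,
               min = 13, max = 36),
    weight_loss = list(
      p_recent_well = 0.06, mean_recent_well = 3.5,
      p_recent_mal = 0.45, mean_recent_mal = 9,
      p_past_well = 0.03, mean_past_well = 8,
      p_past_mal = 0.18, mean_past_mal = 13,
      p_legacy_well = 0.85, mean_legacy_well = 18,
      p_legacy_mal = 0.90, mean_legacy_mal = 18,
      recent_3mo_frac = c(0.5, 0.9)
    ),
    ffmi = list(mean_male = 19.9, sd_male = 1.2,
                mean_female = 17.7, sd_female = 1.0,
                shift_mal = -1.4, loss_coupling = 0.04),
    muscle_agreement = 0.99,
    pgsga = list(lambda_pos_mal = 4.5, lambda_pos_well = 2,
                 lambda_neg = 0.3),
    nrs = list(p_pos_well = 0.50, p_pos_mal = 0.95),
    intake = list(p_reduced_well = 0.10, p_reduced_mal = 0.60)
  )
}

validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n_patients) || length(spec$n_patients) != 1L ||
      is.na(spec$n_patients) || spec$n_patients < 1) {
    stop("'n_patients' must be a positive integer", call. = FALSE)
  }
  check_probability(spec$prevalence, "prevalence")
  check_probability(spec$se, "se")
  check_probability(spec$sp, "sp")
  if (length(spec$se) != length(spec$sp)) {
    stop("'se' and 'sp' must have the same length", call. = FALSE)
  }
  if (any(spec$se + spec$sp <= 1)) {
    bad <- which(spec$se + spec$sp <= 1)
    stop(sprintf(
      "test %s violates the orientation constraint se + sp > 1",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  check_positive(spec$hazard_scale, "hazard_scale")
  check_positive(spec$hr_moderate, "hr_moderate")
  check_positive(spec$hr_severe, "hr_severe")
  check_positive(spec$censoring_rate, "censoring_rate", strict = FALSE)
  check_positive(spec$weibull_shape, "weibull_shape")
  check_probability(spec$severe_fraction, "severe_fraction")
  if (!is.numeric(spec$missing_fraction) ||
      spec$missing_fraction < 0 || spec$missing_fraction >= 1) {
    stop("'missing_fraction' must lie in [0, 1)", call. = FALSE)
  }
  cc <- spec$covariate_config
  if (cc$age$min >= cc$age$max) {
    stop("covariate_config: age range inverted (min >= max)", call. = FALSE)
  }
  if (cc$bmi$min >= cc$bmi$max) {
    stop("covariate_config: bmi range inverted (min >= max)", call. = FALSE)
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  n_patients: %d   prevalence: %.3f\n",
              x$n_patients, x$prevalence))
  cat(sprintf("  tests (PG-SGA, ESPEN, GLIM): Se = %s; Sp = %s\n",
              paste(format(x$se), collapse = ", "),
              paste(format(x$sp), collapse = ", ")))
  cat(sprintf("  survival: baseline %.4f/month, HR moderate %.2f, severe %.2f, censoring %.4f/month\n",
              x$hazard_scale, x$hr_moderate, x$hr_severe, x$censoring_rate))
  cat(sprintf("  missing_fraction: %.3f   seed: %s\n",
              x$missing_fraction,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
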