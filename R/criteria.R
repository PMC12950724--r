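# Deterministic rule engines for the three malnutrition instruments.
#
# All thresholds are implemented literally: diagnosis thresholds use strict
# inequalities ("<" for BMI and FFMI cutoffs, ">" for weight-loss
# percentages), severity grading uses ">=". ESPEN and GLIM are both gated
# on a positive nutritional-risk screen; a negative screen yields
# well-nourished regardless of covariates.

new_diagnosis <- function(tool, malnourished, category, triggered_rules,
                          warnings = character()) {
  stopifnot(malnourished == (category != "well"))
  if (malnourished && !length(triggered_rules)) {
    stop("malnourished diagnosis must carry at least one triggered rule")
  }
  structure(list(tool = tool,
                 malnourished = malnourished,
                 category = category,
                 triggered_rules = triggered_rules,
                 warnings = warnings),
            class = "diagnosis")
}

#' @export
print.diagnosis <- function(x, ...) {
  cat(sprintf("%s: %s (%s)%s\n", x$tool,
              if (x$malnourished) "malnourished" else "well-nourished",
              x$category,
              if (length(x$triggered_rules))
                paste0(" [", paste(x$triggered_rules, collapse = ";"), "]")
              else ""))
  invisible(x)
}

#' Classify nutritional status from a PG-SGA score
#'
#' The additive PG-SGA score is banded: 0--1 well-nourished, 2--3 mildly
#' malnourished, 4--8 moderately malnourished, >= 9 severely malnourished.
#' A score of 2 or more counts as malnutrition. For survival subgroup
#' analyses the bands 2--8 are pooled as "possibly or moderately
#' malnourished", exposed here as `subgroup`.
#'
#' @param score nonnegative integer PG-SGA total score.
#' @return a `diagnosis` with tool "PGSGA", `category` in
#'   well/mild/moderate/severe, and a `subgroup` field in
#'   \{"well", "possibly_moderate", "severe"\}.
#' @export
#' @examples
#' classify_pgsga(1)  # well-nourished
#' classify_pgsga(9)  # severely malnourished
classify_pgsga <- function(score) {
  if (!is.numeric(score) || length(score) != 1L || is.na(score) ||
      score < 0 || score != floor(score)) {
    stop("'score' must be a single nonnegative integer", call. = FALSE)
  }
  category <- if (score <= 1) "well"
  else if (score <= 3) "mild"
  else if (score <= 8) "moderate"
  else "severe"
  d <- new_diagnosis(
    tool = "PGSGA",
    malnourished = score >= 2,
    category = category,
    triggered_rules = if (score >= 2) sprintf("score>=%d", min(score, 9L))
    else character())
  d$subgroup <- if (score <= 1) "well"
  else if (score <= 8) "possibly_moderate"
  else "severe"
  d
}

# pull a scalar field from a one-row data frame or a named list
field <- function(r, name) {
  v <- r[[name]]
  if (is.null(v) || length(v) == 0L) NA else v[[1]]
}

#' Diagnose malnutrition by the ESPEN 2015 consensus criteria
#'
#' For screen-positive patients, malnutrition is diagnosed when any of:
#' \describe{
#'   \item{C1}{BMI < 18.5 kg/m2.}
#'   \item{C2}{Unintentional weight loss > 10% at any time, or > 5% within
#'     the last 3 months, combined with BMI < 20 kg/m2 if aged < 70 or
#'     < 22 kg/m2 if aged >= 70.}
#'   \item{C3}{The same weight-loss clause combined with FFMI < 15 kg/m2
#'     (women) or < 17 kg/m2 (men).}
#' }
#' A negative screen yields well-nourished regardless of other fields. An
#' absent FFMI makes C3 evaluate false with a data-completeness warning
#' recorded on the diagnosis (never an error).
#'
#' @param r a patient record: one-row data frame or named list with fields
#'   `nrs_positive`, `bmi`, `age`, `sex`, `wl_any_time_pct`, `wl_3mo_pct`,
#'   `ffmi` (optional).
#' @return a `diagnosis` with tool "ESPEN", binary category
#'   well/malnourished, and `triggered_rules` listing every condition that
#'   fired ("C1", "C2", "C3").
#' @export
#' @examples
#' diagnose_espen(list(nrs_positive = TRUE, age = 65, sex = "male",
#'                     bmi = 19, wl_3mo_pct = 6, wl_any_time_pct = 6,
#'                     ffmi = 19))
diagnose_espen <- function(r) {
  nrs <- field(r, "nrs_positive")
  if (is.na(nrs)) stop("'nrs_positive' must be known for ESPEN", call. = FALSE)
  if (!isTRUE(as.logical(nrs))) {
    return(new_diagnosis("ESPEN", FALSE, "well", character()))
  }
  bmi <- field(r, "bmi"); age <- field(r, "age"); sex <- field(r, "sex")
  wl_any <- field(r, "wl_any_time_pct"); wl_3mo <- field(r, "wl_3mo_pct")
  ffmi <- field(r, "ffmi")
  warnings <- character()

  wl_clause <- isTRUE(wl_any > 10) || isTRUE(wl_3mo > 5)
  c1 <- isTRUE(bmi < 18.5)
  bmi_cut <- if (isTRUE(age >= 70)) 22 else 20
  c2 <- wl_clause && isTRUE(bmi < bmi_cut)
  if (is.na(ffmi)) {
    c3 <- FALSE
    if (wl_clause) warnings <- c(warnings, "ffmi-missing:C3-not-evaluable")
  } else {
    ffmi_cut <- if (identical(sex, "female")) 15 else 17
    c3 <- wl_clause && ffmi < ffmi_cut
  }
  fired <- c("C1", "C2", "C3")[c(c1, c2, c3)]
  new_diagnosis("ESPEN",
                malnourished = length(fired) > 0,
                category = if (length(fired)) "malnourished" else "well",
                triggered_rules = fired,
                warnings = warnings)
}

#' Diagnose and grade malnutrition by the GLIM criteria
#'
#' Screen-positive patients are assessed against phenotypic criteria
#' (P1 weight loss > 5% within 6 months or > 10% beyond 6 months; P2 low
#' BMI, < 18.5 kg/m2 under age 70 or < 20 kg/m2 at 70+, the Asian cutoffs;
#' P3 reduced muscle mass by either the anthropometric flag or an FFMI
#' below the sex cutoff, whichever is available) and etiologic criteria
#' (E1 reduced intake or assimilation; E2 inflammation / disease burden —
#' met by the underlying malignancy in a cancer cohort). Malnutrition
#' requires at least one of each. Severity is graded from the phenotypic
#' weight loss: severe when loss >= 10% within 6 months or >= 20% beyond
#' 6 months, otherwise moderate. When malnutrition is established without
#' qualifying weight loss (low BMI or muscle mass only) the grade defaults
#' to moderate and `triggered_rules` carries "severity-default".
#'
#' @param r a patient record as for [diagnose_espen()], additionally with
#'   `wl_6mo_pct`, `wl_beyond_6mo_pct`, `muscle_reduced_anthro` (optional),
#'   `reduced_intake`, `has_cancer`.
#' @return a `diagnosis` with tool "GLIM" and category in
#'   well/moderate/severe.
#' @export
#' @examples
#' diagnose_glim(list(nrs_positive = TRUE, age = 60, sex = "male",
#'                    bmi = 22, wl_6mo_pct = 12, wl_beyond_6mo_pct = 0,
#'                    reduced_intake = FALSE, has_cancer = TRUE))
diagnose_glim <- function(r) {
  nrs <- field(r, "nrs_positive")
  if (is.na(nrs)) stop("'nrs_positive' must be known for GLIM", call. = FALSE)
  if (!isTRUE(as.logical(nrs))) {
    return(new_diagnosis("GLIM", FALSE, "well", character()))
  }
  bmi <- field(r, "bmi"); age <- field(r, "age"); sex <- field(r, "sex")
  wl_6mo <- field(r, "wl_6mo_pct"); wl_beyond <- field(r, "wl_beyond_6mo_pct")
  ffmi <- field(r, "ffmi"); muscle <- field(r, "muscle_reduced_anthro")
  intake <- field(r, "reduced_intake"); cancer <- field(r, "has_cancer")
  warnings <- character()

  p1 <- isTRUE(wl_6mo > 5) || isTRUE(wl_beyond > 10)
  bmi_cut <- if (isTRUE(age >= 70)) 20 else 18.5
  p2 <- isTRUE(bmi < bmi_cut)
  ffmi_low <- if (is.na(ffmi)) NA else
    ffmi < (if (identical(sex, "female")) 15 else 17)
  p3 <- isTRUE(as.logical(muscle)) || isTRUE(ffmi_low)
  if (is.na(muscle) && is.na(ffmi)) {
    warnings <- c(warnings, "muscle-data-missing:P3-not-evaluable")
  }
  e1 <- isTRUE(as.logical(intake))
  e2 <- isTRUE(as.logical(cancer))

  fired <- c("P1", "P2", "P3", "E1", "E2")[c(p1, p2, p3, e1, e2)]
  mal <- (p1 || p2 || p3) && (e1 || e2)
  if (!mal) {
    return(new_diagnosis("GLIM", FALSE, "well", character(),
                         warnings = warnings))
  }
  severe <- isTRUE(wl_6mo >= 10) || isTRUE(wl_beyond >= 20)
  if (!severe && !p1) fired <- c(fired, "severity-default")
  new_diagnosis("GLIM", TRUE,
                category = if (severe) "severe" else "moderate",
                triggered_rules = fired,
                warnings = warnings)
}

#' Apply all three criteria to a cohort
#'
#' Runs PG-SGA, ESPEN and GLIM on every record and returns the per-patient
#' test panel in the fixed test order (PG-SGA, ESPEN, GLIM). If the records
#' already carry simulated `test_*` columns (latent-class mode cohorts),
#' those are returned directly.
#'
#' @param records cohort records data frame (see [cohort_schema()]).
#' @return a data frame with `id`, binary columns `pgsga`, `espen`, `glim`,
#'   category columns `pgsga_category`, `pgsga_subgroup`, `glim_category`,
#'   and semicolon-joined `espen_rules` / `glim_rules`.
#' @export
apply_all <- function(records) {
  if (all(paste0("test_", TEST_ORDER) %in% names(records))) {
    out <- data.frame(id = records$id,
                      pgsga = records$test_pgsga,
                      espen = records$test_espen,
                      glim = records$test_glim,
                      stringsAsFactors = FALSE)
    return(out)
  }
  n <- nrow(records)
  out <- data.frame(id = records$id,
                    pgsga = integer(n), espen = integer(n), glim = integer(n),
                    pgsga_category = character(n),
                    pgsga_subgroup = character(n),
                    glim_category = character(n),
                    espen_rules = character(n), glim_rules = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    r <- records[i, , drop = FALSE]
    dp <- tryCatch(classify_pgsga(field(r, "pgsga_score")),
                   error = function(e) stop(sprintf(
                     "record %s: %s", r$id, conditionMessage(e)),
                     call. = FALSE))
    de <- tryCatch(diagnose_espen(r),
                   error = function(e) stop(sprintf(
                     "record %s: %s", r$id, conditionMessage(e)),
                     call. = FALSE))
    dg <- tryCatch(diagnose_glim(r),
                   error = function(e) stop(sprintf(
                     "record %s: %s", r$id, conditionMessage(e)),
                     call. = FALSE))
    out$pgsga[i] <- as.integer(dp$malnourished)
    out$espen[i] <- as.integer(de$malnourished)
    out$glim[i] <- as.integer(dg$malnourished)
    out$pgsga_category[i] <- dp$category
    out$pgsga_subgroup[i] <- dp$subgroup
    out$glim_category[i] <- dg$category
    out$espen_rules[i] <- paste(de$triggered_rules, collapse = ";")
    out$glim_rules[i] <- paste(dg$triggered_rules, collapse = ";")
  }
  out
}

#' Mode imputation for categorical columns
#'
#' Replaces every missing cell in the named columns by that column's most
#' frequent observed value; observed cells are untouched. Ties between
#' modes are broken toward the smallest value (numeric order for numeric
#' columns, lexicographic otherwise), so the result is deterministic.
#'
#' @param table a data frame.
#' @param columns character vector of columns to impute (default: every
#'   column with at least one `NA`).
#' @return the data frame with no missing cells in the named columns.
#' @export
#' @examples
#' mode_impute(data.frame(x = c(1, 1, 2, NA)))
mode_impute <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, anyNA, logical(1))]
  }
  for (col in columns) {
    x <- table[[col]]
    obs <- x[!is.na(x)]
    if (!length(obs)) {
      stop(sprintf("column '%s' has no observed values to impute from", col),
           call. = FALSE)
    }
    tab <- table(obs)
    modes <- names(tab)[tab == max(tab)]
    m <- if (is.numeric(x)) min(as.numeric(modes)) else min(modes)
    if (is.logical(x)) m <- as.logical(m)
    if (is.integer(x)) m <- as.integer(m)
    x[is.na(x)] <- m
    table[[col]] <- x
  }
  table
}
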