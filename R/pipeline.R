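# Orchestration: simulate (or load) -> impute -> diagnose ->
# cross-classify -> fit LCM -> diagnostics -> discrepancy -> survival ->
# consolidated report.

#' Pipeline run configuration
#'
#' Exactly one of `input` (a cohort CSV conforming to [cohort_schema()])
#' or `simulation` (a [cohort_spec()]) must be given.
#'
#' @param input path to a cohort CSV, or NULL to simulate.
#' @param simulation a [cohort_spec()], or NULL to read `input`.
#' @param priors [lcm_priors()] for the latent class fit.
#' @param chains,iterations,burn_in Gibbs run settings (see [gibbs_fit()]).
#' @param seeds integer seed per chain (length `chains`).
#' @param impute run mode imputation on masked baseline fields first.
#' @param complete_case also emit a complete-case sensitivity run.
#' @param adjust adjustment covariates for the Cox models.
#' @param rhat_threshold convergence verdict cutoff (default 1.1).
#' @param verbose print per-stage progress lines.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, simulation = NULL,
                       priors = NULL, chains = 3, iterations = 20000,
                       burn_in = 5000, seeds = seq_len(chains),
                       impute = TRUE, complete_case = FALSE,
                       adjust = NULL, rhat_threshold = 1.1,
                       verbose = FALSE) {
  if (is.null(input) == is.null(simulation)) {
    stop("exactly one of 'input' or 'simulation' must be given",
         call. = FALSE)
  }
  if (chains < 2) {
    stop("convergence diagnostics need >=2 chains; refusing chains < 2",
         call. = FALSE)
  }
  if (length(seeds) != chains) {
    stop("'seeds' must have one entry per chain", call. = FALSE)
  }
  structure(list(input = input, simulation = simulation, priors = priors,
                 chains = chains, iterations = iterations,
                 burn_in = burn_in, seeds = as.integer(seeds),
                 impute = impute, complete_case = complete_case,
                 adjust = adjust, rhat_threshold = rhat_threshold,
                 verbose = verbose),
            class = "run_config")
}

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[nutrilcm] ", fmt), ...))
}

#' Per-tool malnutrition prevalence table
#'
#' @param panel diagnosis panel from [apply_all()].
#' @return data frame with `tool`, `n_positive`, `n`, `percent`
#'   (one decimal, half-up).
#' @export
#' @examples
#' prevalence_table(data.frame(pgsga = c(1, 0, 0), espen = c(1, 1, 0),
#'                             glim = c(0, 0, 1)))
prevalence_table <- function(panel) {
  tools <- intersect(c("pgsga", "espen", "glim"), names(panel))
  n <- nrow(panel)
  data.frame(
    tool = toupper(tools),
    n_positive = vapply(tools, function(t) sum(panel[[t]] == 1L), 0L),
    n = n,
    percent = vapply(tools, function(t) pct_of(sum(panel[[t]] == 1L), n), 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Complete-case subset of a cohort
#'
#' Removes every record with any missing baseline field (all schema
#' columns except follow-up). Both sample sizes are recorded as
#' attributes, mirroring a complete-case sensitivity analysis.
#'
#' @param records cohort records data frame.
#' @return the subset, with attributes `n_full` and `n_complete`; an empty
#'   result raises a warning, not an error.
#' @export
complete_case_subset <- function(records) {
  baseline <- setdiff(names(records), c("followup_months", "event"))
  keep <- !Reduce(`|`, lapply(records[baseline], is.na))
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("complete-case subset is empty", call. = FALSE)
  attr(out, "n_full") <- nrow(records)
  attr(out, "n_complete") <- nrow(out)
  out
}

summarize_baseline <- function(records) {
  out <- list(n = nrow(records))
  if ("age" %in% names(records)) {
    n65 <- sum(records$age >= 65, na.rm = TRUE)
    out$age_ge65 <- list(count = n65, percent = pct_of(n65, nrow(records)))
  }
  if ("sex" %in% names(records)) {
    nm <- sum(records$sex == "male", na.rm = TRUE)
    out$male <- list(count = nm, percent = pct_of(nm, nrow(records)))
  }
  if ("event" %in% names(records)) {
    ne <- sum(records$event, na.rm = TRUE)
    out$deaths <- list(count = ne, percent = pct_of(ne, nrow(records)))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on a simulated or loaded cohort and
#' returns a consolidated report. All randomness flows from the seeds in
#' the configuration, so repeated runs are identical. LCM non-convergence
#' (any Rhat at or above the threshold) flags the report but does not
#' abort the run.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `cohort_summary`, `prevalence`,
#'   `lcm` (posterior summary, convergence table, verdict,
#'   orientation flags), `discrepancy`, `survival` (binary for all tools;
#'   severity for PG-SGA and GLIM), `provenance`, and (if requested)
#'   `complete_case`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose

  if (!is.null(config$simulation)) {
    stage_msg(v, "simulate: n = %d, seed = %s",
              config$simulation$n_patients,
              config$simulation$seed %||% "none")
    cohort <- generate_mechanistic_cohort(config$simulation)
    cohort <- attach_survival(cohort)
    if (config$simulation$missing_fraction > 0) {
      cohort <- inject_missingness(
        cohort, config$simulation$missing_fraction,
        seed = if (!is.null(config$simulation$seed))
          config$simulation$seed + 2L else NULL)
    }
    records <- cohort$records
  } else {
    stage_msg(v, "load: %s", config$input)
    records <- read_cohort(config$input)
    required <- c("id", "pgsga_score", "nrs_positive", "bmi", "age")
    miss <- setdiff(required, names(records))
    if (length(miss)) {
      stop(sprintf("cohort CSV is missing required column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }

  records_raw <- records   # pre-imputation snapshot for the sensitivity run
  if (config$impute) {
    stage_msg(v, "impute: mode imputation on baseline fields")
    baseline <- setdiff(names(records), c("followup_months", "event"))
    with_na <- baseline[vapply(records[baseline], anyNA, logical(1))]
    if (length(with_na)) records <- mode_impute(records, with_na)
  }

  stage_msg(v, "diagnose: applying PG-SGA, ESPEN, GLIM")
  panel <- apply_all(records)
  prevalence <- prevalence_table(panel)

  stage_msg(v, "crossclass + fit-lcm: %d chains x %d iterations",
            config$chains, config$iterations)
  table <- build_cross_class(panel[c("pgsga", "espen", "glim")])
  draws <- gibbs_fit(table, priors = config$priors,
                     chains = config$chains,
                     iterations = config$iterations,
                     burn_in = config$burn_in, seeds = config$seeds)
  draws <- enforce_orientation(draws)
  lcm_summary <- lcm_summarize(draws)
  convergence <- gelman_rubin(draws, threshold = config$rhat_threshold)

  stage_msg(v, "discrepancy: ESPEN/GLIM pathway attribution")
  discrepancy <- build_discrepancy_report(records, panel)

  survival <- NULL
  if (all(c("followup_months", "event") %in% names(records))) {
    stage_msg(v, "survival: KM / log-rank / Cox per tool")
    survival <- list(
      binary = survival_by_nutrition(records, panel, "binary",
                                     adjust = config$adjust),
      severity = survival_by_nutrition(records, panel, "severity",
                                       tools = c("pgsga", "glim"),
                                       adjust = config$adjust))
  }

  report <- structure(list(
    cohort_summary = summarize_baseline(records),
    prevalence = prevalence,
    cross_class = table,
    lcm = list(summary = lcm_summary, convergence = convergence,
               converged = attr(convergence, "converged"),
               orientation_flipped = draws$orientation_flipped),
    discrepancy = discrepancy,
    survival = survival,
    provenance = list(package = "nutrilcm",
                      version = as.character(utils::packageVersion("nutrilcm")),
                      seeds = config$seeds,
                      chains = config$chains,
                      iterations = config$iterations,
                      burn_in = config$burn_in)),
    class = "run_report")

  if (config$complete_case) {
    cc <- complete_case_subset(records_raw)
    cc_panel <- apply_all(cc)
    report$complete_case <- list(
      n_full = attr(cc, "n_full"), n_complete = attr(cc, "n_complete"),
      prevalence = prevalence_table(cc_panel))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("nutrilcm pipeline report\n")
  cat(sprintf("  cohort: n = %d\n", x$cohort_summary$n))
  cat("  prevalence by tool:\n")
  print.data.frame(x$prevalence, row.names = FALSE)
  cat(sprintf("  LCM: %s\n",
              if (x$lcm$converged) "converged" else "NOT converged"))
  print.data.frame(x$lcm$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a run report to JSON (and plain text)
#'
#' @param report a `run_report`.
#' @param path output JSON path; a sibling `.txt` with the printed report
#'   is written alongside when `text = TRUE`.
#' @param text also write the human-readable rendering.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path, text = TRUE) {
  stopifnot(inherits(report, "run_report"))
  serializable <- rapply(unclass(report), function(x) x, how = "replace")
  jsonlite::write_json(serializable, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE, pretty = TRUE)
  if (text) {
    txt <- sub("\\.json$", ".txt", path)
    if (identical(txt, path)) txt <- paste0(path, ".txt")
    utils::capture.output(print(report), file = txt)
  }
  invisible(path)
}
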