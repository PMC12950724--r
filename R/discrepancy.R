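# Attribution of discordant ESPEN/GLIM diagnoses to the rule pathway that
# caused them, with chi-square / Fisher group comparisons.

#' Classify ESPEN/GLIM concordance
#'
#' @param espen,glim binary (0/1 or logical) malnutrition indicators, equal
#'   length.
#' @return factor with levels `both`, `espen_only`, `glim_only`, `neither`.
#' @export
#' @examples
#' classify_concordance(c(1, 1, 0, 0), c(1, 0, 1, 0))
classify_concordance <- function(espen, glim) {
  stopifnot(length(espen) == length(glim))
  e <- as.integer(as.logical(espen)); g <- as.integer(as.logical(glim))
  if (anyNA(e) || anyNA(g)) stop("diagnoses must be non-missing", call. = FALSE)
  factor(ifelse(e == 1 & g == 1, "both",
                ifelse(e == 1, "espen_only",
                       ifelse(g == 1, "glim_only", "neither"))),
         levels = c("both", "espen_only", "glim_only", "neither"))
}

#' Attribute an ESPEN diagnosis to its driving pathway
#'
#' For a patient diagnosed malnourished by ESPEN, identifies which rule
#' feature drove the diagnosis, in the priority order used for the
#' discrepancy table of ESPEN-only diagnoses:
#' \enumerate{
#'   \item `"C2-WL-anytime"` — condition 2 fired, but the weight-loss
#'     clause holds only through "> 10% at any time": there is no
#'     GLIM-qualifying loss (> 5% within 6 months or > 10% beyond
#'     6 months) and the 3-month clause is not met, so the timing of the
#'     loss — not the BMI cutoff — is what GLIM cannot see;
#'   \item `"C2-BMI-band"` — condition 2 fired through a BMI in
#'     \[18.5, 20) with age < 70, the band GLIM's stricter low-BMI cutoff
#'     excludes (the loss itself would have qualified under GLIM);
#'   \item `"C3-FFMI"` — only condition 3 (weight loss + low FFMI) fired;
#'   \item `"C1"` — BMI < 18.5;
#'   \item `"multiple"` — anything else.
#' }
#'
#' @param r the patient record (one-row data frame or named list).
#' @param espen the ESPEN `diagnosis` for the record (must be
#'   malnourished).
#' @param glim the GLIM `diagnosis` (used only to note concordance; the
#'   label logic depends on the record's fields).
#' @return a character pathway label with attribute `rules` (the ESPEN
#'   rules that fired).
#' @export
attribute_espen_pathway <- function(r, espen, glim = NULL) {
  stopifnot(inherits(espen, "diagnosis"), espen$tool == "ESPEN")
  if (!espen$malnourished) {
    stop("pathway attribution is defined only for ESPEN-malnourished patients",
         call. = FALSE)
  }
  fired <- espen$triggered_rules
  bmi <- field(r, "bmi"); age <- field(r, "age")
  wl_any <- field(r, "wl_any_time_pct"); wl_3mo <- field(r, "wl_3mo_pct")
  wl_6mo <- field(r, "wl_6mo_pct"); wl_beyond <- field(r, "wl_beyond_6mo_pct")

  glim_wl <- isTRUE(wl_6mo > 5) || isTRUE(wl_beyond > 10)
  label <-
    if ("C2" %in% fired && isTRUE(wl_any > 10) && !glim_wl &&
        !isTRUE(wl_3mo > 5)) {
      "C2-WL-anytime"
    } else if ("C2" %in% fired && isTRUE(bmi >= 18.5) && isTRUE(bmi < 20) &&
               isTRUE(age < 70)) {
      "C2-BMI-band"
    } else if (identical(fired, "C3")) {
      "C3-FFMI"
    } else if (isTRUE(bmi < 18.5)) {
      "C1"
    } else {
      "multiple"
    }
  structure(label, rules = fired)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic `sum((O - E)^2 / E)` without continuity correction,
#' with `df = (r - 1)(c - 1)` and the upper chi-square tail p-value.
#'
#' @param table matrix of nonnegative integer counts, at least 2 x 2.
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
#' @examples
#' chi_square(rbind(c(10, 20), c(20, 10)))
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("need at least a 2x2 table", call. = FALSE)
  }
  if (any(table < 0) || any(table != floor(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal row or column", call. = FALSE)
  }
  # small expected cells are handled by the caller's Fisher rule, so the
  # usual approximation warning is noise here
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), expected = ht$expected)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by hypergeometric enumeration: the sum of
#' probabilities of all tables (with the observed margins) no more likely
#' than the observed one.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts.
#' @return the two-sided p-value.
#' @export
#' @examples
#' fisher_exact(rbind(c(1, 9), c(11, 3)))
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) {
    stop("Fisher's exact test here handles 2x2 tables only", call. = FALSE)
  }
  if (any(table < 0) || any(table != floor(table))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  stats::fisher.test(table)$p.value
}

#' Build the ESPEN/GLIM discrepancy report
#'
#' Partitions the cohort by concordance, attributes every ESPEN-only
#' diagnosis to its driving pathway, and compares characteristics
#' (age < 70, GLIM-qualifying weight loss, ESPEN-only "> 10% at any time"
#' loss, reduced FFMI, reduced muscle mass) between the ESPEN-only and
#' both-positive groups, using the chi-square test unless any expected
#' cell count is below 5, in which case Fisher's exact test is used.
#' Percentages are reported to one decimal, rounding half up.
#'
#' @param records cohort records data frame.
#' @param panel diagnosis panel from [apply_all()] (binary `espen`, `glim`
#'   columns aligned with `records`).
#' @return a `discrepancy_report`: list with `groups` (named sizes),
#'   `pathways` (data frame of counts/percentages of ESPEN-only patients),
#'   `characteristics` (comparison rows with the test used and p-value),
#'   and `pathway_labels` (per ESPEN-only patient).
#' @export
build_discrepancy_report <- function(records, panel) {
  stopifnot(nrow(records) == nrow(panel))
  conc <- classify_concordance(panel$espen, panel$glim)
  groups <- c(total = nrow(records), table(conc))
  names(groups) <- c("total", levels(conc))

  eo_idx <- which(conc == "espen_only")
  labels <- character(length(eo_idx))
  for (j in seq_along(eo_idx)) {
    i <- eo_idx[j]
    r <- records[i, , drop = FALSE]
    labels[j] <- as.character(attribute_espen_pathway(r, diagnose_espen(r)))
  }
  n_eo <- length(eo_idx)
  path_levels <- c("C2-WL-anytime", "C2-BMI-band", "C3-FFMI", "C1", "multiple")
  path_counts <- table(factor(labels, levels = path_levels))
  pathways <- data.frame(
    pathway = path_levels,
    count = as.integer(path_counts),
    percent = if (n_eo > 0) pct_of(as.integer(path_counts), n_eo) else
      rep(NA_real_, length(path_levels)),
    stringsAsFactors = FALSE)

  characteristics <- NULL
  both_idx <- which(conc == "both")
  if (n_eo > 0 && length(both_idx) > 0 && "age" %in% names(records)) {
    feats <- list(
      age_lt70 = records$age < 70,
      glim_weight_loss = records$wl_6mo_pct > 5 | records$wl_beyond_6mo_pct > 10,
      espen_only_weight_loss = records$wl_any_time_pct > 10 &
        !(records$wl_6mo_pct > 5 | records$wl_beyond_6mo_pct > 10),
      reduced_ffmi = records$ffmi < ifelse(records$sex == "female", 15, 17),
      reduced_muscle = records$muscle_reduced_anthro |
        records$ffmi < ifelse(records$sex == "female", 15, 17)
    )
    rows <- lapply(names(feats), function(nm) {
      f <- feats[[nm]]
      a <- sum(f[eo_idx], na.rm = TRUE); b <- sum(f[both_idx], na.rm = TRUE)
      tab <- rbind(c(a, n_eo - a), c(b, length(both_idx) - b))
      use_fisher <- tryCatch(
        any(chi_square(tab)$expected < 5), error = function(e) TRUE)
      p <- if (use_fisher) fisher_exact(tab) else chi_square(tab)$p
      data.frame(characteristic = nm,
                 espen_only_n = a, espen_only_pct = pct_of(a, n_eo),
                 both_n = b, both_pct = pct_of(b, length(both_idx)),
                 test = if (use_fisher) "fisher" else "chi-square",
                 p = p, stringsAsFactors = FALSE)
    })
    characteristics <- do.call(rbind, rows)
  }

  structure(list(groups = groups, pathways = pathways,
                 characteristics = characteristics,
                 pathway_labels = labels),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  g <- x$groups
  cat(sprintf("ESPEN/GLIM concordance (N = %d): both %d, ESPEN-only %d, GLIM-only %d, neither %d\n",
              g["total"], g["both"], g["espen_only"], g["glim_only"],
              g["neither"]))
  cat("ESPEN-only diagnostic pathways:\n")
  print.data.frame(x$pathways, row.names = FALSE)
  if (!is.null(x$characteristics)) {
    cat("Group comparisons (ESPEN-only vs both):\n")
    print.data.frame(x$characteristics, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
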