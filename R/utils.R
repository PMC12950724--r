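# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; clinical tables conventionally
#' round half up, so percentages such as 255/1081 print as 23.6.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded with halves going away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a count as a percentage of a denominator
#'
#' @param count numeric numerator.
#' @param total numeric denominator (> 0).
#' @param digits decimal places (default 1, the usual table convention).
#' @return numeric percentage rounded half up.
#' @keywords internal
pct_of <- function(count, total, digits = 1) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, digits)
}

# Validation helpers ---------------------------------------------------------

check_probability <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("'%s' must be numeric with no missing values", name),
         call. = FALSE)
  }
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (any(x < lo) || any(x > hi)) {
    stop(sprintf("'%s' must lie in [%s, %s]", name,
                 if (allow_zero) "0" else "(0", if (allow_one) "1]" else "1)"),
         call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x) || (strict && any(x <= 0)) ||
      (!strict && any(x < 0))) {
    stop(sprintf("'%s' must be %s", name,
                 if (strict) "a positive number" else "nonnegative"),
         call. = FALSE)
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

# %||% as in rlang, kept internal to avoid the dependency
`%||%` <- function(a, b) if (is.null(a)) b else a
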