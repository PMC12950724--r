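# Survival machinery implemented from first principles: product-limit
# estimator, log-rank test, and Cox proportional hazards via the partial
# likelihood (Efron or Breslow ties) maximized by damped Newton-Raphson.

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`. Censorings
#' tied with events leave the risk set after the events at that time. The
#' median is the smallest time at which S(t) drops to 0.5 or below; if S
#' never crosses 0.5 the median is undefined and reported as `NA`.
#'
#' @param times positive follow-up times.
#' @param events binary event indicators (1 = event, 0 = censored).
#' @return a `km_curve`: data frame `steps` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (one row per distinct observed time),
#'   plus `median` and `n`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$steps
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(times) == length(events))
  if (any(times <= 0) || anyNA(times)) {
    stop("'times' must be positive and non-missing", call. = FALSE)
  }
  events <- as.integer(events)
  if (!all(events %in% c(0L, 1L))) {
    stop("'events' must be binary", call. = FALSE)
  }
  ut <- sort(unique(times))
  n_risk <- n_event <- n_censor <- integer(length(ut))
  for (j in seq_along(ut)) {
    n_risk[j] <- sum(times >= ut[j])
    n_event[j] <- sum(times == ut[j] & events == 1L)
    n_censor[j] <- sum(times == ut[j] & events == 0L)
  }
  surv <- cumprod(1 - n_event / n_risk)
  steps <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                      n_censor = n_censor, surv = surv)
  med_idx <- which(surv <= 0.5)
  median <- if (length(med_idx)) ut[med_idx[1]] else NA_real_
  structure(list(steps = steps, median = median, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, median survival %s\n",
              x$n, sum(x$steps$n_event),
              if (is.na(x$median)) "not reached" else
                sprintf("%.1f months", x$median)))
  invisible(x)
}

#' Log-rank test across two or more groups
#'
#' At each distinct event time the observed events per group are compared
#' with their hypergeometric expectation given the risk sets; the
#' statistic is `(O - E)' V^-1 (O - E)` over the first G - 1 groups, with
#' G - 1 degrees of freedom and an upper chi-square tail p-value.
#'
#' @param times,events as in [km_estimate()].
#' @param group group labels (coerced to factor); every level must be
#'   nonempty.
#' @return a `logrank_result` list: `statistic`, `df`, `p`,
#'   `observed`/`expected` per group.
#' @export
log_rank <- function(times, events, group) {
  group <- factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2) {
    stop("need >=2 nonempty groups", call. = FALSE)
  }
  stopifnot(length(times) == length(events),
            length(times) == length(group))
  events <- as.integer(events)
  G <- nlevels(group)
  ev_times <- sort(unique(times[events == 1L]))
  O <- E <- numeric(G)
  V <- matrix(0, G - 1, G - 1)
  for (t in ev_times) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    d_j <- sum(times == t & events == 1L)
    n_gj <- tabulate(group[at_risk], nbins = G)
    d_gj <- tabulate(group[times == t & events == 1L], nbins = G)
    O <- O + d_gj
    E <- E + n_gj * d_j / n_j
    if (n_j > 1) {
      p_g <- n_gj / n_j
      mult <- d_j * (n_j - d_j) / (n_j - 1)
      for (g in seq_len(G - 1)) for (h in seq_len(G - 1)) {
        V[g, h] <- V[g, h] +
          mult * p_g[g] * ((g == h) - p_g[h])
      }
    }
  }
  u <- (O - E)[seq_len(G - 1)]
  statistic <- tryCatch(as.numeric(t(u) %*% solve(V, u)),
                        error = function(e) 0)
  structure(list(statistic = statistic, df = G - 1,
                 p = stats::pchisq(statistic, G - 1, lower.tail = FALSE),
                 observed = O, expected = E,
                 groups = levels(group)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

# Partial likelihood, gradient and information for given beta.
# Efron ties: for event time with d tied events, the l-th (l = 0..d-1)
# denominator subtracts l/d of the tied subjects' risk weights.
cox_loglik <- function(beta, X, times, events, ties) {
  n <- nrow(X); p <- ncol(X)
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  ord <- order(times, decreasing = TRUE)
  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  S0 <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- 1
  while (i <= n) {
    t_cur <- times[ord[i]]
    # add everyone with this time to the risk set
    j <- i
    while (j <= n && times[ord[j]] == t_cur) {
      k <- ord[j]
      S0 <- S0 + w[k]
      S1 <- S1 + w[k] * X[k, ]
      S2 <- S2 + w[k] * tcrossprod(X[k, ])
      j <- j + 1
    }
    dead <- ord[i:(j - 1)][events[ord[i:(j - 1)]] == 1L]
    d <- length(dead)
    if (d > 0) {
      S0D <- sum(w[dead])
      S1D <- colSums(X[dead, , drop = FALSE] * w[dead])
      S2D <- matrix(0, p, p)
      for (k in dead) S2D <- S2D + w[k] * tcrossprod(X[k, ])
      ll <- ll + sum(eta[dead])
      U <- U + colSums(X[dead, , drop = FALSE])
      cs <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
      for (c_l in cs) {
        phi <- S0 - c_l * S0D
        mu <- (S1 - c_l * S1D) / phi
        ll <- ll - log(phi)
        U <- U - mu
        I <- I + (S2 - c_l * S2D) / phi - tcrossprod(mu)
      }
    }
    i <- j
  }
  list(loglik = ll, gradient = U, information = I)
}

#' Cox proportional hazards regression
#'
#' Maximizes the partial likelihood by damped Newton-Raphson (step-halving
#' when a step would decrease the likelihood), with the Efron tie
#' correction by default. Standard errors come from the inverse observed
#' information; confidence intervals are Wald:
#' `exp(beta +/- 1.96 se)`.
#'
#' @param X covariate matrix (or vector for a single covariate); columns
#'   are used as-is (center/encode beforehand).
#' @param times,events as in [km_estimate()]; at least one event required.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return a `cox_fit`: data frame `coefficients` with `term`, `beta`,
#'   `se`, `hr`, `lower`, `upper`, `p`; plus `loglik`, `score_test` (the
#'   score chi-square at beta = 0), `iterations`, `converged`, `ties`.
#'   Non-convergence is flagged, never silent; a monotone likelihood
#'   (separation) triggers a warning.
#' @export
cox_fit <- function(X, times, events, ties = c("efron", "breslow"),
                    max_iter = 30, tol = 1e-9) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  events <- as.integer(events)
  stopifnot(nrow(X) == length(times), length(times) == length(events))
  if (sum(events) < 1) stop("need at least one event", call. = FALSE)
  p <- ncol(X)

  # degenerate constant columns get beta = 0 by construction
  const <- apply(X, 2, function(v) max(v) == min(v))
  beta <- numeric(p)
  cur <- cox_loglik(beta, X, times, events, ties)
  score_U <- cur$gradient; score_I <- cur$information
  active <- which(!const)
  score_test <- if (length(active))
    tryCatch(as.numeric(t(score_U[active]) %*%
                          solve(score_I[active, active, drop = FALSE],
                                score_U[active])),
             error = function(e) NA_real_)
  else 0

  converged <- length(active) == 0
  it <- 0
  if (length(active)) {
    for (it in seq_len(max_iter)) {
      step <- numeric(p)
      step[active] <- tryCatch(
        solve(cur$information[active, active, drop = FALSE],
              cur$gradient[active]),
        error = function(e) rep(NA_real_, length(active)))
      if (anyNA(step)) break
      # damping: halve until the likelihood does not decrease
      lambda <- 1
      repeat {
        cand <- beta + lambda * step
        new <- cox_loglik(cand, X, times, events, ties)
        if (new$loglik >= cur$loglik - 1e-12 || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      delta <- max(abs(cand - beta))
      beta <- cand
      cur <- new
      if (delta < tol || max(abs(cur$gradient[active])) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("Cox fit did not converge; estimates are flagged", call. = FALSE)
  }
  if (any(abs(beta) > 15)) {
    warning(paste("very large coefficient: possible monotone likelihood",
                  "(complete separation)"), call. = FALSE)
  }
  se <- rep(NA_real_, p)
  if (length(active)) {
    vc <- tryCatch(solve(cur$information[active, active, drop = FALSE]),
                   error = function(e) matrix(NA_real_, length(active),
                                              length(active)))
    se[active] <- sqrt(diag(as.matrix(vc)))
  }
  se[const] <- NA_real_
  z <- beta / se
  coefficients <- data.frame(
    term = colnames(X),
    beta = beta, se = se, hr = exp(beta),
    lower = exp(beta - 1.959963984540054 * se),
    upper = exp(beta + 1.959963984540054 * se),
    p = 2 * stats::pnorm(-abs(z)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefficients, loglik = cur$loglik,
                 score_test = score_test, iterations = it,
                 converged = converged, ties = ties, n = nrow(X),
                 n_events = sum(events)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): n = %d, events = %d%s\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print.data.frame(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

severity_labels <- function(tool, panel) {
  switch(tool,
         pgsga = factor(panel$pgsga_subgroup,
                        levels = c("well", "possibly_moderate", "severe")),
         glim = factor(panel$glim_category,
                       levels = c("well", "moderate", "severe")),
         espen = stop(paste("the ESPEN criteria do not grade malnutrition",
                            "severity; severity grouping is not available",
                            "for ESPEN"), call. = FALSE))
}

#' Survival stratified by nutritional diagnosis
#'
#' For each requested tool, builds Kaplan-Meier curves per nutrition
#' group, a log-rank comparison, and a Cox fit with the malnutrition
#' indicator(s) plus optional adjustment covariates. Binary grouping uses
#' the tool's malnourished flag; severity grouping uses PG-SGA's pooled
#' 2--8 / >= 9 subgroups or GLIM's moderate/severe grades. ESPEN carries
#' no severity grading, so requesting severity for ESPEN is refused with
#' an error rather than silently falling back to binary.
#'
#' @param records cohort records with `followup_months` and `event`.
#' @param panel diagnosis panel from [apply_all()] (category columns
#'   required for severity grouping).
#' @param grouping `"binary"` or `"severity"`.
#' @param tools tools to analyze (default all three; ESPEN is dropped
#'   automatically only if *not* explicitly requested with severity).
#' @param adjust character vector of numeric/logical record columns to
#'   adjust the Cox model for.
#' @return named list per tool: `curves` (list of `km_curve` per group),
#'   `log_rank`, `cox`.
#' @export
survival_by_nutrition <- function(records, panel,
                                  grouping = c("binary", "severity"),
                                  tools = c("pgsga", "espen", "glim"),
                                  adjust = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(all(c("followup_months", "event") %in% names(records)),
            nrow(records) == nrow(panel))
  times <- records$followup_months
  events <- records$event

  adj_mat <- NULL
  if (length(adjust)) {
    missing_cols <- setdiff(adjust, names(records))
    if (length(missing_cols)) {
      stop(sprintf("adjustment covariates not in records: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    adj_mat <- sapply(adjust, function(col) as.numeric(records[[col]]))
    colnames(adj_mat) <- adjust
  }

  out <- list()
  for (tool in tools) {
    grp <- if (grouping == "binary") {
      factor(ifelse(panel[[tool]] == 1, "malnourished", "well"),
             levels = c("well", "malnourished"))
    } else {
      severity_labels(tool, panel)
    }
    grp <- droplevels(grp)
    curves <- lapply(levels(grp), function(lv) {
      km_estimate(times[grp == lv], events[grp == lv])
    })
    names(curves) <- levels(grp)
    lr <- log_rank(times, events, grp)
    dummies <- stats::model.matrix(~grp)[, -1, drop = FALSE]
    colnames(dummies) <- sub("^grp", paste0(tool, ":"), colnames(dummies))
    X <- if (is.null(adj_mat)) dummies else cbind(dummies, adj_mat)
    out[[tool]] <- list(curves = curves, log_rank = lr,
                        cox = cox_fit(X, times, events))
  }
  out
}
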