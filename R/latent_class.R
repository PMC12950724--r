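# Bayesian latent class model for K conditionally independent binary
# diagnostic tests without a gold standard, fitted by data-augmentation
# Gibbs sampling. With one population and K = 3 tests the model is
# just-identifiable: 7 parameters (prevalence + Se/Sp per test) against
# the 7 degrees of freedom of the 2^3 cross-classification.

pattern_bits <- function(k_tests) {
  # row p+1 holds the K binary results of pattern p, test k on bit k-1
  patterns <- 0:(2^k_tests - 1)
  m <- sapply(seq_len(k_tests) - 1L,
              function(b) bitwAnd(patterns, bitwShiftL(1L, b)) > 0L)
  matrix(as.integer(m), nrow = length(patterns))
}

#' Cross-classify per-patient test panels
#'
#' Counts patients by their K-test result pattern. Pattern index is
#' `sum(y_k * 2^(k-1))` with the fixed test order (PG-SGA, ESPEN, GLIM),
#' so pattern 0 is all-negative and pattern `2^K - 1` all-positive.
#'
#' @param panels matrix or data frame of binary results, one row per
#'   patient, one column per test; may carry an `id` column which is used
#'   in error messages.
#' @return a `cross_class_table`: list with `k_tests`, integer `counts`
#'   of length `2^K` (named by the bit pattern), and `n`.
#' @export
#' @examples
#' build_cross_class(rbind(c(1, 1, 1), c(0, 0, 0), c(1, 1, 1)))
build_cross_class <- function(panels) {
  if (is.data.frame(panels)) {
    ids <- panels$id
    panels <- as.matrix(panels[setdiff(names(panels), "id")])
  } else {
    ids <- NULL
    panels <- as.matrix(panels)
  }
  if (nrow(panels) == 0L) stop("empty cohort", call. = FALSE)
  bad <- which(!(panels %in% c(0L, 1L)) | is.na(panels),
               arr.ind = FALSE)
  if (length(bad)) {
    row <- ((bad[1] - 1) %% nrow(panels)) + 1
    stop(sprintf("non-binary test result for patient %s",
                 if (!is.null(ids)) ids[row] else row), call. = FALSE)
  }
  K <- ncol(panels)
  pattern <- as.integer(panels %*% 2^(seq_len(K) - 1))
  counts <- tabulate(pattern + 1L, nbins = 2^K)
  names(counts) <- vapply(0:(2^K - 1), function(p)
    paste(rev(as.integer(intToBits(p))[seq_len(K)]), collapse = ""),
    character(1))
  structure(list(k_tests = K, counts = counts, n = sum(counts)),
            class = "cross_class_table")
}

#' @export
print.cross_class_table <- function(x, ...) {
  cat(sprintf("Cross-classification of %d tests, N = %d\n", x$k_tests, x$n))
  print(x$counts)
  invisible(x)
}

#' Latent-class cell probability of a test-result pattern
#'
#' Under conditional independence given the latent state, the probability
#' of observing pattern y is the two-class mixture
#' \deqn{P(y) = \pi \prod_k Se_k^{y_k} (1-Se_k)^{1-y_k}
#'       + (1-\pi) \prod_k (1-Sp_k)^{y_k} Sp_k^{1-y_k}.}
#'
#' @param params list with `prevalence`, `se`, `sp` (vectors of length K).
#' @param pattern integer pattern index/indices in `0:(2^K - 1)` (bit k-1
#'   is test k), or missing to return the full vector of `2^K` cell
#'   probabilities (which sums to 1).
#' @return numeric vector of probabilities.
#' @export
#' @examples
#' p <- list(prevalence = 0.3, se = c(1, 1, 1), sp = c(1, 1, 1))
#' cell_probability(p, 7)  # all-positive: 0.3
cell_probability <- function(params, pattern = NULL) {
  check_probability(params$prevalence, "prevalence")
  check_probability(params$se, "se")
  check_probability(params$sp, "sp")
  K <- length(params$se)
  stopifnot(length(params$sp) == K)
  bits <- pattern_bits(K)
  if (is.null(pattern)) pattern <- 0:(2^K - 1)
  stopifnot(all(pattern >= 0), all(pattern < 2^K))
  b <- bits[pattern + 1L, , drop = FALSE]
  a_y <- apply(b, 1, function(y)
    prod(params$se^y * (1 - params$se)^(1 - y)))
  b_y <- apply(b, 1, function(y)
    prod((1 - params$sp)^y * params$sp^(1 - y)))
  params$prevalence * a_y + (1 - params$prevalence) * b_y
}

#' Prior specification for the latent class model
#'
#' Beta hyperparameters for the prevalence and each test's sensitivity and
#' specificity. Defaults are flat Beta(1, 1) throughout; informative pairs
#' can be supplied per parameter.
#'
#' @param prevalence,se,sp Beta (a, b) pairs: `prevalence` a length-2
#'   vector; `se` and `sp` 2-column matrices with one row per test (a
#'   single pair is recycled).
#' @param k_tests number of tests (default 3).
#' @return an `lcm_priors` list.
#' @export
lcm_priors <- function(prevalence = c(1, 1), se = c(1, 1), sp = c(1, 1),
                       k_tests = 3) {
  expand <- function(x, name) {
    m <- if (is.matrix(x)) x else
      matrix(x, nrow = k_tests, ncol = 2, byrow = TRUE)
    if (nrow(m) != k_tests || ncol(m) != 2 || any(m <= 0)) {
      stop(sprintf("'%s' must give positive Beta (a, b) pairs for %d tests",
                   name, k_tests), call. = FALSE)
    }
    m
  }
  stopifnot(length(prevalence) == 2, all(prevalence > 0))
  structure(list(prevalence = prevalence,
                 se = expand(se, "se"), sp = expand(sp, "sp"),
                 k_tests = k_tests),
            class = "lcm_priors")
}

lcm_param_names <- function(K) {
  test_names <- if (K == length(TEST_ORDER)) TEST_ORDER else
    paste0("t", seq_len(K))
  c("prevalence", paste0("se_", test_names), paste0("sp_", test_names))
}

#' Fit the latent class model by data-augmentation Gibbs sampling
#'
#' The model is fully conjugate given the latent diseased counts, so each
#' sweep (i) allocates, for every pattern y, a latent diseased count
#' `z_y ~ Binomial(n_y, pi a_y / (pi a_y + (1-pi) b_y))` where `a_y`, `b_y`
#' are the class-conditional pattern probabilities, then (ii) draws the
#' prevalence and every Se/Sp from their Beta full conditionals. Each chain
#' is initialized by an overdispersed draw from the priors and driven by
#' its own seed, so runs are exactly reproducible.
#'
#' With K = 2 tests in a single population the model is not identifiable
#' without informative priors; a warning is emitted in that case.
#'
#' @param table a `cross_class_table` from [build_cross_class()].
#' @param priors an [lcm_priors()]; defaults to flat Beta(1, 1).
#' @param chains number of chains (default 3).
#' @param iterations total sweeps per chain (default 20000).
#' @param burn_in sweeps discarded per chain (default 5000;
#'   `iterations > burn_in` required).
#' @param seeds integer seed per chain (length `chains`).
#' @return an `lcm_draws` object: list with `draws` (list of
#'   `(iterations - burn_in) x (2K + 1)` matrices, one per chain, columns
#'   named `prevalence`, `se_*`, `sp_*`), plus the run settings.
#' @export
gibbs_fit <- function(table, priors = NULL, chains = 3, iterations = 20000,
                      burn_in = 5000, seeds = seq_len(chains)) {
  stopifnot(inherits(table, "cross_class_table"))
  K <- table$k_tests
  if (K > 12) {
    stop("more than 12 tests: the 2^K pattern space is impractically large",
         call. = FALSE)
  }
  if (K == 2) {
    warning(paste("K = 2 tests in a single population is not identifiable",
                  "without informative priors"), call. = FALSE)
  }
  if (is.null(priors)) priors <- lcm_priors(k_tests = K)
  stopifnot(priors$k_tests == K)
  if (iterations <= burn_in || burn_in < 0) {
    stop("'iterations' must exceed 'burn_in' (and burn_in >= 0)",
         call. = FALSE)
  }
  if (length(seeds) != chains) {
    stop("one seed per chain is required", call. = FALSE)
  }

  bits <- pattern_bits(K)           # 2^K x K
  counts <- as.numeric(table$counts)
  N <- sum(counts)
  n_keep <- iterations - burn_in
  par_names <- lcm_param_names(K)
  pos <- bits == 1L                 # logical 2^K x K

  run_chain <- function(seed) {
    set.seed(seed)
    # overdispersed start: an independent draw from the priors per chain
    pi <- stats::rbeta(1, priors$prevalence[1], priors$prevalence[2])
    se <- stats::rbeta(K, priors$se[, 1], priors$se[, 2])
    sp <- stats::rbeta(K, priors$sp[, 1], priors$sp[, 2])
    out <- matrix(NA_real_, n_keep, 2 * K + 1,
                  dimnames = list(NULL, par_names))
    for (it in seq_len(iterations)) {
      a_y <- exp(bits %*% log(se) + (1 - bits) %*% log1p(-se))
      b_y <- exp(bits %*% log1p(-sp) + (1 - bits) %*% log(sp))
      pz <- as.numeric(pi * a_y / (pi * a_y + (1 - pi) * b_y))
      pz[!is.finite(pz)] <- 0.5  # both classes at probability zero
      z <- stats::rbinom(2^K, counts, pz)
      nz <- counts - z
      sz <- sum(z)
      pi <- stats::rbeta(1, priors$prevalence[1] + sz,
                         priors$prevalence[2] + N - sz)
      for (k in seq_len(K)) {
        zp <- sum(z[pos[, k]]);  zn <- sz - zp
        wp <- sum(nz[pos[, k]]); wn <- sum(nz) - wp
        se[k] <- stats::rbeta(1, priors$se[k, 1] + zp, priors$se[k, 2] + zn)
        sp[k] <- stats::rbeta(1, priors$sp[k, 1] + wn, priors$sp[k, 2] + wp)
      }
      if (it > burn_in) out[it - burn_in, ] <- c(pi, se, sp)
    }
    out
  }

  draws <- lapply(seeds, run_chain)
  structure(list(draws = draws, k_tests = K, chains = chains,
                 iterations = iterations, burn_in = burn_in, seeds = seeds,
                 param_names = par_names, oriented = FALSE,
                 orientation_flipped = logical(chains)),
            class = "lcm_draws")
}

#' @export
print.lcm_draws <- function(x, ...) {
  cat(sprintf("LCM posterior draws: %d chains x %d retained (burn-in %d), %d tests\n",
              x$chains, nrow(x$draws[[1]]), x$burn_in, x$k_tests))
  if (x$oriented && any(x$orientation_flipped)) {
    cat(sprintf("  orientation relabeling applied to chain(s): %s\n",
                paste(which(x$orientation_flipped), collapse = ", ")))
  }
  invisible(x)
}

#' Resolve the two-class label-switching ambiguity
#'
#' The latent class likelihood is invariant under the mirror relabeling
#' `pi -> 1 - pi`, `Se_k <-> 1 - Sp_k`: every fit has two equivalent modes.
#' Each chain whose posterior mean violates the orientation constraint
#' `sum_k (Se_k + Sp_k) > K` is mapped onto the constrained mode by the
#' global relabeling; the affected chains are flagged on the returned
#' object.
#'
#' @param draws an `lcm_draws` object.
#' @return the draws, relabeled where needed, with `oriented = TRUE` and
#'   `orientation_flipped` marking the chains that were mirrored.
#' @export
enforce_orientation <- function(draws) {
  stopifnot(inherits(draws, "lcm_draws"))
  K <- draws$k_tests
  se_cols <- 1 + seq_len(K)
  sp_cols <- 1 + K + seq_len(K)
  flipped <- logical(length(draws$draws))
  for (c in seq_along(draws$draws)) {
    m <- colMeans(draws$draws[[c]])
    if (sum(m[se_cols]) + sum(m[sp_cols]) <= K) {
      d <- draws$draws[[c]]
      mirrored <- d
      mirrored[, 1] <- 1 - d[, 1]
      mirrored[, se_cols] <- 1 - d[, sp_cols]
      mirrored[, sp_cols] <- 1 - d[, se_cols]
      draws$draws[[c]] <- mirrored
      flipped[c] <- TRUE
    }
  }
  draws$oriented <- TRUE
  draws$orientation_flipped <- flipped
  draws
}

#' Posterior summaries of latent class draws
#'
#' Pools the chains and reports, per parameter, the posterior mean, median
#' and the equal-tailed 95% credible interval (2.5th and 97.5th pooled
#' percentiles, R's default type-7 quantile rule).
#'
#' @param draws an `lcm_draws` object with at least 50 retained draws
#'   pooled across chains.
#' @return an `lcm_summary` data frame with columns `parameter`, `mean`,
#'   `median`, `lower`, `upper`.
#' @export
lcm_summarize <- function(draws) {
  stopifnot(inherits(draws, "lcm_draws"))
  pooled <- do.call(rbind, draws$draws)
  if (nrow(pooled) < 50) {
    stop("need at least 50 retained draws to summarize", call. = FALSE)
  }
  q <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  out <- data.frame(parameter = colnames(pooled),
                    mean = colMeans(pooled),
                    median = q[2, ], lower = q[1, ], upper = q[3, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("lcm_summary", "data.frame")
  out
}

#' Gelman-Rubin convergence diagnostics
#'
#' For each parameter, computes the within-chain variance W (mean of the
#' per-chain sample variances), the between-chain variance
#' `B = n * var(chain means)`, and the potential scale reduction factor
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W}},}
#' together with an effective sample size from the pooled autocorrelations
#' (Geyer initial positive sequence truncation). Identical chains give
#' `B = 0` and hence `Rhat = sqrt((n-1)/n)`; chains stuck at distinct
#' constants give `W = 0`, reported as `Rhat = Inf` with a warning.
#'
#' @param draws an `lcm_draws` with at least 2 chains of length >= 10.
#' @param threshold Rhat below which a parameter is judged converged
#'   (default 1.1).
#' @return a `convergence_report` data frame with columns `parameter`,
#'   `W`, `B`, `rhat`, `ess`, `converged`, and an attribute
#'   `converged` (TRUE when every parameter passes).
#' @export
gelman_rubin <- function(draws, threshold = 1.1) {
  stopifnot(inherits(draws, "lcm_draws"))
  m <- length(draws$draws)
  if (m < 2) stop("diagnostics need >=2 chains", call. = FALSE)
  n <- nrow(draws$draws[[1]])
  if (n < 10 || any(vapply(draws$draws, nrow, 0L) != n)) {
    stop("chains must have equal length >= 10", call. = FALSE)
  }
  P <- ncol(draws$draws[[1]])
  W <- B <- rhat <- ess <- numeric(P)
  for (p in seq_len(P)) {
    ch <- sapply(draws$draws, function(d) d[, p])   # n x m
    means <- colMeans(ch)
    vars <- apply(ch, 2, stats::var)
    W[p] <- mean(vars)
    B[p] <- n * stats::var(means)
    if (W[p] == 0) {
      rhat[p] <- if (B[p] == 0) 1 else Inf
      if (B[p] > 0) {
        warning(sprintf(
          "parameter '%s': zero within-chain variance with distinct chains; Rhat reported as Inf",
          colnames(draws$draws[[1]])[p]), call. = FALSE)
      }
    } else {
      rhat[p] <- sqrt(((n - 1) / n * W[p] + B[p] / n) / W[p])
    }
    ess[p] <- ess_pooled(ch)
  }
  out <- data.frame(parameter = colnames(draws$draws[[1]]),
                    W = W, B = B, rhat = rhat, ess = ess,
                    converged = is.finite(rhat) & rhat < threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("convergence_report", "data.frame")
  attr(out, "converged") <- all(out$converged)
  attr(out, "threshold") <- threshold
  out
}

# effective sample size over m chains: m*n / (1 + 2 sum rho_t), with the
# chain-averaged autocorrelations truncated at the first nonpositive
# adjacent pair sum (Geyer initial positive sequence)
ess_pooled <- function(ch) {
  n <- nrow(ch); m <- ncol(ch)
  v <- mean(apply(ch, 2, stats::var))
  if (v == 0) return(NA_real_)
  max_lag <- min(n - 1, 1000L)
  rho <- rowMeans(sapply(seq_len(m), function(c) {
    ac <- stats::acf(ch[, c], lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[-1]
    as.numeric(ac)
  }))
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  max(m * n / (1 + 2 * s), 1)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Gelman-Rubin diagnostics (threshold %.2f): %s\n",
              attr(x, "threshold"),
              if (attr(x, "converged")) "all parameters converged"
              else "NOT converged"))
  print.data.frame(x, digits = 4)
  invisible(x)
}
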