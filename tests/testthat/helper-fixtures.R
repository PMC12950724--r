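# Shared fixtures: records are built in code, never stored.

# a screen-positive record with unremarkable covariates; override fields
# via ...
make_record <- function(...) {
  r <- list(id = "T1", age = 60, sex = "male", bmi = 24,
            wl_3mo_pct = 0, wl_6mo_pct = 0, wl_beyond_6mo_pct = 0,
            wl_any_time_pct = 0, ffmi = 20,
            muscle_reduced_anthro = FALSE, pgsga_score = 0,
            nrs_positive = TRUE, reduced_intake = FALSE, has_cancer = TRUE)
  utils::modifyList(r, list(...))
}

# independent enumeration oracle for the latent-class cell probabilities:
# literal sum over the two latent classes with explicit bit loops
oracle_cell_prob <- function(prev, se, sp, pattern) {
  K <- length(se)
  bits <- integer(K)
  p <- pattern
  for (k in seq_len(K)) {
    bits[k] <- p %% 2
    p <- p %/% 2
  }
  total <- 0
  for (d in c(1, 0)) {
    term <- if (d == 1) prev else 1 - prev
    for (k in seq_len(K)) {
      p_pos <- if (d == 1) se[k] else 1 - sp[k]
      term <- term * (if (bits[k] == 1) p_pos else 1 - p_pos)
    }
    total <- total + term
  }
  total
}

# textbook Pearson chi-square computed directly from the definition
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
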