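test_that("cross-classification counts patients by bit pattern", {
  tab <- build_cross_class(rbind(c(1, 1, 1), c(0, 0, 0), c(1, 1, 1)))
  expect_equal(tab$n, 3)
  expect_equal(unname(tab$counts[8]), 2)   # pattern 7, all positive
  expect_equal(unname(tab$counts[1]), 1)   # pattern 0
  expect_equal(sum(tab$counts), 3)
  expect_error(build_cross_class(matrix(numeric(0), 0, 3)), "empty")
  expect_error(
    build_cross_class(data.frame(id = "A", a = 2, b = 0, c = 1)), "A")
})

test_that("cross-class frequencies converge to the model cell probabilities", {
  spec <- cohort_spec(n_patients = 1e4, prevalence = 0.25,
                      se = c(0.80, 0.84, 0.57), sp = c(0.99, 0.43, 0.81),
                      seed = 2)
  coh <- generate_latent_class_cohort(spec)
  tab <- build_cross_class(coh$records[paste0("test_",
                                              c("pgsga", "espen", "glim"))])
  p <- cell_probability(list(prevalence = 0.25, se = spec$se, sp = spec$sp))
  for (j in 1:8) {
    se_j <- sqrt(p[j] * (1 - p[j]) / 1e4)
    expect_lt(abs(tab$counts[j] / 1e4 - p[j]), 3 * se_j + 1e-9)
  }
})

test_that("cell probabilities match brute-force enumeration to 1e-12", {
  # degenerate checks
  perfect <- list(prevalence = 0.3, se = c(1, 1, 1), sp = c(1, 1, 1))
  expect_equal(cell_probability(perfect, 7), 0.3)
  expect_equal(cell_probability(perfect, 0), 0.7)
  expect_equal(sum(cell_probability(perfect)), 1)
  coin <- list(prevalence = 0.5, se = rep(0.5, 3), sp = rep(0.5, 3))
  expect_equal(cell_probability(coin), rep(0.125, 8))
  # random parameter draws against the enumeration oracle
  set.seed(404)
  for (i in 1:1000) {
    K <- sample(2:4, 1)
    prm <- list(prevalence = runif(1), se = runif(K), sp = runif(K))
    pat <- sample(0:(2^K - 1), 1)
    expect_equal(cell_probability(prm, pat),
                 oracle_cell_prob(prm$prevalence, prm$se, prm$sp, pat),
                 tolerance = 1e-12)
  }
})

test_that("cell probabilities sum to one and are mirror-invariant", {
  set.seed(71)
  for (i in 1:200) {
    prm <- list(prevalence = runif(1), se = runif(3), sp = runif(3))
    p <- cell_probability(prm)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    mirror <- list(prevalence = 1 - prm$prevalence,
                   se = 1 - prm$sp, sp = 1 - prm$se)
    expect_equal(p, cell_probability(mirror), tolerance = 1e-12)
  }
})

test_that("single-test fit with point-mass Se/Sp priors matches the conjugate posterior", {
  # Se = Sp = 1 forced by Beta(1e6, 1): the latent state equals the test,
  # so the prevalence posterior is Beta(1 + positives, 1 + negatives)
  pos <- 137; neg <- 363
  panels <- matrix(c(rep(1, pos), rep(0, neg)), ncol = 1)
  tab <- build_cross_class(panels)
  pri <- lcm_priors(se = c(1e6, 1), sp = c(1e6, 1), k_tests = 1)
  d <- gibbs_fit(tab, pri, chains = 2, iterations = 6000, burn_in = 1000,
                 seeds = c(1, 2))
  pooled <- do.call(rbind, d$draws)[, "prevalence"]
  exact_q <- stats::qbeta(c(0.025, 0.5, 0.975), 1 + pos, 1 + neg)
  mc_q <- stats::quantile(pooled, c(0.025, 0.5, 0.975), names = FALSE)
  expect_equal(mc_q, exact_q, tolerance = 0.02)
  expect_equal(mean(pooled), (1 + pos) / (2 + pos + neg), tolerance = 0.005)
})

test_that("degenerate all-positive table concentrates prevalence near 1", {
  panels <- matrix(1L, nrow = 500, ncol = 3)
  tab <- build_cross_class(panels)
  d <- gibbs_fit(tab, chains = 2, iterations = 4000, burn_in = 1000,
                 seeds = c(5, 6))
  d <- enforce_orientation(d)
  s <- lcm_summarize(d)
  expect_gt(s$median[s$parameter == "prevalence"], 0.9)
})

test_that("Gibbs marginals agree with a grid posterior on a K=2 instance", {
  # test 1 pinned to Se = Sp ~ 1 by strong priors; grid over the
  # remaining prevalence, se_2, sp_2 with flat priors
  set.seed(12)
  true <- list(prevalence = 0.35, se = c(1, 0.8), sp = c(1, 0.75))
  status <- rbinom(200, 1, true$prevalence)
  y1 <- status
  y2 <- rbinom(200, 1, ifelse(status == 1, true$se[2], 1 - true$sp[2]))
  tab <- build_cross_class(cbind(y1, y2))
  pri <- lcm_priors(se = rbind(c(1e6, 1), c(1, 1)),
                    sp = rbind(c(1e6, 1), c(1, 1)), k_tests = 2)
  d <- suppressWarnings(
    gibbs_fit(tab, pri, chains = 2, iterations = 12000, burn_in = 2000,
              seeds = c(3, 4)))
  pooled <- do.call(rbind, d$draws)

  g <- seq(0.0025, 0.9975, by = 0.005)
  counts <- as.numeric(tab$counts)   # patterns 00, 10, 01, 11 (test1 = bit 0)
  post <- array(0, c(length(g), length(g), length(g)))
  for (i in seq_along(g)) {
    pi <- g[i]
    # with test 1 perfect, pattern prob: y1 = 1 -> diseased branch only
    for (j in seq_along(g)) {
      se2 <- g[j]
      p10 <- pi * (1 - se2); p11 <- pi * se2
      sp2 <- g
      p00 <- (1 - pi) * sp2; p01 <- (1 - pi) * (1 - sp2)
      post[i, j, ] <- counts[1] * log(p00) + counts[2] * log(p10) +
        counts[3] * log(p01) + counts[4] * log(p11)
    }
  }
  w <- exp(post - max(post))
  w <- w / sum(w)
  grid_mean <- c(
    prevalence = sum(apply(w, 1, sum) * g),
    se_2 = sum(apply(w, 2, sum) * g),
    sp_2 = sum(apply(w, 3, sum) * g))
  expect_equal(mean(pooled[, "prevalence"]), grid_mean["prevalence"],
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(mean(pooled[, "se_t2"]), grid_mean["se_2"],
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(mean(pooled[, "sp_t2"]), grid_mean["sp_2"],
               tolerance = 0.02, ignore_attr = TRUE)
})

test_that("sampler is reproducible and validates its inputs", {
  tab <- build_cross_class(rbind(c(1, 1, 1), c(0, 0, 0), c(1, 0, 1),
                                 c(0, 1, 0)))
  d1 <- gibbs_fit(tab, chains = 2, iterations = 300, burn_in = 100,
                  seeds = c(9, 10))
  d2 <- gibbs_fit(tab, chains = 2, iterations = 300, burn_in = 100,
                  seeds = c(9, 10))
  expect_identical(d1$draws, d2$draws)
  expect_error(gibbs_fit(tab, iterations = 100, burn_in = 100), "burn_in")
  expect_error(gibbs_fit(tab, chains = 2, seeds = 1), "seed")
  k2 <- build_cross_class(cbind(c(1, 0), c(0, 1)))
  expect_warning(gibbs_fit(k2, lcm_priors(k_tests = 2), chains = 2,
                           iterations = 200, burn_in = 50, seeds = c(1, 2)),
                 "not identifiable")
})

test_that("posterior summaries follow the stated percentile rule", {
  mk <- function(x) {
    structure(list(draws = list(matrix(x, ncol = 1,
                                       dimnames = list(NULL, "prevalence"))),
                   k_tests = 1, chains = 1, burn_in = 0,
                   param_names = "prevalence", oriented = FALSE,
                   orientation_flipped = FALSE),
              class = "lcm_draws")
  }
  s <- lcm_summarize(mk(rep(0.5, 200)))
  expect_equal(unlist(s[1, c("mean", "median", "lower", "upper")]),
               c(mean = 0.5, median = 0.5, lower = 0.5, upper = 0.5))
  grid <- seq(0.01, 0.99, by = 0.01)
  s <- lcm_summarize(mk(grid))
  expect_equal(s$lower, 0.0345, tolerance = 1e-10)
  expect_equal(s$upper, 0.9655, tolerance = 1e-10)
  # mirroring the draws mirrors the summary
  sm <- lcm_summarize(mk(1 - grid))
  expect_equal(sm$mean, 1 - s$mean)
  expect_equal(sm$lower, 1 - s$upper)
  expect_equal(sm$upper, 1 - s$lower)
  expect_error(lcm_summarize(mk(runif(30))), "at least 50")
})

test_that("orientation enforcement maps mirrored chains onto the constrained mode", {
  spec <- cohort_spec(n_patients = 2000, seed = 13)
  coh <- generate_latent_class_cohort(spec)
  tab <- build_cross_class(coh$records[paste0("test_",
                                              c("pgsga", "espen", "glim"))])
  d <- gibbs_fit(tab, chains = 2, iterations = 3000, burn_in = 500,
                 seeds = c(21, 22))
  d <- enforce_orientation(d)   # start from the constrained mode
  # manufacture a mixed-label fit: mirror chain 2 wholesale
  K <- 3; se_cols <- 1 + 1:K; sp_cols <- 1 + K + 1:K
  mirrored <- d$draws[[2]]
  tmp <- mirrored[, se_cols]
  mirrored[, se_cols] <- 1 - mirrored[, sp_cols]
  mirrored[, sp_cols] <- 1 - tmp
  mirrored[, 1] <- 1 - mirrored[, 1]
  d_mixed <- d
  d_mixed$draws[[2]] <- mirrored

  # mirroring leaves the likelihood of every draw unchanged
  prm <- function(row) list(prevalence = row[1], se = row[se_cols],
                            sp = row[sp_cols])
  for (i in c(1, 50, 100)) {
    expect_equal(cell_probability(prm(d$draws[[2]][i, ])),
                 cell_probability(prm(mirrored[i, ])), tolerance = 1e-12)
  }

  fixed <- enforce_orientation(d_mixed)
  expect_true(fixed$orientation_flipped[2])
  expect_false(fixed$orientation_flipped[1])
  # after relabeling the chains agree within MC error
  m1 <- colMeans(fixed$draws[[1]]); m2 <- colMeans(fixed$draws[[2]])
  expect_lt(max(abs(m1 - m2)), 0.05)
  # an already-oriented fit is untouched
  again <- enforce_orientation(fixed)
  expect_identical(again$draws, fixed$draws)
  expect_false(any(again$orientation_flipped))
})

test_that("shrink factors behave as the formula dictates", {
  mk <- function(chains) {
    structure(list(draws = chains, k_tests = 1, chains = length(chains),
                   burn_in = 0, param_names = "prevalence",
                   oriented = FALSE,
                   orientation_flipped = logical(length(chains))),
              class = "lcm_draws")
  }
  col <- function(x) matrix(x, ncol = 1, dimnames = list(NULL, "prevalence"))
  n <- 500
  set.seed(31)
  x <- runif(n, 0.2, 0.6)
  # identical chains: B = 0, Rhat = sqrt((n-1)/n)
  r <- gelman_rubin(mk(list(col(x), col(x))))
  expect_equal(r$B, 0)
  expect_equal(r$rhat, sqrt((n - 1) / n), tolerance = 1e-12)
  # iid same-distribution chains mix essentially perfectly
  chains <- lapply(1:3, function(i) col(runif(10000)))
  r <- gelman_rubin(mk(chains))
  expect_lt(r$rhat, 1.01)
  expect_true(r$converged)
  # chains at disjoint constants: W = 0 sentinel
  expect_warning(
    r <- gelman_rubin(mk(list(col(rep(0.2, n)), col(rep(0.8, n))))),
    "Inf")
  expect_true(is.infinite(r$rhat))
  expect_false(r$converged)
  expect_error(gelman_rubin(mk(list(col(x)))), ">=2 chains")
})
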