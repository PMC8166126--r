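test_that("beta-binomial pmf has the right special cases and normalization", {
  # theta = 2, p = 0.5 gives Beta(1, 1): discrete uniform on 0:n
  expect_equal(betabinom_logpmf(0:10, 10, 0.5, 2), rep(log(1 / 11), 11))
  # normalization for several (n, p, theta)
  for (case in list(c(5, 0.3, 4), c(12, 0.8, 1.5), c(30, 0.05, 60))) {
    s <- sum(exp(betabinom_logpmf(0:case[1], case[1], case[2], case[3])))
    expect_equal(s, 1, tolerance = 1e-12)
  }
  # large-precision limit approaches the binomial monotonically
  gap <- function(theta) max(abs(betabinom_logpmf(0:20, 20, 0.3, theta) -
                                   dbinom(0:20, 20, 0.3, log = TRUE)))
  expect_lt(gap(1e6), 1e-3)
  expect_lt(gap(1e6), gap(1e4))
  expect_lt(gap(1e4), gap(1e2))
  expect_error(betabinom_logpmf(3, 10, 0, 5), "p must")
  expect_error(betabinom_logpmf(11, 10, 0.5, 5), "k must")
})

test_that("expected allele fractions follow the error and bias matrices", {
  # no error, no bias: pi passes through
  expect_equal(expected_allele_fractions(list(pi = 0.7, delta = 0, phi = 0.5))$p_tumor,
               0.7)
  # symmetry at pi = 0.5: error mixing alone changes nothing
  ef <- expected_allele_fractions(list(pi = 0.5, delta = 0.02, phi = 0.5))
  expect_equal(ef$p_tumor, 0.5)
  expect_equal(ef$p_normal, 0.5)
  # explicit 2x2 matrix-product oracle
  matrix_oracle <- function(pi, delta, phi) {
    v <- c(1 - pi, pi) %*%
      matrix(c(1 - delta, delta, delta, 1 - delta), 2, 2) %*%
      diag(c(2 * (1 - phi), 2 * phi))
    v[2] / sum(v)
  }
  expect_equal(expected_allele_fractions(list(pi = 0.5, delta = 0, phi = 0.6))$p_tumor,
               matrix_oracle(0.5, 0, 0.6))
  expect_equal(expected_allele_fractions(list(pi = 0.5, delta = 0, phi = 0.6))$p_tumor,
               0.6)
  set.seed(3)
  for (i in 1:20) {
    pi <- runif(1, 0.05, 0.95); delta <- runif(1, 0, 0.1); phi <- runif(1, 0.2, 0.8)
    expect_equal(expected_allele_fractions(list(pi = pi, delta = delta, phi = phi))$p_tumor,
                 matrix_oracle(pi, delta, phi))
  }
  # strictly increasing in pi for fixed delta < 0.5
  ps <- vapply(seq(0.05, 0.95, 0.05), function(p)
    expected_allele_fractions(list(pi = p, delta = 0.05, phi = 0.35))$p_tumor,
    numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("the likelihood composes tumor and normal beta-binomial terms", {
  expect_identical(log_likelihood(data.frame(tumor_a = numeric(0),
                                             tumor_b = numeric(0),
                                             normal_a = numeric(0),
                                             normal_b = numeric(0)),
                                  list(pi = 0.7, delta = 0, phi = 0.5, theta = 50)),
                   0)
  counts <- data.frame(tumor_a = 3, tumor_b = 7, normal_a = 5, normal_b = 5)
  ll <- log_likelihood(counts, list(pi = 0.7, delta = 0, phi = 0.5, theta = 50))
  expect_equal(ll, betabinom_logpmf(3, 10, 0.3, 50) +
                 betabinom_logpmf(5, 10, 0.5, 50))
})

test_that("the likelihood is symmetric under A/B relabeling with pi -> 1-pi, phi -> 1-phi", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    counts <- data.frame(tumor_a = rpois(n, 20), tumor_b = rpois(n, 25),
                         normal_a = rpois(n, 22), normal_b = rpois(n, 22)) + 1
    swapped <- data.frame(tumor_a = counts$tumor_b, tumor_b = counts$tumor_a,
                          normal_a = counts$normal_b, normal_b = counts$normal_a)
    par <- list(pi = runif(1, 0.1, 0.9), delta = runif(1, 0, 0.08),
                phi = runif(1, 0.25, 0.75), theta = runif(1, 5, 300))
    par_sw <- list(pi = 1 - par$pi, delta = par$delta, phi = 1 - par$phi,
                   theta = par$theta)
    expect_equal(log_likelihood(counts, par), log_likelihood(swapped, par_sw))
  }
})

test_that("the log posterior adds independent prior terms", {
  counts <- data.frame(tumor_a = c(10, 14), tumor_b = c(30, 22),
                       normal_a = c(20, 18), normal_b = c(21, 20))
  pr <- ai_priors()
  par <- list(pi = 0.62, delta = 0.01, phi = 0.48, theta = 120)
  hand <- log_likelihood(counts, par) +
    0 +                                                   # uniform pi
    (1 - 1) * log(par$delta) + (50 - 1) * log1p(-par$delta) +
    (20 - 1) * log(par$phi) + (20 - 1) * log1p(-par$phi) +
    -log(par$theta)
  expect_equal(log_posterior(par, counts, pr), hand)
  # flat priors: posterior - likelihood constant in params
  flat <- ai_priors(delta = list(family = "uniform", lower = 1e-6, upper = 0.1),
                    phi = list(family = "uniform", lower = 0.2, upper = 0.8),
                    theta = list(family = "uniform", lower = 1, upper = 1e4))
  d1 <- log_posterior(par, counts, flat) - log_likelihood(counts, par)
  par2 <- list(pi = 0.3, delta = 0.05, phi = 0.7, theta = 10)
  d2 <- log_posterior(par2, counts, flat) - log_likelihood(counts, par2)
  expect_equal(d1, d2)
  # outside the prior box
  expect_identical(log_posterior(list(pi = 0.999, delta = 0.01, phi = 0.5,
                                      theta = 100), counts, pr), -Inf)
})

test_that("the compiled objective agrees with the reference log posterior", {
  set.seed(11)
  pr <- ai_priors()
  for (i in 1:10) {
    n <- sample(2:6, 1)
    counts <- data.frame(tumor_a = rpois(n, 30), tumor_b = rpois(n, 30),
                         normal_a = rpois(n, 30), normal_b = rpois(n, 30)) + 1
    par <- c(pi = runif(1, 0.05, 0.95), delta = runif(1, 1e-5, 0.09),
             phi = runif(1, 0.25, 0.75), theta = runif(1, 2, 5000))
    lp_cpp <- aiselect:::cpp_log_posterior(
      unname(par), counts$tumor_a, counts$tumor_a + counts$tumor_b,
      counts$normal_a, counts$normal_a + counts$normal_b,
      aiselect:::priors_matrix(pr))
    expect_equal(lp_cpp, log_posterior(as.list(par), counts, pr),
                 tolerance = 1e-10)
  }
})

test_that("the MAP fit dominates a dense grid of the posterior", {
  sim <- simulate_cohort(sim_config(n_snps = 3, n_samples = 60,
                                    coverage_mean = 50, het_prob = 1,
                                    event_rate = 1, promoted_fraction = 0.75,
                                    pi_true = 0.8, delta_true = 0.005,
                                    phi_true = 0.55, theta_true = 60,
                                    purity = 1, seed = 23))
  pr <- ai_priors()
  grid <- expand.grid(pi = seq(0.05, 0.95, 0.05),
                      phi = seq(0.25, 0.75, 0.05),
                      theta = c(2, 10, 50, 200, 1000),
                      delta = c(1e-5, 0.005, 0.05))
  for (i in 1:3) {
    counts <- snp_counts(sim$cohort, i)
    fit <- fit_map(counts, priors = pr)
    expect_true(fit$converged)
    grid_lp <- apply(grid, 1, function(g)
      log_posterior(as.list(g), counts, pr))
    expect_gte(fit$log_posterior, max(grid_lp) - 1e-6)
  }
})

test_that("the estimator recovers pi on model-faithful data and the null value on balanced data", {
  # balanced locus: pi_hat within 0.05 of 0.5
  sim0 <- simulate_cohort(null_config(10, 150, 60, seed = 31))
  fit0 <- ai_fit(sim0$cohort)
  expect_true(all(abs(fit0$table$pi - 0.5) < 0.05))
  # imbalanced loci: recovery within 0.05
  sim1 <- simulate_cohort(calibration_config(10, 200, 80, pi_true = 0.8, seed = 32))
  fit1 <- ai_fit(sim1$cohort)
  expect_true(all(fit1$table$converged))
  expect_lt(abs(mean(fit1$table$pi) - 0.8), 0.05)
})

test_that("mapping bias is absorbed by phi, not by pi", {
  cfg <- sim_config(n_snps = 10, n_samples = 200, coverage_mean = 80,
                    het_prob = 1, event_rate = 0, pi_true = 0.5,
                    delta_true = 0, phi_true = 0.6, theta_true = 150,
                    purity = 1, seed = 33)
  fit <- ai_fit(simulate_cohort(cfg)$cohort)
  expect_lt(abs(mean(fit$table$pi) - 0.5), 0.05)
  expect_lt(abs(mean(fit$table$phi) - 0.6), 0.05)
})

test_that("fit_map handles degenerate inputs per its contract", {
  expect_error(fit_map(data.frame(tumor_a = numeric(0), tumor_b = numeric(0),
                                  normal_a = numeric(0), normal_b = numeric(0))),
               "at least one")
  # single sample still returns a finite fit
  f <- fit_map(data.frame(tumor_a = 10, tumor_b = 30, normal_a = 20,
                          normal_b = 22))
  expect_true(is.finite(f$log_posterior))
  expect_identical(f$n_het, 1L)
})

test_that("ai_fit methods expose the coefficient table", {
  sim <- simulate_cohort(sim_config(n_snps = 6, n_samples = 30, seed = 2,
                                    het_prob = 1))
  fit <- ai_fit(sim$cohort)
  cf <- coef(fit)
  expect_identical(dim(cf), c(6L, 4L))
  expect_identical(colnames(cf), c("pi", "delta", "phi", "theta"))
  expect_identical(rownames(cf), sim$cohort$loci$snp_id)
  s <- summary(fit)
  expect_identical(s$n_snps, 6L)
  expect_output(print(fit), "SNPs")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
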