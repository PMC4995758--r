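test_that("the MCMC schedule arithmetic is validated", {
  cfg <- mcmc_config()
  expect_equal(cfg$n_retained, 200)   # (50000 - 10000) / 200
  expect_error(mcmc_config(iterations = 100, burn_in = 200), "burn_in")
  expect_error(mixture_prior(pi0 = 1.2), "pi0")
})

test_that("with everything in the effect component the posterior is conjugate", {
  set.seed(1)
  n <- 60
  x <- matrix(rnorm(n), 1, dimnames = list("p1", NULL))
  x <- x - rowMeans(x)
  y <- drop(0.5 * x) + rnorm(n, sd = 1)
  y <- y - mean(y)
  s2e <- 1; s2g1 <- 0.4
  res <- gibbs_sample(x, y,
                      prior = mixture_prior(pi0 = 1e-9, sigma2_g1 = s2g1),
                      mcmc = mcmc_config(iterations = 20000,
                                         burn_in = 2000, thin = 100,
                                         seed = 2),
                      fix_variances = TRUE, fix_pi = TRUE,
                      include_intercept = FALSE, sigma2_e = s2e)
  xv <- drop(x)
  post_mean <- sum(xv * y) / (sum(xv^2) + s2e / s2g1)
  post_sd <- sqrt(s2e / (sum(xv^2) + s2e / s2g1))
  expect_equal(res$result$pip, 1)
  expect_lt(abs(res$result$effect_mean - post_mean), 4 * post_sd / sqrt(500))
})

test_that("posterior inclusion matches exhaustive enumeration on 3-probe systems", {
  set.seed(3)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 2] <- 0.6 * X[, 1] + 0.8 * X[, 2]     # correlated pair
  X <- scale(X, scale = FALSE)
  y <- drop(0.35 * X[, 1] - 0.25 * X[, 3]) + rnorm(n, sd = 1)
  y <- y - mean(y)
  pi0 <- 0.7; s2g0 <- 0.001; s2g1 <- 0.3; s2e <- 1

  oracle <- bvs_enumerate_pip(X, y, pi0, s2g0, s2g1, s2e)
  res <- gibbs_sample(t(X), y,
                      prior = mixture_prior(pi0 = pi0, sigma2_g0 = s2g0,
                                            sigma2_g1 = s2g1),
                      mcmc = mcmc_config(iterations = 60000,
                                         burn_in = 5000, thin = 200,
                                         seed = 4),
                      fix_variances = TRUE, fix_pi = TRUE,
                      include_intercept = FALSE, sigma2_e = s2e)
  # oracle must be non-trivial for this to mean anything
  expect_true(any(oracle > 0.05 & oracle < 0.95))
  expect_lt(max(abs(res$result$pip - oracle)), 0.02)
})

test_that("a null response leaves almost no probes included", {
  set.seed(5)
  x <- matrix(rnorm(300 * 100), 300)
  y <- rnorm(100)
  res <- gibbs_sample(x, y, mcmc = mcmc_config(iterations = 4000,
                                               burn_in = 1000, thin = 30,
                                               seed = 6))
  expect_lt(mean(res$result$pip > 0.5), 0.01)
})

test_that("Bayes factors are posterior-to-prior odds with a finite-sample guard", {
  expect_equal(compute_bayes_factors(0.01, pi1 = 0.01), 1)
  expect_equal(compute_bayes_factors(0.5, pi1 = 0.01), 99)
  p <- seq(0.05, 0.95, 0.1)
  expect_true(all(diff(compute_bayes_factors(p, 0.01)) > 0))
  # guard keeps BF finite at pip = 1 from a finite chain
  expect_true(is.finite(compute_bayes_factors(1, 0.01, n_samples = 200)))
  expect_error(compute_bayes_factors(0.5, pi1 = 0), "strictly")
  expect_error(compute_bayes_factors(0.5, pi1 = 1), "strictly")
})

test_that("Bayes-factor selection applies inclusive, monotone thresholds", {
  res <- data.frame(probe_id = c("a", "b"), bf = c(11.03, 9.9))
  expect_equal(select_significant_bf(res, 10), "a")
  res2 <- data.frame(probe_id = letters[1:5], bf = c(2, 6, 11, 4, 30))
  expect_true(all(select_significant_bf(res2, 10) %in%
                    select_significant_bf(res2, 5)))
  expect_equal(select_significant_bf(res2[0, ], 10), character(0))
})

test_that("posterior means shrink relative to per-probe OLS on orthogonal designs", {
  set.seed(7)
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 8), n)))[, 1:8] * sqrt(n)  # orthogonal
  X <- scale(X, scale = FALSE)
  y <- drop(X %*% c(0.8, 0.4, rep(0, 6))) + rnorm(n)
  res <- gibbs_sample(t(X), y, mcmc = mcmc_config(iterations = 6000,
                                                  burn_in = 1000,
                                                  thin = 25, seed = 8))
  ols <- drop(crossprod(X, y - mean(y))) / colSums(X^2)
  expect_true(all(abs(res$result$effect_mean) <= abs(ols) + 0.02))
})

test_that("chains are reproducible under a seed and tracked by diagnostics", {
  set.seed(9)
  x <- matrix(rnorm(50 * 40), 50)
  y <- rnorm(40)
  cfg <- mcmc_config(iterations = 2000, burn_in = 500, thin = 10, seed = 10)
  a <- gibbs_sample(x, y, mcmc = cfg)
  b <- gibbs_sample(x, y, mcmc = cfg)
  expect_identical(a$result, b$result)
  expect_identical(a$trace, b$trace)
  expect_equal(a$n_retained, 150)
  diag <- check_chain(a)
  expect_true(is.finite(diag$z))
})
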