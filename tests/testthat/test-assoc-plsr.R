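test_that("rmse computes the root mean squared error exactly", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:2), "mismatch")
})

test_that("one component on a single predictor reproduces simple OLS", {
  set.seed(1)
  X <- matrix(rnorm(30), 30, 1)
  y <- drop(1.5 * X) + rnorm(30, sd = 0.3)
  fit <- fit_pls(X, y, n_lv = 1)
  expect_equal(predict(fit, X), unname(fitted(lm(y ~ X))),
               tolerance = 1e-10)
})

test_that("full-rank PLS equals multivariate OLS", {
  set.seed(2)
  n <- 30; p <- 6
  X <- matrix(rnorm(n * p), n)
  y <- drop(X %*% rnorm(p)) + rnorm(n)
  ols <- unname(coef(lm(y ~ X))[-1])
  for (sc in c(TRUE, FALSE)) {
    fit <- fit_pls(X, y, n_lv = p, scale = sc)
    expect_equal(unname(fit$coef[, fit$n_lv]), ols, tolerance = 1e-8)
    expect_equal(predict(fit, X), unname(fitted(lm(y ~ X))),
                 tolerance = 1e-8)
  }
  expect_error(fit_pls(X, y, n_lv = 40), "rank")
})

test_that("an orthogonal response yields null coefficients", {
  set.seed(3)
  X <- scale(matrix(rnorm(40 * 3), 40), scale = FALSE)
  y <- rnorm(40); y <- y - mean(y)
  y <- y - X %*% solve(crossprod(X), crossprod(X, y))  # project out X
  fit <- fit_pls(X, drop(y), n_lv = 2)
  expect_lt(max(abs(fit$coef)), 1e-8)
})

test_that("PLS predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(4)
  n <- 40; p <- 12
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("v", 1:p)))
  y <- drop(X[, 1] - 0.5 * X[, 2]) + rnorm(n, sd = 0.5)
  fit <- fit_pls(X, y, n_lv = 3, scale = TRUE)
  ref <- mixOmics::pls(X, y, ncomp = 3, scale = TRUE, mode = "regression")
  pred_ref <- predict(ref, X)$predict[, 1, 3]
  expect_equal(unname(predict(fit, X, ncomp = 3)), unname(pred_ref),
               tolerance = 1e-6)
})

test_that("cross-validation recovers the generating number of latent directions", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 36; p <- 24
    T2 <- qr.Q(qr(matrix(rnorm(n * 2), n)))[, 1:2] * sqrt(n)
    L <- matrix(rnorm(2 * p), 2)
    L <- L / sqrt(rowSums(L^2)) * sqrt(p)   # both directions equally loaded
    X <- T2 %*% L + matrix(rnorm(n * p, sd = 0.6), n)
    y <- drop(T2 %*% c(1, 1)) + rnorm(n, sd = 0.3)
    sel <- select_lv_by_cv(X, y, lv_grid = 1:6, folds = 4, repeats = 10,
                           seed = s)
    if (sel$n_lv == 2) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("pure-noise responses make extra components unprofitable", {
  worse <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    X <- matrix(rnorm(40 * 20), 40)
    y <- rnorm(40)
    tab <- select_lv_by_cv(X, y, lv_grid = c(1, 3, 6), folds = 5,
                           repeats = 3, seed = s)$cv_table
    if (tab$mean_rmse[3] >= tab$mean_rmse[1]) worse <- worse + 1
  }
  expect_gte(worse, 4)
})

test_that("leave-one-out with one repeat matches direct computation", {
  set.seed(6)
  n <- 12
  X <- matrix(rnorm(n * 3), n)
  y <- drop(X %*% c(1, 0, -1)) + rnorm(n, sd = 0.2)
  sel <- select_lv_by_cv(X, y, lv_grid = 1:2, folds = n, repeats = 1,
                         seed = 7)
  for (lv in 1:2) {
    errs <- vapply(seq_len(n), function(i) {
      f <- fit_pls(X[-i, ], y[-i], lv)
      rmse(y[i], predict(f, X[i, , drop = FALSE], ncomp = lv))
    }, 0)
    expect_equal(sel$cv_table$mean_rmse[lv], mean(errs), tolerance = 1e-10)
  }
})

test_that("variable importance ranks causal probes and ignores inert ones", {
  set.seed(8)
  n <- 80; p <- 20
  X <- matrix(rnorm(n * p), n)
  X[, 7] <- 0                      # constant probe: zero weight everywhere
  y <- drop(2 * X[, 3]) + rnorm(n, sd = 0.4)
  fit <- fit_pls(X, y, n_lv = 3)
  vim <- compute_vim(fit)
  expect_equal(unname(vim[7]), 0)
  expect_equal(unname(which.max(vim)), 3)
  expect_true(all(vim >= 0))

  # invariant to sample reordering
  perm <- sample(n)
  fit2 <- fit_pls(X[perm, ], y[perm], n_lv = 3)
  expect_equal(compute_vim(fit2), vim, tolerance = 1e-10)

  # VIP variant is non-negative with mean-square p-normalization
  vip <- compute_vim(fit, method = "vip")
  expect_true(all(vip >= 0))
  expect_equal(mean(vip^2), 1, tolerance = 0.05)
})

test_that("cross-validated RMSE is invariant to probe column order", {
  set.seed(9)
  X <- matrix(rnorm(40 * 8), 40)
  y <- drop(X %*% rnorm(8)) + rnorm(40)
  a <- select_lv_by_cv(X, y, lv_grid = 1:3, folds = 5, repeats = 2,
                       seed = 11)
  b <- select_lv_by_cv(X[, 8:1], y, lv_grid = 1:3, folds = 5, repeats = 2,
                       seed = 11)
  expect_equal(a$cv_table$mean_rmse, b$cv_table$mean_rmse,
               tolerance = 1e-10)
})

test_that("the three-step PLSR protocol selects causal probes", {
  probe_hits <- 0; snp_hits <- 0
  for (s in 1:8) {
    sim <- flowering_like_sim(seed = 200 + s, n_probes = 300,
                              n_offspring = 160, n_causal = 2)
    th <- compute_theta_s(sim$intensities)
    x <- mean_center(filter_by_theta_range(th)$theta)
    y <- sim$phenotypes[colnames(x)]
    scan <- genome_scan_lr(x, y)
    keep <- prefilter_by_f(scan, 4)
    res <- run_plsr_association(t(x[keep, , drop = FALSE]), y,
                                folds = 5, repeats = 3, seed = s)
    causal_kept <- intersect(sim$causal$probe_id, keep)
    if (length(causal_kept) &&
        all(causal_kept %in% res$significant)) probe_hits <- probe_hits + 1
    # each SNP is carried by two near-identical probes; PLS splits the
    # coefficient between them, so detection is also assessed per SNP
    causal_snp <- sub("_p[12]$", "", sim$causal$probe_id)
    sig_snp <- unique(sub("_p[12]$", "", res$significant))
    if (all(causal_snp %in% sig_snp)) snp_hits <- snp_hits + 1
  }
  expect_gte(probe_hits, 7)   # >= 80% of seeds: causal probes at VIM >= 2
  expect_gte(snp_hits, 7)
})

test_that("threshold semantics and determinism of the PLSR scan", {
  set.seed(10)
  X <- matrix(rnorm(60 * 10), 60,
              dimnames = list(NULL, paste0("p", 1:10)))
  y <- drop(2 * X[, 2]) + rnorm(60, sd = 0.5)
  a <- run_plsr_association(X, y, folds = 5, repeats = 2, seed = 3)
  b <- run_plsr_association(X, y, folds = 5, repeats = 2, seed = 3)
  expect_identical(a$vim, b$vim)
  expect_identical(a$n_lv, b$n_lv)

  inf_thr <- run_plsr_association(X, y, folds = 5, repeats = 2,
                                  vim_threshold = Inf, seed = 3)
  expect_equal(inf_thr$significant, character(0))
  lo <- run_plsr_association(X, y, folds = 5, repeats = 2,
                             vim_threshold = 0.1, seed = 3)
  expect_true(all(a$significant %in% lo$significant))
  expect_error(run_plsr_association(X[, 0], y), "empty")
})
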