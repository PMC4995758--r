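#' Root mean squared error
#'
#' \eqn{RMSE = \sqrt{\frac{1}{n}\sum_i (\gamma_i - \hat\gamma_i)^2}}.
#'
#' @param observed,predicted numeric vectors of equal length (n >= 1).
#' @return non-negative scalar.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("length mismatch: ", length(observed), " vs ", length(predicted))
  if (length(observed) == 0) stop("empty input")
  sqrt(mean((observed - predicted)^2))
}

#' Fit a partial least squares regression model
#'
#' Univariate-response orthogonal-scores PLS (NIPALS): each latent
#' component's weight vector is proportional to the covariance of the
#' (deflated) predictors with the response, scores are the projections,
#' and the predictor matrix is deflated after each component. Predictors
#' and response are centered; predictors are optionally scaled to unit
#' variance (default TRUE). With as many components as the predictor
#' rank, the fit coincides with multivariate ordinary least squares.
#'
#' @param X samples x probes predictor matrix.
#' @param y numeric response.
#' @param n_lv number of latent variables (components).
#' @param scale scale predictor columns to unit sd (default TRUE);
#'   constant columns are left unscaled.
#' @return object of class \code{pls_fit}: weights \code{W}, X-loadings
#'   \code{P}, y-loadings \code{q}, scores \code{T}, per-component
#'   coefficient increments and cumulative coefficients on the original
#'   predictor scale, centers/scales, \code{n_lv} actually extracted.
#' @export
fit_pls <- function(X, y, n_lv, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n >= 2)
  if (n_lv > min(n - 1, p))
    stop("n_lv = ", n_lv, " exceeds the rank bound min(n-1, p) = ",
         min(n - 1, p))
  x_center <- colMeans(X)
  x_scale <- if (scale) {
    s <- apply(X, 2, sd); s[s == 0 | is.na(s)] <- 1; s
  } else rep(1, p)
  y_center <- mean(y)
  E <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  f <- y - y_center

  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  k <- 0L
  for (h in seq_len(n_lv)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(f^2)))) break  # residual signal gone
    w <- w / nw
    t_h <- drop(E %*% w)
    tt <- sum(t_h^2)
    if (tt < 1e-24) break
    p_h <- drop(crossprod(E, t_h)) / tt
    q_h <- sum(f * t_h) / tt
    E <- E - tcrossprod(t_h, p_h)
    f <- f - q_h * t_h
    k <- h
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h; q[h] <- q_h
  }
  if (k == 0L) {
    W <- matrix(0, p, 1); P <- matrix(0, p, 1)
    Tm <- matrix(0, n, 1); q <- 0
    R <- matrix(0, p, 1)
  } else {
    W <- W[, seq_len(k), drop = FALSE]; P <- P[, seq_len(k), drop = FALSE]
    Tm <- Tm[, seq_len(k), drop = FALSE]; q <- q[seq_len(k)]
    # R maps (scaled, centered) X to scores: T = E0 R
    R <- W %*% solve(crossprod(P, W))
  }
  # per-component coefficient increments on the scaled-X basis
  coef_inc_scaled <- sweep(R, 2, q, "*")
  coef_scaled <- t(apply(coef_inc_scaled, 1, cumsum))
  if (k <= 1) coef_scaled <- matrix(coef_scaled, nrow = p)
  coef_orig <- coef_scaled / x_scale
  structure(list(W = W, P = P, q = q, T = Tm, R = R,
                 coef_inc_scaled = coef_inc_scaled,
                 coef_scaled = coef_scaled, coef = coef_orig,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, n_lv = k,
                 probe_id = colnames(X) %||% as.character(seq_len(p))),
            class = "pls_fit")
}

#' Predict from a PLS fit
#'
#' @param object a \code{pls_fit}.
#' @param newdata samples x probes matrix on the original scale.
#' @param ncomp number of components to use (default: all extracted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$n_lv, ...) {
  ncomp <- min(ncomp, object$n_lv)
  newdata <- as.matrix(newdata)
  if (ncomp < 1) return(rep(object$y_center, nrow(newdata)))
  b <- object$coef[, ncomp]
  drop(sweep(newdata, 2, object$x_center) %*% b) + object$y_center
}

#' Choose the number of latent variables by repeated cross-validation
#'
#' For every component count in \code{lv_grid}, computes the RMSE of
#' held-out predictions over \code{folds}-fold cross-validation repeated
#' \code{repeats} times (one PLS fit per training fold at the maximum
#' component count; nested predictions give every smaller count for
#' free). The chosen count minimizes the mean RMSE, ties going to the
#' smaller count.
#'
#' @param X samples x probes matrix (calibration set).
#' @param y response.
#' @param lv_grid component counts to assess (default 1:10, truncated to
#'   the rank bound).
#' @param folds,repeats cross-validation layout (defaults 10 and 20).
#' @param scale passed to \code{\link{fit_pls}}.
#' @param seed integer seed for the fold assignments.
#' @return list: \code{n_lv} (chosen), \code{cv_table} data.frame
#'   (\code{n_lv}, \code{mean_rmse}, \code{sd_rmse}).
#' @export
select_lv_by_cv <- function(X, y, lv_grid = 1:10, folds = 10L,
                            repeats = 20L, scale = TRUE, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  lv_grid <- lv_grid[lv_grid <= min(n - ceiling(n / folds) - 1, ncol(X))]
  if (length(lv_grid) == 0) stop("no feasible component count in the grid")
  max_lv <- max(lv_grid)
  set.seed(seed)
  rmse_mat <- matrix(NA_real_, repeats * folds, length(lv_grid))
  row <- 0L
  for (r in seq_len(repeats)) {
    fold_of <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      if (sum(test) < 1 || sum(!test) < 2)
        stop("fold with too few samples; reduce folds")
      fit <- fit_pls(X[!test, , drop = FALSE], y[!test], max_lv,
                     scale = scale)
      row <- row + 1L
      for (g in seq_along(lv_grid)) {
        pred <- predict(fit, X[test, , drop = FALSE], ncomp = lv_grid[g])
        rmse_mat[row, g] <- rmse(y[test], pred)
      }
    }
  }
  cv_table <- data.frame(n_lv = lv_grid,
                         mean_rmse = colMeans(rmse_mat),
                         sd_rmse = apply(rmse_mat, 2, sd))
  list(n_lv = lv_grid[which.min(cv_table$mean_rmse)], cv_table = cv_table)
}

#' Variable importance of a PLS fit
#'
#' Default (\code{method = "wsac"}): the weighted sum of the absolute
#' per-component regression-coefficient contributions, the weight of a
#' component being the fraction of response variance it explains —
#' \eqn{VIM_j = \sum_h \omega_h |b_{jh}|} with
#' \eqn{\omega_h = q_h^2 \|t_h\|^2 / \sum_l q_l^2 \|t_l\|^2} and
#' \eqn{b_{jh}} the coefficient increment of probe j in component h (on
#' the standardized predictor scale). \code{method = "vip"} gives the
#' classical variable-importance-in-projection score
#' \eqn{VIP_j = \sqrt{p \sum_h \omega_h w_{jh}^2}} instead.
#'
#' @param model a \code{pls_fit}.
#' @param ncomp components to include (default: all extracted).
#' @param method \code{"wsac"} (default) or \code{"vip"}.
#' @return named non-negative numeric vector, one score per probe.
#' @export
compute_vim <- function(model, ncomp = model$n_lv,
                        method = c("wsac", "vip")) {
  method <- match.arg(method)
  ncomp <- min(ncomp, model$n_lv)
  h_idx <- seq_len(max(ncomp, 1))
  ss <- model$q[h_idx]^2 * colSums(model$T[, h_idx, drop = FALSE]^2)
  w <- if (sum(ss) > 0) ss / sum(ss) else rep(0, length(ss))
  vim <- if (method == "wsac") {
    drop(abs(model$coef_inc_scaled[, h_idx, drop = FALSE]) %*% w)
  } else {
    p <- nrow(model$W)
    sqrt(p * drop(model$W[, h_idx, drop = FALSE]^2 %*% w))
  }
  setNames(vim, model$probe_id)
}

#' PLSR association on the F-prefiltered probe subset
#'
#' The three-step multivariate protocol: (1) a seeded 80/20 split into
#' calibration and test samples; (2) repeated 10-fold cross-validation on
#' the calibration set over 1-10 latent variables, choosing the count
#' with the lowest mean RMSE; (3) a final fit on the calibration set,
#' variable-importance scoring with significance at
#' \code{vim_threshold}, and the test-set RMSE as an out-of-sample check.
#'
#' @param X samples x probes matrix restricted to the prefiltered subset
#'   (see \code{\link{prefilter_by_f}}).
#' @param y response per sample (e.g. DEBVs).
#' @param calibration_fraction fraction of samples in the calibration set
#'   (default 0.8).
#' @param lv_grid,folds,repeats cross-validation protocol (defaults 1:10,
#'   10, 20).
#' @param vim_threshold significance threshold on the importance score
#'   (default 2).
#' @param vim_method passed to \code{\link{compute_vim}}.
#' @param scale standardize predictors (default TRUE).
#' @param seed integer seed (split and fold assignments).
#' @return list of class \code{pls_scan}: \code{n_lv}, \code{cv_table},
#'   \code{vim} (data.frame \code{probe_id}, \code{vim},
#'   \code{significant}), \code{significant} (probe ids),
#'   \code{test_rmse}, \code{fit}.
#' @export
run_plsr_association <- function(X, y, calibration_fraction = 0.8,
                                 lv_grid = 1:10, folds = 10L,
                                 repeats = 20L, vim_threshold = 2,
                                 vim_method = "wsac", scale = TRUE,
                                 seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("empty probe subset: nothing to fit")
  stopifnot(calibration_fraction > 0, calibration_fraction < 1)
  n <- nrow(X)
  set.seed(seed)
  cal <- sort(sample.int(n, round(calibration_fraction * n)))
  test <- setdiff(seq_len(n), cal)
  sel <- select_lv_by_cv(X[cal, , drop = FALSE], y[cal],
                         lv_grid = lv_grid, folds = folds,
                         repeats = repeats, scale = scale,
                         seed = seed + 1L)
  fit <- fit_pls(X[cal, , drop = FALSE], y[cal], sel$n_lv, scale = scale)
  vim <- compute_vim(fit, method = vim_method)
  vim_df <- data.frame(probe_id = names(vim), vim = unname(vim),
                       significant = unname(vim) >= vim_threshold,
                       stringsAsFactors = FALSE)
  test_rmse <- if (length(test))
    rmse(y[test], predict(fit, X[test, , drop = FALSE])) else NA_real_
  structure(list(n_lv = sel$n_lv, cv_table = sel$cv_table, vim = vim_df,
                 significant = vim_df$probe_id[vim_df$significant],
                 test_rmse = test_rmse, fit = fit),
            class = "pls_scan")
}
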