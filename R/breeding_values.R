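#' Fit the repeated-measurements mixed model by REML
#'
#' Fits \eqn{y = \alpha + block + plate + g + e} with fixed block and
#' plate effects, a random per-sample genetic intercept
#' \eqn{g \sim N(0, \sigma^2_g)} and residual \eqn{e \sim N(0,
#' \sigma^2_e)}, samples treated as unrelated (identity covariance; no
#' kinship matrix). The restricted log-likelihood is profiled over the
#' variance ratio \eqn{\lambda = \sigma^2_g / \sigma^2_e} and maximized
#' by bounded search on \eqn{\log \lambda}; the random-intercept
#' structure makes \eqn{H^{-1} = (I + \lambda Z Z')^{-1}} available in
#' closed form, so each likelihood evaluation is O(records). BLUPs (the
#' EBVs) and their prediction error variances come from the mixed-model
#' equations at the REML estimates.
#'
#' @param records data.frame with columns \code{sample_id},
#'   \code{value}, and optionally factor columns \code{block} and
#'   \code{plate} (either may be absent or single-level, in which case it
#'   is dropped from the fixed part).
#' @param tol convergence tolerance on log-lambda (default 1e-10).
#' @return object of class \code{mixed_model_fit}: \code{alpha},
#'   \code{fixed} (named effect estimates, reference-level coding),
#'   \code{sigma2_g}, \code{sigma2_e}, \code{ebv}, \code{pev} (named per
#'   sample), \code{reml_loglik}, \code{n_records}, \code{n_samples}.
#' @export
fit_mixed_model <- function(records, tol = 1e-10) {
  stopifnot(all(c("sample_id", "value") %in% names(records)))
  y <- records$value
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  id <- factor(records$sample_id)
  n_samples <- nlevels(id)
  if (n_samples < 2) stop("need at least 2 samples")
  N <- length(y)

  form <- "~ 1"
  for (f in c("block", "plate")) {
    if (!is.null(records[[f]]) && length(unique(records[[f]])) > 1)
      form <- paste(form, "+", f)
  }
  X <- model.matrix(as.formula(form), data = records)
  p <- qr(X)$rank
  if (p < ncol(X))
    stop("fixed-effect design not of full rank (confounded block/plate)")

  zi <- as.integer(id)                   # record -> sample index
  n_i <- tabulate(zi, n_samples)         # records per sample

  # H^{-1} v = v - Z D Z'v with D = diag(lambda / (1 + lambda * n_i))
  Hinv_mult <- function(M, lambda) {
    d <- lambda / (1 + lambda * n_i)
    ZtM <- rowsum(M, zi, reorder = TRUE)
    M - (d * ZtM)[zi, , drop = FALSE]
  }

  profile <- function(loglambda) {
    lambda <- exp(loglambda)
    HiX <- Hinv_mult(X, lambda)
    Hiy <- Hinv_mult(matrix(y), lambda)
    A <- crossprod(X, HiX)
    b <- crossprod(X, Hiy)
    beta <- solve(A, b)
    yPy <- drop(crossprod(y, Hiy) - crossprod(b, beta))
    s2 <- yPy / (N - p)
    logdetH <- sum(log1p(lambda * n_i))
    ll <- -0.5 * ((N - p) * log(s2) + logdetH +
                    determinant(A, logarithm = TRUE)$modulus[1] + (N - p))
    list(ll = ll, beta = beta, s2 = s2, lambda = lambda)
  }

  # boundary (sigma2_g = 0) value for comparison
  p0 <- profile(-Inf + 0)  # lambda = 0 via exp(-Inf) = 0
  opt <- optimize(function(l) profile(l)$ll, interval = c(-30, 30),
                  maximum = TRUE, tol = tol)
  best <- profile(opt$maximum)
  if (!is.finite(best$ll)) stop("REML did not converge (non-finite likelihood)")
  if (p0$ll >= best$ll) best <- p0   # variance pinned at zero

  sigma2_e <- best$s2
  sigma2_g <- best$lambda * sigma2_e
  beta <- drop(best$beta)
  names(beta) <- colnames(X)

  # mixed-model equations at the estimates: BLUPs and PEV
  if (sigma2_g > 0) {
    Z <- matrix(0, N, n_samples)
    Z[cbind(seq_len(N), zi)] <- 1
    C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X),
                     crossprod(Z) + diag(sigma2_e / sigma2_g, n_samples)))
    rhs <- c(crossprod(X, y), crossprod(Z, y))
    Cinv <- solve(C)
    sol <- Cinv %*% rhs
    ebv <- drop(sol[(p + 1):(p + n_samples)])
    pev <- sigma2_e * diag(Cinv)[(p + 1):(p + n_samples)]
  } else {
    ebv <- rep(0, n_samples)
    pev <- rep(0, n_samples)
  }
  names(ebv) <- names(pev) <- levels(id)

  structure(list(alpha = beta[1], fixed = beta,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 ebv = ebv, pev = pev,
                 reml_loglik = best$ll, n_records = N,
                 n_samples = n_samples),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("REML mixed-model fit:", x$n_records, "records,",
      x$n_samples, "samples\n")
  cat(sprintf("  sigma2_g = %.6g  sigma2_e = %.6g  (h2 per record = %.3f)\n",
              x$sigma2_g, x$sigma2_e,
              x$sigma2_g / (x$sigma2_g + x$sigma2_e)))
  invisible(x)
}

#' Deregress estimated breeding values
#'
#' BLUP shrinks EBVs toward zero by their reliability
#' \eqn{r^2_i = 1 - PEV_i / \sigma^2_g}; deregression undoes the
#' attenuation, \eqn{debv_i = ebv_i / r^2_i}, so the deregressed values
#' can serve as an unshrunken response for association. PEV is the
#' prediction error variance of the EBV delivered by the mixed-model
#' equations.
#'
#' @param fit a \code{mixed_model_fit}, or a list with elements
#'   \code{ebv}, \code{pev}, \code{sigma2_g}.
#' @return data.frame (\code{sample_id}, \code{ebv}, \code{pev},
#'   \code{r2}, \code{debv}).
#' @export
deregress <- function(fit) {
  ebv <- fit$ebv; pev <- fit$pev; s2g <- fit$sigma2_g
  if (!isTRUE(s2g > 0)) stop("sigma2_g must be positive to deregress")
  if (any(pev < 0)) stop("negative PEV")
  if (any(pev >= s2g))
    stop("PEV >= sigma2_g for sample(s) ",
         paste(names(ebv)[pev >= s2g], collapse = ", "),
         ": reliability <= 0, deregression undefined")
  r2 <- 1 - pev / s2g
  data.frame(sample_id = names(ebv) %||% as.character(seq_along(ebv)),
             ebv = unname(ebv), pev = unname(pev), r2 = unname(r2),
             debv = unname(ebv / r2), stringsAsFactors = FALSE)
}
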