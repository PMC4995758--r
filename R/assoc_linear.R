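#' Per-probe linear regression genome scan
#'
#' Ordinary least squares of the response on each probe's centered
#' continuous genotype, \eqn{Y_i = \alpha + \beta x_i + \epsilon_i}, with
#' two-sided p-values from the t distribution on n-2 degrees of freedom.
#' The scan is fully vectorized over probes when there are no missing
#' values; probes with missing genotypes fall back to pairwise-complete
#' computation. Monomorphic probes (zero genotype variance) carry no
#' test and are reported with p = 1 and \code{degenerate = TRUE}.
#'
#' @param x probes x samples matrix of (centered) genotype values.
#' @param y numeric response per sample (e.g. DEBVs).
#' @param q_threshold significance threshold on the q-value (default
#'   0.01).
#' @param pi0 optional fixed pi0 passed to \code{\link{compute_qvalues}}.
#' @return data.frame of class \code{linear_scan} with per-probe columns
#'   \code{probe_id}, \code{beta}, \code{se}, \code{t}, \code{f},
#'   \code{p}, \code{r2}, \code{q}, \code{significant},
#'   \code{degenerate}, plus attribute \code{pi0}.
#' @export
genome_scan_lr <- function(x, y, q_threshold = 0.01, pi0 = NULL) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(y))
    stop("dimension mismatch: ", ncol(x), " genotype columns vs ",
         length(y), " phenotypes")
  if (any(!is.finite(y))) stop("non-finite response values")
  m <- nrow(x); n <- length(y)

  if (!anyNA(x)) {
    xc <- x - rowMeans(x)
    yc <- y - mean(y)
    sxx <- rowSums(xc^2)
    sxy <- drop(xc %*% yc)
    syy <- sum(yc^2)
    df <- rep(n - 2L, m)
  } else {
    sxx <- sxy <- syy_v <- numeric(m); df <- integer(m)
    for (i in seq_len(m)) {
      ok <- is.finite(x[i, ])
      if (sum(ok) < 3) { sxx[i] <- 0; df[i] <- 0L; next }
      xi <- x[i, ok] - mean(x[i, ok]); yi <- y[ok] - mean(y[ok])
      sxx[i] <- sum(xi^2); sxy[i] <- sum(xi * yi)
      syy_v[i] <- sum(yi^2); df[i] <- sum(ok) - 2L
    }
    syy <- syy_v
  }

  degenerate <- sxx <= .Machine$double.eps * n | df < 1
  beta <- ifelse(degenerate, NA_real_, sxy / sxx)
  r2 <- ifelse(degenerate | syy == 0, 0, sxy^2 / (sxx * syy))
  rss <- pmax(syy - ifelse(degenerate, 0, beta^2 * sxx), 0)
  se <- ifelse(degenerate, NA_real_, sqrt(rss / df / sxx))
  tstat <- ifelse(degenerate | se == 0,
                  ifelse(degenerate, NA_real_, Inf), beta / se)
  p <- ifelse(degenerate, 1, 2 * pt(-abs(tstat), df))

  q <- rep(1, m)
  if (any(!degenerate)) {
    qres <- compute_qvalues(p[!degenerate], pi0 = pi0)
    q[!degenerate] <- qres$qvalues
  } else {
    qres <- list(pi0 = NA_real_)
  }
  out <- data.frame(
    probe_id = rownames(x) %||% as.character(seq_len(m)),
    beta = beta, se = se, t = tstat, f = tstat^2, p = p, r2 = r2,
    q = q, significant = !degenerate & q <= q_threshold,
    degenerate = degenerate, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "pi0") <- qres$pi0
  class(out) <- c("linear_scan", "data.frame")
  out
}

#' Storey q-values from a vector of p-values
#'
#' Estimates the null proportion pi0 from the p-value spectrum —
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m (1-\lambda))} over
#' the grid lambda = 0.05, 0.10, ..., 0.90, extrapolated to lambda = 1
#' with a cubic smoothing spline and clamped to (0, 1] — and converts
#' p-values to q-values by the step-up rule
#' \eqn{q_{(i)} = \hat\pi_0 \min_{j \ge i} m\, p_{(j)} / j}. With fewer
#' than 100 p-values the spectrum is too short to smooth and pi0 is fixed
#' at 1, which reduces the procedure to Benjamini-Hochberg.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param pi0 optional: fix pi0 instead of estimating it.
#' @return list: \code{qvalues} (same order as \code{p}), \code{pi0}.
#' @export
compute_qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100) {
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.90, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = 1)$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  list(qvalues = q, pi0 = pi0)
}

#' F-statistic prefilter for multivariate association
#'
#' Keeps the probes whose single-probe regression F statistic reaches
#' \code{f_min} (default 4), in input order; this is the probe subset the
#' partial least squares engine runs on.
#'
#' @param scan a \code{linear_scan} result.
#' @param f_min minimum F statistic (inclusive).
#' @return character vector of probe ids.
#' @export
prefilter_by_f <- function(scan, f_min = 4) {
  scan$probe_id[!scan$degenerate & is.finite(scan$f) & scan$f >= f_min]
}
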