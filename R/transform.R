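#' Quantile-normalize paired allele intensity matrices
#'
#' Forces every sample (column) to the same signal distribution — the
#' across-sample mean of order statistics — while preserving within-sample
#' ranks; ties are resolved by averaging over tied ranks. The A and B
#' channels of each sample are stacked and normalized together, so a
#' sample's full probe-signal distribution is equalized, then unstacked.
#' A single-sample input is returned unchanged. Delegates the column
#' normalization to \code{limma::normalizeQuantiles}.
#'
#' @param intensities list with positive matrices \code{A} and \code{B}
#'   (probes x samples, matching dimnames).
#' @return list with normalized \code{A} and \code{B}.
#' @export
quantile_normalize <- function(intensities) {
  A <- intensities$A; B <- intensities$B
  stopifnot(is.matrix(A), is.matrix(B), all(dim(A) == dim(B)))
  if (ncol(A) <= 1L) return(list(A = A, B = B))
  stacked <- rbind(A, B)
  if (anyNA(stacked)) stop("missing intensities: normalize complete columns")
  norm <- limma::normalizeQuantiles(stacked, ties = TRUE)
  n <- nrow(A)
  list(A = structure(norm[seq_len(n), , drop = FALSE], dimnames = dimnames(A)),
       B = structure(norm[n + seq_len(n), , drop = FALSE],
                     dimnames = dimnames(B)))
}

#' Transform allele intensities to continuous genotypes
#'
#' Computes per probe and sample the continuous genotype value
#' \eqn{\theta = \log_2 B - \log_2 A} and the signal strength
#' \eqn{s = (\log_2 A + \log_2 B)/2}. Missing intensities propagate as
#' missing theta/s.
#'
#' @param intensities list with positive matrices \code{A} and \code{B}.
#' @return list of class \code{theta_matrix} with matrices \code{theta}
#'   and \code{s}.
#' @export
compute_theta_s <- function(intensities) {
  A <- intensities$A; B <- intensities$B
  stopifnot(all(dim(A) == dim(B)))
  bad <- which(!is.na(A) & !is.na(B) & (A <= 0 | B <= 0), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("non-positive signal at probe %s, sample %s",
                 rownames(A)[i] %||% i, colnames(A)[j] %||% j))
  }
  la <- log2(A); lb <- log2(B)
  out <- list(theta = lb - la, s = (la + lb) / 2)
  class(out) <- "theta_matrix"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-allelic continuous genotype value
#'
#' For technologies reporting counts of four alleles, the target allele's
#' continuous genotype is its log2 count minus the sum of the log2 counts
#' of the other three alleles:
#' \eqn{\theta_i = \log_2 G_i - \sum_{j \ne i} \log_2 G_j}.
#' Restricted to two observed alleles this reduces to the bi-allelic
#' log-ratio (for \code{i} the second allele). Note the statistic scales
#' with total depth because three log counts are subtracted — it is
#' implemented exactly as defined, alternatives to the log transform are
#' an open question of the method itself.
#'
#' @param counts positive numeric vector of length 4 (allele counts), or
#'   a 4-column matrix (rows = observations).
#' @param i target allele index in 1..4.
#' @return theta_i per observation.
#' @export
compute_theta_multiallelic <- function(counts, i) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  stopifnot(ncol(counts) == 4, i %in% 1:4)
  if (any(counts <= 0, na.rm = TRUE))
    stop("zero or negative allele count: log undefined (no pseudo-count applied)")
  lg <- log2(counts)
  drop(lg[, i] - rowSums(lg[, -i, drop = FALSE]))
}

#' Filter probes by theta range (segregation filter)
#'
#' Association needs segregation: probes whose theta values span less
#' than \code{min_range} across samples are removed. Ranges use
#' pairwise-complete samples.
#'
#' @param theta a \code{theta_matrix} or a plain theta matrix.
#' @param min_range minimum retained range (default 2).
#' @return list: \code{theta} (filtered, same class as input) and
#'   \code{report} data.frame (\code{probe_id}, \code{theta_range},
#'   \code{retained}).
#' @export
filter_by_theta_range <- function(theta, min_range = 2) {
  th <- if (inherits(theta, "theta_matrix")) theta$theta else theta
  rng <- apply(th, 1L, function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) return(NA_real_)
    max(x) - min(x)
  })
  keep <- !is.na(rng) & rng >= min_range
  report <- data.frame(
    probe_id = rownames(th) %||% as.character(seq_len(nrow(th))),
    theta_range = rng, retained = keep, row.names = NULL,
    stringsAsFactors = FALSE)
  if (inherits(theta, "theta_matrix")) {
    out <- list(theta = theta$theta[keep, , drop = FALSE],
                s = theta$s[keep, , drop = FALSE])
    class(out) <- "theta_matrix"
  } else {
    out <- th[keep, , drop = FALSE]
  }
  list(theta = out, report = report)
}

#' Mean-center genotype values per probe
#'
#' Subtracts the per-probe (row) mean, computed over non-missing samples,
#' giving the centered genotype covariate x used by every association
#' engine. Idempotent.
#'
#' @param theta a \code{theta_matrix} or plain matrix.
#' @return centered matrix (plain matrix).
#' @export
mean_center <- function(theta) {
  th <- if (inherits(theta, "theta_matrix")) theta$theta else theta
  th - rowMeans(th, na.rm = TRUE)
}
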