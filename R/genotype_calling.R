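#' Naive nearest-centre genotype caller
#'
#' Assigns each theta value the dosage whose cluster centre is nearest,
#' with ties broken toward the lower dosage. This is the "genotype
#' classes" comparator: it deliberately mirrors the behaviour a
#' fixed-cluster caller exhibits — every sample gets a class, there is no
#' outlier category — so the cost of misclassification under overlapping
#' clusters can be measured against the continuous-genotype route.
#'
#' Two centre modes: \code{"fixed"} uses \code{centers} (default
#' ploidy+1 equally spaced values on [-2, 2], the equal-spacing
#' expectation for allele-ratio clusters); \code{"adaptive"} spaces the
#' centres per probe over the central 95 percent of that probe's theta
#' values, clamped to the global [-2, 2] span, which is the fairer
#' comparator when cluster positions drift.
#'
#' @param theta a \code{theta_matrix} or plain probes x samples matrix.
#' @param ploidy even integer (default 6).
#' @param centers strictly increasing numeric vector of length ploidy+1
#'   (fixed mode), or NULL for the default.
#' @param mode \code{"fixed"} or \code{"adaptive"}.
#' @return list of class \code{call_result}: \code{dosage} (integer
#'   matrix), \code{covariate} (difference between first- and
#'   second-allele counts, (ploidy - d) - d), \code{confidence}
#'   (distance to the nearest centre), \code{centers}.
#' @export
call_nearest_cluster <- function(theta, ploidy = 6L, centers = NULL,
                                 mode = c("fixed", "adaptive")) {
  mode <- match.arg(mode)
  th <- if (inherits(theta, "theta_matrix")) theta$theta else theta
  if (is.null(centers)) centers <- seq(-2, 2, length.out = ploidy + 1)
  if (length(centers) != ploidy + 1)
    stop("centers must have length ploidy + 1")
  if (any(diff(centers) <= 0)) stop("centers must be strictly increasing")

  assign_row <- function(x, ctr) {
    d <- abs(outer(x, ctr, "-"))
    # ties toward the lower dosage: max.col on negated distance with
    # ties.method "first" picks the smallest index among minima
    max.col(-d, ties.method = "first") - 1L
  }
  n_probes <- nrow(th)
  dosage <- matrix(NA_integer_, n_probes, ncol(th), dimnames = dimnames(th))
  conf <- matrix(NA_real_, n_probes, ncol(th), dimnames = dimnames(th))
  for (i in seq_len(n_probes)) {
    x <- th[i, ]
    ctr <- if (mode == "fixed") centers else {
      qs <- quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      lo <- max(qs[1], -2); hi <- min(qs[2], 2)
      if (hi <= lo) { lo <- -2; hi <- 2 }
      seq(lo, hi, length.out = ploidy + 1)
    }
    ok <- is.finite(x)
    d <- assign_row(x[ok], ctr)
    dosage[i, ok] <- d
    conf[i, ok] <- abs(x[ok] - ctr[d + 1L])
  }
  structure(list(dosage = dosage,
                 covariate = (ploidy - 2 * dosage),
                 confidence = conf, centers = centers, mode = mode,
                 ploidy = as.integer(ploidy)),
            class = "call_result")
}

#' Compare continuous-genotype and genotype-class association scans
#'
#' Pairs two linear scans over the same probes and response — one on
#' continuous genotype values, one on covariates derived from called
#' classes — and labels each probe's significance agreement.
#'
#' @param continuous,classed \code{linear_scan} results over the same
#'   probe universe.
#' @return list of class \code{assoc_comparison}: \code{table}
#'   (per-probe paired p/q and agreement label in both /
#'   continuous_only / class_only / neither), \code{counts} (label
#'   tabulation), \code{p_correlation} (Pearson correlation of -log10 p).
#' @export
compare_associations <- function(continuous, classed) {
  if (!setequal(continuous$probe_id, classed$probe_id) ||
      nrow(continuous) != nrow(classed)) {
    diff <- union(setdiff(continuous$probe_id, classed$probe_id),
                  setdiff(classed$probe_id, continuous$probe_id))
    stop("probe sets differ between the two scans: ",
         paste(head(diff, 10), collapse = ", "))
  }
  classed <- classed[match(continuous$probe_id, classed$probe_id), ]
  agreement <- ifelse(continuous$significant & classed$significant, "both",
               ifelse(continuous$significant, "continuous_only",
               ifelse(classed$significant, "class_only", "neither")))
  tab <- data.frame(probe_id = continuous$probe_id,
                    p_continuous = continuous$p, q_continuous = continuous$q,
                    p_class = classed$p, q_class = classed$q,
                    agreement = agreement, stringsAsFactors = FALSE)
  counts <- table(factor(agreement, levels = c("both", "continuous_only",
                                               "class_only", "neither")))
  ok <- continuous$p > 0 & classed$p > 0
  structure(list(table = tab, counts = counts,
                 p_correlation = suppressWarnings(
                   cor(-log10(continuous$p[ok]), -log10(classed$p[ok])))),
            class = "assoc_comparison")
}
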