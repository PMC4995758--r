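#' Simulate paired allele signal intensities from dosages
#'
#' Produces A/B array signals whose log2 contrast theta is, in
#' expectation, an affine and strictly increasing function of dosage:
#' cluster centres are equally spaced, centre(d) = theta_span *
#' (2 d / ploidy - 1), spanning \code{[-theta_span, theta_span]}. Mean signal strength s dips quadratically for the
#' homozygous classes (log-scale signals make homozygotes darker on one
#' channel). Independent Gaussian noise of sd \code{noise_sd} is added to
#' each log2 signal, so within-class theta noise has sd
#' \code{sqrt(2) * noise_sd}; large \code{noise_sd} merges the ploidy+1
#' clusters into a continuum.
#'
#' @param dosages integer probes x samples matrix in [0, ploidy].
#' @param ploidy even integer (default 6).
#' @param noise_sd non-negative sd of the per-channel log2 noise.
#' @param signal_level baseline mean log2 signal (default 10).
#' @param theta_span half-range of cluster centres; centres run from
#'   \code{-theta_span} to \code{+theta_span} (default 2, so the
#'   noise-free theta range is 4).
#' @param s_dip drop in s between the balanced heterozygote and a
#'   homozygote (default 0.5).
#' @param seed integer seed.
#' @return list with positive matrices \code{A} and \code{B} (linear
#'   scale), same dimnames as \code{dosages}.
#' @export
simulate_intensities <- function(dosages, ploidy = 6L, noise_sd = 0.15,
                                 signal_level = 10, theta_span = 2,
                                 s_dip = 0.5, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  frac <- 2 * dosages / ploidy - 1           # -1 .. 1
  mu_theta <- theta_span * frac              # equally spaced centres
  mu_s <- signal_level - s_dip * frac^2      # homozygotes darker
  n <- length(dosages)
  log2A <- mu_s - mu_theta / 2 + rnorm(n, sd = noise_sd)
  log2B <- mu_s + mu_theta / 2 + rnorm(n, sd = noise_sd)
  A <- 2^matrix(log2A, nrow(dosages), dimnames = dimnames(dosages))
  B <- 2^matrix(log2B, nrow(dosages), dimnames = dimnames(dosages))
  list(A = A, B = B)
}

#' Simulate phenotypes with a known causal architecture
#'
#' Generates one phenotype value per sample as the sum of an
#' environmental term and scaled causal-dosage terms:
#' \deqn{Y_i = \sqrt{1 - \sum_j \pi_j}\, N(0,1) +
#'   \sum_j a_{ij} \sqrt{\pi_j / (ploidy\, f_j (1 - f_j))}}
#' where \eqn{a_{ij}} is the (uncentred) dosage of sample i at causal
#' probe j, \eqn{f_j} the empirical B-allele frequency
#' (mean dosage / ploidy) and \eqn{\pi_j} the variance explained by probe
#' j, so \eqn{\sum_j \pi_j} is the narrow-sense heritability. The scaling
#' assumes binomial dosage variance \eqn{ploidy\, f(1-f)}; in an F1
#' population the dosage law is hypergeometric-convolution rather than
#' binomial, so the realized heritability deviates from the nominal one
#' (report realized values for F1-structured runs).
#'
#' @param dosages probes x samples dosage matrix.
#' @param causal_probes character vector of probe ids (rows of
#'   \code{dosages}).
#' @param pi_j numeric vector of explained variances, one per causal
#'   probe, with \code{sum(pi_j) <= 1}.
#' @param ploidy scaling constant in the denominator (default 6).
#' @param seed integer seed.
#' @return named numeric vector of phenotypes, one per sample.
#' @export
simulate_phenotypes <- function(dosages, causal_probes, pi_j,
                                ploidy = 6L, seed = NULL) {
  stopifnot(length(causal_probes) == length(pi_j), all(pi_j >= 0))
  if (sum(pi_j) > 1) stop("sum(pi_j) must be <= 1")
  missing <- setdiff(causal_probes, rownames(dosages))
  if (length(missing))
    stop("causal probes not in dosage matrix: ",
         paste(missing, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  a <- dosages[causal_probes, , drop = FALSE]
  f <- rowMeans(a) / ploidy
  if (any(f <= 0 | f >= 1))
    stop("monomorphic causal probe (allele frequency 0 or 1): ",
         paste(causal_probes[f <= 0 | f >= 1], collapse = ", "))
  w <- sqrt(pi_j / (ploidy * f * (1 - f)))
  y <- sqrt(1 - sum(pi_j)) * rnorm(ncol(a)) + drop(crossprod(a, w))
  setNames(y, colnames(dosages))
}

#' Simulate replicated phenotype records with block and plate effects
#'
#' Builds the repeated-measurement table the mixed-model fit consumes:
#' each sample is observed \code{reps} times, records are assigned to
#' blocks and plates cyclically, and
#' \code{y = alpha + block + plate + g + N(0, sigma2_e)} per record.
#'
#' @param g named numeric vector of true genetic values per sample.
#' @param reps records per sample (>= 1).
#' @param n_blocks,n_plates numbers of factor levels.
#' @param block_effects,plate_effects effect vectors (recycled/defaulted
#'   to 0).
#' @param sigma2_e residual variance (>= 0).
#' @param alpha population mean.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample_id}, \code{block},
#'   \code{plate}, \code{value}.
#' @export
simulate_repeated_measurements <- function(g, reps = 2L, n_blocks = 2L,
                                           n_plates = 2L,
                                           block_effects = NULL,
                                           plate_effects = NULL,
                                           sigma2_e = 1, alpha = 0,
                                           seed = NULL) {
  if (reps < 1) stop("reps must be >= 1")
  if (sigma2_e < 0) stop("sigma2_e must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(block_effects)) block_effects <- rep(0, n_blocks)
  if (is.null(plate_effects)) plate_effects <- rep(0, n_plates)
  n <- length(g)
  ids <- if (is.null(names(g))) sprintf("S%03d", seq_len(n)) else names(g)
  sample_id <- rep(ids, each = reps)
  rep_idx <- rep(seq_len(reps), times = n)
  block <- ((rep_idx - 1L) %% n_blocks) + 1L
  plate <- ((rep(seq_len(n), each = reps) + rep_idx - 2L) %% n_plates) + 1L
  value <- alpha + block_effects[block] + plate_effects[plate] +
    rep(g, each = reps) + rnorm(n * reps, sd = sqrt(sigma2_e))
  data.frame(sample_id = sample_id,
             block = factor(block), plate = factor(plate),
             value = value, stringsAsFactors = FALSE)
}

#' Simulate a complete F1 study
#'
#' Convenience driver tying the pieces together: map, parents, offspring
#' dosages, causal-probe selection, phenotypes and intensities. Defaults
#' emulate the validation study's conditions: 228 offspring, hexaploid,
#' 18 chromosomes, heritability 0.78 split equally over the causal
#' probes; probe count is scaled by the caller.
#'
#' Causal probes are drawn among well-segregating probes (one probe per
#' SNP, empirical allele frequency inside \code{causal_freq_range}), so
#' a causal locus is never wiped out by the segregation filter.
#'
#' @param n_probes,n_chromosomes,ploidy,n_offspring population dimensions.
#' @param n_causal number of causal probes (study grid: 2..10).
#' @param h2 heritability; \code{pi_j = h2/n_causal} each.
#' @param noise_sd intensity noise (per log2 channel).
#' @param allele_freq_range parental B-allele frequency range.
#' @param causal_freq_range empirical offspring allele-frequency window
#'   causal probes are drawn from (default 0.2-0.8).
#' @param phenotype_sd sd the phenotype vector is rescaled to (default 1,
#'   i.e. no rescaling beyond the unit-variance construction).
#' @param seed integer seed driving every stage.
#' @return list with \code{map}, \code{parents}, \code{dosages},
#'   \code{intensities} (list A,B), \code{phenotypes}, \code{causal}
#'   (data.frame probe_id, pi_j), \code{config}.
#' @export
simulate_f1_population <- function(n_probes = 2000L, n_chromosomes = 18L,
                                   ploidy = 6L, n_offspring = 228L,
                                   n_causal = 5L, h2 = 0.78,
                                   noise_sd = 0.15,
                                   allele_freq_range = c(0.1, 0.9),
                                   causal_freq_range = c(0.2, 0.8),
                                   phenotype_sd = 1, seed = 1L) {
  stopifnot(n_causal >= 1, h2 >= 0, h2 <= 1)
  set.seed(seed)
  map <- make_linkage_map(n_probes, n_chromosomes)
  parents <- simulate_parents(map, ploidy, allele_freq_range)
  dosages <- simulate_offspring(parents, map, n_offspring)

  f <- rowMeans(dosages) / ploidy
  segregating <- which(f >= min(causal_freq_range) &
                         f <= max(causal_freq_range))
  snp_of <- map$snp_id[segregating]
  pick_pool <- segregating[!duplicated(snp_of)]
  if (length(pick_pool) < n_causal)
    stop("not enough segregating SNPs for the requested causal count")
  causal_idx <- sample(pick_pool, n_causal)
  causal <- data.frame(probe_id = map$probe_id[causal_idx],
                       pi_j = rep(h2 / n_causal, n_causal),
                       stringsAsFactors = FALSE)
  y <- if (h2 > 0 || n_causal > 0)
    simulate_phenotypes(dosages, causal$probe_id, causal$pi_j, ploidy)
  else setNames(rnorm(ncol(dosages)), colnames(dosages))
  if (phenotype_sd != 1) y <- y / sd(y) * phenotype_sd
  intensities <- simulate_intensities(dosages, ploidy, noise_sd)
  list(map = map, parents = parents, dosages = dosages,
       intensities = intensities, phenotypes = y, causal = causal,
       config = list(n_probes = n_probes, n_chromosomes = n_chromosomes,
                     ploidy = ploidy, n_offspring = n_offspring,
                     n_causal = n_causal, h2 = h2, noise_sd = noise_sd,
                     allele_freq_range = allele_freq_range,
                     phenotype_sd = phenotype_sd, seed = seed))
}
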