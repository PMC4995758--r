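#' Cross-method overlap of significant probe sets
#'
#' Venn-style summary for the three association engines: set sizes, all
#' pairwise intersections and the triple intersection. The region counts
#' satisfy inclusion-exclusion by construction.
#'
#' @param sets named list of character vectors (significant probe ids per
#'   method).
#' @return list of class \code{overlap_summary}: \code{sizes},
#'   \code{pairwise} (named intersection counts), \code{triple},
#'   \code{union_size}, \code{regions} (exclusive region counts).
#' @export
overlap_summary <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (is.null(names(sets))) names(sets) <- paste0("method", seq_along(sets))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  sizes <- vapply(sets, length, 0L)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  pairwise <- vapply(pairs, function(p)
    length(intersect(sets[[p[1]]], sets[[p[2]]])), 0L)
  names(pairwise) <- vapply(pairs, paste, "", collapse = "&")
  triple <- if (length(sets) >= 3)
    length(Reduce(intersect, sets[nm[1:3]])) else NA_integer_
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, nm))
  key <- apply(member, 1, function(z) paste(nm[z], collapse = "&"))
  regions <- table(key)
  structure(list(sizes = sizes, pairwise = pairwise, triple = triple,
                 union_size = length(universe), regions = regions),
            class = "overlap_summary")
}

#' Probe/SNP/contig structure of a significant probe set
#'
#' Each SNP is interrogated by up to two probes (forward/reverse strand);
#' significant probes therefore arrive as duplicate pairs (both probes of
#' a SNP) or singletons. Contigs carry up to three SNPs, so significant
#' markers cluster 1-3 per contig. This summary reports both
#' distributions.
#'
#' @param significant_probes character vector of probe ids.
#' @param map \code{linkage_map} covering every significant probe.
#' @return list of class \code{contig_summary}: \code{n_significant},
#'   \code{n_duplicate_probes} (probes whose partner probe is also
#'   significant), \code{n_duplicated_snps}, \code{n_single_probe_snps},
#'   \code{snp_table} (snp_id, n_probes_significant),
#'   \code{contig_hist} (significant SNPs per contig, tabulated).
#' @export
summarize_contig_structure <- function(significant_probes, map) {
  missing <- setdiff(significant_probes, map$probe_id)
  if (length(missing))
    stop("probes missing from map: ", paste(head(missing, 10), collapse = ", "))
  if (length(significant_probes) == 0) {
    return(structure(list(n_significant = 0L, n_duplicate_probes = 0L,
                          n_duplicated_snps = 0L, n_single_probe_snps = 0L,
                          snp_table = data.frame(snp_id = character(),
                                                 n_probes_significant = integer()),
                          contig_hist = table(integer())),
                     class = "contig_summary"))
  }
  sub <- map[map$probe_id %in% significant_probes, ]
  per_snp <- table(sub$snp_id)
  snp_table <- data.frame(snp_id = names(per_snp),
                          n_probes_significant = as.integer(per_snp),
                          stringsAsFactors = FALSE)
  contig_of_snp <- map$contig_id[match(snp_table$snp_id, map$snp_id)]
  contig_hist <- table(table(contig_of_snp))
  structure(list(
    n_significant = length(unique(significant_probes)),
    n_duplicate_probes = sum(per_snp[per_snp >= 2]),
    n_duplicated_snps = sum(per_snp >= 2),
    n_single_probe_snps = sum(per_snp == 1),
    snp_table = snp_table,
    contig_hist = contig_hist), class = "contig_summary")
}

#' End-to-end association run over one simulated (or loaded) dataset
#'
#' Orchestrates the full workflow: quantile normalization, theta/s
#' transformation, segregation filter (theta range >= 2), mean-centering,
#' optional mixed-model DEBV step when repeated phenotype records are
#' supplied, then the three association engines and their overlap. All
#' thresholds default to the study protocol: q <= 0.01, BF >= 10,
#' VIM >= 2, F >= 4 prefilter for PLSR.
#'
#' @param data list with \code{intensities} (list A, B), \code{map}, and
#'   either \code{phenotypes} (one value per sample, used directly as the
#'   response) or \code{records} (repeated measurements for
#'   \code{\link{fit_mixed_model}} + \code{\link{deregress}}).
#' @param q_threshold,bf_min,vim_threshold,f_min engine thresholds.
#' @param normalize run quantile normalization first (default TRUE).
#' @param min_theta_range segregation filter threshold (default 2).
#' @param mcmc \code{\link{mcmc_config}} for the Bayesian engine.
#' @param prior \code{\link{mixture_prior}}.
#' @param pls_folds,pls_repeats,pls_lv_grid PLSR protocol.
#' @param seed integer seed.
#' @return list of class \code{trait_association}: \code{lr},
#'   \code{bayes}, \code{pls}, \code{overlap}, \code{filter_report},
#'   \code{debv} (NULL without records), \code{x} (centered genotypes),
#'   \code{y}, \code{manifest}.
#' @export
run_trait_association <- function(data, q_threshold = 0.01, bf_min = 10,
                                  vim_threshold = 2, f_min = 4,
                                  normalize = TRUE, min_theta_range = 2,
                                  mcmc = mcmc_config(),
                                  prior = mixture_prior(),
                                  pls_folds = 10L, pls_repeats = 20L,
                                  pls_lv_grid = 1:10, seed = 1L) {
  stage <- "normalize"
  res <- tryCatch({
    ints <- if (normalize) quantile_normalize(data$intensities)
            else data$intensities
    stage <- "transform"
    th <- compute_theta_s(ints)
    flt <- filter_by_theta_range(th, min_theta_range)
    x <- mean_center(flt$theta)
    if (nrow(x) == 0) stop("no probes pass the segregation filter")

    stage <- "breeding_values"
    debv <- NULL
    if (!is.null(data$records)) {
      fit <- fit_mixed_model(data$records)
      debv <- deregress(fit)
      y <- setNames(debv$debv, debv$sample_id)[colnames(x)]
    } else {
      y <- data$phenotypes[colnames(x)]
    }
    if (any(is.na(y))) stop("response missing for some samples")

    stage <- "assoc_linear"
    lr <- genome_scan_lr(x, y, q_threshold = q_threshold)

    stage <- "assoc_bayes"
    bayes <- gibbs_sample(x, y, prior = prior, mcmc = mcmc,
                          bf_min = bf_min)

    stage <- "assoc_plsr"
    keep <- prefilter_by_f(lr, f_min)
    pls <- if (length(keep) >= 1) {
      run_plsr_association(t(x[keep, , drop = FALSE]), y,
                           lv_grid = pls_lv_grid, folds = pls_folds,
                           repeats = pls_repeats,
                           vim_threshold = vim_threshold, seed = seed)
    } else NULL

    stage <- "overlap"
    sets <- list(LR = lr$probe_id[lr$significant],
                 bayes = select_significant_bf(bayes, bf_min),
                 PLSR = if (is.null(pls)) character(0) else pls$significant)
    list(lr = lr, bayes = bayes, pls = pls,
         overlap = overlap_summary(sets),
         filter_report = flt$report, debv = debv, x = x, y = y,
         manifest = list(seed = seed, q_threshold = q_threshold,
                         bf_min = bf_min, vim_threshold = vim_threshold,
                         f_min = f_min, min_theta_range = min_theta_range,
                         normalize = normalize, mcmc = unclass(mcmc),
                         prior = unclass(prior),
                         package_version =
                           as.character(utils::packageVersion("thetaGWAS"))))
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  class(res) <- "trait_association"
  res
}

#' Replicated simulation study of the linear-regression engine
#'
#' For each combination of causal-probe count and heritability, and each
#' replicate: simulate an F1 population (genotypes by polysomic meiosis,
#' phenotypes with the scaled causal-dosage model), run the linear scan
#' on the mean-centered true dosages, and record the number of q <= 0.01
#' probes and how many causal probes were recovered. Genotypes are
#' re-simulated per replicate and shared across the heritability grid.
#'
#' @param n_causal_grid causal-probe counts (study grid 2..10).
#' @param h2_grid heritabilities to cover (default 0.78).
#' @param replicates replicates per combination (study protocol: 100).
#' @param n_probes,n_chromosomes,n_offspring,ploidy population scale.
#' @param causal_freq_range allele-frequency window for causal probes.
#' @param q_threshold significance threshold (default 0.01).
#' @param seed integer seed.
#' @return data.frame with one row per (n_causal, h2, replicate):
#'   \code{n_significant}, \code{n_causal_recovered}, \code{n_tested}.
#' @export
run_simulation_study <- function(n_causal_grid = 2:10, h2_grid = 0.78,
                                 replicates = 100L, n_probes = 5000L,
                                 n_chromosomes = 18L, n_offspring = 228L,
                                 ploidy = 6L,
                                 causal_freq_range = c(0.2, 0.8),
                                 q_threshold = 0.01, seed = 1L) {
  rows <- list()
  for (nc in n_causal_grid) {
    for (rep_i in seq_len(replicates)) {
      rep_seed <- seed + 1000L * match(nc, n_causal_grid) + rep_i
      set.seed(rep_seed)
      map <- make_linkage_map(n_probes, n_chromosomes)
      parents <- simulate_parents(map, ploidy)
      dosages <- simulate_offspring(parents, map, n_offspring)
      f <- rowMeans(dosages) / ploidy
      pool <- which(f >= min(causal_freq_range) &
                      f <= max(causal_freq_range))
      pool <- pool[!duplicated(map$snp_id[pool])]
      causal <- sample(pool, nc)
      x <- mean_center(dosages)
      poly <- apply(dosages, 1, function(r) length(unique(r)) > 1)
      for (h2 in h2_grid) {
        y <- if (h2 > 0)
          simulate_phenotypes(dosages, map$probe_id[causal],
                              rep(h2 / nc, nc), ploidy)
        else setNames(rnorm(n_offspring), colnames(dosages))
        scan <- genome_scan_lr(x[poly, , drop = FALSE], y,
                               q_threshold = q_threshold)
        sig <- scan$probe_id[scan$significant]
        rows[[length(rows) + 1L]] <- data.frame(
          n_causal = nc, h2 = h2, replicate = rep_i,
          n_significant = length(sig),
          n_causal_recovered = sum(map$probe_id[causal] %in% sig),
          n_tested = sum(poly))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
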