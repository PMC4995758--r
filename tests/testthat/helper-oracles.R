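# Independent oracles used across the suite. These deliberately take
# brute-force or closed-form routes that share no code with the
# implementation they check.

# log-density of a multivariate normal via Cholesky
dmvnorm_log <- function(y, Sigma) {
  L <- chol(Sigma)
  z <- backsolve(L, y, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# exhaustive posterior inclusion probabilities for the two-component
# mixture model with fixed variances and mixture weight: integrate the
# effects out of every indicator configuration in closed form
bvs_enumerate_pip <- function(X, y, pi0, sigma2_g0, sigma2_g1, sigma2_e) {
  p <- ncol(X)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  logw <- apply(configs, 1, function(d) {
    v <- ifelse(d == 1, sigma2_g1, sigma2_g0)
    Sigma <- X %*% (v * t(X)) + diag(sigma2_e, nrow(X))
    dmvnorm_log(y, Sigma) + sum(log(ifelse(d == 1, 1 - pi0, pi0)))
  })
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  drop(crossprod(configs, w))
}

# closed-form ANOVA variance-component estimators for a balanced
# one-way random-effects design (n groups x r replicates)
anova_oneway_vc <- function(values, group) {
  r <- unique(table(group))
  stopifnot(length(r) == 1)
  gm <- mean(values)
  group_means <- tapply(values, group, mean)
  n <- length(group_means)
  msa <- r * sum((group_means - gm)^2) / (n - 1)
  mse <- sum((values - group_means[group])^2) / (n * (r - 1))
  list(sigma2_e = mse, sigma2_g = (msa - mse) / r, msa = msa, mse = mse)
}

# exhaustive gamete-dosage law at a single unlinked locus: enumerate
# every subset of ploidy/2 transmitted homologues
enumerate_gamete_law <- function(alleles) {
  ploidy <- length(alleles)
  sub <- utils::combn(ploidy, ploidy / 2)
  counts <- apply(sub, 2, function(s) sum(alleles[s]))
  table(factor(counts, levels = 0:(ploidy / 2))) / ncol(sub)
}

# single-probe map fixture at an arbitrary position
one_probe_map <- function() {
  structure(data.frame(probe_id = "pr1", chrom = 1L, pos_cM = 50,
                       snp_id = "snp1", contig_id = "ctg1",
                       stringsAsFactors = FALSE),
            class = c("linkage_map", "data.frame"))
}

# small flowering-like study used by several power-style tests:
# hexaploid F1, heritability 0.78, phenotypes scaled to the flowering
# trait's DEBV spread (sd 19)
flowering_like_sim <- function(seed, n_probes = 400L, n_offspring = 150L,
                               n_causal = 3L, noise_sd = 0.15) {
  simulate_f1_population(n_probes = n_probes, n_offspring = n_offspring,
                         n_causal = n_causal, h2 = 0.78,
                         noise_sd = noise_sd, phenotype_sd = 19,
                         seed = seed)
}
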