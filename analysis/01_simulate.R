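#!/usr/bin/env Rscript
# Simulate the study population.
#
# The real dataset (a hexaploid chrysanthemum F1 cross measured on a
# custom Axiom array) is confidential, so every downstream step runs on
# a synthetic population with the same statistical structure: 228 F1
# offspring from two simulated hexaploid parents, probes laid out two
# per SNP and up to three SNPs per contig on 18 chromosomes, allele
# intensities whose theta clusters partially overlap, and a
# flowering-like trait (h2 = 0.78, DEBV-scale sd 19). Probe count is
# scaled to 2,000 to keep this driver quick; every statistic downstream
# is reported relative to that scale.

library(thetaGWAS)

out_dir <- "results/study"
sim <- simulate_f1_population(
  n_probes = 2000, n_chromosomes = 18, ploidy = 6, n_offspring = 228,
  n_causal = 5, h2 = 0.78, noise_sd = 0.25, phenotype_sd = 19,
  seed = 2026)

# repeated raw measurements feeding the mixed model: 2 records per
# offspring in 2 blocks / 4 plates with moderate environmental effects
g <- sim$phenotypes - mean(sim$phenotypes)
sim$records <- simulate_repeated_measurements(
  g, reps = 2, n_blocks = 2, n_plates = 4,
  block_effects = c(3, -3), plate_effects = c(2, 0, -1, -1),
  sigma2_e = var(g) * 0.25, alpha = mean(sim$phenotypes), seed = 2027)

write_simulation(sim, out_dir)

cat("Simulated", nrow(sim$dosages), "probes x", ncol(sim$dosages),
    "offspring on", sim$config$n_chromosomes, "chromosomes\n")
cat("Causal probes (pi_j = 0.156 each, sum = 0.78):\n")
print(sim$causal)
f <- rowMeans(sim$dosages[sim$causal$probe_id, ]) / 6
cat("Causal allele frequencies:", round(f, 3), "\n")
cat("Files written to", out_dir, "\n")
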