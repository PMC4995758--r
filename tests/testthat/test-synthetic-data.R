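test_that("linkage map satisfies its structural invariants", {
  for (s in 1:3) {
    map <- make_linkage_map(n_probes = 501, n_chromosomes = 5, seed = s)
    expect_equal(nrow(map), 501)
    expect_true(all(map$pos_cM >= 0))
    for (ch in unique(map$chrom))
      expect_false(is.unsorted(map$pos_cM[map$chrom == ch]))
    snps_per_contig <- tapply(map$snp_id, map$contig_id,
                              function(x) length(unique(x)))
    expect_lte(max(snps_per_contig), 3)
    # both probes of a SNP sit at the same position
    pos_per_snp <- tapply(map$pos_cM, map$snp_id,
                          function(x) diff(range(x)))
    expect_equal(max(pos_per_snp), 0)
  }
  corrupt <- make_linkage_map(100, 3, seed = 1)
  corrupt$pos_cM[1] <- -5
  expect_error(validate_linkage_map(corrupt), "non-negative")
})

test_that("degenerate allele frequencies give fixed parental dosages", {
  map <- make_linkage_map(40, 2, seed = 1)
  all_b <- simulate_parents(map, allele_freq_range = c(1, 1), seed = 2)
  expect_true(all(parental_dosage(all_b) == 6))
  all_a <- simulate_parents(map, allele_freq_range = c(0, 0), seed = 2)
  expect_true(all(parental_dosage(all_a) == 0))
  expect_error(simulate_parents(map, ploidy = 5), "even")
})

test_that("parental dosage mean matches the binomial expectation", {
  map <- make_linkage_map(20000, 10, seed = 3)
  par <- simulate_parents(map, allele_freq_range = c(0.5, 0.5), seed = 4)
  d <- parental_dosage(par)
  # dosages are shared within a SNP: count each SNP once
  keep <- !duplicated(map$snp_id)
  mc_se <- sqrt(6 * 0.25 / sum(keep))
  expect_lt(abs(mean(d[keep, "P1"]) - 3), 3 * mc_se)
  expect_lt(abs(mean(d[keep, "P2"]) - 3), 3 * mc_se)
})

test_that("gametes from a fully homozygous parent are constant", {
  map <- one_probe_map()
  hom <- matrix(1L, 1, 6, dimnames = list("pr1", NULL))
  d <- simulate_gametes(hom, map, n = 50, seed = 1)
  expect_true(all(d == 3))
})

test_that("gamete dosage law matches the enumerated hypergeometric law", {
  # enumeration oracle agrees with the closed form for every dosage
  for (d in 0:6) {
    alleles <- c(rep(1, d), rep(0, 6 - d))
    expect_equal(unname(as.vector(enumerate_gamete_law(alleles))),
                 unname(gamete_dosage_law(d, 6)))
  }
  # triplex parent: (1, 9, 9, 1)/20, checked by chi-square simulation
  expect_equal(unname(gamete_dosage_law(3, 6)), c(1, 9, 9, 1) / 20)
  map <- one_probe_map()
  hom <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 1, 6,
                dimnames = list("pr1", NULL))
  d <- simulate_gametes(hom, map, n = 20000, seed = 11)
  obs <- tabulate(d + 1L, 4L)
  chi <- chisq.test(obs, p = c(1, 9, 9, 1) / 20)
  expect_gt(chi$p.value, 0.001)
})

test_that("completely linked probes never recombine", {
  map <- structure(data.frame(probe_id = c("a", "b"), chrom = 1L,
                              pos_cM = c(10, 10),
                              snp_id = c("s1", "s2"),
                              contig_id = "c1", stringsAsFactors = FALSE),
                   class = c("linkage_map", "data.frame"))
  hom <- rbind(a = c(1L, 1L, 1L, 0L, 0L, 0L),
               b = c(1L, 1L, 1L, 0L, 0L, 0L))
  d <- simulate_gametes(hom, map, n = 1000, seed = 5)
  expect_true(all(d[1, ] == d[2, ]))
})

test_that("offspring dosages are gamete sums within bounds", {
  map <- make_linkage_map(80, 3, seed = 6)
  parents <- simulate_parents(map, seed = 7)
  off <- simulate_offspring(parents, map, n_offspring = 60, seed = 8)
  expect_equal(dim(off), c(80, 60))
  expect_true(all(off >= 0 & off <= 6))
  expect_true(is.integer(off))
  expect_error(simulate_offspring(parents, map, n_offspring = 0),
               "positive")

  # fixed-dosage parents: 6 + 0 everywhere -> every offspring 3
  p6 <- simulate_parents(map, allele_freq_range = c(1, 1), seed = 1)
  p6$P2[] <- 0L
  off2 <- simulate_offspring(p6, map, n_offspring = 10, seed = 2)
  expect_true(all(off2 == 3))
})

test_that("offspring allele frequency matches the parental mid-frequency", {
  map <- make_linkage_map(400, 4, seed = 9)
  parents <- simulate_parents(map, seed = 10)
  off <- simulate_offspring(parents, map, n_offspring = 300, seed = 11)
  mid <- rowMeans(parental_dosage(parents)) / 6
  emp <- rowMeans(off) / 6
  # every probe within a generous MC band, and no systematic bias
  expect_lt(max(abs(emp - mid)), 0.12)
  expect_lt(abs(mean(emp - mid)), 0.005)
})

test_that("intensity model reproduces the theta cluster geometry", {
  dos <- matrix(rep(0:6, each = 10), nrow = 1,
                dimnames = list("pr1", NULL))
  ints <- simulate_intensities(dos, noise_sd = 0, seed = 1)
  th <- compute_theta_s(ints)
  expect_equal(length(unique(round(drop(th$theta), 10))), 7)
  centres <- as.numeric(tapply(drop(th$theta), drop(dos), unique))
  expect_true(all(diff(centres) > 0))
  expect_equal(diff(centres), rep(diff(centres)[1], 6))  # equal spacing
  expect_equal(centres[4], 0)                            # balanced alleles
  s_by_class <- tapply(drop(th$s), drop(dos), unique)
  expect_lt(s_by_class["0"], s_by_class["3"])            # homozygotes darker
  expect_lt(s_by_class["6"], s_by_class["3"])
})

test_that("within-class theta noise has sd sqrt(2) * noise_sd", {
  dos <- matrix(3L, 1, 4000, dimnames = list("pr1", NULL))
  ints <- simulate_intensities(dos, noise_sd = 0.2, seed = 2)
  th <- compute_theta_s(ints)
  sd_hat <- sd(drop(th$theta))
  se <- sqrt(2) * 0.2 / sqrt(2 * 4000)   # se of a normal sd estimate
  expect_lt(abs(sd_hat - sqrt(2) * 0.2), 4 * se)
})

test_that("phenotype simulator follows the scaled causal-dosage model", {
  set.seed(3)
  dos <- matrix(rbinom(2 * 800, 6, 0.5), nrow = 2,
                dimnames = list(c("c1", "c2"), NULL))
  # sum(pi) = 0: standard normal environment only
  y0 <- simulate_phenotypes(dos, character(0), numeric(0), seed = 4)
  expect_equal(length(y0), 800)
  expect_lt(abs(sd(y0) - 1), 0.1)

  # one causal probe, pi = 0.5, f ~ 0.5: genetic variance contribution 0.5
  y1 <- simulate_phenotypes(dos, "c1", 0.5, seed = 5)
  f <- mean(dos["c1", ]) / 6
  w <- sqrt(0.5 / (6 * f * (1 - f)))
  expect_lt(abs(var(dos["c1", ] * w) - 0.5), 0.06)
  expect_lt(abs(var(y1) - 1), 0.12)

  mono <- matrix(6L, 1, 10, dimnames = list("m", NULL))
  expect_error(simulate_phenotypes(mono, "m", 0.5), "monomorphic")
  expect_error(simulate_phenotypes(dos, c("c1", "c2"), c(0.6, 0.6)),
               "<= 1")
})

test_that("regression R2 on causal dosages approaches the heritability", {
  set.seed(6)
  n <- 5000
  dos <- matrix(rbinom(5 * n, 6, rep(runif(5, 0.3, 0.7), n)), nrow = 5,
                dimnames = list(paste0("c", 1:5), NULL))
  y <- simulate_phenotypes(dos, rownames(dos), rep(0.78 / 5, 5), seed = 7)
  r2 <- summary(lm(y ~ t(dos)))$r.squared
  expect_lt(abs(r2 - 0.78), 0.02)
})

test_that("repeated-measurement records follow the block/plate model", {
  g <- setNames(c(1, -1, 0.5), c("a", "b", "c"))
  rec0 <- simulate_repeated_measurements(g, reps = 2, sigma2_e = 0,
                                         seed = 1)
  expect_equal(rec0$value, rep(g, each = 2), ignore_attr = TRUE)

  rec <- simulate_repeated_measurements(g, reps = 2, n_blocks = 2,
                                        block_effects = c(1, -1),
                                        sigma2_e = 0, seed = 2)
  by_sample <- split(rec, rec$sample_id)
  for (df in by_sample)
    expect_equal(diff(df$value), diff(c(1, -1)[as.integer(df$block)]))
  expect_error(simulate_repeated_measurements(g, sigma2_e = -1),
               "non-negative")
})

test_that("the full study simulator is reproducible under a seed", {
  a <- simulate_f1_population(n_probes = 120, n_offspring = 30, seed = 99)
  b <- simulate_f1_population(n_probes = 120, n_offspring = 30, seed = 99)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$causal, b$causal)
})
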