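---
title: "Continuous-genotype association in polyploids: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-genotype association in polyploids: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A bi-allelic array probe reports two signal intensities, A and B. In a
diploid the log-ratio of the two clusters into three well-separated
groups and assigning each sample to a cluster (genotype calling)
removes noise essentially for free. In a hexaploid there are up to
seven dosage classes squeezed onto the same signal range: cluster
spacing shrinks, clusters drift and overlap, and a hard assignment
starts to destroy more information than it removes. The alternative
implemented here is to skip calling altogether and carry the
continuous genotype value

$$\theta = \log_2(B) - \log_2(A), \qquad
  s = \tfrac{1}{2}\left(\log_2(A) + \log_2(B)\right)$$

directly into association, treating $\theta$ as a noisy but monotone
proxy for allele dosage. For four-allele count data the analogous
contrast $\theta_i = \log_2 G_i - \sum_{j \neq i} \log_2 G_j$ is
provided (`compute_theta_multiallelic`); note that subtracting three
log-counts makes it scale with total depth — it is implemented as
defined, and better transforms are an open problem, not something this
package silently "fixes".

Preprocessing is deliberately minimal: quantile normalization across
samples (A and B channels of a sample stacked, so each sample's whole
signal distribution is equalized; ties share averaged ranks), the
transform above, a segregation filter that drops probes whose
$\theta$ range across samples is below 2 (association requires
segregation; the threshold is the study's), and per-probe
mean-centering.

## Response: deregressed breeding values

Replicated raw measurements are reduced to one response per individual
via the mixed model $y = \alpha + \beta^{(block)} + \beta^{(plate)} +
g + e$, with $g \sim N(0, \sigma^2_g)$ per individual and $e \sim
N(0, \sigma^2_e)$, fitted by REML. Individuals are treated as
unrelated (identity covariance): the model as specified carries no
kinship, and in a single bi-parental F1 the additive relationship
matrix is close to compound-symmetric, where the common part is
absorbed by the intercept. The restricted likelihood is profiled over
$\lambda = \sigma^2_g/\sigma^2_e$; the random-intercept structure
gives $(I + \lambda ZZ')^{-1}$ in closed form, so each evaluation is
O(records) and the one-dimensional search (bounded, on
$\log \lambda$, tolerance $10^{-10}$, with an explicit boundary check
at $\sigma^2_g = 0$) is exact enough to match closed-form balanced
ANOVA estimators to $10^{-6}$ relative error.

EBVs (BLUPs) and their prediction error variances come from the
mixed-model equations at the REML estimates. Deregression divides each
EBV by its reliability $r^2_i = 1 - PEV_i/\sigma^2_g$, undoing BLUP
shrinkage so the association response is not attenuated. One subtlety:
with an unknown population mean, $PEV_i$ contains an irreducible
$\sigma^2_g/n$ term (the mean and the average genetic value are
confounded), so $PEV \to \sigma^2_g/n$ rather than 0 in the noiseless
limit; reliabilities remain below 1 accordingly. Deregression refuses
to run when $PEV_i \geq \sigma^2_g$ (non-positive reliability).

## The three association engines

**Linear regression.** Per probe, $Y_i = \alpha + \beta x_i +
\epsilon_i$ on the centered genotype; two-sided p from $t_{n-2}$.
Monomorphic probes carry no test: they are flagged, assigned p = 1,
and excluded from the multiple-testing universe. P-values become
q-values by the Storey procedure: $\hat\pi_0(\lambda)$ on the grid
$\lambda = 0.05, \dots, 0.90$, smoothed with a cubic spline (df 3) and
extrapolated to $\lambda = 1$, clamped to (0, 1]; below 100 p-values
the spectrum is too short to smooth and $\hat\pi_0 = 1$ is used, which
reduces the step-up rule to Benjamini–Hochberg. Significance is
declared at q ≤ 0.01.

**Bayesian variable selection.** All probes enter one regression with
the two-component mixture prior on each effect:
$a_k \sim \pi_0 N(0, \sigma^2_{g0}) + (1-\pi_0) N(0, \sigma^2_{g1})$,
defaults $\pi_0 = 0.99$, $\sigma^2_{g0} = 0.001$, $\sigma^2_{g1} =
0.1$, and a Beta(10, 1) hyperprior on $\pi_0$ — read as favouring the
null component (mean 10/11), consistent with $\pi_0 = 0.99$. The Gibbs
sampler updates each probe's indicator and effect jointly (indicator
from the effect-marginalized conditional, then the conjugate normal),
which avoids the notorious mixing failure of separate single-move
spike-and-slab updates. The schedule is 50,000 sweeps, 10,000 burn-in,
thin 200; inclusion probabilities and mean effects are averaged over
*every* post-burn-in sweep (200 thinned draws alone would put ~0.035
of Monte-Carlo noise on an inclusion probability, too coarse to be
useful), while the thinned states feed the traces and a split-chain
stationarity check on the residual variance.

The component variances are sampled. A flat prior makes the
conditional of a momentarily empty component improper; naively
freezing the variance at its last draw lets the slab wander to
enormous values, after which no probe can ever enter it (a
Lindley-type degeneracy we hit in development). Both variances
therefore carry weak scaled-inverse-$\chi^2$ priors (df 4) anchored at
the configured settings, which keeps empty components proper while
letting the data dominate as soon as a handful of probes populate the
component; an ordering constraint ($\sigma^2_{g0} \leq \sigma^2_{g1}$)
pins the labels. Both variances can also be held fixed, which is how
the sampler is checked against exhaustive enumeration over all $2^p$
indicator configurations on small systems.

The Bayes factor of a probe is its posterior-to-prior inclusion odds
$BF_j = [\hat p_j/(1-\hat p_j)]/[\pi_1/(1-\pi_1)]$, with a half-count
guard on $\hat p_j$ so a finite chain cannot produce an infinite BF;
significance at BF ≥ 10.

**PLSR.** On the probes passing an F ≥ 4 univariate prefilter:
an 80/20 calibration/test split (seeded shuffle; no stratification
variable exists), 10-fold cross-validation repeated 20 times over 1–10
latent variables choosing the lowest mean RMSE (ties to fewer
components), a final orthogonal-scores (NIPALS) fit, and
variable-importance scores. The VIM is the explained-variance-weighted
sum of absolute per-component coefficient contributions
($\omega_h$ = fraction of response variance explained by component
$h$); the classical VIP ($\sqrt{p \sum_h \omega_h w_{jh}^2}$) is
available behind a switch. Predictors are standardized by default
(toggleable). Significance at VIM ≥ 2 — an *absolute* threshold, which
only makes sense on a particular response scale: with deregressed
values spread like the real traits (sd 6–64), causal-probe VIMs land
in the 2–4 range, which is why the synthetic "flowering-like" fixtures
rescale phenotypes to sd 19. The threshold's calibration is fragile by
construction (the ranking is not): the bundled analysis shows a run
where the causal probes occupy the top VIM ranks yet none clears 2.

## The class-based comparator

`call_nearest_cluster` assigns every sample the dosage with the
nearest $\theta$ centre — ties toward the lower dosage, centres either
fixed (equally spaced on [−2, 2], the equal-spacing expectation) or
adaptive per probe (equally spaced over the central 95% of that
probe's $\theta$, clamped to [−2, 2]), the latter being the fairer
comparator when clusters drift. Deliberately, every sample is
assigned and there is no outlier class: the point is to mirror the
behaviour being criticized. The association covariate from calls is
the difference of the two allele counts, $(ploidy - d) - d$, an affine
function of dosage. `compare_associations` pairs the two scans probe
by probe and labels agreement.

## What the simulator emulates — and what it does not

The generator reproduces the study conditions: 228 F1 offspring of two
phased hexaploid parents; probes two per SNP (same locus, independent
intensity noise) with ≤3 SNPs per contig on 18 chromosomes (uniform
positions, 100 cM each — chromosome lengths, marker spacing and
parental phasing of the real population are unknown, so these are
explicit stand-ins); meiosis by random bivalent pairing with Haldane
crossovers (no interference) and one transmitted chromatid per
bivalent, giving the hypergeometric gamete-dosage law
$C(d,k)C(n-d, n/2-k)/C(n, n/2)$ at unlinked loci. No multivalents,
no double reduction, no preferential pairing, no mixed
disomic/polysomic inheritance — the simplest fully polysomic model.

Intensities: log-scale A/B signals with equally spaced $\theta$
centres spanning [−2, 2] (so the noise-free range is 4 and a
segregating probe passes the range-2 filter), a quadratic dip in $s$
for homozygotes, and independent Gaussian noise per channel, so
within-class $\theta$ noise is $\sqrt{2}\,\sigma$. With per-channel
noise around 0.45 adjacent classes (spacing 2/3) merge into the
continuum regime; the bundled study uses 0.25.

Phenotypes: $Y_i = \sqrt{1 - \sum_j \pi_j}\, N(0,1) + \sum_j a_{ij}
\sqrt{\pi_j/(6 f_j (1-f_j))}$ with $a_{ij}$ the raw (uncentred)
dosage — the mean offset is irrelevant to association — and $f_j$ the
*empirical offspring* allele frequency (the formula's frequency is
otherwise unspecified, and the empirical value needs no pedigree
assumptions). The scaling assumes binomial dosage variance
$6f(1-f)$; F1 dosages are a convolution of two hypergeometrics, so
realized heritability deviates from nominal in F1-structured runs.
Calibration is therefore checked where the algebra is exact — dosages
drawn Binomial(6, f) — at n = 10,000, where the $R^2$ of phenotype on
causal dosages recovers the configured 0.78 within Monte-Carlo error.
Causal probes are drawn one per SNP among loci with empirical
frequency in [0.2, 0.8], explained variance split equally; a
monomorphic causal probe is an error, not a silent skip.

Passing tests on these simulations show that the engines do what they
claim under polysomic F1 structure with overlapping clusters. They do
not show robustness to the things the generator leaves out: cluster
drift and asymmetric cluster shapes, batch effects, outlier samples,
tri/tetra-allelic probes, sub-genome fractionation, genotyping errors
correlated between the two probes of a SNP, or non-normal traits.

## Numerical choices and problem sizes

Seeds control every stochastic step; identical configuration plus seed
reproduces outputs bit for bit. Degenerate inputs have defined
behaviour throughout (monomorphic probes flagged, empty components
kept proper, confounded fixed effects rejected, odd ploidy rejected).
Default test and analysis scales were chosen so the whole suite runs
in minutes on one core: populations of 200–5,000 probes × 120–228
offspring, 100 null datasets of 5,000 × 228 for the false-discovery
check, 20 replicates per heritability level in the scaled simulation
study, and the full 50,000-sweep MCMC schedule reserved for the
analysis driver at 2,000 probes (~2 minutes). The study-scale
numbers (55,825 probes; 100 replicates) are representable — nothing
in the code depends on the reduced sizes — and the simulation-study
counts scale proportionally (at 2,000 probes, medians around 15
significant probes correspond to the order of several hundred at full
probe count).

## Known limitations

* Gamete simulation is exact only under strict bivalent pairing;
  species with frequent multivalents (double reduction) will show
  higher-variance dosage laws than simulated here.
* The Bayes-factor definition is the posterior/prior odds of
  component membership; other definitions exist, and real-data BF
  values from other software are not comparable number-for-number.
* The VIM ≥ 2 rule inherits the response scale; compare VIM rankings,
  not thresholded counts, across traits with different spreads.
* The q-value $\hat\pi_0$ smoother needs a few hundred p-values to be
  stable; small scans silently fall back to Benjamini–Hochberg.
* Linkage mapping, haplotype phasing and imputation from low-coverage
  sequencing are out of scope.
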