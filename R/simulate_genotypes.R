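#' Simulate phased parental genomes for a bi-parental cross
#'
#' Draws two fully phased parents for an even-ploidy species. For each
#' SNP a B-allele frequency is drawn uniformly from
#' \code{allele_freq_range} and every homologue of both parents carries
#' the B allele independently with that probability. The two probes of a
#' SNP share the SNP's alleles, so duplicate-probe structure is preserved
#' downstream.
#'
#' @param map a \code{linkage_map} (see \code{\link{make_linkage_map}}).
#' @param ploidy even integer, default 6 (hexaploid). Odd ploidy is
#'   rejected: the bivalent meiosis model requires homologues to pair.
#' @param allele_freq_range length-2 numeric in [0,1]; per-SNP B-allele
#'   frequency range. A degenerate range (e.g. \code{c(1,1)}) fixes the
#'   frequency.
#' @param seed integer seed.
#' @return list of class \code{parental_genome}: \code{P1}, \code{P2}
#'   (binary probes x ploidy matrices, 1 = B allele), \code{ploidy},
#'   \code{map}.
#' @export
simulate_parents <- function(map, ploidy = 6L,
                             allele_freq_range = c(0.1, 0.9),
                             seed = NULL) {
  if (ploidy %% 2L != 0L || ploidy < 2L)
    stop("ploidy must be a positive even integer (bivalent meiosis model)")
  stopifnot(length(allele_freq_range) == 2,
            all(allele_freq_range >= 0), all(allele_freq_range <= 1))
  if (!is.null(seed)) set.seed(seed)

  snp <- factor(map$snp_id, levels = unique(map$snp_id))
  n_snps <- nlevels(snp)
  freq <- runif(n_snps, min(allele_freq_range), max(allele_freq_range))
  draw <- function() {
    h <- matrix(rbinom(n_snps * ploidy, 1L, rep(freq, ploidy)),
                nrow = n_snps, ncol = ploidy)
    h <- h[as.integer(snp), , drop = FALSE]
    rownames(h) <- map$probe_id
    h
  }
  out <- list(P1 = draw(), P2 = draw(), ploidy = as.integer(ploidy),
              map = map)
  class(out) <- "parental_genome"
  out
}

#' Parental dosage matrix
#'
#' @param parents a \code{parental_genome}.
#' @return probes x 2 integer matrix of B-allele dosages.
#' @export
parental_dosage <- function(parents) {
  cbind(P1 = rowSums(parents$P1), P2 = rowSums(parents$P2))
}

# Haldane map function: recombination fraction from distance in cM
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

# one transmitted chromatid from a bivalent of two homologues, as a
# Markov chain of Haldane switch events along the marker positions
.chromatid <- function(h1, h2, r) {
  m <- length(h1)
  switches <- c(runif(1) < 0.5, runif(m - 1L) < r)
  state <- cumsum(switches) %% 2L
  ifelse(state == 0L, h1, h2)
}

#' Simulate one gamete by polysomic bivalent meiosis
#'
#' Homologues pair at random into ploidy/2 bivalents independently at
#' each chromosome and each meiosis (polysomic inheritance, no
#' preferential pairing, no multivalents, no double reduction).
#' Crossovers are placed along each bivalent with the Haldane map
#' function (no interference) on the map's cM positions, and one
#' recombinant chromatid per bivalent is transmitted, so the gamete
#' carries ploidy/2 homologues.
#'
#' @param homologs binary probes x ploidy matrix of one parent (rows must
#'   match \code{map$probe_id}).
#' @param map the \code{linkage_map}; every probe row must be mapped.
#' @param seed optional seed (omit when called inside a seeded stream).
#' @return binary probes x (ploidy/2) matrix.
#' @export
simulate_gamete <- function(homologs, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ploidy <- ncol(homologs)
  if (ploidy %% 2L != 0L) stop("even ploidy required")
  if (nrow(homologs) != nrow(map))
    stop("unmapped probe: homolog rows and map rows differ")
  n_biv <- ploidy %/% 2L
  out <- matrix(0L, nrow(homologs), n_biv)
  for (ch in unique(map$chrom)) {
    rows <- which(map$chrom == ch)
    r <- haldane_r(diff(map$pos_cM[rows]))
    pairing <- matrix(sample.int(ploidy), nrow = 2L)
    for (b in seq_len(n_biv)) {
      out[rows, b] <- .chromatid(homologs[rows, pairing[1L, b]],
                                 homologs[rows, pairing[2L, b]], r)
    }
  }
  rownames(out) <- rownames(homologs)
  out
}

#' Batch of gamete dosages from one parent
#'
#' Repeated independent meioses; returns B-allele dosages per probe. Used
#' for checking the hypergeometric gamete-dosage law at large n.
#'
#' @inheritParams simulate_gamete
#' @param n number of gametes.
#' @return probes x n integer dosage matrix.
#' @export
simulate_gametes <- function(homologs, map, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n),
         function(i) rowSums(simulate_gamete(homologs, map)),
         numeric(nrow(homologs)))
}

#' Exact gamete dosage law under bivalent polysomic meiosis
#'
#' For an unlinked locus, transmitting ploidy/2 of the ploidy homologues
#' uniformly at random (no double reduction) gives the hypergeometric law
#' P(k) = C(d,k) C(ploidy-d, ploidy/2-k) / C(ploidy, ploidy/2).
#'
#' @param parent_dosage number of B homologues d, 0..ploidy.
#' @param ploidy even integer.
#' @return named probability vector over gamete dosages 0..ploidy/2.
#' @export
gamete_dosage_law <- function(parent_dosage, ploidy = 6L) {
  g <- ploidy %/% 2L
  k <- 0:g
  p <- choose(parent_dosage, k) * choose(ploidy - parent_dosage, g - k) /
    choose(ploidy, g)
  setNames(p, k)
}

#' Simulate an F1 offspring dosage matrix
#'
#' Each offspring receives one gamete from each parent; its dosage at a
#' probe is the sum of the two gamete dosages.
#'
#' @param parents a \code{parental_genome}.
#' @param map linkage map (defaults to the one stored in \code{parents}).
#' @param n_offspring population size (default 228).
#' @param seed integer seed.
#' @return integer probes x n_offspring dosage matrix in [0, ploidy],
#'   with sample ids \code{F1_001}, ... as column names.
#' @export
simulate_offspring <- function(parents, map = parents$map,
                               n_offspring = 228L, seed = NULL) {
  if (n_offspring <= 0) stop("n_offspring must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_probes <- nrow(map)
  out <- matrix(0L, n_probes, n_offspring)
  for (i in seq_len(n_offspring)) {
    out[, i] <- as.integer(
      rowSums(simulate_gamete(parents$P1, map)) +
        rowSums(simulate_gamete(parents$P2, map)))
  }
  dimnames(out) <- list(map$probe_id,
                        sprintf("F1_%03d", seq_len(n_offspring)))
  out
}
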