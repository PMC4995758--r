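#' Build a synthetic linkage map with array-probe structure
#'
#' Generates the marker scaffold the simulator and the reporting tools
#' work on: SNPs placed uniformly at random on equally long chromosomes,
#' each SNP interrogated by up to two array probes (forward and reverse
#' strand, sharing the SNP's position and genotype), and consecutive SNPs
#' grouped into assembly contigs of at most \code{max_snps_per_contig}
#' SNPs.
#'
#' When \code{n_probes} is odd the last SNP receives a single probe, so
#' exact probe counts (e.g. 55,825) are representable.
#'
#' @param n_probes total number of probes.
#' @param n_chromosomes number of chromosomes (default 18).
#' @param chrom_length_cM chromosome length in centiMorgan (default 100).
#' @param probes_per_snp probes interrogating each SNP (default 2).
#' @param max_snps_per_contig upper bound on distinct SNPs per contig
#'   (default 3); contig sizes are drawn uniformly from 1..max.
#' @param seed integer seed for reproducibility.
#' @return A \code{data.frame} of class \code{linkage_map} with columns
#'   \code{probe_id}, \code{chrom}, \code{pos_cM}, \code{snp_id},
#'   \code{contig_id}, sorted by chromosome then position.
#' @export
make_linkage_map <- function(n_probes,
                             n_chromosomes = 18L,
                             chrom_length_cM = 100,
                             probes_per_snp = 2L,
                             max_snps_per_contig = 3L,
                             seed = NULL) {
  stopifnot(n_probes >= 1, n_chromosomes >= 1, chrom_length_cM > 0,
            probes_per_snp >= 1, max_snps_per_contig >= 1)
  if (!is.null(seed)) set.seed(seed)

  n_snps <- ceiling(n_probes / probes_per_snp)
  chrom <- sort(sample.int(n_chromosomes, n_snps, replace = TRUE))
  pos <- runif(n_snps, 0, chrom_length_cM)
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  snp_id <- sprintf("snp%06d", seq_len(n_snps))

  # contigs: runs of 1..max consecutive SNPs, never spanning chromosomes
  contig_of <- integer(n_snps)
  cid <- 0L; i <- 1L
  while (i <= n_snps) {
    cid <- cid + 1L
    size <- sample.int(max_snps_per_contig, 1L)
    j <- min(i + size - 1L, n_snps)
    # truncate run at a chromosome boundary
    j <- i + sum(chrom[i:j] == chrom[i]) - 1L
    contig_of[i:j] <- cid
    i <- j + 1L
  }
  contig_id <- sprintf("contig%06d", contig_of)

  # expand SNPs to probes; last SNP may carry fewer probes
  reps <- rep(probes_per_snp, n_snps)
  excess <- sum(reps) - n_probes
  if (excess > 0) reps[n_snps] <- reps[n_snps] - excess
  idx <- rep(seq_len(n_snps), reps)
  strand <- unlist(lapply(reps, seq_len), use.names = FALSE)
  map <- data.frame(
    probe_id = sprintf("%s_p%d", snp_id[idx], strand),
    chrom = chrom[idx],
    pos_cM = pos[idx],
    snp_id = snp_id[idx],
    contig_id = contig_id[idx],
    stringsAsFactors = FALSE
  )
  class(map) <- c("linkage_map", "data.frame")
  validate_linkage_map(map)
  map
}

#' Validate the structural invariants of a linkage map
#'
#' Checks non-negative, within-chromosome sorted positions, a single
#' chromosome per probe, and at most three distinct SNPs per contig.
#'
#' @param map a \code{linkage_map} data frame.
#' @param max_snps_per_contig contig-size bound to enforce (default 3).
#' @return \code{map}, invisibly; errors on violation.
#' @export
validate_linkage_map <- function(map, max_snps_per_contig = 3L) {
  need <- c("probe_id", "chrom", "pos_cM", "snp_id", "contig_id")
  if (!all(need %in% names(map)))
    stop("map must have columns: ", paste(need, collapse = ", "))
  if (any(map$pos_cM < 0)) stop("map positions must be non-negative")
  if (anyDuplicated(map$probe_id)) stop("duplicated probe_id in map")
  for (ch in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == ch]
    if (is.unsorted(p)) stop("positions not sorted within chromosome ", ch)
  }
  chrom_per_snp <- tapply(map$chrom, map$snp_id, function(x) length(unique(x)))
  if (any(chrom_per_snp > 1)) stop("a SNP maps to more than one chromosome")
  snps_per_contig <- tapply(map$snp_id, map$contig_id,
                            function(x) length(unique(x)))
  if (any(snps_per_contig > max_snps_per_contig))
    stop("a contig carries more than ", max_snps_per_contig, " SNPs")
  invisible(map)
}
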