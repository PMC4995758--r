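#' Write a simulated study to disk
#'
#' Emits the plain-text file set downstream steps read: \code{A.tsv} and
#' \code{B.tsv} (probes x samples, first column \code{probe_id}),
#' \code{dosages.tsv} (simulation truth), \code{causal_probes.tsv}
#' (\code{probe_id}, \code{pi_j}), \code{map.tsv}, and
#' \code{phenotypes.csv} (either one value per sample or the repeated
#' records).
#'
#' @param sim output of \code{\link{simulate_f1_population}} (optionally
#'   with a \code{records} element).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, file) {
    dt <- data.table::data.table(probe_id = rownames(m))
    dt <- cbind(dt, data.table::as.data.table(m))
    data.table::fwrite(dt, file.path(dir, file), sep = "\t")
  }
  wm(sim$intensities$A, "A.tsv")
  wm(sim$intensities$B, "B.tsv")
  wm(sim$dosages, "dosages.tsv")
  data.table::fwrite(sim$causal, file.path(dir, "causal_probes.tsv"),
                     sep = "\t")
  data.table::fwrite(as.data.frame(sim$map), file.path(dir, "map.tsv"),
                     sep = "\t")
  pheno <- if (!is.null(sim$records)) sim$records else
    data.frame(sample_id = names(sim$phenotypes),
               value = unname(sim$phenotypes))
  data.table::fwrite(pheno, file.path(dir, "phenotypes.csv"))
  invisible(dir)
}

#' Read an intensity matrix pair
#'
#' @param a_file,b_file TSV files as written by
#'   \code{\link{write_simulation}}.
#' @return list with matrices \code{A}, \code{B}.
#' @export
read_intensities <- function(a_file, b_file) {
  rd <- function(f) {
    dt <- data.table::fread(f)
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt[[1]]
    m
  }
  list(A = rd(a_file), B = rd(b_file))
}

#' Read a linkage map TSV
#'
#' @param file path to \code{map.tsv}.
#' @return validated \code{linkage_map} data.frame.
#' @export
read_linkage_map <- function(file) {
  map <- as.data.frame(data.table::fread(file))
  class(map) <- c("linkage_map", "data.frame")
  validate_linkage_map(map)
  map
}

#' Write a linear scan result
#'
#' @param scan a \code{linear_scan}.
#' @param file output TSV path.
#' @export
write_scan <- function(scan, file) {
  data.table::fwrite(as.data.frame(scan), file, sep = "\t")
  invisible(file)
}
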