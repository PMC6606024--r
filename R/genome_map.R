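#' Build a uniform genome map
#'
#' A genome map holds, per chromosome, a physical length in base pairs and a
#' genetic length in Morgans.  Crossovers in [meiosis()] occur at a rate equal
#' to the genetic length, uniformly over the physical length (no
#' interference, sex-averaged map).
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param bp_per_chrom physical length of every chromosome, in bp.
#' @param morgans_per_chrom genetic length of every chromosome, in Morgans.
#'   May be 0, in which case meiosis never recombines on that chromosome.
#' @return A `genome_map`: a data.frame with columns `chrom`, `bp`,
#'   `morgans`, one row per chromosome.
#' @examples
#' make_genome_map(19, 130e6, 0.7)  # mouse-like autosome scaffold, 13.3 M
#' @export
make_genome_map <- function(n_chrom, bp_per_chrom, morgans_per_chrom) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (bp_per_chrom <= 0) stop("bp_per_chrom must be positive")
  if (morgans_per_chrom < 0) stop("morgans_per_chrom must be >= 0")
  map <- data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    bp = rep(as.numeric(bp_per_chrom), n_chrom),
    morgans = rep(as.numeric(morgans_per_chrom), n_chrom),
    stringsAsFactors = FALSE
  )
  class(map) <- c("genome_map", "data.frame")
  map
}

as_genome_map <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "bp", "morgans") %in% names(x)))
  if (anyDuplicated(x$chrom)) stop("chromosome names must be unique")
  if (any(x$bp <= 0)) stop("physical lengths must be positive")
  if (any(x$morgans < 0)) stop("genetic lengths must be >= 0")
  class(x) <- c("genome_map", "data.frame")
  x
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome map: %d chromosomes, %.3g bp, %.3g Morgans total\n",
              nrow(x), sum(x$bp), sum(x$morgans)))
  NextMethod()
}
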