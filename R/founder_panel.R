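#' Simulate a founder haplotype panel
#'
#' Emulates an outbred commercial breeding stock: a small pool of ancestral
#' base haplotypes is drawn with independent alleles per site at a
#' site-specific frequency from a U-shaped spectrum (Beta(1/2, 1/2) truncated
#' at `maf_floor`), and each founder haplotype is then built as a mosaic of
#' those base haplotypes with exponentially distributed block lengths.  Sites
#' monomorphic in the realized panel are dropped, so every retained site
#' segregates.
#'
#' @param map a [make_genome_map()] object.
#' @param n_founders number of diploid founder individuals (two haplotypes
#'   each).
#' @param snp_density expected sites per bp (default 1/4000: one SNP per
#'   4 kbp, the density typical of commercial outbred mouse stocks).
#' @param ancestral_pool number of ancestral base haplotypes (>= 2; default
#'   18, the number of source haplotypes behind a CD-1-like stock).
#' @param block_length mean mosaic block length in bp (default 500 kbp).
#' @param maf_floor lower truncation of the ancestral-pool site frequency
#'   spectrum, in `[0, 0.5)`.
#' @param seed optional integer seed; the panel records it.
#' @return A `founder_panel`: list with `map`, `sites` (per-chromosome
#'   integer positions, 0-based internally), `hap` (per-chromosome matrix of
#'   0/1 alleles, one row per founder haplotype; rows `2i-1`, `2i` belong to
#'   founder `i`), `n_founders`, `ancestral_pool`, `seed`.
#' @export
make_founder_panel <- function(map, n_founders, snp_density = 1 / 4000,
                               ancestral_pool = 18, block_length = 5e5,
                               maf_floor = 0.05, seed = NULL) {
  map <- as_genome_map(map)
  if (ancestral_pool < 2) stop("ancestral_pool must be >= 2")
  if (snp_density <= 0) stop("snp_density must be positive")
  if (maf_floor < 0 || maf_floor >= 0.5) stop("maf_floor must be in [0, 0.5)")
  if (!is.null(seed)) withr::local_seed(seed)

  n_hap <- 2L * n_founders
  sites <- vector("list", nrow(map))
  hap <- vector("list", nrow(map))
  names(sites) <- names(hap) <- map$chrom
  for (c in seq_len(nrow(map))) {
    L <- map$bp[c]
    n_sites <- stats::rpois(1, snp_density * L)
    pos <- sort(stats::runif(n_sites, 0, L))
    pos <- floor(pos)
    pos <- pos[!duplicated(pos)]
    n_sites <- length(pos)
    if (n_sites == 0) {
      sites[[c]] <- numeric(0)
      hap[[c]] <- matrix(0L, n_hap, 0)
      next
    }
    # ancestral pool: U-shaped frequency spectrum, truncated
    f <- truncated_beta_half(n_sites, maf_floor)
    base <- matrix(stats::rbinom(ancestral_pool * n_sites, 1L, rep(f, each = ancestral_pool)),
                   nrow = ancestral_pool, ncol = n_sites)
    # founder haplotypes: mosaics with exponential block lengths
    H <- matrix(0L, n_hap, n_sites)
    for (h in seq_len(n_hap)) {
      bks <- 0
      repeat {
        nxt <- bks[length(bks)] + stats::rexp(1, 1 / block_length)
        if (nxt >= L) break
        bks <- c(bks, nxt)
      }
      src <- sample.int(ancestral_pool, length(bks), replace = TRUE)
      H[h, ] <- base[cbind(src[findInterval(pos, bks)], seq_len(n_sites))]
    }
    keep <- colSums(H) > 0L & colSums(H) < n_hap
    sites[[c]] <- pos[keep]
    hap[[c]] <- H[, keep, drop = FALSE]
  }
  if (sum(lengths(sites)) == 0)
    stop("empty panel: no segregating sites produced (density too low or degenerate pool)")
  structure(list(map = map, sites = sites, hap = hap,
                 n_founders = as.integer(n_founders),
                 ancestral_pool = as.integer(ancestral_pool), seed = seed),
            class = "founder_panel")
}

# Beta(1/2,1/2) truncated to [floor, 1-floor] by inverse-CDF sampling
truncated_beta_half <- function(n, floor_) {
  lo <- stats::pbeta(floor_, 0.5, 0.5)
  hi <- stats::pbeta(1 - floor_, 0.5, 0.5)
  stats::qbeta(stats::runif(n, lo, hi), 0.5, 0.5)
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf(
    "founder panel: %d founders (%d haplotypes), %d segregating sites on %d chromosomes\n",
    x$n_founders, 2 * x$n_founders, sum(lengths(x$sites)), nrow(x$map)))
  invisible(x)
}

#' Pooled alternate-allele frequencies of a founder panel
#'
#' @param panel a [make_founder_panel()] object.
#' @return list per chromosome of frequencies (one per site).
#' @export
panel_frequencies <- function(panel) {
  lapply(panel$hap, function(H) if (ncol(H)) colMeans(H) else numeric(0))
}

#' Mean adjacent-site r-squared of a panel
#'
#' Linkage disequilibrium summary used to characterize founder LD: squared
#' correlation of allele indicators between neighbouring sites, averaged over
#' the panel haplotypes.
#' @param panel a [make_founder_panel()] object.
#' @return mean r^2 over all adjacent site pairs (NA if < 2 sites).
#' @export
adjacent_r2 <- function(panel) {
  vals <- unlist(lapply(panel$hap, function(H) {
    if (ncol(H) < 2) return(numeric(0))
    sapply(seq_len(ncol(H) - 1), function(j) {
      suppressWarnings(stats::cor(H[, j], H[, j + 1]))^2
    })
  }))
  mean(vals, na.rm = TRUE)
}
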