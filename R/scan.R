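#' Polarized two-timepoint allele frequencies
#'
#' Per site, the polarization allele is the minor allele at the first
#' timepoint (ties go to the alternate allele); `q0` and `q_t` are its
#' frequencies at the two timepoints over non-missing chromosomes.  (The
#' delta-z-squared statistic itself is invariant to polarization.)
#'
#' @param g0,g1 genotype matrices (individuals x sites of 0/1/2; same site
#'   set, e.g. from [read_genotypes()] or [seed_snps()]).
#' @param sites data.frame chrom / pos matching the columns.
#' @return data.frame: chrom, pos, q0, q1, n0, n1 (chromosome counts),
#'   `flipped` (TRUE where the reference-panel alternate allele was the
#'   major allele at timepoint 0).
#' @export
polarized_freq <- function(g0, g1, sites) {
  stopifnot(ncol(g0) == ncol(g1), ncol(g0) == nrow(sites))
  n0 <- 2 * colSums(!is.na(g0))
  n1 <- 2 * colSums(!is.na(g1))
  p0 <- colSums(g0, na.rm = TRUE) / n0
  p1 <- colSums(g1, na.rm = TRUE) / n1
  flip <- p0 > 0.5 # minor allele at timepoint 0; tie -> alternate
  data.frame(chrom = sites$chrom, pos = sites$pos,
             q0 = ifelse(flip, 1 - p0, p0),
             q1 = ifelse(flip, 1 - p1, p1),
             n0 = n0, n1 = n1, flipped = flip,
             stringsAsFactors = FALSE)
}

#' Squared shift of variance-stabilized allele frequency
#'
#' `z(q) = 2 * asin(sqrt(q))` maps frequencies to `[0, pi]`; under binomial
#' drift the per-generation variance of `z` is `1/(2 Ne)` independent of
#' the starting frequency.  The statistic `(z(q1) - z(q0))^2` ranges from 0
#' to `pi^2`.
#'
#' @param q0,q1 frequencies in `[0, 1]` (vectorized).
#' @return squared z shift.
#' @examples
#' delta_z2(0, 1)        # pi^2
#' delta_z2(0.25, 0.75)  # pi^2 / 9
#' @export
delta_z2 <- function(q0, q1) {
  (2 * asin(sqrt(q1)) - 2 * asin(sqrt(q0)))^2
}

#' Window a per-site track into adjacent fixed-width windows
#'
#' Windows tile every chromosome from coordinate 0 in 0-based half-open
#' intervals; a site at position exactly `k * window` (1-based `pos = k *
#' window + 1`) belongs to window `k`.  Windows without SNPs carry `NA`
#' (missing), not zero.
#'
#' @param track data.frame with `chrom`, `pos` (1-based) and a `value`
#'   column (default `dz2`).
#' @param window window width in bp (default 10 kbp).
#' @param map optional [make_genome_map()]; when given, windows tile whole
#'   chromosomes, otherwise they stop at the last site.
#' @param value name of the column to average.
#' @return data.frame: chrom, start (0-based), end, mean value, n_snps.
#' @export
window_stats <- function(track, window = 1e4, map = NULL, value = "dz2") {
  stopifnot(value %in% names(track))
  chroms <- if (!is.null(map)) map$chrom else unique(track$chrom)
  out <- lapply(chroms, function(ch) {
    t_c <- track[track$chrom == ch, ]
    max_bp <- if (!is.null(map)) map$bp[map$chrom == ch] else
      if (nrow(t_c)) max(t_c$pos) else 0
    n_win <- max(1L, ceiling(max_bp / window))
    w <- floor((t_c$pos - 1) / window) # 0-based window index
    mean_v <- rep(NA_real_, n_win)
    n_snps <- integer(n_win)
    if (nrow(t_c)) {
      agg_n <- tapply(t_c[[value]], w, length)
      agg_m <- tapply(t_c[[value]], w, mean)
      idx <- as.integer(names(agg_n)) + 1L
      n_snps[idx] <- agg_n
      mean_v[idx] <- agg_m
    }
    data.frame(chrom = ch, start = (seq_len(n_win) - 1) * window,
               end = pmin(seq_len(n_win) * window,
                          if (!is.null(map)) max_bp else seq_len(n_win) * window),
               value = mean_v, n_snps = n_snps, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  names(res)[names(res) == "value"] <- value
  rownames(res) <- NULL
  res
}

#' Per-site and windowed delta-z-squared profile
#'
#' Convenience wrapper: [polarized_freq()] then [delta_z2()], averaged in
#' adjacent windows ([window_stats()]).
#'
#' @inheritParams polarized_freq
#' @inheritParams window_stats
#' @return list with `sites` (per-site track incl. `dz2`) and `windows`.
#' @export
dz2_profile <- function(g0, g1, sites, window = 1e4, map = NULL) {
  fr <- polarized_freq(g0, g1, sites)
  fr$dz2 <- delta_z2(fr$q0, fr$q1)
  list(sites = fr, windows = window_stats(fr, window, map))
}

#' Weir-Cockerham F_ST between two populations
#'
#' Per-site variance-components estimator of Weir & Cockerham (1984) for
#' two alleles and two populations, computed from genotype matrices (the
#' observed heterozygosity enters component c).  The windowed value is the
#' ratio of summed numerator over summed denominator components.  Sites
#' monomorphic across both populations are undefined and excluded from
#' windows.
#'
#' @param gA,gB genotype matrices (individuals x sites, 0/1/2, NA allowed).
#' @param sites data.frame chrom / pos.
#' @param window optional window width; NULL for per-site only.
#' @param map optional genome map for full tiling.
#' @return list with `sites` (chrom, pos, fst, a, d = a+b+c) and, when
#'   `window` is given, `windows` (chrom, start, end, fst, n_snps).
#' @export
fst_weir_cockerham <- function(gA, gB, sites, window = NULL, map = NULL) {
  n1 <- colSums(!is.na(gA))
  n2 <- colSums(!is.na(gB))
  if (any(n1 < 2) || any(n2 < 2)) stop("need >= 2 genotyped samples per population")
  p1 <- colMeans(gA, na.rm = TRUE) / 2
  p2 <- colMeans(gB, na.rm = TRUE) / 2
  h1 <- colMeans(gA == 1L, na.rm = TRUE)
  h2 <- colMeans(gB == 1L, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  d <- a + b + cc
  mono <- pbar == 0 | pbar == 1
  fst <- ifelse(mono | d == 0, NA_real_, a / d)
  per_site <- data.frame(chrom = sites$chrom, pos = sites$pos,
                         fst = fst, a = a, d = d, stringsAsFactors = FALSE)
  if (is.null(window)) return(list(sites = per_site))
  ok <- per_site[!mono, ]
  wa <- window_stats(ok, window, map, value = "a")
  wd <- window_stats(ok, window, map, value = "d")
  # ratio of summed components; means cancel the shared n_snps
  windows <- data.frame(chrom = wa$chrom, start = wa$start, end = wa$end,
                        fst = wa$a / wd$d,
                        n_snps = wa$n_snps, stringsAsFactors = FALSE)
  list(sites = per_site, windows = windows)
}

#' Diversity summaries of a genotype matrix
#'
#' Nucleotide diversity `pi` uses the unbiased per-site estimator
#' `2 n q (1 - q) / (n - 1)` over `n` non-missing chromosomes, averaged per
#' window per bp; heterozygosity is the observed fraction of heterozygous
#' genotypes; `S` counts segregating sites.
#'
#' @param g genotype matrix (individuals x sites, 0/1/2).
#' @param sites data.frame chrom / pos.
#' @param window window width in bp for the per-bp pi track.
#' @param map optional genome map for full tiling.
#' @return list: `pi_windows` (chrom, start, end, pi per bp, n_snps),
#'   `heterozygosity`, `segregating_sites`, `pi_site` (per-site values).
#' @export
diversity <- function(g, sites, window = 1e4, map = NULL) {
  n <- 2 * colSums(!is.na(g))
  q <- colSums(g, na.rm = TRUE) / n
  pi_site <- ifelse(n > 1, 2 * n * q * (1 - q) / (n - 1), NA_real_)
  trk <- data.frame(chrom = sites$chrom, pos = sites$pos, pi = pi_site)
  w <- window_stats(trk, window, map, value = "pi")
  w$pi <- ifelse(is.na(w$pi), 0, w$pi * w$n_snps) / (w$end - w$start)
  list(pi_windows = w[, c("chrom", "start", "end", "pi", "n_snps")],
       heterozygosity = mean(g == 1L, na.rm = TRUE),
       segregating_sites = sum(q > 0 & q < 1),
       pi_site = pi_site)
}

#' Export a windowed track as BED-compatible TSV / BEDGRAPH
#'
#' @param windows data.frame from [window_stats()].
#' @param path output file.
#' @param format "tsv" (chrom, start, end, stat, n_snps, with header) or
#'   "bedgraph" (4 columns, no header, missing windows dropped).
#' @param value stat column name.
#' @export
write_track <- function(windows, path, format = c("tsv", "bedgraph"),
                        value = setdiff(names(windows), c("chrom", "start", "end", "n_snps"))[1]) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(windows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ok <- !is.na(windows[[value]])
    utils::write.table(windows[ok, c("chrom", "start", "end", value)], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
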