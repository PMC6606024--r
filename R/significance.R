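#' Genome-wide maximum of a windowed profile
#'
#' @param windows data.frame from [window_stats()] (value column `dz2` by
#'   default); missing (no-SNP) windows are ignored.
#' @param value value column name.
#' @return the maximum windowed value.
#' @export
genomewide_max <- function(windows, value = "dz2") {
  v <- windows[[value]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all windows are missing")
  max(v)
}

#' Critical value from a null distribution of genome-wide maxima
#'
#' The threshold is the `ceiling(n * (1 - alpha))`-th order statistic of
#' the maxima, so that the empirical exceedance probability is at most
#' `alpha`.
#'
#' @param maxima numeric vector of genome-wide maxima, one per simulated
#'   null replicate (n >= 20).
#' @param alpha significance level (default 0.05, i.e. the 95th quantile).
#' @return the critical value.
#' @examples
#' critical_value(1:100, 0.05)  # 95
#' @export
critical_value <- function(maxima, alpha = 0.05) {
  n <- length(maxima)
  if (n < 20) stop("need >= 20 replicate maxima")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  sort(maxima)[ceiling(n * (1 - alpha))]
}

#' Call sweep peaks with hitchhiking extension
#'
#' Significant windows (windowed value >= `threshold`) are processed in
#' descending rank order; each peak's span grows outward in blocks of
#' `ext_snps` SNPs per side, a side stopping when its latest block contains
#' no single SNP with per-site value above `stop` (the stopping block is
#' still absorbed into the span).  Windows absorbed by a span are removed
#' from the candidate list; overlapping spans are merged.  Cores are the
#' contiguous runs of significant windows.
#'
#' @param windows windowed profile (chrom, start, end, dz2, n_snps).
#' @param track per-site track (chrom, pos, dz2).
#' @param threshold critical windowed value (from [critical_value()]).
#' @param stop per-site stopping level (default `0.2 * pi^2`).
#' @param ext_snps SNPs per extension block and side (default 100).
#' @param value value column name in both inputs.
#' @return data.frame of peaks: rank, chrom, span_start, span_end,
#'   core_start, core_end, peak_start, peak_value (0-based half-open
#'   spans), ordered by peak value.
#' @export
call_peaks <- function(windows, track, threshold, stop = 0.2 * pi^2,
                       ext_snps = 100, value = "dz2") {
  if (threshold < stop) stop("threshold must be >= stopping level")
  sig <- which(!is.na(windows[[value]]) & windows[[value]] >= threshold)
  if (!length(sig)) return(empty_peaks())
  # rank order: descending value, ties by (chrom, start)
  sig <- sig[order(-windows[[value]][sig],
                   as.character(windows$chrom[sig]), windows$start[sig])]
  sig_mask <- !is.na(windows[[value]]) & windows[[value]] >= threshold
  peaks <- list()
  taken <- rep(FALSE, nrow(windows))
  for (w in sig) {
    if (taken[w]) next
    ch <- windows$chrom[w]
    t_c <- track[track$chrom == ch, ]
    ord <- order(t_c$pos)
    pos <- t_c$pos[ord]
    val <- t_c[[value]][ord]
    # contiguous run of significant windows containing the peak window:
    # extension blocks grow outward from the edges of this run
    run <- sig_run(windows, sig_mask, w)
    run_start <- min(windows$start[run])
    run_end <- max(windows$end[run])
    # sites inside the run (1-based pos in 0-based half-open windows)
    in_w <- which(pos - 1 >= run_start & pos - 1 < run_end)
    lo <- if (length(in_w)) min(in_w) else
      max(1L, findInterval(run_start, pos))
    hi <- if (length(in_w)) max(in_w) else lo
    # extend right
    repeat {
      blk <- seq.int(hi + 1L, length.out = ext_snps)
      blk <- blk[blk <= length(pos)]
      if (!length(blk)) break
      hi <- max(blk)
      if (!any(val[blk] > stop)) break
    }
    # extend left
    repeat {
      blk <- seq.int(lo - ext_snps, length.out = ext_snps)
      blk <- blk[blk >= 1L]
      if (!length(blk)) break
      lo <- min(blk)
      if (!any(val[blk] > stop)) break
    }
    span <- c(pos[lo] - 1, pos[hi]) # 0-based half-open, covering the sites
    span[1] <- min(span[1], run_start)
    span[2] <- max(span[2], run_end)
    # absorb windows overlapped by the span
    absorbed <- windows$chrom == ch & windows$start < span[2] &
      windows$end > span[1]
    taken[absorbed] <- TRUE
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = ch, span_start = span[1], span_end = span[2],
      peak_start = windows$start[w], peak_value = windows[[value]][w],
      stringsAsFactors = FALSE)
  }
  pk <- do.call(rbind, peaks)
  pk <- merge_spans(pk)
  # cores: contiguous runs of significant windows within each span
  sig_all <- !is.na(windows[[value]]) & windows[[value]] >= threshold
  pk$core_start <- NA_real_
  pk$core_end <- NA_real_
  for (i in seq_len(nrow(pk))) {
    ws <- which(windows$chrom == pk$chrom[i] & sig_all &
                  windows$start >= pk$span_start[i] &
                  windows$end <= pk$span_end[i])
    # the run containing the peak window
    runs <- split(ws, cumsum(c(1, diff(ws) != 1)))
    run <- runs[[which(vapply(runs, function(r)
      any(windows$start[r] == pk$peak_start[i]), TRUE))[1]]]
    pk$core_start[i] <- min(windows$start[run])
    pk$core_end[i] <- max(windows$end[run])
  }
  pk <- pk[order(-pk$peak_value), ]
  pk$rank <- seq_len(nrow(pk))
  rownames(pk) <- NULL
  pk[, c("rank", "chrom", "span_start", "span_end", "core_start", "core_end",
         "peak_start", "peak_value")]
}

# indices of the maximal run of consecutive significant windows (same
# chromosome, adjacent tiling positions) containing window w
sig_run <- function(windows, sig_mask, w) {
  idx <- which(windows$chrom == windows$chrom[w])
  idx <- idx[order(windows$start[idx])]
  k <- match(w, idx)
  run <- k
  j <- k
  while (j > 1 && sig_mask[idx[j - 1]] &&
         windows$end[idx[j - 1]] == windows$start[idx[j]]) {
    j <- j - 1
    run <- c(j, run)
  }
  j <- k
  while (j < length(idx) && sig_mask[idx[j + 1]] &&
         windows$start[idx[j + 1]] == windows$end[idx[j]]) {
    j <- j + 1
    run <- c(run, j)
  }
  idx[run]
}

empty_peaks <- function() {
  data.frame(rank = integer(0), chrom = character(0),
             span_start = numeric(0), span_end = numeric(0),
             core_start = numeric(0), core_end = numeric(0),
             peak_start = numeric(0), peak_value = numeric(0),
             stringsAsFactors = FALSE)
}

# merge overlapping/adjacent spans, keeping the strongest peak of each group
merge_spans <- function(pk) {
  pk <- pk[order(pk$chrom, pk$span_start), ]
  out <- list()
  cur <- pk[1, ]
  for (i in seq_len(nrow(pk))[-1]) {
    row <- pk[i, ]
    if (row$chrom == cur$chrom && row$span_start <= cur$span_end) {
      cur$span_end <- max(cur$span_end, row$span_end)
      if (row$peak_value > cur$peak_value) {
        cur$peak_value <- row$peak_value
        cur$peak_start <- row$peak_start
      }
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

#' Parallelism of significant windows between two lines
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the 2x2
#' window classification both / A only / B only / neither.
#'
#' @param sig_a,sig_b logical vectors over the same windows, or window
#'   counts if `total` is given as counts.
#' @param total total number of windows (only when passing counts
#'   `c(both, a_only, b_only)`).
#' @return list: `chisq`, `p`, `table`, and `warning` if an expected cell
#'   is below 1.
#' @export
parallelism_chisq <- function(sig_a, sig_b, total = NULL) {
  if (is.logical(sig_a)) {
    both <- sum(sig_a & sig_b)
    a_only <- sum(sig_a & !sig_b)
    b_only <- sum(!sig_a & sig_b)
    neither <- sum(!sig_a & !sig_b)
  } else {
    both <- sig_a[1]; a_only <- sig_a[2]; b_only <- sig_a[3]
    neither <- total - both - a_only - b_only
  }
  O <- c(both, a_only, b_only, neither)
  N <- sum(O)
  rA <- (both + a_only) / N
  rB <- (both + b_only) / N
  E <- N * c(rA * rB, rA * (1 - rB), (1 - rA) * rB, (1 - rA) * (1 - rB))
  # empty margins make cells degenerate (O = E = 0): they contribute 0
  chisq <- sum(ifelse(E > 0, (O - E)^2 / E, 0))
  warn <- if (any(E < 1)) "expected cell below 1" else NULL
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       table = matrix(O, 2, dimnames = list(c("B", "notB"), c("A", "notA"))),
       expected = E, warning = warn)
}

#' Pearson correlation between two windowed profiles
#'
#' @param wa,wb windowed profiles over the same tiling (value column
#'   `dz2`); only windows non-missing in both are used (>= 10 required).
#' @param value value column name.
#' @return list: `r`, `n_windows`.
#' @export
profile_correlation <- function(wa, wb, value = "dz2") {
  ok <- !is.na(wa[[value]]) & !is.na(wb[[value]])
  if (sum(ok) < 10) stop("need >= 10 shared non-missing windows")
  x <- wa[[value]][ok]
  y <- wb[[value]][ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in a profile; correlation undefined")
  list(r = stats::cor(x, y), n_windows = sum(ok))
}

#' Interval permutation test (feature overlap / nearest distance)
#'
#' Places the query spans uniformly at random on the genome, without
#' overlap among themselves, `n` times; the statistic is the number of
#' features hit (`overlap` mode, upper tail) or the mean distance to the
#' nearest feature (`nearest_distance` mode, lower tail).  The p-value is
#' the quantile rank of the observed statistic among the permuted ones; an
#' observed statistic more extreme than every permutation is reported as
#' `1/(n + 1)` with `less_than = TRUE`.
#'
#' @param query data.frame chrom / start / end (0-based half-open spans).
#' @param features data.frame chrom / start / end.
#' @param map a [make_genome_map()] object (the permutation universe).
#' @param n number of permutations (default 1000).
#' @param mode "overlap" or "nearest_distance".
#' @param seed optional integer seed.
#' @param max_retry placement retries per permutation.
#' @return list: `p`, `observed`, `permuted`, `mode`, `less_than`.
#' @export
interval_permutation <- function(query, features, map, n = 1000,
                                 mode = c("overlap", "nearest_distance"),
                                 seed = NULL, max_retry = 1000) {
  mode <- match.arg(mode)
  if (!nrow(features)) stop("features must be non-empty")
  if (!is.null(seed)) withr::local_seed(seed)
  # shared seqlevels (the map) so placements on feature-free chromosomes
  # compare cleanly
  feat <- GenomicRanges::GRanges(factor(features$chrom, levels = map$chrom),
                                 IRanges::IRanges(features$start + 1, features$end))
  stat <- function(q) {
    gr <- GenomicRanges::GRanges(factor(q$chrom, levels = map$chrom),
                                 IRanges::IRanges(q$start + 1, q$end))
    if (mode == "overlap") {
      length(unique(S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(gr, feat))))
    } else {
      d <- GenomicRanges::distanceToNearest(gr, feat)
      mean(S4Vectors::mcols(d)$distance)
    }
  }
  obs <- stat(query)
  widths <- query$end - query$start
  if (any(widths > max(map$bp))) stop("query span longer than every chromosome")
  perm <- vapply(seq_len(n), function(i) {
    stat(place_random(widths, map, max_retry))
  }, 0)
  p <- if (mode == "overlap") mean(perm >= obs) else mean(perm <= obs)
  less <- p == 0
  if (less) p <- 1 / (n + 1)
  list(p = p, observed = obs, permuted = perm, mode = mode, less_than = less)
}

# uniform placement of spans on the genome without mutual overlap
place_random <- function(widths, map, max_retry) {
  placed <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  for (w in widths) {
    ok_chrom <- which(map$bp >= w)
    for (r in seq_len(max_retry)) {
      c <- ok_chrom[sample.int(length(ok_chrom), 1,
                               prob = map$bp[ok_chrom] - w + 1)]
      s <- floor(stats::runif(1, 0, map$bp[c] - w + 1))
      hit <- placed$chrom == map$chrom[c] & placed$start < s + w & placed$end > s
      if (!any(hit)) {
        placed <- rbind(placed, data.frame(chrom = map$chrom[c], start = s,
                                           end = s + w))
        break
      }
      if (r == max_retry) stop("could not place spans without overlap")
    }
  }
  placed
}
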