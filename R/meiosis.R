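#' Junction-genome construction and meiosis (reference engine)
#'
#' A diploid genome is a list with one element per chromosome; each
#' chromosome is `list(p1, l1, p2, l2)`: breakpoint positions (bp, starting
#' at 0, strictly increasing) and founder-haplotype labels for the two
#' homologs.  Segment `j` covers `[p[j], p[j+1])` (the last one runs to the
#' chromosome end); adjacent segments always carry distinct labels.
#'
#' `founder_genome()` builds the trivial single-segment genome of founder
#' `i`, whose two homologs carry labels `2i - 1` and `2i`.
#'
#' @param i founder index (1-based).
#' @param map a [make_genome_map()] object.
#' @return a junction genome.
#' @export
founder_genome <- function(i, map) {
  lapply(seq_len(nrow(map)), function(c) {
    list(p1 = 0, l1 = 2L * i - 1L, p2 = 0, l2 = 2L * i)
  })
}

#' Meiosis on a junction genome
#'
#' Per chromosome the crossover count is Poisson with mean equal to the
#' genetic length in Morgans; crossover positions are i.i.d. uniform on the
#' physical length (no interference).  The gamete alternates between the two
#' parental homologs at crossovers, starting from a fair-coin homolog.
#'
#' This is the pure-R reference implementation; [run_experiment()] uses a
#' compiled equivalent consuming the identical RNG stream, and the two are
#' tested for exact agreement.
#'
#' @param parent a junction genome.
#' @param map a [make_genome_map()] object.
#' @param record set TRUE to attach the crossover realization (positions and
#'   starting homolog) per chromosome, for site-by-site oracle checks.
#' @return a haploid gamete: list per chromosome of `list(pos, lab)` (and
#'   `xo`, `start` when `record = TRUE`).
#' @export
meiosis <- function(parent, map, record = FALSE) {
  lapply(seq_len(nrow(map)), function(c) {
    chr <- parent[[c]]
    L <- map$bp[c]
    k <- stats::rpois(1, map$morgans[c])
    xs <- sort(stats::runif(k, 0, L))
    start <- if (stats::runif(1) < 0.5) 1L else 2L
    g <- splice_homologs(chr, xs, start, L)
    if (record) {
      g$xo <- xs
      g$start <- start
    }
    g
  })
}

# deterministic part of meiosis: splice the two homologs at crossovers xs,
# beginning on homolog `start`
splice_homologs <- function(chr, xs, start, L) {
  bounds <- c(0, xs, L)
  pos <- numeric(0)
  lab <- integer(0)
  cur <- start
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]
    b <- bounds[i + 1L]
    if (b > a) {
      hp <- if (cur == 1L) chr$p1 else chr$p2
      hl <- if (cur == 1L) chr$l1 else chr$l2
      j <- findInterval(a, hp)
      while (j <= length(hp) && hp[j] < b) {
        s <- max(hp[j], a)
        if (length(lab) && lab[length(lab)] == hl[j]) {
          # merge with previous equal-label segment
        } else {
          pos <- c(pos, s)
          lab <- c(lab, hl[j])
        }
        j <- j + 1L
      }
    }
    cur <- 3L - cur
  }
  list(pos = pos, lab = lab)
}

# R-engine analogue of cpp_make_offspring.  Matches the compiled engine's
# RNG draw order exactly: per offspring, chromosome by chromosome, sire
# gamete then dam gamete.
r_make_offspring <- function(pop, sire, dam, map, record = FALSE) {
  lapply(seq_along(sire), function(i) {
    ind <- vector("list", nrow(map))
    for (c in seq_len(nrow(map))) {
      m1 <- map[c, , drop = FALSE]
      class(m1) <- c("genome_map", "data.frame")
      gs <- meiosis(pop[[sire[i]]][c], m1, record)[[1]]
      gd <- meiosis(pop[[dam[i]]][c], m1, record)[[1]]
      ind[[c]] <- list(p1 = gs$pos, l1 = gs$lab, p2 = gd$pos, l2 = gd$lab)
      if (record) {
        ind[[c]]$xo1 <- gs$xo; ind[[c]]$start1 <- gs$start
        ind[[c]]$xo2 <- gd$xo; ind[[c]]$start2 <- gd$start
      }
    }
    ind
  })
}

#' Founder-haplotype labels of a homolog at given positions
#'
#' @param pos,lab homolog breakpoint vectors.
#' @param at positions (bp) to query.
#' @return integer labels.
#' @export
labels_at <- function(pos, lab, at) lab[findInterval(at, pos)]
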