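#' Define a trait model
#'
#' The trait is the sum of three components: an infinitesimal polygenic
#' background with variance `V_g`, realized as a dense grid of loci with
#' i.i.d. Gaussian founder-haplotype effects; a discrete component of
#' `n_discrete_loci` evenly spaced loci with total variance `V_s`; and a
#' Gaussian non-genetic component with variance `V_e`.  Each genetic
#' component's per-chromosome variance share is proportional to the
#' chromosome's genetic map length.
#'
#' Defaults give heritability h^2 = 0.4 (V_g = V_s = 0.2, V_e = 0.6, total
#' phenotypic variance 1), split 1:1 between background and discrete
#' components.
#'
#' @param V_g infinitesimal-background variance.
#' @param V_s discrete-locus component variance.
#' @param V_e environmental variance.
#' @param n_discrete_loci discrete loci genome-wide (default 1e4), allocated
#'   to chromosomes proportionally to map length, remainder to the longest.
#' @param grid_per_morgan density of the infinitesimal grid (default 1000
#'   loci per Morgan, i.e. 10 per cM).
#' @param phi composite-trait exponent (see [composite_trait()]).
#' @return a `trait_model` list.
#' @export
trait_model <- function(V_g = 0.2, V_s = 0.2, V_e = 0.6,
                        n_discrete_loci = 1e4, grid_per_morgan = 1000,
                        phi = -0.57) {
  stopifnot(V_g >= 0, V_s >= 0, V_e >= 0, V_g + V_s + V_e > 0)
  structure(list(V_g = V_g, V_s = V_s, V_e = V_e,
                 n_discrete_loci = as.integer(n_discrete_loci),
                 grid_per_morgan = grid_per_morgan, phi = phi),
            class = "trait_model")
}

#' Heritability of a trait model
#' @param model a [trait_model()].
#' @export
heritability <- function(model) {
  with(model, (V_g + V_s) / (V_g + V_s + V_e))
}

# Evenly spaced positions for n loci on a chromosome of length L bp
even_positions <- function(n, L) if (n == 0) numeric(0) else (seq_len(n) - 0.5) / n * L

# Allocate n loci to chromosomes proportional to genetic length, remainder
# to the longest chromosomes (ties broken by order).
allocate_loci <- function(n, morgans) {
  if (sum(morgans) == 0) return(rep(0L, length(morgans)))
  raw <- n * morgans / sum(morgans)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(morgans, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Draw founder-haplotype effect tables
#'
#' Assigns i.i.d. Gaussian effects to every founder haplotype label at every
#' grid locus, for both genetic components, scaled so that the
#' founder-population variance of breeding values equals `V_g + V_s` and
#' each chromosome's share is proportional to its map length.  (Founders
#' carry two unique labels each, so the founder breeding-value variance per
#' component and chromosome is `2 * L_c * sigma_c^2`.)
#'
#' Effects are stored as per-label cumulative sums over loci so that the
#' contribution of a genome segment is a difference of two table entries.
#'
#' @param model a [trait_model()].
#' @param map a [make_genome_map()] object.
#' @param n_labels number of founder haplotype labels (2 per founder).
#' @param seed optional integer seed.
#' @return an `effect_tables` list: `vg` and `vs`, each a per-chromosome
#'   list of `gpos` (locus positions) and `cum` (`n_labels x (L+1)`
#'   cumulative effect matrix).
#' @export
make_effects <- function(model, map, n_labels, seed = NULL) {
  map <- as_genome_map(map)
  if (!is.null(seed)) withr::local_seed(seed)
  total_m <- sum(map$morgans)
  build <- function(V_total, n_per_chrom) {
    lapply(seq_len(nrow(map)), function(c) {
      L <- n_per_chrom[c]
      if (L == 0 || V_total == 0 || total_m == 0)
        return(list(gpos = numeric(0), cum = matrix(0, n_labels, 1)))
      V_c <- V_total * map$morgans[c] / total_m
      sigma <- sqrt(V_c / (2 * L))
      eff <- matrix(stats::rnorm(n_labels * L, 0, sigma), n_labels, L)
      cum <- cbind(0, t(apply(eff, 1, cumsum)))
      list(gpos = even_positions(L, map$bp[c]), cum = cum)
    })
  }
  n_vg <- as.integer(round(map$morgans * model$grid_per_morgan))
  n_vs <- allocate_loci(model$n_discrete_loci, map$morgans)
  structure(list(vg = build(model$V_g, n_vg), vs = build(model$V_s, n_vs),
                 n_labels = as.integer(n_labels), seed = seed),
            class = "effect_tables")
}

# rescale effect tables so genetic variance drops to a fraction rho (used
# when a major locus takes over part of the initial genetic variance)
scale_effects <- function(effects, rho) {
  sc <- sqrt(rho)
  for (comp in c("vg", "vs")) {
    effects[[comp]] <- lapply(effects[[comp]], function(g) {
      g$cum <- g$cum * sc
      g
    })
  }
  effects
}

#' Breeding value and phenotype of junction genomes
#'
#' The breeding value is the sum, over both homologs, of the effects at grid
#' loci covered by each founder segment; the phenotype adds a
#' `Normal(0, V_e)` draw.
#'
#' @param genomes a list of junction genomes (or a single genome).
#' @param effects an [make_effects()] table.
#' @param model a [trait_model()].
#' @param map a [make_genome_map()] object.
#' @param engine "cpp" (compiled) or "r" (reference).
#' @return data.frame with columns `bv`, `phenotype`.
#' @export
trait_value <- function(genomes, effects, model, map, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!is.null(genomes$p1) || (length(genomes) && !is.null(genomes[[1]]$p1)))
    genomes <- list(genomes) # single genome
  check_labels(genomes, effects$n_labels)
  bv <- breeding_values(genomes, effects, map, engine)
  data.frame(bv = bv,
             phenotype = bv + stats::rnorm(length(bv), 0, sqrt(model$V_e)))
}

check_labels <- function(genomes, n_labels) {
  mx <- max(vapply(genomes, function(g)
    max(vapply(g, function(chr) max(chr$l1, chr$l2), 0)), 0))
  if (mx > n_labels)
    stop("effect table missing founder labels present in the genome")
}

breeding_values <- function(genomes, effects, map, engine = "cpp") {
  if (engine == "cpp") {
    cpp_breeding_values(genomes, list(effects$vg, effects$vs), map$bp)
  } else {
    vapply(genomes, function(g) {
      r_bv_one(g, effects$vg, map) + r_bv_one(g, effects$vs, map)
    }, 0)
  }
}

# reference R implementation of the segment-sum breeding value
r_bv_one <- function(genome, grids, map) {
  v <- 0
  for (c in seq_len(nrow(map))) {
    gr <- grids[[c]]
    if (!length(gr$gpos)) next
    for (h in c("1", "2")) {
      pos <- genome[[c]][[paste0("p", h)]]
      lab <- genome[[c]][[paste0("l", h)]]
      ends <- c(pos[-1], map$bp[c])
      for (j in seq_along(pos)) {
        i1 <- findInterval(pos[j], gr$gpos, left.open = TRUE) + 1L
        i2 <- findInterval(ends[j], gr$gpos, left.open = TRUE)
        # loci i1..i2 have gpos in [pos[j], ends[j])
        if (i2 >= i1) v <- v + gr$cum[lab[j], i2 + 1L] - gr$cum[lab[j], i1]
      }
    }
  }
  v
}

#' Composite fitness trait from tibia length and body mass
#'
#' Selection score `ln(T) + phi * ln(B)`: monotone increasing in tibia
#' length `T` and, for `phi < 0`, decreasing in body mass `B`.
#'
#' @param T tibia length (> 0, arbitrary units).
#' @param B body mass (> 0, arbitrary units).
#' @param phi composite exponent (dimensionless).
#' @return numeric score(s).
#' @examples
#' composite_trait(2, 1, -0.57)  # log(2)
#' @export
composite_trait <- function(T, B, phi) {
  if (any(T <= 0) || any(B <= 0)) stop("T and B must be positive")
  log(T) + phi * log(B)
}

#' Estimate the composite-trait exponent from realized breeder choices
#'
#' Grid search over `phi` maximizing the fraction of actually chosen
#' breeders that are recovered by ranking candidates on
#' [composite_trait()] within each family-by-sex group.  Ties in the
#' concordance are broken toward the `phi` closest to 0.
#'
#' @param candidates data.frame with columns `family`, `sex`, `T`, `B`,
#'   `chosen` (logical; exactly one chosen per family-sex group).
#' @param grid candidate `phi` values (default -2..0 step 0.01).
#' @return list with `phi`, `concordance`, and the full `curve`
#'   (data.frame phi/concordance).
#' @export
estimate_phi <- function(candidates, grid = seq(-2, 0, by = 0.01)) {
  stopifnot(all(c("family", "sex", "T", "B", "chosen") %in% names(candidates)))
  groups <- split(seq_len(nrow(candidates)),
                  interaction(candidates$family, candidates$sex, drop = TRUE))
  if (any(lengths(groups) < 2))
    stop("need at least 2 candidates per family-sex group")
  conc <- vapply(grid, function(phi) {
    score <- composite_trait(candidates$T, candidates$B, phi)
    hit <- vapply(groups, function(idx) {
      top <- idx[which.max(score[idx])]
      isTRUE(candidates$chosen[top])
    }, TRUE)
    mean(hit)
  }, 0)
  best <- which(conc == max(conc))
  pick <- best[which.min(abs(grid[best]))] # tie: closest to 0
  list(phi = grid[pick], concordance = conc[pick],
       curve = data.frame(phi = grid, concordance = conc))
}
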