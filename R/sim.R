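#' Run an artificial-selection experiment down a pedigree
#'
#' Gene-drops junction genomes down the pedigree generated by
#' [make_pedigree()]: founders get their own haplotype labels, every
#' offspring genome is one [meiosis()] gamete from its sire plus one from
#' its dam, and in each generation the breeding male and female of every
#' family are chosen by the selection rule -- under `"truncation"` the
#' largest-phenotype male and female (ties to the lowest id), under
#' `"random"` (control lines) a uniform draw.  Selected breeders are paired
#' with a circular family shift, so sibling matings never occur.
#'
#' Per generation the realized selection differential `S` (phenotypic
#' superiority of selected parents) and response `R` (shift of the cohort
#' mean), both in units of the model phenotypic standard deviation, and the
#' mean inbreeding coefficient `F` (fraction of genome identical by descent
#' from the founder generation) are recorded.
#'
#' @param pedigree a [make_pedigree()] object.
#' @param map a [make_genome_map()] object.
#' @param model a [trait_model()].
#' @param selection `"truncation"` or `"random"`.
#' @param panel optional [make_founder_panel()]; if given, its founder count
#'   must equal the pedigree founder count (labels then index panel
#'   haplotypes, used by [seed_snps()]).
#' @param effects optional precomputed [make_effects()] table; drawn
#'   internally otherwise.
#' @param major_locus optional `list(chrom, pos, a, q0)`: one biallelic
#'   locus with additive effect `a` (phenotypic s.d. per copy of the focal
#'   allele) at the stated position, starting at frequency `q0` among
#'   founder haplotypes; `V_g + V_s` are rescaled so the total initial
#'   genetic variance is unchanged.  Its frequency trajectory is recorded
#'   per generation.
#' @param seed optional integer seed (all randomness flows from it).
#' @param engine `"cpp"` (compiled fast path) or `"r"` (pure-R reference;
#'   identical RNG stream, required for `record_xo`).
#' @param keep_generations generations whose genomes are retained (default
#'   founders and the last generation).
#' @param compute_F compute the per-generation inbreeding series (switch
#'   off to save time in large replicate sweeps).
#' @param record_xo record crossover realizations (R engine only), for
#'   site-by-site oracle reconstruction.
#' @return A `sim_result`: list with `pedigree` (realized: sire/dam ids,
#'   `bv`, `phenotype`, `selected`), `stats` (per-generation mean
#'   phenotype, S, R, F), `genomes` (named by kept generation: `ids`,
#'   `genomes`), `trajectory` (major-locus frequency per generation, or
#'   NULL), plus `map`, `model`, `n_labels`, `seed`.
#' @export
run_experiment <- function(pedigree, map, model, selection = c("truncation", "random"),
                           panel = NULL, effects = NULL, major_locus = NULL,
                           seed = NULL, engine = c("cpp", "r"),
                           keep_generations = NULL, compute_F = TRUE,
                           record_xo = FALSE) {
  selection <- match.arg(selection)
  engine <- match.arg(engine)
  map <- as_genome_map(map)
  if (record_xo && engine != "r") stop("record_xo requires engine = 'r'")
  if (!is.null(seed)) withr::local_seed(seed)

  n_pairs <- attr(pedigree, "n_pairs")
  founders <- pedigree[pedigree$generation == 0L, ]
  n_founders <- nrow(founders)
  if (!is.null(panel) && panel$n_founders != n_founders)
    stop("pedigree generation 0 size must equal panel founder count")
  n_labels <- 2L * n_founders
  sigma_p <- sqrt(model$V_g + model$V_s + model$V_e)

  locus <- NULL
  if (!is.null(major_locus)) {
    locus <- init_major_locus(major_locus, model, n_labels)
    model <- locus$model
  }
  if (is.null(effects)) effects <- make_effects(model, map, n_labels)
  if (!is.null(locus) && locus$rho < 1) effects <- scale_effects(effects, locus$rho)

  max_gen <- max(pedigree$generation)
  if (is.null(keep_generations)) keep_generations <- c(0L, max_gen)

  ped <- as.data.frame(pedigree)
  ped$sire <- NA_integer_
  ped$dam <- NA_integer_
  ped$bv <- NA_real_
  ped$phenotype <- NA_real_
  ped$selected <- FALSE

  # founders
  pop <- lapply(seq_len(n_founders), founder_genome, map = map)
  pop_ids <- founders$id
  tv <- breeding_values(pop, effects, map, engine)
  if (!is.null(locus)) tv <- tv + locus$a * locus_copies(pop, locus)
  phen <- tv + stats::rnorm(n_founders, 0, sqrt(model$V_e))
  i0 <- match(pop_ids, ped$id)
  ped$bv[i0] <- tv
  ped$phenotype[i0] <- phen
  ped$selected[i0] <- TRUE # all founders breed

  stats_df <- data.frame(generation = 0:max_gen, mean_phenotype = NA_real_,
                         S = NA_real_, R = NA_real_, F = NA_real_)
  stats_df$mean_phenotype[1] <- mean(phen)
  stats_df$F[1] <- 0
  traj <- if (!is.null(locus)) rep(NA_real_, max_gen + 1L) else NULL
  if (!is.null(locus)) traj[1] <- mean(locus_copies(pop, locus)) / 2

  kept <- list()
  if (0L %in% keep_generations)
    kept[["0"]] <- list(ids = pop_ids, genomes = pop)

  # founder "selection": one breeding pair per family by construction
  sel_m <- founders$id[founders$sex == "M"][order(founders$family[founders$sex == "M"])]
  sel_f <- founders$id[founders$sex == "F"][order(founders$family[founders$sex == "F"])]

  for (g in seq_len(max_gen)) {
    cohort <- ped[ped$generation == g, ]
    # family f is bred by the selected male of family f and the selected
    # female of a random other family (a fresh derangement per generation:
    # random re-pairing excluding sibling pairs, as in the real design --
    # fixed pairing schemes such as a circular shift create ring-like local
    # relatedness and inflate inbreeding)
    fam_shift <- derangement(n_pairs)
    sire_id <- sel_m[cohort$family]
    dam_id <- sel_f[fam_shift[cohort$family]]
    sire_idx <- match(sire_id, pop_ids)
    dam_idx <- match(dam_id, pop_ids)

    off <- if (engine == "cpp") {
      cpp_make_offspring(pop, sire_idx, dam_idx, map$bp, map$morgans)
    } else {
      r_make_offspring(pop, sire_idx, dam_idx, map, record = record_xo)
    }
    bv <- breeding_values(off, effects, map, engine)
    if (!is.null(locus)) bv <- bv + locus$a * locus_copies(off, locus)
    phen <- bv + stats::rnorm(length(bv), 0, sqrt(model$V_e))

    i <- match(cohort$id, ped$id)
    ped$sire[i] <- sire_id
    ped$dam[i] <- dam_id
    ped$bv[i] <- bv
    ped$phenotype[i] <- phen

    stats_df$mean_phenotype[g + 1L] <- mean(phen)
    stats_df$R[g + 1L] <- (mean(phen) - stats_df$mean_phenotype[g]) / sigma_p
    if (compute_F) stats_df$F[g + 1L] <- mean(cpp_ibd_fraction(off, map$bp))
    if (!is.null(locus)) traj[g + 1L] <- mean(locus_copies(off, locus)) / 2

    # choose next breeders per family
    sel <- select_breeders(cohort, phen, selection)
    ped$selected[match(sel$ids, ped$id)] <- TRUE
    stats_df$S[g + 1L] <- (mean(phen[match(sel$ids, cohort$id)]) - mean(phen)) / sigma_p
    sel_m <- sel$male
    sel_f <- sel$female

    pop <- off
    pop_ids <- cohort$id
    if (g %in% keep_generations)
      kept[[as.character(g)]] <- list(ids = pop_ids, genomes = pop)
  }

  structure(list(pedigree = ped, stats = stats_df, genomes = kept,
                 trajectory = traj, map = map, model = model,
                 n_labels = n_labels, selection = selection,
                 major_locus = if (is.null(locus)) NULL else locus[c("chrom", "pos", "a", "q0", "alleles")],
                 seed = seed),
            class = "sim_result")
}

# random permutation of 1..n with no fixed point (no sibling matings)
derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

# pick the breeding male and female of each family: max phenotype under
# truncation (ties to lowest id), uniform under random
select_breeders <- function(cohort, phen, selection) {
  fams <- sort(unique(cohort$family))
  male <- integer(length(fams))
  female <- integer(length(fams))
  for (f in fams) {
    for (s in c("M", "F")) {
      idx <- which(cohort$family == f & cohort$sex == s)
      if (!length(idx)) stop("family without both sexes")
      pick <- if (selection == "truncation") {
        cand <- idx[phen[idx] == max(phen[idx])]
        cand[which.min(cohort$id[cand])]
      } else {
        idx[sample.int(length(idx), 1)]
      }
      if (s == "M") male[f] <- cohort$id[pick] else female[f] <- cohort$id[pick]
    }
  }
  list(male = male, female = female, ids = c(male, female))
}

init_major_locus <- function(ml, model, n_labels) {
  stopifnot(!is.null(ml$chrom), !is.null(ml$pos), !is.null(ml$a), !is.null(ml$q0))
  if (ml$q0 <= 0 || ml$q0 >= 1) stop("q0 must be in (0,1)")
  V_locus <- 2 * ml$q0 * (1 - ml$q0) * ml$a^2
  V_gen <- model$V_g + model$V_s
  if (ml$a != 0 && V_locus >= V_gen)
    stop("|a| too large: infinitesimal variance rescaling would be negative")
  rho <- if (V_gen > 0) (V_gen - V_locus) / V_gen else 1
  n_alt <- round(ml$q0 * n_labels)
  alleles <- integer(n_labels)
  alleles[sample.int(n_labels, n_alt)] <- 1L
  list(chrom = ml$chrom, pos = ml$pos, a = ml$a, q0 = n_alt / n_labels,
       alleles = alleles, rho = rho, model = model)
}

# focal-allele copies per individual at the major locus
locus_copies <- function(pop, locus) {
  vapply(pop, function(g) {
    chr <- g[[locus$chrom]]
    locus$alleles[labels_at(chr$p1, chr$l1, locus$pos)] +
      locus$alleles[labels_at(chr$p2, chr$l2, locus$pos)]
  }, 0L)
}

#' Per-generation mean inbreeding of a simulation
#'
#' @param sim a [run_experiment()] result.
#' @return data.frame generation / F.
#' @export
inbreeding_series <- function(sim) {
  sim$stats[, c("generation", "F")]
}

#' Effective population size from an inbreeding series
#'
#' Fits `1 - F_t = (1 - dF)^t` by least squares on `log(1 - F)` (through
#' the origin) and returns `Ne = 1 / (2 dF)`.  A constant-zero series gives
#' `Ne = Inf` (no drift).  A non-monotone series (beyond a small tolerance)
#' triggers a warning but is fitted anyway.
#'
#' @param F_series numeric vector of mean inbreeding per generation
#'   (generation 0 first), or the data.frame from [inbreeding_series()].
#' @return list with `Ne`, `delta_F`.
#' @export
ne_from_inbreeding <- function(F_series) {
  if (is.data.frame(F_series)) F_series <- F_series$F
  F_series <- F_series[!is.na(F_series)]
  if (length(F_series) < 3) stop("need >= 3 generations of F")
  if (any(diff(F_series) < -0.05))
    warning("inbreeding series is non-monotone; fitting anyway")
  t <- seq_along(F_series) - 1
  y <- log(1 - F_series)
  b <- sum(t * y) / sum(t * t)
  dF <- 1 - exp(b)
  list(Ne = if (dF <= 0) Inf else 1 / (2 * dF), delta_F = dF)
}

#' Seed SNP genotypes onto simulated junction genomes
#'
#' Reconstructs SNP genotypes for the retained generations of a simulation
#' by assigning panel alleles to founder haplotype labels and reading
#' genotypes off the junction mosaic.  Because founder phase is not
#' observable in a real low-coverage study, three assignment schemes bound
#' the unknown founder linkage disequilibrium; they are applied within the
#' shared-ancestry intervals induced by the union of all junction
#' breakpoints across the sampled individuals:
#'
#' * `no_ld`: every founder haplotype gets independent alleles per site at
#'   the pooled panel frequency (linkage equilibrium);
#' * `min_ld`: each founder's observed diploid genotypes are kept and
#'   heterozygous sites are phased by a fair coin per site;
#' * `max_ld`: heterozygous sites are phased consistently within each
#'   shared-ancestry interval (all alternate alleles onto one homolog);
#' * `exact`: the panel's true phased haplotypes (synthetic-truth mode,
#'   available only because the panel is simulated).
#'
#' Homozygous founder sites are identical under all schemes.
#'
#' @param sim a [run_experiment()] result (with retained genomes).
#' @param panel the [make_founder_panel()] the experiment was founded on.
#' @param ld_mode one of `"no_ld"`, `"min_ld"`, `"max_ld"`, `"exact"`.
#' @param generations which retained generations to genotype (default all).
#' @param seed optional integer seed for the phasing randomness.
#' @return list per generation: `ids`, `geno` (individuals x sites matrix of
#'   0/1/2 alternate-allele counts), `hap1`/`hap2` (per-homolog alleles),
#'   and `sites` (data.frame chrom / pos, 1-based).
#' @export
seed_snps <- function(sim, panel, ld_mode = c("no_ld", "min_ld", "max_ld", "exact"),
                      generations = NULL, seed = NULL) {
  ld_mode <- match.arg(ld_mode)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(generations)) generations <- names(sim$genomes)
  generations <- as.character(generations)
  if (!all(generations %in% names(sim$genomes)))
    stop("requested generation was not retained by run_experiment")
  map <- sim$map
  n_labels <- sim$n_labels
  if (2L * panel$n_founders != n_labels)
    stop("panel does not match the simulated founders")

  # assignment matrices per chromosome (n_labels x n_sites), shared across
  # generations so descent correlations are preserved
  A <- lapply(seq_len(nrow(map)), function(c) {
    H <- panel$hap[[c]]
    if (!ncol(H)) return(H)
    switch(ld_mode,
      exact = H,
      no_ld = {
        # linkage equilibrium at the observed frequencies: each site's
        # realized alternate-allele count is kept and permuted across the
        # haplotype slots independently per site (a binomial redraw would
        # add spurious frequency-composition noise, inflating rare-site
        # z shifts)
        K <- colSums(H)
        A <- matrix(0L, n_labels, ncol(H))
        for (s in seq_len(ncol(H)))
          A[sample.int(n_labels, K[s]), s] <- 1L
        A
      },
      min_ld = phase_matrix(H, iv = NULL),
      max_ld = {
        iv <- ancestry_intervals(sim, c, generations)
        phase_matrix(H, iv = findInterval(panel$sites[[c]], iv))
      })
  })

  out <- lapply(generations, function(gn) {
    slot <- sim$genomes[[gn]]
    n_ind <- length(slot$genomes)
    hap1 <- hap2 <- list()
    for (c in seq_len(nrow(map))) {
      s <- panel$sites[[c]]
      if (!length(s)) next
      h1 <- h2 <- matrix(0L, n_ind, length(s))
      for (i in seq_len(n_ind)) {
        chr <- slot$genomes[[i]][[c]]
        h1[i, ] <- A[[c]][cbind(labels_at(chr$p1, chr$l1, s), seq_along(s))]
        h2[i, ] <- A[[c]][cbind(labels_at(chr$p2, chr$l2, s), seq_along(s))]
      }
      hap1[[map$chrom[c]]] <- h1
      hap2[[map$chrom[c]]] <- h2
    }
    sites <- data.frame(
      chrom = rep(map$chrom, lengths(panel$sites)),
      pos = unlist(panel$sites, use.names = FALSE) + 1, # 1-based, VCF style
      stringsAsFactors = FALSE)
    h1 <- do.call(cbind, hap1)
    h2 <- do.call(cbind, hap2)
    list(ids = slot$ids, geno = h1 + h2, hap1 = h1, hap2 = h2, sites = sites)
  })
  names(out) <- generations
  attr(out, "ld_mode") <- ld_mode
  out
}

# diploid-genotype-preserving phasing of the founder panel: per founder,
# G = h1 + h2; homozygous sites are forced, heterozygous sites are phased
# by a fair coin per (founder, site) (min LD, iv = NULL) or, under max LD,
# deterministically: every founder's alternate alleles go to the same
# designated haplotype slot within each shared-ancestry interval (the slot
# flips by one shared coin per interval), putting all het sites of the
# panel in perfect coupling within an interval
phase_matrix <- function(H, iv = NULL) {
  n_f <- nrow(H) / 2L
  S <- ncol(H)
  out <- matrix(0L, nrow(H), S)
  if (!is.null(iv)) {
    coin <- stats::runif(max(iv)) < 0.5
    cc_iv <- coin[iv] # TRUE: alt alleles on the second slot
  }
  for (f in seq_len(n_f)) {
    G <- H[2L * f - 1L, ] + H[2L * f, ]
    cc <- if (is.null(iv)) stats::runif(S) < 0.5 else cc_iv
    het <- G == 1L
    a1 <- as.integer(G == 2L)
    a2 <- as.integer(G == 2L)
    a1[het] <- as.integer(!cc[het])
    a2[het] <- as.integer(cc[het])
    out[2L * f - 1L, ] <- a1
    out[2L * f, ] <- a2
  }
  out
}

# partition boundaries induced by the union of all junction breakpoints of
# the sampled individuals on chromosome c
ancestry_intervals <- function(sim, c, generations) {
  bk <- unlist(lapply(generations, function(gn) {
    lapply(sim$genomes[[gn]]$genomes, function(g) c(g[[c]]$p1, g[[c]]$p2))
  }))
  sort(unique(c(0, bk)))
}
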