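# Junction-based genotype reconstruction vs. brute-force per-site gene
# dropping with the same crossover realizations (recorded by the reference
# engine).

brute_force_alleles <- function(sim, panel) {
  map <- sim$map
  gens <- sort(as.integer(names(sim$genomes)))
  ids_gen <- lapply(as.character(gens), function(g) sim$genomes[[g]]$ids)
  # per individual: list per chromosome of rbind(hap1, hap2) site alleles
  alleles <- list()
  founders <- sim$genomes[["0"]]
  for (i in seq_along(founders$ids)) {
    id <- founders$ids[i]
    alleles[[as.character(id)]] <- lapply(seq_len(nrow(map)), function(c)
      rbind(panel$hap[[c]][2 * i - 1, ], panel$hap[[c]][2 * i, ]))
  }
  ped <- sim$pedigree
  for (g in gens[gens > 0]) {
    slot <- sim$genomes[[as.character(g)]]
    for (i in seq_along(slot$ids)) {
      id <- slot$ids[i]
      row <- ped[ped$id == id, ]
      gnm <- slot$genomes[[i]]
      ind <- vector("list", nrow(map))
      for (c in seq_len(nrow(map))) {
        s <- panel$sites[[c]]
        chr <- gnm[[c]]
        ind[[c]] <- rbind(
          drop_gamete(alleles[[as.character(row$sire)]][[c]], s,
                      chr$xo1, chr$start1),
          drop_gamete(alleles[[as.character(row$dam)]][[c]], s,
                      chr$xo2, chr$start2))
      }
      alleles[[as.character(id)]] <- ind
    }
  }
  alleles
}

# copy alleles site by site: site at position p comes from the parental
# homolog determined by the number of crossovers at or below p
drop_gamete <- function(parent, sites, xo, start) {
  n_below <- findInterval(sites, sort(xo))
  hom <- ifelse(n_below %% 2 == 0, start, 3L - start)
  parent[cbind(hom, seq_along(sites))]
}

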