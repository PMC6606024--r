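# Shared fixtures: everything is generated in code, no stored data.

tiny_map <- function(n_chrom = 2, bp = 5e6, morgans = 0.5) {
  make_genome_map(n_chrom, bp, morgans)
}

# hand-built founder panel with fully controlled haplotypes:
# hap = list per chromosome of (2*n_founders x n_sites) 0/1 matrices,
# sites = list per chromosome of 0-based positions
manual_panel <- function(map, sites, hap) {
  structure(list(map = map, sites = sites, hap = hap,
                 n_founders = as.integer(nrow(hap[[1]]) / 2),
                 ancestral_pool = NA_integer_, seed = NULL),
            class = "founder_panel")
}

# small experiment used by several scan/significance tests
small_experiment <- function(seed, n_pairs = 8, n_gen = 6, offspring = 8,
                             map = tiny_map(), selection = "random",
                             panel_seed = seed + 1) {
  panel <- make_founder_panel(map, 2 * n_pairs, seed = panel_seed)
  ped <- make_pedigree(n_pairs, n_gen, offspring, seed = seed + 2)
  sim <- run_experiment(ped, map, trait_model(), selection = selection,
                        panel = panel, seed = seed + 3, compute_F = FALSE)
  list(map = map, panel = panel, ped = ped, sim = sim)
}

expect_valid_homolog <- function(pos, lab, L) {
  expect_equal(pos[1], 0)
  if (length(pos) > 1) {
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos < L))
    expect_true(all(lab[-1] != lab[-length(lab)]))
  }
}
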