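test_that("random selection yields no systematic response", {
  map <- tiny_map()
  model <- trait_model()
  R <- vapply(1:30, function(r) {
    ped <- make_pedigree(6, 4, 6, seed = r)
    sim <- run_experiment(ped, map, model, selection = "random", seed = r,
                          compute_F = FALSE)
    mean(sim$stats$R, na.rm = TRUE)
  }, 0)
  expect_lt(abs(mean(R)), 3 * sd(R) / sqrt(length(R)))
})

test_that("zero heritability gives selection without response", {
  map <- tiny_map()
  model <- trait_model(V_g = 0, V_s = 0, V_e = 1)
  res <- vapply(1:30, function(r) {
    ped <- make_pedigree(6, 4, 8, seed = r)
    sim <- run_experiment(ped, map, model, selection = "truncation", seed = r,
                          compute_F = FALSE)
    c(S = mean(sim$stats$S, na.rm = TRUE), R = mean(sim$stats$R, na.rm = TRUE))
  }, c(S = 0, R = 0))
  expect_gt(mean(res["S", ]), 0.5) # strong selection differential
  expect_lt(abs(mean(res["R", ])), 3 * sd(res["R", ]) / sqrt(30))
})

test_that("early response follows the within-family breeder's equation", {
  # under within-family truncation only half the additive variance is
  # selectable: R = h2_w * S with h2_w = (V_A/2) / (V_A/2 + V_E)
  map <- make_genome_map(5, 5e6, 0.6)
  model <- trait_model() # V_A = 0.4, V_E = 0.6 -> h2_w = 0.25
  res <- vapply(1:50, function(r) {
    ped <- make_pedigree(8, 2, 8, seed = r)
    sim <- run_experiment(ped, map, model, selection = "truncation",
                          seed = 1000 + r, compute_F = FALSE)
    c(S = sim$stats$S[2], R = sim$stats$R[3])
  }, c(S = 0, R = 0))
  h2w <- 0.2 / 0.8
  pred <- h2w * mean(res["S", ])
  se <- sd(res["R", ]) / sqrt(50)
  expect_equal(mean(res["R", ]), pred, tolerance = 3.5 * se / pred)
})

test_that("inbreeding starts at zero and follows known oracles", {
  map <- make_genome_map(10, 1e7, 1) # large genome: low IBD sampling noise
  # full-sib line oracle: F of the t-th full-sib generation follows
  # F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4, with F of the first litter = 0
  rec <- c(0, 0.25, 0.375, 0.5)
  obs <- withr::with_seed(5, {
    Fs <- matrix(0, 120, 4)
    for (r in 1:120) {
      sire <- founder_genome(1, map)
      dam <- founder_genome(2, map)
      for (t in 1:4) {
        kids <- pedscan:::r_make_offspring(list(sire, dam), c(1, 1), c(2, 2), map)
        Fs[r, t] <- mean(pedscan:::cpp_ibd_fraction(kids, map$bp))
        sire <- kids[[1]]
        dam <- kids[[2]]
      }
    }
    colMeans(Fs)
  })
  expect_equal(obs, rec, tolerance = 0.035)
})

test_that("ne_from_inbreeding inverts the drift recursion", {
  F_exact <- 1 - (1 - 1 / 92)^(0:17)
  expect_equal(ne_from_inbreeding(F_exact)$Ne, 46, tolerance = 1e-6)
  expect_equal(ne_from_inbreeding(rep(0, 10))$Ne, Inf)
  expect_warning(ne_from_inbreeding(c(0, 0.3, 0.1, 0.4)), "non-monotone")
  expect_error(ne_from_inbreeding(c(0, 0.1)))
})

test_that("simulated lines drift at a plausible effective size", {
  map <- tiny_map()
  model <- trait_model()
  Ne <- vapply(1:8, function(r) {
    ped <- make_pedigree(8, 8, 8, seed = r)
    sim <- run_experiment(ped, map, model, selection = "truncation", seed = r)
    ne_from_inbreeding(sim$stats$F)$Ne
  }, 0)
  # 16 breeders with equalized family sizes: Ne between N and 4N
  expect_gt(mean(Ne), 16)
  expect_lt(mean(Ne), 64)
})

test_that("major locus: null effect is neutral, larger effects sweep harder", {
  map <- tiny_map()
  model <- trait_model()
  dq <- sapply(c(0, 0.25, 0.6), function(a) {
    mean(vapply(1:30, function(r) {
      ped <- make_pedigree(8, 8, 8, seed = 500 + r)
      sim <- run_experiment(ped, map, model, selection = "truncation",
                            major_locus = list(chrom = 1, pos = 2.5e6,
                                               a = a, q0 = 0.25),
                            seed = 500 + r, compute_F = FALSE,
                            keep_generations = integer(0))
      sim$trajectory[9] - sim$trajectory[1]
    }, 0))
  })
  expect_lt(abs(dq[1]), 0.08) # a = 0: drift only
  expect_true(all(diff(dq) > 0)) # monotone in a
  # an effect too large for the variance rescaling errors
  expect_error(run_experiment(make_pedigree(4, 1, 4, seed = 1), map, model,
                              major_locus = list(chrom = 1, pos = 1, a = 2,
                                                 q0 = 0.5)),
               "rescal")
})

test_that("neutral seeded-site drift variance matches the realized Ne", {
  map <- tiny_map()
  model <- trait_model()
  res <- vapply(1:150, function(r) {
    ped <- make_pedigree(8, 6, 8, seed = 700 + r)
    sim <- run_experiment(ped, map, model, selection = "random",
                          major_locus = list(chrom = 1, pos = 2.5e6,
                                             a = 0, q0 = 0.5),
                          seed = 700 + r, keep_generations = integer(0))
    c(dq = sim$trajectory[7] - sim$trajectory[1],
      Ne = ne_from_inbreeding(sim$stats$F)$Ne)
  }, c(dq = 0, Ne = 0))
  expect_lt(abs(mean(res["dq", ])), 3 * sd(res["dq", ]) / sqrt(150))
  Ne <- mean(res["Ne", ])
  pred <- 0.25 * (1 - (1 - 1 / (2 * Ne))^6)
  expect_equal(var(res["dq", ]), pred, tolerance = 0.25)
})

test_that("seeding schemes agree exactly where phase cannot matter", {
  map <- make_genome_map(1, 1000, 0) # no recombination: one ancestry interval
  hap <- matrix(0L, 8, 3)
  hap[1, ] <- 1L # founder 1 heterozygous at all three sites
  panel <- manual_panel(map, sites = list(chr1 = c(99, 499, 899)),
                        hap = list(chr1 = hap))
  ped <- make_pedigree(2, 1, 4, seed = 1)
  sim <- run_experiment(ped, map, trait_model(), panel = panel, seed = 2,
                        keep_generations = 0L)
  painted <- lapply(c("min_ld", "max_ld", "exact"), function(m)
    seed_snps(sim, panel, m, seed = 3)[["0"]])
  # founders 2-4 are homozygous everywhere: identical under all phasings
  for (p in painted[-3]) {
    expect_identical(p$geno[2:4, ], painted[[3]]$geno[2:4, ])
    expect_identical(p$hap1[2:4, ], painted[[3]]$hap1[2:4, ])
  }
  # diploid genotypes are preserved by every phasing scheme
  for (p in painted) expect_identical(p$geno, painted[[3]]$geno)
  # max LD puts founder 1's three heterozygous sites in perfect coupling
  mx <- painted[[2]]
  h <- rbind(mx$hap1[1, ], mx$hap2[1, ])
  expect_true(identical(sort(rowSums(h)), c(0, 3)))
})
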