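test_that("delta_z2 matches closed forms and is symmetric", {
  expect_equal(delta_z2(0, 1), pi^2)
  expect_equal(delta_z2(0.3, 0.3), 0)
  expect_equal(delta_z2(0.25, 0.75), pi^2 / 9)
  q <- seq(0, 1, by = 0.1)
  expect_equal(delta_z2(q, rev(q)), delta_z2(rev(q), q))
  expect_true(all(delta_z2(runif(50), runif(50)) <= pi^2 + 1e-12))
})

test_that("polarization uses the timepoint-0 minor allele, ties to alt", {
  sites <- data.frame(chrom = "chr1", pos = 1:3)
  # 10 diploids: alt counts 3/20, 10/20, 16/20
  g0 <- rbind(c(0, 1, 2), c(1, 1, 2), c(1, 1, 2), c(1, 1, 2),
              c(0, 1, 2), c(0, 1, 2), c(0, 1, 2), c(0, 1, 2),
              c(0, 1, 0), c(0, 1, 0))
  g1 <- matrix(1, 10, 3)
  fr <- polarized_freq(g0, g1, sites)
  expect_equal(fr$q0, c(3 / 20, 0.5, 4 / 20))
  expect_equal(fr$flipped, c(FALSE, FALSE, TRUE))
  expect_equal(fr$q1, c(0.5, 0.5, 0.5))
  expect_equal(fr$n0, rep(20, 3))
})

test_that("windows follow the half-open tiling convention", {
  trk <- data.frame(chrom = "chr1",
                    pos = c(5, 500, 9000, 10001, 25000),
                    dz2 = c(0.1, 0.2, 0.3, 1, 2))
  w <- window_stats(trk, window = 1e4)
  expect_equal(w$start, c(0, 10000, 20000))
  expect_equal(w$dz2[1], 0.2) # mean of 0.1, 0.2, 0.3
  expect_equal(w$n_snps, c(3L, 1L, 1L))
  # pos 10001 (1-based) = coordinate 10000 -> window 2 (half-open)
  expect_equal(w$dz2[2], 1)
  # empty windows are missing, not zero
  map <- make_genome_map(1, 5e4, 0)
  trk$chrom <- "chr1"
  w2 <- window_stats(trk, 1e4, map)
  expect_equal(nrow(w2), 5)
  expect_true(is.na(w2$dz2[4]))
  expect_equal(w2$n_snps[4], 0L)
})

test_that("Weir-Cockerham F_ST matches a direct transcription of the 1984 components", {
  # two populations of 25 diploids in exact Hardy-Weinberg proportions:
  # p = 0.2 (1 hom alt, 8 het, 16 hom ref) vs p = 0.8 (mirrored)
  gA <- c(rep(2, 1), rep(1, 8), rep(0, 16))
  gB <- c(rep(0, 1), rep(1, 8), rep(2, 16))
  sites <- data.frame(chrom = "chr1", pos = 1)
  got <- fst_weir_cockerham(matrix(gA, 25), matrix(gB, 25), sites)$sites
  # independent step-by-step oracle
  oracle <- local({
    n1 <- 25; n2 <- 25; p1 <- mean(gA) / 2; p2 <- mean(gB) / 2
    h1 <- mean(gA == 1); h2 <- mean(gB == 1); r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a / (a + b + cc)
  })
  expect_equal(got$fst, oracle)
  expect_gt(got$fst, 0.4) # strongly differentiated

  # identical frequencies -> ~0; fixed difference -> 1
  g_same <- matrix(c(rep(1, 10), rep(0, 15)), 25)
  same <- fst_weir_cockerham(g_same, g_same, sites)$sites$fst
  expect_lt(abs(same), 0.05)
  fixA <- matrix(0, 30, 1)
  fixB <- matrix(2, 30, 1)
  expect_equal(fst_weir_cockerham(fixA, fixB, sites)$sites$fst, 1)
  # monomorphic across both: undefined
  expect_true(is.na(fst_weir_cockerham(fixA, fixA, sites)$sites$fst))
})

test_that("windowed F_ST equals per-site F_ST for singleton windows", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 15000))
  gA <- cbind(c(rep(2, 5), rep(0, 15)), c(rep(1, 10), rep(0, 10)))
  gB <- cbind(c(rep(0, 18), rep(2, 2)), c(rep(1, 4), rep(0, 16)))
  res <- fst_weir_cockerham(gA, gB, sites, window = 1e4)
  expect_equal(res$windows$fst[1:2], res$sites$fst[1:2])
})

test_that("diversity summaries follow the unbiased estimator", {
  # one site, q = 0.5, 4 chromosomes: pi = 2*4*0.25/3
  g <- matrix(c(0, 2), 2, 1)
  sites <- data.frame(chrom = "chr1", pos = 5000)
  d <- diversity(g, sites, window = 1e4)
  expect_equal(d$pi_site, 2 * 4 * 0.25 / 3)
  expect_equal(d$pi_windows$pi[1], d$pi_site / 1e4)
  expect_equal(d$segregating_sites, 1)
  expect_equal(d$heterozygosity, 0)
  # monomorphic matrix
  g0 <- matrix(0, 4, 2)
  d0 <- diversity(g0, data.frame(chrom = "chr1", pos = c(1, 2)), 1e4)
  expect_equal(d0$segregating_sites, 0)
  expect_equal(sum(d0$pi_windows$pi), 0)
})

test_that("VCF writing round-trips through VariantAnnotation", {
  fx <- small_experiment(20, n_pairs = 4, n_gen = 2, offspring = 4,
                         map = tiny_map(1, 2e5, 0.2))
  sn <- seed_snps(fx$sim, fx$panel, "exact")
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_vcf(sn[[1]]$hap1, sn[[1]]$hap2, sn[[1]]$sites, fx$map, f)
  rg <- read_genotypes(f)
  expect_equal(unname(rg$geno), unname(sn[[1]]$geno) + 0)
  expect_equal(rg$sites$pos, as.integer(sn[[1]]$sites$pos))
  expect_equal(rg$n_skipped, 0)
})

test_that("non-biallelic records are skipped and counted", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1",
    "chr1\t20\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0\t1/2",
    "chr1\t30\t.\tAC\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "chr1\t40\t.\tC\tG\t.\tPASS\t.\tGT\t./.\t0/1\t1/1"), f)
  rg <- read_genotypes(f)
  expect_equal(dim(rg$geno), c(3L, 2L))
  expect_equal(rg$n_skipped, 2)
  expect_true(is.na(rg$geno[1, 2]))
  expect_error(read_genotypes(f, samples = "nope"), "no samples matched")
})
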