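test_that("genomewide_max takes the max over non-missing windows", {
  w <- data.frame(chrom = "chr1", start = c(0, 1e4, 2e4), end = c(1e4, 2e4, 3e4),
                  dz2 = c(0.1, 0.5, 0.3), n_snps = c(1L, 1L, 1L))
  expect_equal(genomewide_max(w), 0.5)
  expect_equal(genomewide_max(w[2, ]), 0.5)
  w$dz2[2] <- NA
  expect_equal(genomewide_max(w), 0.3)
  w$dz2 <- NA
  expect_error(genomewide_max(w), "missing")
})

test_that("critical_value is the ceiling(n(1-alpha)) order statistic", {
  expect_equal(critical_value(sample(1:100), 0.05), 95)
  expect_equal(critical_value(rep(3.3, 25)), 3.3)
  expect_equal(critical_value(sample(1:20), 0.5), 10)
  expect_error(critical_value(1:10), ">= 20")
  expect_error(critical_value(1:50, 0))
})

test_that("call_peaks reproduces the hand-traced extension toy", {
  # 300 sites, one per 100 bp window; sites 100-110 at 0.9 pi^2 (the
  # significant core), 111-160 decaying from 0.45 pi^2 to just above
  # 0.2 pi^2, everything else at 0.01 pi^2; extension blocks of 25 SNPs
  n <- 300
  val <- rep(0.01 * pi^2, n)
  val[100:110] <- 0.9 * pi^2
  val[111:160] <- seq(0.45, 0.21, length.out = 50) * pi^2
  pos <- (seq_len(n) - 1) * 100 + 50 # 1-based positions
  track <- data.frame(chrom = "chr1", pos = pos, dz2 = val)
  wins <- window_stats(track, window = 100)
  pk <- call_peaks(wins, track, threshold = 0.5 * pi^2, stop = 0.2 * pi^2,
                   ext_snps = 25)
  expect_equal(nrow(pk), 1)
  # right side: blocks 111-135 and 136-160 contain sites above the stop
  # level, 161-185 does not -> span ends with site 185; left side stops
  # after one block (sites 75-99)
  expect_equal(pk$span_start, pos[75] - 1)
  expect_equal(pk$span_end, pos[185])
  # core = contiguous significant windows = sites 100..110's windows
  expect_equal(pk$core_start, 9900)
  expect_equal(pk$core_end, 11000)
  expect_equal(pk$peak_value, 0.9 * pi^2)

  # flat profile below threshold: nothing
  flat <- track
  flat$dz2 <- 0.01
  expect_equal(nrow(call_peaks(window_stats(flat, 100), flat, 0.5 * pi^2)), 0)

  # isolated significant window with quiet flanks: core = span = window
  iso <- track
  iso$dz2 <- 0.01 * pi^2
  iso$dz2[150] <- 0.9 * pi^2
  pk2 <- call_peaks(window_stats(iso, 100), iso, 0.5 * pi^2, ext_snps = 25)
  expect_equal(nrow(pk2), 1)
  expect_equal(c(pk2$core_start, pk2$core_end), c(14900, 15000))
  # span adds exactly one stopped block per side
  expect_equal(pk2$span_start, pos[125] - 1)
  expect_equal(pk2$span_end, pos[175])
})

test_that("parallelism chi-square matches the hand calculation", {
  # both=5, A-only=5, B-only=5, neither=85: E = {1, 9, 9, 81}
  res <- parallelism_chisq(c(5, 5, 5), total = 100)
  expect_equal(res$chisq, 16 + 16 / 9 + 16 / 9 + 16 / 81, tolerance = 1e-12)
  expect_equal(res$chisq, 19.75, tolerance = 0.002)
  # doubling all cells doubles the statistic
  res2 <- parallelism_chisq(c(10, 10, 10), total = 200)
  expect_equal(res2$chisq, 2 * res$chisq)
  # exact independence: chi-square 0, p 1
  a <- rep(c(TRUE, FALSE), c(10, 90))
  b <- rep(rep(c(TRUE, FALSE), c(1, 9)), 10)
  res0 <- parallelism_chisq(a, b)
  expect_equal(res0$chisq, 0)
  expect_equal(res0$p, 1)
  expect_match(parallelism_chisq(c(1, 1, 1), total = 1000)$warning, "below 1")
})

test_that("profile correlation behaves at the boundaries", {
  w <- data.frame(dz2 = runif(50))
  expect_equal(profile_correlation(w, w)$r, 1)
  w2 <- w
  w2$dz2[1:45] <- NA
  expect_error(profile_correlation(w, w2), ">= 10")
  const <- data.frame(dz2 = rep(1, 50))
  expect_error(profile_correlation(w, const), "zero variance")
})

test_that("interval permutation p-values match analytic placement odds", {
  map <- make_genome_map(1, 1e6, 0)
  feat <- data.frame(chrom = "chr1", start = 0, end = 1e4)
  query <- data.frame(chrom = "chr1", start = 0, end = 1e4)
  res <- interval_permutation(query, feat, map, n = 1000, mode = "overlap",
                              seed = 1)
  expect_equal(res$observed, 1)
  # a 10 kbp query placed uniformly on a 1 Mbp chromosome overlaps the one
  # 10 kbp feature with probability ~1e4 / 9.9e5 ~ 1%
  expect_gt(res$p, 0.002)
  expect_lt(res$p, 0.03)

  # saturated features: every permutation ties the observed statistic
  sat <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  res2 <- interval_permutation(query, sat, map, n = 100, seed = 2)
  expect_equal(res2$p, 1)

  # observed beyond every permutation: reported below 1/n
  map2 <- make_genome_map(4, 1e6, 0)
  feat5 <- data.frame(chrom = "chr1", start = (0:4) * 2e5, end = (0:4) * 2e5 + 100)
  q5 <- data.frame(chrom = "chr1", start = (0:4) * 2e5, end = (0:4) * 2e5 + 100)
  res3 <- interval_permutation(q5, feat5, map2, n = 200, seed = 3)
  expect_true(res3$less_than)
  expect_equal(res3$p, 1 / 201)

  # distance mode: on-feature query is closer than random placements
  res4 <- interval_permutation(query, feat, map, n = 200,
                               mode = "nearest_distance", seed = 4)
  expect_equal(res4$observed, 0)
  expect_lt(res4$p, 0.05)
})
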