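test_that("wf_transition is a proper genic-selection kernel", {
  Tm <- wf_transition(46, 0.228)
  expect_equal(dim(Tm), c(93, 93))
  expect_equal(rowSums(Tm), rep(1, 93), tolerance = 1e-12)
  # absorbing boundaries
  expect_equal(Tm[1, 1], 1)
  expect_equal(Tm[93, 93], 1)
  # deterministic part: q* = q(1+s)/(1+sq); q = 0.17, s = 0.228 -> 0.20096
  q <- 0.17
  qs <- q * 1.228 / (1 + 0.228 * q)
  expect_equal(qs, 0.20096, tolerance = 1e-4)
  # mean of the row at count 2Ne*q equals 2Ne*q*
  i <- round(92 * q) + 1
  qi <- (i - 1) / 92
  mu <- sum((0:92) * Tm[i, ])
  expect_equal(mu, 92 * qi * 1.228 / (1 + 0.228 * qi), tolerance = 1e-9)
  # s = 0: neutral kernel, mean preserved
  T0 <- wf_transition(46, 0)
  expect_equal(sum((0:92) * T0[i, ]), i - 1, tolerance = 1e-9)
  expect_error(wf_transition(46, -1))
})

test_that("estimate_s recovers the deterministic ln-odds slope", {
  # 0.17 -> 0.87 in 17 generations: s = exp(d ln-odds / 17) - 1 = 0.228
  tr <- data.frame(generation = c(0, 17), count = c(170, 870), n_chr = 1000)
  det <- estimate_s(tr, Ne = Inf)
  expect_equal(det$s_hat, 0.228, tolerance = 0.015)
  # finite-Ne HMM lands nearby, with a wider CI containing the estimate
  hmm <- estimate_s(tr, Ne = 46)
  expect_equal(hmm$s_hat, 0.228, tolerance = 0.05)
  expect_true(hmm$ci[1] <= hmm$s_hat && hmm$s_hat <= hmm$ci[2])
  expect_equal(hmm$delta_q, 0.7)
})

test_that("no change means no selection", {
  # huge Ne (deterministic limit) and huge samples, constant frequency
  tr <- data.frame(generation = 0:5, count = rep(500, 6), n_chr = 1000)
  est <- estimate_s(tr, Ne = Inf, s_grid = seq(-0.2, 0.2, 0.005))
  expect_equal(est$s_hat, 0, tolerance = 1e-9)
  # and a modest finite population agrees
  est46 <- estimate_s(tr, Ne = 46, s_grid = seq(-0.2, 0.2, 0.005))
  expect_lt(abs(est46$s_hat), 0.02)
})

test_that("degenerate trajectories error as specified", {
  expect_error(estimate_s(data.frame(generation = 0, count = 1, n_chr = 10)),
               ">= 2")
  expect_error(estimate_s(data.frame(generation = 0:3, count = 0, n_chr = 10)),
               "unidentifiable")
  expect_error(estimate_s(data.frame(generation = 0:1, count = c(5, 11),
                                     n_chr = 10)), "exceeds")
})

test_that("allele relabeling reflects the genic estimate", {
  # relabeling q -> 1-q maps s -> -s/(1+s)
  withr::with_seed(8, {
    n <- 92
    cnt <- numeric(10)
    q <- 0.3
    for (t in 1:10) {
      q <- q * 1.3 / (1 + 0.3 * q)
      cnt[t] <- rbinom(1, n, q)
    }
    tr <- data.frame(generation = 1:10, count = cnt, n_chr = n)
    tr_flip <- transform(tr, count = n_chr - count)
    e <- estimate_s(tr, Ne = 46)
    ef <- estimate_s(tr_flip, Ne = 46)
    expect_equal(ef$s_hat, -e$s_hat / (1 + e$s_hat), tolerance = 0.05)
  })
})

test_that("missing generations are bridged by chained transitions", {
  tr_full <- data.frame(generation = 0:8,
                        count = c(30, 32, 35, 38, 40, 44, 47, 50, 53),
                        n_chr = 92)
  tr_gap <- tr_full[c(1, 3, 5, 9), ]
  e_full <- estimate_s(tr_full, Ne = 46)
  e_gap <- estimate_s(tr_gap, Ne = 46)
  expect_equal(e_gap$s_hat, e_full$s_hat, tolerance = 0.5)
  expect_true(diff(e_gap$ci) >= diff(e_full$ci) - 1e-9) # less data, wider CI
})

test_that("drift envelope matches the closed-form drift variance", {
  env <- drift_envelope(0.3, 46, 10, n_paths = 2e4, seed = 9)
  expect_equal(env$lo[1], 0.3)
  expect_equal(env$hi[1], 0.3)
  v <- attr(env, "variance")
  t <- 10
  pred <- 0.3 * 0.7 * (1 - (1 - 1 / 92)^t)
  expect_equal(v[t + 1], pred, tolerance = 0.05)
  # a strong sweep escapes the 95% band
  env17 <- drift_envelope(0.17, 46, 17, n_paths = 2e4, seed = 10)
  expect_gt(0.98, env17$hi[18])
})

test_that("contribution arithmetic matches the printed example", {
  expect_equal(contribution_arithmetic(0.36, c(0.68, 0.81), 12.9), 4.157,
               tolerance = 1e-3)
  expect_equal(contribution_arithmetic(0, 0.5, 10), 0)
  expect_equal(contribution_arithmetic(1, 0.5, 10), 10)
  expect_error(contribution_arithmetic(1, 0.5, 0))
})

test_that("calibrated contribution is zero at a null target and monotone", {
  map <- tiny_map()
  res0 <- contribution_simulated(map = map, n_pairs = 6, n_generations = 4,
                                 offspring = 6, target_dq = 0, n_reps = 5,
                                 n_calib = 2, seed = 11)
  expect_equal(res0$a, 0)
  expect_equal(res0$contribution_mean, 0)
})
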