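#' Wright-Fisher transition distribution under genic selection
#'
#' One generation of a population of `Ne` diploids: the next-generation
#' focal-allele count is `Binomial(2 Ne, q*)` with `q* = q (1 + s) / (1 + s
#' q)` -- genic selection, every copy of the focal allele having relative
#' fitness `1 + s`.  `q = 0` and `q = 1` are absorbing.
#'
#' @param Ne effective population size (diploids).
#' @param s genic selection coefficient (> -1).
#' @return the `(2Ne + 1) x (2Ne + 1)` transition matrix (rows: current
#'   count 0..2Ne; columns: next count); rows sum to 1.
#' @export
wf_transition <- function(Ne, s) {
  if (s <= -1) stop("s must be > -1")
  n <- 2 * Ne
  q <- (0:n) / n
  qs <- q * (1 + s) / (1 + s * q)
  t(vapply(qs, function(p) stats::dbinom(0:n, n, p), numeric(n + 1)))
}

#' Precompute Wright-Fisher kernels over a grid of s
#'
#' @param Ne effective population size.
#' @param s_grid grid of selection coefficients.
#' @return a `wf_kernel` list (transition matrix per grid point).
#' @export
wf_kernel <- function(Ne, s_grid = seq(-0.5, 1, by = 0.005)) {
  structure(list(Ne = Ne, s_grid = s_grid,
                 T = lapply(s_grid, function(s) wf_transition(Ne, s))),
            class = "wf_kernel")
}

#' Estimate a selection coefficient from an allele-frequency trajectory
#'
#' Hidden-Markov likelihood: the latent population count evolves by
#' [wf_transition()] (missing generations are bridged by chaining
#' transitions, not interpolation); each observed generation contributes a
#' binomial emission of the sampled focal-allele count given the latent
#' frequency.  The likelihood is maximized over the `s` grid and the
#' confidence interval is the likelihood-ratio 1.92-drop (asymptotic 95%)
#' region.
#'
#' With `Ne = Inf` the latent dynamics are deterministic (the ln-odds of
#' the allele grow by `ln(1 + s)` per generation), which is the
#' closed-form limit useful for two-point trajectories.
#'
#' @param traj data.frame with columns `generation`, `count` (focal-allele
#'   copies observed), `n_chr` (chromosomes sampled); generations strictly
#'   increasing, gaps allowed.
#' @param Ne effective population size (46 by default, typical of a small
#'   selection line; always explicit in the output).
#' @param s_grid grid of candidate s values.
#' @param kernel optional precomputed [wf_kernel()] (must match `Ne` and
#'   `s_grid`); avoids rebuilding transition matrices in replicate sweeps.
#' @return an `s_estimate` list: `s_hat`, `ci` (c(lo, hi)), `loglik`
#'   (data.frame s / loglik), `delta_q`, `Ne`.
#' @export
estimate_s <- function(traj, Ne = 46, s_grid = seq(-0.5, 1, by = 0.005),
                       kernel = NULL) {
  stopifnot(all(c("generation", "count", "n_chr") %in% names(traj)))
  traj <- traj[order(traj$generation), ]
  if (nrow(traj) < 2) stop("need >= 2 observed generations")
  if (any(traj$count > traj$n_chr)) stop("count exceeds sample size")
  if (all(traj$count == 0)) stop("allele never observed: s unidentifiable")
  q_obs <- traj$count / traj$n_chr
  dq <- q_obs[nrow(traj)] - q_obs[1]

  ll <- if (is.infinite(Ne)) {
    vapply(s_grid, function(s) loglik_deterministic(traj, s), 0)
  } else {
    if (is.null(kernel)) kernel <- wf_kernel(Ne, s_grid)
    if (!isTRUE(all.equal(kernel$s_grid, s_grid)) || kernel$Ne != Ne)
      stop("kernel does not match Ne / s_grid")
    vapply(seq_along(s_grid), function(i) loglik_hmm(traj, Ne, kernel$T[[i]]), 0)
  }
  best <- which.max(ll)
  keep <- ll >= ll[best] - qchisq_drop()
  structure(list(s_hat = s_grid[best],
                 ci = c(min(s_grid[keep]), max(s_grid[keep])),
                 loglik = data.frame(s = s_grid, loglik = ll),
                 delta_q = dq, Ne = Ne),
            class = "s_estimate")
}

qchisq_drop <- function() 1.92 # LR 95% half-width on the log-likelihood

loglik_hmm <- function(traj, Ne, Tm) {
  n <- 2 * Ne
  q_lat <- (0:n) / n
  # uniform prior over latent counts at the first observed generation
  alpha <- rep(1 / (n + 1), n + 1)
  ll <- 0
  gens <- traj$generation
  for (i in seq_len(nrow(traj))) {
    if (i > 1) {
      steps <- gens[i] - gens[i - 1]
      for (k in seq_len(steps)) alpha <- as.vector(alpha %*% Tm)
    }
    em <- stats::dbinom(traj$count[i], traj$n_chr[i], q_lat)
    alpha <- alpha * em
    norm <- sum(alpha)
    if (norm == 0) return(-Inf)
    ll <- ll + log(norm)
    alpha <- alpha / norm
  }
  ll
}

loglik_deterministic <- function(traj, s) {
  q <- traj$count[1] / traj$n_chr[1]
  if (q == 0 || q == 1) return(-Inf)
  ll <- 0
  gens <- traj$generation
  for (i in seq_len(nrow(traj))[-1]) {
    steps <- gens[i] - gens[i - 1]
    for (k in seq_len(steps)) q <- q * (1 + s) / (1 + s * q)
    ll <- ll + stats::dbinom(traj$count[i], traj$n_chr[i], q, log = TRUE)
  }
  ll
}

#' Neutral drift envelope of an allele-frequency trajectory
#'
#' Simulates neutral Wright-Fisher paths from `q0` and returns the
#' per-generation empirical `(alpha/2, 1 - alpha/2)` bands (the region a
#' neutrally drifting allele stays inside with probability `1 - alpha`).
#'
#' @param q0 starting frequency in (0, 1).
#' @param Ne effective population size.
#' @param generations number of generations simulated.
#' @param alpha band tail probability (default 0.05: 95% envelope).
#' @param n_paths simulated paths (default 1e5).
#' @param seed optional integer seed.
#' @return data.frame: generation, lo, hi, plus the per-generation path
#'   variance as attribute `variance`.
#' @export
drift_envelope <- function(q0, Ne, generations, alpha = 0.05, n_paths = 1e5,
                           seed = NULL) {
  if (q0 <= 0 || q0 >= 1) stop("q0 must be in (0,1)")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- 2 * Ne
  q <- rep(q0, n_paths)
  lo <- hi <- va <- numeric(generations + 1)
  lo[1] <- hi[1] <- q0
  va[1] <- 0
  for (t in seq_len(generations)) {
    q <- stats::rbinom(n_paths, n, q) / n
    qs <- stats::quantile(q, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo[t + 1] <- qs[1]
    hi[t + 1] <- qs[2]
    va[t + 1] <- stats::var(q)
  }
  out <- data.frame(generation = 0:generations, lo = lo, hi = hi)
  attr(out, "variance") <- va
  out
}

#' Response contribution of a locus from effect size and frequency change
#'
#' `100 * (2 * mean(delta_q) * per_allele_effect) / total_increase`: the
#' share of a total trait increase attributable to a locus whose allele,
#' with per-copy effect `per_allele_effect` (in % of the trait), rose by
#' `delta_q` in frequency.
#'
#' @param per_allele_effect per-copy effect, in percent of the trait.
#' @param delta_q frequency change(s), one per line (averaged).
#' @param total_increase total trait increase, in percent.
#' @return contribution in percent of the total response.
#' @examples
#' contribution_arithmetic(0.36, c(0.68, 0.81), 12.9)  # ~4.16
#' @export
contribution_arithmetic <- function(per_allele_effect, delta_q, total_increase) {
  if (total_increase <= 0) stop("total_increase must be positive")
  100 * (2 * mean(delta_q) * per_allele_effect) / total_increase
}

#' Simulated response contribution of a calibrated major locus
#'
#' Runs the pedigree simulator with one additive biallelic locus against
#' the infinitesimal background, bisecting on the locus effect `a` until
#' the mean replicate frequency change hits `target_dq`, then reports the
#' per-replicate contribution `2 a delta_q / total response` over
#' `n_reps` final replicates (mean and min-max limits).
#'
#' @param map,model,panel_args experiment configuration; `map` defaults to
#'   a mouse-like scaffold of 19 chromosomes x 0.7 Morgans.
#' @param n_pairs,n_generations,offspring breeding design (defaults: 16
#'   pairs, 17 generations, constant 12 -- a small-mammal selection line
#'   with within-family truncation).
#' @param q0 starting frequency of the focal allele.
#' @param target_dq target mean frequency change (default 0.7).
#' @param locus_chrom,locus_pos_frac where the locus sits (chromosome
#'   index and fractional position).
#' @param n_reps final replicates (>= 100 for stable limits).
#' @param n_calib replicates per bisection evaluation.
#' @param tol calibration tolerance on mean delta-q.
#' @param a_bounds bisection bracket for the effect (phenotypic s.d. per
#'   copy).
#' @param max_iter bisection iterations.
#' @param seed optional integer seed.
#' @return list: `contribution_mean`, `contribution_limits`, `a`,
#'   `mean_dq`, `replicates` (data.frame dq / total_R / contribution).
#' @export
contribution_simulated <- function(map = make_genome_map(19, 130e6, 0.7),
                                   model = trait_model(),
                                   n_pairs = 16, n_generations = 17,
                                   offspring = 12, q0 = 0.17,
                                   target_dq = 0.7, locus_chrom = 1,
                                   locus_pos_frac = 0.5, n_reps = 100,
                                   n_calib = 30, tol = 0.02,
                                   a_bounds = c(0, 1), max_iter = 5,
                                   seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  locus_pos <- locus_pos_frac * map$bp[locus_chrom]
  sigma_p <- sqrt(model$V_g + model$V_s + model$V_e)

  one_rep <- function(a) {
    ped <- make_pedigree(n_pairs, n_generations, offspring)
    sim <- run_experiment(ped, map, model,
                          selection = "truncation",
                          major_locus = list(chrom = locus_chrom,
                                             pos = locus_pos, a = a, q0 = q0),
                          keep_generations = integer(0), compute_F = FALSE)
    dq <- sim$trajectory[length(sim$trajectory)] - sim$trajectory[1]
    total_R <- (sim$stats$mean_phenotype[n_generations + 1] -
                  sim$stats$mean_phenotype[1]) / sigma_p
    c(dq = dq, total_R = total_R)
  }
  mean_dq <- function(a, n) mean(vapply(seq_len(n), function(i) one_rep(a)["dq"], 0))

  if (target_dq == 0) {
    a <- 0
  } else {
    lo <- a_bounds[1]
    hi <- a_bounds[2]
    if (mean_dq(hi, n_calib) < target_dq)
      stop("target delta-q unreachable within the effect bound")
    a <- (lo + hi) / 2
    for (i in seq_len(max_iter)) {
      m <- mean_dq(a, n_calib)
      if (abs(m - target_dq) <= tol) break
      if (m < target_dq) lo <- a else hi <- a
      a <- (lo + hi) / 2
    }
    # refinement: the mean-dq(a) response is smooth and locally linear, so
    # fit it on a small bracket around the bisection output and solve for
    # the target (bisection alone, with Monte-Carlo noise in each
    # evaluation, tends to stop a calibration-noise width off target)
    da <- c(-0.06, -0.03, 0, 0.03, 0.06)
    grid_a <- pmin(pmax(a + da, a_bounds[1]), a_bounds[2])
    grid_m <- vapply(grid_a, mean_dq, 0, n = 2 * n_calib)
    fit <- stats::lm(grid_m ~ grid_a)
    slope <- stats::coef(fit)[2]
    if (is.finite(slope) && slope > 0.2) {
      a_star <- (target_dq - stats::coef(fit)[1]) / slope
      a <- min(max(a_star, min(grid_a)), max(grid_a))
    }
  }
  reps <- t(vapply(seq_len(n_reps), function(i) one_rep(a), c(dq = 0, total_R = 0)))
  # a and the total response are both converted to trait units: 2 a dq is
  # the locus' contribution to the mean trait shift, total_R * sigma_p the
  # whole shift
  contrib <- 100 * 2 * a * reps[, "dq"] / (reps[, "total_R"] * sigma_p)
  res <- data.frame(dq = reps[, "dq"], total_R = reps[, "total_R"],
                    contribution = contrib)
  list(contribution_mean = mean(contrib),
       contribution_limits = range(contrib),
       a = a, mean_dq = mean(reps[, "dq"]), replicates = res)
}
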