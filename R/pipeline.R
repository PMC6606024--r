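#' Run configuration
#'
#' A serializable, round-trippable description of a full pipeline run; all
#' outputs embed its hash and seed.
#'
#' @param seed integer master seed.
#' @param n_pairs,n_generations,offspring breeding design.
#' @param n_chrom,bp_per_chrom,morgans_per_chrom genome scaffold.
#' @param snp_density,ancestral_pool,block_length founder-panel knobs.
#' @param V_g,V_s,V_e,phi trait model.
#' @param lines named selection modes, e.g. `c(LS1 = "truncation", LS2 =
#'   "truncation", Ctrl = "random")`.
#' @param ld_mode SNP seeding scheme(s).
#' @param alpha significance level.
#' @param window window width in bp.
#' @param n_threshold_reps simulated null replicates behind thresholds.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_pairs = 16, n_generations = 17,
                       offspring = 12, n_chrom = 2, bp_per_chrom = 5e6,
                       morgans_per_chrom = 0.5, snp_density = 1 / 4000,
                       ancestral_pool = 18, block_length = 5e5,
                       V_g = 0.2, V_s = 0.2, V_e = 0.6, phi = -0.57,
                       lines = c(LS1 = "truncation", LS2 = "truncation",
                                 Ctrl = "random"),
                       ld_mode = "min_ld", alpha = 0.05, window = 1e4,
                       n_threshold_reps = 20) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("run config (hash", config_hash(x), ")\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Hash / save / load a run configuration
#' @param cfg a [run_config()].
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(cfg_serializable(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

# named vectors must serialize as JSON objects, not bare arrays
cfg_serializable <- function(cfg) {
  x <- unclass(cfg)
  x$lines <- as.list(x$lines)
  x
}

#' @rdname config_hash
#' @param path JSON file.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg_serializable(cfg), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname config_hash
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$lines <- unlist(cfg$lines)
  do.call(run_config, cfg[names(cfg) %in% names(formals(run_config))])
}

cfg_map <- function(cfg) make_genome_map(cfg$n_chrom, cfg$bp_per_chrom,
                                         cfg$morgans_per_chrom)
cfg_model <- function(cfg) trait_model(cfg$V_g, cfg$V_s, cfg$V_e, phi = cfg$phi)

# deterministic per-purpose sub-seeds below 2^31
sub_seed <- function(seed, k) (seed * 1000003L + k) %% 2147483647L

#' Simulate all lines of a configured experiment and write VCFs
#'
#' For each configured line: founder panel, pedigree, [run_experiment()],
#' [seed_snps()] at generations 0 and `n_generations`, and one phased VCF
#' per timepoint, plus a JSON run report (config hash, seed, S/R/F series,
#' trajectories).
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created).
#' @return list per line: `sim`, `snps`, `vcf` (paths), plus `report`
#'   path; invisibly.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  map <- cfg_map(cfg)
  model <- cfg_model(cfg)
  hash <- config_hash(cfg)
  out <- list()
  report <- list(config_hash = hash, seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("pedscan")),
                 lines = list())
  for (k in seq_along(cfg$lines)) {
    ln <- names(cfg$lines)[k]
    panel <- make_founder_panel(map, 2 * cfg$n_pairs, cfg$snp_density,
                                cfg$ancestral_pool, cfg$block_length,
                                seed = sub_seed(cfg$seed, 10 * k + 1))
    ped <- make_pedigree(cfg$n_pairs, cfg$n_generations, cfg$offspring,
                         seed = sub_seed(cfg$seed, 10 * k + 2))
    sim <- run_experiment(ped, map, model, selection = cfg$lines[[k]],
                          panel = panel, seed = sub_seed(cfg$seed, 10 * k + 3))
    snps <- seed_snps(sim, panel, cfg$ld_mode,
                      seed = sub_seed(cfg$seed, 10 * k + 4))
    vcfs <- character(0)
    for (gn in names(snps)) {
      p <- file.path(out_dir, sprintf("%s_F%s.vcf", ln, gn))
      s <- snps[[gn]]
      write_genotype_vcf(s$hap1, s$hap2, s$sites, map, p,
                         ids = paste0(ln, "_", s$ids))
      vcfs[gn] <- p
    }
    out[[ln]] <- list(sim = sim, snps = snps, vcf = vcfs)
    # report stores file names, not absolute paths, so reruns into other
    # directories produce byte-identical reports
    report$lines[[ln]] <- list(selection = cfg$lines[[k]],
                               S = sim$stats$S, R = sim$stats$R,
                               F = sim$stats$F, vcf = basename(unname(vcfs)))
  }
  rp <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out$report <- rp
  invisible(out)
}

#' Null distribution of genome-wide maxima for a configured design
#'
#' Repeats the full chain (panel, pedigree, experiment, SNP seeding, scan)
#' under the given selection and LD scheme and records each replicate's
#' genome-wide maximum windowed delta-z-squared -- the simulation-derived
#' null used by [critical_value()].
#'
#' @param cfg a [run_config()].
#' @param n_reps replicates (>= 20).
#' @param ld_mode seeding scheme for this replicate set.
#' @param selection selection mode of the simulated replicates.
#' @param seed integer seed.
#' @return a `threshold_set` list: `maxima`, `threshold`, `alpha`,
#'   `ld_mode`, `selection`, `n_reps`, `seed`.
#' @export
simulate_threshold_set <- function(cfg, n_reps = cfg$n_threshold_reps,
                                   ld_mode = cfg$ld_mode,
                                   selection = "random", seed = cfg$seed) {
  map <- cfg_map(cfg)
  model <- cfg_model(cfg)
  maxima <- vapply(seq_len(n_reps), function(r) {
    panel <- make_founder_panel(map, 2 * cfg$n_pairs, cfg$snp_density,
                                cfg$ancestral_pool, cfg$block_length,
                                seed = sub_seed(seed, 3 * r))
    ped <- make_pedigree(cfg$n_pairs, cfg$n_generations, cfg$offspring,
                         seed = sub_seed(seed, 3 * r + 1))
    sim <- run_experiment(ped, map, model, selection = selection,
                          panel = panel, seed = sub_seed(seed, 3 * r + 2),
                          compute_F = FALSE)
    prof <- scan_sim(sim, panel, ld_mode, cfg$window,
                     seed = sub_seed(seed, 3 * r + 2))
    genomewide_max(prof$windows)
  }, 0)
  structure(list(maxima = maxima,
                 threshold = critical_value(maxima, cfg$alpha),
                 alpha = cfg$alpha, ld_mode = ld_mode, selection = selection,
                 n_reps = n_reps, seed = seed),
            class = "threshold_set")
}

# seed SNPs at first/last generation and build the dz2 profile
scan_sim <- function(sim, panel, ld_mode, window, seed = NULL) {
  snps <- seed_snps(sim, panel, ld_mode, seed = seed)
  g0 <- snps[[1]]$geno
  g1 <- snps[[length(snps)]]$geno
  dz2_profile(g0, g1, snps[[1]]$sites, window, sim$map)
}

#' Scan simulated or external VCFs and call peaks
#'
#' Chains the scan and significance stages: delta-z-squared profiles per
#' line, thresholds from [simulate_threshold_set()], [call_peaks()], a
#' parallelism report between the first two selected lines, and a summary
#' table (rank, span, peak, core, delta-q per line, specificity class).  A
#' peak is classified `Parallel` when both selected lines are significant
#' over overlapping spans, line-specific otherwise.
#'
#' @param vcf_pairs named list per line: `c(f0 = path, f17 = path)`.
#' @param cfg a [run_config()].
#' @param thresholds optional named numeric (per line) or a single value;
#'   computed by simulation when NULL.
#' @param out_dir optional directory for BED/TSV/BEDGRAPH outputs.
#' @return list: `profiles`, `thresholds`, `peaks` (per line), `summary`,
#'   `parallelism` (NULL with a message when < 2 selected lines).
#' @export
cmd_scan_and_call <- function(vcf_pairs, cfg, thresholds = NULL,
                              out_dir = NULL) {
  map <- cfg_map(cfg)
  profiles <- lapply(vcf_pairs, function(p) {
    a <- read_genotypes(p[[1]])
    b <- read_genotypes(p[[2]])
    dz2_profile(a$geno, b$geno, a$sites, cfg$window, map)
  })
  if (is.null(thresholds)) {
    ts <- simulate_threshold_set(cfg)
    thresholds <- stats::setNames(rep(ts$threshold, length(profiles)),
                                  names(profiles))
  } else if (length(thresholds) == 1) {
    thresholds <- stats::setNames(rep(thresholds, length(profiles)),
                                  names(profiles))
  }
  peaks <- lapply(names(profiles), function(ln) {
    # small designs can push the simulated threshold below the default
    # hitchhiking stop level; the stop can never exceed the threshold
    call_peaks(profiles[[ln]]$windows, profiles[[ln]]$sites, thresholds[[ln]],
               stop = min(0.2 * pi^2, thresholds[[ln]]))
  })
  names(peaks) <- names(profiles)

  selected <- names(cfg$lines)[cfg$lines != "random"]
  selected <- intersect(selected, names(profiles))
  parallelism <- NULL
  if (length(selected) >= 2) {
    a <- selected[1]
    b <- selected[2]
    sa <- sig_windows(profiles[[a]]$windows, thresholds[[a]])
    sb <- sig_windows(profiles[[b]]$windows, thresholds[[b]])
    parallelism <- parallelism_chisq(sa, sb)
    parallelism$profile_r <- profile_correlation(profiles[[a]]$windows,
                                                 profiles[[b]]$windows)$r
  } else {
    message("parallelism report skipped: fewer than 2 selected lines")
  }
  summary <- peak_summary(peaks, profiles, thresholds, selected)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ln in names(profiles)) {
      write_track(profiles[[ln]]$windows,
                  file.path(out_dir, paste0(ln, "_dz2.bedgraph")), "bedgraph")
      utils::write.table(peaks[[ln]], file.path(out_dir, paste0(ln, "_peaks.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(summary, file.path(out_dir, "peak_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(profiles = profiles, thresholds = thresholds, peaks = peaks,
       summary = summary, parallelism = parallelism)
}

sig_windows <- function(windows, threshold) {
  !is.na(windows$dz2) & windows$dz2 >= threshold
}

# Table-1-like summary across lines: every peak of every line, annotated
# with per-line delta-q over its core span and a specificity class
peak_summary <- function(peaks, profiles, thresholds, selected) {
  rows <- list()
  for (ln in names(peaks)) {
    pk <- peaks[[ln]]
    if (!nrow(pk)) next
    for (i in seq_len(nrow(pk))) {
      dq <- vapply(names(profiles), function(l2) {
        s <- profiles[[l2]]$sites
        in_core <- s$chrom == pk$chrom[i] & s$pos - 1 >= pk$core_start[i] &
          s$pos - 1 < pk$core_end[i]
        if (!any(in_core)) return(NA_real_)
        mean(s$q1[in_core] - s$q0[in_core])
      }, 0)
      other <- setdiff(selected, ln)
      type <- if (ln %in% selected && length(other)) {
        hit <- vapply(other, function(l2) {
          pk2 <- peaks[[l2]]
          any(pk2$chrom == pk$chrom[i] & pk2$span_start < pk$span_end[i] &
                pk2$span_end > pk$span_start[i])
        }, TRUE)
        if (any(hit)) "Parallel" else paste0(ln, "-specific")
      } else paste0(ln, "-specific")
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(line = ln), pk[i, ],
        stats::setNames(as.data.frame(as.list(dq)), paste0("dq_", names(dq))),
        data.frame(type = type))
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
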