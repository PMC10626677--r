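#' Built-in simulation studies
#'
#' Pre-defined desk-scale simulation studies used to calibrate and validate
#' the four scans; the same study definitions back the package's tests and
#' the reproduction script.  Parameter choices are discussed in the methods
#' vignette: hard sweeps are simulated at `2Ns = 200` (N = 1000, s = 0.1)
#' so the sweep duration is short on the coalescent timescale, with
#' `r/mu = 4` giving a sweep footprint of roughly 130 kb; ROH-prone data
#' use a small population (N = 100) with a livestock-like per-bp
#' recombination rate so multi-Mb autozygous segments occur.
#'
#' @name studies
NULL

#' Neutral calibration study for iHS/nSL standardisation
#'
#' Simulates `n_chrom` neutral chromosomes and returns the standardised
#' iHS and nSL scores plus their Kolmogorov-Smirnov distances from the
#' standard normal.
#'
#' @param seed master seed.
#' @param n_chrom number of 2 Mb chromosomes (default 8).
#' @return list with `ihs_std`, `nsl_std`, `ks_ihs`, `ks_nsl`, `n_scored`.
#' @export
calibration_study_haplo <- function(seed = 1L, n_chrom = 10) {
  p <- sim_params(n_diploids = 50, seq_length_bp = 2e6, mu = 2.5e-7,
                  r = 2.5e-7, pop_size_N = 200, s = 0, seed = seed)
  d <- sim_study_dataset(n_chrom = n_chrom, params = p, seed = seed)
  ih <- haplo_stage(d$haps, d$variants, "ihs")
  ns <- haplo_stage(d$haps, d$variants, "nsl")
  ihs_std <- ih$track$std[!is.na(ih$track$std)]
  nsl_std <- ns$track$std[!is.na(ns$track$std)]
  ks <- function(x) suppressWarnings(
    stats::ks.test(x, "pnorm")$statistic[[1]])
  list(ihs_std = ihs_std, nsl_std = nsl_std,
       ks_ihs = ks(ihs_std), ks_nsl = ks(nsl_std),
       n_scored = min(length(ihs_std), length(nsl_std)))
}

#' Neutral calibration study for eROHi outlier rates
#'
#' Simulates ROH-prone neutral data (small population, livestock-like
#' recombination rate, long chromosomes) and measures the fraction of SNPs
#' called eROHi outliers (`-log10 P >= 4`) per replicate.
#'
#' @param seed master seed.
#' @param n_reps replicates (default 20).
#' @param n_chrom chromosomes per replicate (default 2).
#' @return list with per-replicate `outlier_fraction` and its mean.
#' @export
calibration_study_roh <- function(seed = 1L, n_reps = 20, n_chrom = 2) {
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_reps)
  frac <- vapply(rep_seeds, function(s) {
    p <- sim_params(n_diploids = 25, seq_length_bp = 1e7, mu = 1e-7,
                    r = 1e-8, pop_size_N = 100, s = 0, seed = s)
    d <- sim_study_dataset(n_chrom = n_chrom, params = p, seed = s)
    runs <- detect_roh_all(d$geno, d$variants)
    inc <- suppressWarnings(
      eroi_scores(roh_incidence(runs, d$variants, nrow(d$geno))))
    mean(inc$neglog10p >= 4)
  }, 0)
  list(outlier_fraction = frac, mean_fraction = mean(frac))
}

sweep_rep_params <- function(seed, s = 0.1) {
  sim_params(n_diploids = 50, seq_length_bp = 2e6, mu = 2.5e-8, r = 1e-7,
             pop_size_N = 1000, s = s, target_freq = 1, seed = seed)
}

#' One sweep-recovery replicate
#'
#' Simulates one 2 Mb chromosome (hard sweep at the midpoint, or neutral),
#' runs all four scans with footprint-scaled ROH parameters, and reports
#' the CLR argmax position and whether a >= 2-method consensus region
#' contains the sweep position.
#'
#' @param seed replicate seed.
#' @param sweep simulate a sweep (TRUE) or matched neutral data (FALSE).
#' @param s selection coefficient for sweep replicates.
#' @param grid_size CLR grid points (default 250).
#' @return list with `clr_argmax_bp`, `clr_max`, `neutral_clr_mean`,
#'   `sweep_pos_bp`, `consensus_hit`, `n_consensus`.
#' @export
recovery_replicate <- function(seed, sweep = TRUE, s = 0.1,
                               grid_size = 250) {
  p <- sweep_rep_params(seed, s = if (sweep) s else 0)
  d <- if (sweep) simulate_sweep(p) else simulate_neutral(p)
  target <- p$sweep_pos_bp
  geno <- haps_to_geno(d$haps)
  # ROH parameters scaled to the simulated sweep footprint (~130 kb)
  rp <- roh_params(min_length_bp = 1e5, min_snps = 10, max_gap_bp = 1e5,
                   min_density_snp_per_bp = 1 / 2e4)
  runs <- detect_roh_all(geno, d$variants, rp)
  inc <- suppressWarnings(
    eroi_scores(roh_incidence(runs, d$variants, nrow(geno))))
  roh_reg <- call_eroi_regions(inc)
  ih <- haplo_stage(d$haps, d$variants, "ihs")
  ns <- haplo_stage(d$haps, d$variants, "nsl")
  pol <- polarize_haps(d$haps, d$variants)
  counts <- colSums(pol$haps)
  sfs <- empirical_sfs(counts, nrow(d$haps))
  g <- clr_scan(d$variants, counts, sfs, grid_size = grid_size)
  thr <- empirical_threshold(g, top_fraction = 2 / grid_size)
  cons <- build_consensus(list(roh_reg, ih$regions, ns$regions,
                               thr$regions))
  hit <- nrow(cons) > 0 &&
    any(cons$start_bp <= target & cons$end_bp >= target)
  list(clr_argmax_bp = g$grid_pos[which.max(g$lambda)],
       clr_max = max(g$lambda),
       clr_mean = mean(g$lambda),
       sweep_pos_bp = target,
       consensus_hit = hit,
       n_consensus = nrow(cons))
}

#' Sweep parameter-recovery study
#'
#' Runs `n_reps` hard-sweep replicates and `n_reps` matched neutral
#' replicates (see [recovery_replicate()]), summarising CLR localisation
#' and multi-method consensus power.
#'
#' @param seed master seed.
#' @param n_reps replicates per arm (default 30).
#' @param tol_bp CLR localisation tolerance (default 200 kb).
#' @return list with recovery proportions, consensus hit counts, and the
#'   one-sided proportion-test P value.
#' @export
recovery_study <- function(seed = 1L, n_reps = 30, tol_bp = 2e5) {
  set.seed(seed)
  sweep_seeds <- sample.int(2^31 - 2, n_reps)
  neut_seeds <- sample.int(2^31 - 2, n_reps)
  sw <- lapply(sweep_seeds, recovery_replicate, sweep = TRUE)
  nu <- lapply(neut_seeds, recovery_replicate, sweep = FALSE)
  err <- vapply(sw, function(r) abs(r$clr_argmax_bp - r$sweep_pos_bp), 0)
  hit_sw <- vapply(sw, function(r) r$consensus_hit, NA)
  hit_nu <- vapply(nu, function(r) r$consensus_hit, NA)
  pt <- stats::prop.test(c(sum(hit_sw), sum(hit_nu)),
                         c(n_reps, n_reps), alternative = "greater")
  list(clr_within_tol = mean(err <= tol_bp),
       clr_err_bp = err,
       sweep_clr_max = vapply(sw, function(r) r$clr_max, 0),
       neutral_clr_mean = mean(vapply(nu, function(r) r$clr_mean, 0)),
       consensus_hits_sweep = sum(hit_sw),
       consensus_hits_neutral = sum(hit_nu),
       n_reps = n_reps,
       prop_test_p = pt$p.value)
}
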