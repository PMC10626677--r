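#' Simulation parameters for the Wright-Fisher generator
#'
#' Bundles the parameters of a single simulated chromosome: a diploid
#' Wright-Fisher population of constant size `pop_size_N` evolves for a
#' burn-in of `8 * pop_size_N` discrete generations under infinite-sites
#' mutation (rate `mu` per bp per generation) and crossover recombination
#' (rate `r` per bp per generation); optionally a single positively selected
#' allele (additive fitness `1, 1+s, 1+2s`) is then introduced at
#' `sweep_pos_bp` and the trajectory is conditioned (by resampling) on the
#' allele reaching population frequency `target_freq`, after which
#' `n_diploids` individuals are sampled.
#'
#' @param n_diploids number of diploid individuals sampled.
#' @param seq_length_bp chromosome length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param r per-bp per-generation recombination rate.
#' @param pop_size_N diploid effective population size.
#' @param s selection coefficient of the sweep allele; 0 means neutral.
#' @param sweep_pos_bp focal position of the selected site (defaults to the
#'   chromosome midpoint).
#' @param target_freq required sweep-allele population frequency at sampling
#'   time, in (0, 1].
#' @param seed integer seed.
#' @param burnin_factor burn-in length in units of `pop_size_N` generations.
#' @param max_tries retry budget for sweep-trajectory conditioning.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_diploids = 50, seq_length_bp = 2e6, mu = 1e-8,
                       r = 1e-8, pop_size_N = 500, s = 0,
                       sweep_pos_bp = NULL, target_freq = 1, seed = 1L,
                       burnin_factor = 8, max_tries = 10000L) {
  if (is.null(sweep_pos_bp)) sweep_pos_bp <- floor(seq_length_bp / 2)
  p <- list(n_diploids = as.integer(n_diploids),
            seq_length_bp = as.numeric(seq_length_bp),
            mu = as.numeric(mu), r = as.numeric(r),
            pop_size_N = as.integer(pop_size_N), s = as.numeric(s),
            sweep_pos_bp = as.numeric(sweep_pos_bp),
            target_freq = as.numeric(target_freq), seed = as.integer(seed),
            burnin_factor = as.numeric(burnin_factor),
            max_tries = as.integer(max_tries))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$seq_length_bp <= 0) stop("seq_length_bp must be positive")
  if (p$mu <= 0 || p$r < 0) stop("mutation/recombination rates must be positive")
  if (p$n_diploids < 1 || p$n_diploids > p$pop_size_N)
    stop("n_diploids must be in [1, pop_size_N]")
  if (p$s < 0) stop("s must be >= 0")
  if (p$target_freq <= 0 || p$target_freq > 1)
    stop("target_freq must be in (0, 1]")
  if (p$sweep_pos_bp < 1 || p$sweep_pos_bp > p$seq_length_bp)
    stop("sweep_pos_bp outside the chromosome")
  invisible(p)
}

new_variant_table <- function(chrom, pos_bp, snp_id = NULL, allele_a = "A",
                              allele_b = "G", ancestral = "a") {
  n <- length(pos_bp)
  if (is.null(snp_id)) snp_id <- sprintf("snp_%s_%d", chrom, seq_len(n))
  data.frame(chrom = rep(as.character(chrom), n), pos_bp = as.numeric(pos_bp),
             snp_id = snp_id,
             allele_a = rep_len(allele_a, n), allele_b = rep_len(allele_b, n),
             ancestral = rep_len(ancestral, n), stringsAsFactors = FALSE)
}

run_wf <- function(params, chrom = "1") {
  p <- validate_sim_params(params)
  burnin <- as.integer(ceiling(p$burnin_factor * p$pop_size_N))
  max_sweep_gens <- as.integer(ceiling(500 / max(p$s, 0.01) +
                                         20 * p$pop_size_N))
  res <- wf_sim_cpp(p$n_diploids, p$seq_length_bp, p$mu, p$r, p$pop_size_N,
                    p$s, p$sweep_pos_bp - 0.5, p$target_freq, burnin,
                    p$max_tries, max_sweep_gens)
  if (!isTRUE(res$success))
    stop(sprintf("sweep conditioning failed after %d tries", res$tries))
  S <- length(res$pos_bp)
  # random ref/alt letters; allele a is the ancestral (absence-of-mutation)
  bases <- c("A", "C", "G", "T")
  aa <- sample(bases, S, replace = TRUE)
  bb <- vapply(aa, function(x) sample(setdiff(bases, x), 1L), "")
  variants <- new_variant_table(chrom, res$pos_bp, allele_a = aa,
                                allele_b = unname(bb), ancestral = "a")
  haps <- res$haps
  nh <- nrow(haps)
  samples <- data.frame(sample_id = sprintf("ind_%03d", seq_len(nh / 2)),
                        stringsAsFactors = FALSE)
  rownames(haps) <- paste0(rep(samples$sample_id, each = 2), c("_1", "_2"))
  truth <- list(chrom = as.character(chrom),
                sweep_pos_bp = p$sweep_pos_bp, s = p$s,
                realized_freq = res$sweep_count / res$n_haplotypes,
                focal_is_site = any(res$is_focal),
                focal_site_idx = if (any(res$is_focal)) which(res$is_focal)
                                 else NA_integer_,
                tries = res$tries,
                derived_counts = colSums(haps))
  list(haps = haps, variants = variants, samples = samples, truth = truth)
}

#' Simulate a neutral phased SNP dataset
#'
#' @param params a [sim_params()] object with `s = 0`.
#' @param chrom chromosome label for the output map.
#' @return list with `haps` (2n x S binary matrix, 1 = derived), `variants`
#'   (variant table), `samples`, and `truth` (simulation sidecar).
#' @export
simulate_neutral <- function(params, chrom = "1") {
  if (params$s != 0) stop("simulate_neutral requires s = 0")
  set.seed(params$seed)
  run_wf(params, chrom)
}

#' Simulate a hard selective sweep
#'
#' Forward Wright-Fisher with a single selected site; trajectories are
#' resampled (from the same standing variation) until the sweep allele
#' reaches `target_freq`, within the `max_tries` retry budget.
#'
#' @inheritParams simulate_neutral
#' @export
simulate_sweep <- function(params, chrom = "1") {
  if (params$s <= 0) stop("simulate_sweep requires s > 0")
  set.seed(params$seed)
  run_wf(params, chrom)
}

#' Collapse phased haplotypes to diploid dosages
#'
#' @param haps 2n x S binary haplotype matrix (rows 2i-1, 2i belong to
#'   individual i).
#' @return n x S matrix of allele-b dosages in 0/1/2.
#' @export
haps_to_geno <- function(haps) {
  n <- nrow(haps) / 2
  g <- haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
    haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(g) <- sub("_1$", "", rownames(haps)[seq(1, 2 * n, by = 2)])
  g
}

#' Add QC stressors to a genotype matrix
#'
#' Sets a uniform random fraction of genotype calls to missing and appends
#' duplicate individuals and Mendelian parent-child composites (one allele
#' drawn from the parent, one from the population frequencies), with flagged
#' IDs, to exercise the call-rate and relatedness filters.
#'
#' @param geno samples x variants dosage matrix (0/1/2/NA).
#' @param missing_rate fraction of calls set missing, in `[0, 1)`.
#' @param n_duplicates,n_parent_child number of duplicate / offspring
#'   individuals appended.
#' @param seed integer seed.
#' @return list with the degraded `geno` and a `samples` data frame whose
#'   `relation`/`source_id` columns flag the constructed individuals.
#' @export
degrade <- function(geno, missing_rate = 0, n_duplicates = 0,
                    n_parent_child = 0, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  set.seed(seed)
  samples <- data.frame(sample_id = rownames(geno),
                        relation = "original",
                        source_id = NA_character_,
                        stringsAsFactors = FALSE)
  p_b <- colMeans(geno, na.rm = TRUE) / 2
  add <- list()
  if (n_duplicates > 0) {
    src <- sample(nrow(geno), n_duplicates, replace = n_duplicates > nrow(geno))
    for (k in seq_len(n_duplicates)) {
      row <- geno[src[k], , drop = TRUE]
      add[[length(add) + 1L]] <- list(row = row, relation = "duplicate",
                                      source = rownames(geno)[src[k]],
                                      id = sprintf("dup_%02d", k))
    }
  }
  if (n_parent_child > 0) {
    src <- sample(nrow(geno), n_parent_child,
                  replace = n_parent_child > nrow(geno))
    for (k in seq_len(n_parent_child)) {
      par <- geno[src[k], , drop = TRUE]
      transmitted <- ifelse(is.na(par), NA,
                            ifelse(par == 2, 1L,
                                   ifelse(par == 0, 0L,
                                          rbinom(length(par), 1L, 0.5))))
      other <- rbinom(length(par), 1L, p_b)
      add[[length(add) + 1L]] <- list(row = transmitted + other,
                                      relation = "child",
                                      source = rownames(geno)[src[k]],
                                      id = sprintf("child_%02d", k))
    }
  }
  if (length(add)) {
    extra <- do.call(rbind, lapply(add, `[[`, "row"))
    rownames(extra) <- vapply(add, `[[`, "", "id")
    geno <- rbind(geno, extra)
    samples <- rbind(samples,
                     data.frame(sample_id = vapply(add, `[[`, "", "id"),
                                relation = vapply(add, `[[`, "", "relation"),
                                source_id = vapply(add, `[[`, "", "source"),
                                stringsAsFactors = FALSE))
  }
  if (missing_rate > 0) {
    drop <- runif(length(geno)) < missing_rate
    geno[drop] <- NA
  }
  list(geno = geno, samples = samples)
}

#' Simulate a multi-chromosome study-shaped dataset
#'
#' Chromosomes are simulated independently (each with its own seed derived
#' from `seed`) and concatenated, emulating a per-chromosome analysis of a
#' SNP-array dataset.  `sweep_chroms` selects which chromosomes carry a hard
#' sweep at `sweep_pos_bp`.
#'
#' @param n_chrom number of chromosomes.
#' @param params template [sim_params()]; its `s`/`target_freq` are applied
#'   on sweep chromosomes only.
#' @param sweep_chroms integer vector of chromosome indices carrying sweeps.
#' @param seed master seed.
#' @return list with `haps`, `geno`, `variants`, `samples`, `truth` (one
#'   truth record per chromosome).
#' @export
sim_study_dataset <- function(n_chrom = 2, params = sim_params(),
                              sweep_chroms = integer(0), seed = 1L) {
  set.seed(seed)
  chrom_seeds <- sample.int(2^31 - 2, n_chrom)
  out_h <- list(); out_v <- list(); out_t <- list()
  for (ch in seq_len(n_chrom)) {
    p <- params
    p$seed <- chrom_seeds[ch]
    if (!(ch %in% sweep_chroms)) { p$s <- 0; p$target_freq <- 1 }
    res <- if (p$s > 0) simulate_sweep(p, chrom = as.character(ch))
           else simulate_neutral(p, chrom = as.character(ch))
    out_h[[ch]] <- res$haps
    out_v[[ch]] <- res$variants
    out_t[[ch]] <- res$truth
    samples <- res$samples
  }
  haps <- do.call(cbind, out_h)
  variants <- do.call(rbind, out_v)
  variants$snp_id <- sprintf("snp%06d", seq_len(nrow(variants)))
  list(haps = haps, geno = haps_to_geno(haps), variants = variants,
       samples = samples, truth = out_t)
}

#' Mean pairwise nucleotide diversity per bp
#'
#' @param haps binary haplotype matrix.
#' @param seq_length_bp chromosome length in bp.
#' @export
nucleotide_diversity <- function(haps, seq_length_bp) {
  nh <- nrow(haps)
  j <- colSums(haps)
  sum(2 * j * (nh - j) / (nh * (nh - 1))) / seq_length_bp
}
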