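# Small in-code fixtures shared across test files.

random_haps <- function(n_hap, n_snp, seed, p = NULL) {
  set.seed(seed)
  if (is.null(p)) p <- runif(n_snp, 0.1, 0.9)
  m <- vapply(p, function(pp) rbinom(n_hap, 1L, pp), integer(n_hap))
  storage.mode(m) <- "integer"
  m
}

random_dosage_chrom <- function(n_snp, seed, span_bp = 3e6) {
  set.seed(seed)
  pos <- sort(sample.int(span_bp, n_snp))
  dosage <- sample(c(0L, 1L, 2L, NA), n_snp, replace = TRUE,
                   prob = c(0.45, 0.08, 0.45, 0.02))
  list(dosage = dosage, pos = pos)
}

# HWE genotype matrix from given allele-b frequencies (independent sites).
hwe_geno <- function(n_ind, freqs, seed) {
  set.seed(seed)
  g <- vapply(freqs, function(p) rbinom(n_ind, 2L, p), integer(n_ind))
  rownames(g) <- sprintf("ind_%03d", seq_len(n_ind))
  g
}

toy_variants <- function(pos, chrom = "1") {
  data.frame(chrom = chrom, pos_bp = pos,
             snp_id = sprintf("s%03d", seq_along(pos)),
             allele_a = "A", allele_b = "G", ancestral = "a",
             stringsAsFactors = FALSE)
}

small_sim <- function(seed = 1, s = 0, n = 30, N = 100, L = 1e6,
                      mu = 1e-7, r = 1e-7, target = 1) {
  p <- sim_params(n_diploids = n, seq_length_bp = L, mu = mu, r = r,
                  pop_size_N = N, s = s, target_freq = target, seed = seed)
  if (s > 0) simulate_sweep(p) else simulate_neutral(p)
}
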