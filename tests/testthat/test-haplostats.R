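test_that("EHH is 1 over identical carriers and 0 when all differ", {
  # 4 derived carriers identical everywhere; 4 ancestral all distinct at
  # the adjacent SNP
  haps <- rbind(matrix(rep(c(1, 1, 1, 1, 1), 4), 4, byrow = TRUE),
                cbind(rep(0, 4), c(0, 1, 0, 1), c(0, 0, 1, 1),
                      c(1, 0, 0, 1), c(0, 1, 1, 0)))
  storage.mode(haps) <- "integer"
  pos <- 1:5 * 1000
  der <- ehh(haps, pos, focal_idx = 1, core_allele = 1, cutoff = 0)
  expect_equal(der$ehh, rep(1, 5))
  anc <- ehh(haps, pos, focal_idx = 1, core_allele = 0)
  expect_equal(anc$ehh[1], 1)
  expect_equal(anc$ehh[2], 1 / 3) # two identical pairs of four carriers
  # by the second flank all four carrier haplotypes are distinct
  expect_equal(anc$ehh[3], 0)
  # two carriers differing at the adjacent SNP: EHH drops to 0 at once
  two <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  expect_equal(ehh(two, c(100, 200), 1, 0)$ehh[2], 0)
  expect_error(ehh(haps[1:4, ], pos, 1, 0), "carriers")
})

test_that("EHH equals the all-pairs oracle on random fixtures", {
  for (fix in 1:60) {
    haps <- random_haps(8, 12, seed = fix + 1000)
    pos <- sort(sample.int(5e5, 12))
    for (allele in 0:1) {
      focal <- 6
      if (sum(haps[, focal] == allele) < 2) next
      got <- ehh(haps, pos, focal, allele, cutoff = 0, max_gap_bp = Inf)
      want <- oracle_ehh(haps, pos, focal, allele)
      expect_equal(got$ehh, want, tolerance = 1e-12,
                   info = paste("fixture", fix, "allele", allele))
    }
  }
})

test_that("EHH truncates at the cutoff and at large gaps", {
  haps <- random_haps(10, 20, seed = 2100)
  pos <- c(1:10 * 1000, 3e5 + 1:10 * 1000) # a 290 kb gap in the middle
  got <- ehh(haps, pos, focal_idx = 5, core_allele = haps[1, 5],
             cutoff = 0, max_gap_bp = 2e5)
  expect_true(all(is.na(got$ehh[11:20]))) # never crosses the gap
})

test_that("mirror-image haplotype structure gives raw iHS of zero", {
  blk <- random_haps(4, 9, seed = 5)
  haps <- rbind(cbind(blk[, 1:4], 1L, blk[, 6:9]),
                cbind(blk[, 1:4], 0L, blk[, 6:9]))
  pos <- sort(sample.int(1e5, 9))
  tr <- ihs_scan(haps, toy_variants(pos), maf_min = 0.05)
  expect_equal(tr$raw[5], 0, tolerance = 1e-12)
})

test_that("swapping ancestral and derived labels flips the iHS sign", {
  haps <- random_haps(20, 15, seed = 6)
  pos <- sort(sample.int(2e5, 15))
  v <- toy_variants(pos)
  t1 <- ihs_scan(haps, v)
  hf <- haps; hf[, 8] <- 1L - hf[, 8]
  t2 <- ihs_scan(hf, v)
  if (!is.na(t1$raw[8]) && !is.na(t2$raw[8]))
    expect_equal(t1$raw[8], -t2$raw[8], tolerance = 1e-12)
  expect_false(all(is.na(t1$raw)))
})

test_that("nSL pair lengths: identical haplotypes span all sites", {
  m <- 9
  base <- random_haps(4, m, seed = 7)
  hd <- rep(1L, m) # two identical derived haplotypes
  haps <- rbind(hd, hd, cbind(base[, 1:4], 0L, base[, 6:9]))
  pos <- 1:m * 1000
  tr <- nsl_scan(haps, toy_variants(pos), maf_min = 0.05)
  # SL_D is the all-pairs mean over the two derived carriers: exactly m
  sl <- exp(-tr$raw[5]) * oracle_sl_mean(haps, pos, 5, 0)
  expect_equal(sl, m, tolerance = 1e-9)
})

test_that("nSL equals the exhaustive all-pairs computation", {
  for (fix in 1:60) {
    haps <- random_haps(6, 10, seed = fix + 3000)
    pos <- sort(sample.int(3e5, 10))
    v <- toy_variants(pos)
    tr <- nsl_scan(haps, v, maf_min = 0, max_gap_bp = 2e5,
                   gap_scale_bp = 2e4)
    for (focal in c(3, 5, 8)) {
      if (tr$skip_code[focal] != 0) next
      want <- log(oracle_sl_mean(haps, pos, focal, 0, 2e5, 2e4) /
                    oracle_sl_mean(haps, pos, focal, 1, 2e5, 2e4))
      expect_equal(tr$raw[focal], want, tolerance = 1e-12,
                   info = paste("fixture", fix, "focal", focal))
    }
  }
})

test_that("swapping labels flips the nSL sign", {
  haps <- random_haps(12, 14, seed = 8)
  pos <- sort(sample.int(1e5, 14))
  v <- toy_variants(pos)
  t1 <- nsl_scan(haps, v)
  hf <- haps; hf[, 7] <- 1L - hf[, 7]
  t2 <- nsl_scan(hf, v)
  if (!is.na(t1$raw[7]) && !is.na(t2$raw[7]))
    expect_equal(t1$raw[7], -t2$raw[7], tolerance = 1e-12)
})

test_that("partial sweeps drive raw iHS negative among hitchhiking SNPs", {
  # like-for-like comparison within the high-derived-frequency class:
  # near the sweep these SNPs ride the swept haplotype (long derived
  # EHH, raw << 0); at matched frequencies elsewhere they are old alleles
  near_vs_far <- vapply(81:84, function(seed) {
    p <- sweepstack:::sweep_rep_params(seed, s = 0.1)
    p$target_freq <- 0.8
    d <- simulate_sweep(p)
    pol <- polarize_haps(d$haps, d$variants)
    tr <- ihs_scan(pol$haps, d$variants)
    hf <- tr$freq_derived > 0.7 & tr$freq_derived < 0.9 & !is.na(tr$raw)
    near <- abs(tr$pos_bp - d$truth$sweep_pos_bp) <= 1e5
    c(mean(tr$raw[hf & near]), mean(tr$raw[hf & !near]))
  }, numeric(2))
  expect_lt(mean(near_vs_far[1, ], na.rm = TRUE),
            mean(near_vs_far[2, ], na.rm = TRUE))
  # and the focal-region signal is substantial, not just ordered
  expect_lt(mean(near_vs_far[1, ], na.rm = TRUE), -0.5)
})

test_that("standardisation centres and scales within frequency bins", {
  set.seed(9)
  raw <- rnorm(5000, mean = 2, sd = 3)
  freq <- runif(5000, 0.05, 0.95)
  std <- standardize_scores(raw, freq, n_bins = 100)
  bin <- ceiling(freq * 100)
  for (b in unique(bin)[1:20]) {
    idx <- which(bin == b)
    if (length(idx) < 2) next
    expect_equal(mean(std[idx]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(std[idx]), 1, tolerance = 1e-10)
  }
  # single-bin degenerate case equals plain z-scoring
  std1 <- standardize_scores(raw, freq, n_bins = 1)
  expect_equal(std1, (raw - mean(raw)) / stats::sd(raw), tolerance = 1e-12)
  # idempotence
  std2 <- standardize_scores(std, freq, n_bins = 100)
  expect_equal(std2, std, tolerance = 1e-12)
})

test_that("two-tailed tail transform hits the reference values", {
  expect_equal(neglog_two_tailed_p(0), 0, tolerance = 1e-12)
  expect_equal(neglog_two_tailed_p(1.959964), 1.301, tolerance = 1e-3)
  expect_equal(neglog_two_tailed_p(3.890592), 4.000, tolerance = 1e-3)
  expect_equal(neglog_two_tailed_p(-3.890592), 4.000, tolerance = 1e-3)
})

test_that("window significance needs the minimum number of extreme SNPs", {
  track <- data.frame(chrom = "1",
                      pos_bp = c(1e5, 1.5e5, 2e5, 8e5, 8.5e5),
                      neglog10p = c(4.1, 4.1, 4.1, 4.2, 4.2))
  ws <- window_scan(track, window_bp = 5e5, step_bp = 1e5, threshold = 4,
                    min_hits = 3)
  expect_true(any(ws$windows$significant))
  # the two-hit cluster at 0.8 Mb is not significant on its own
  late <- ws$windows$start_bp >= 6e5
  expect_false(any(ws$windows$significant[late]))
  expect_equal(nrow(ws$regions), 1)
})

test_that("merged region bounds equal the union of flagged windows", {
  set.seed(10)
  for (rep in 1:20) {
    track <- data.frame(chrom = "1",
                        pos_bp = sort(sample.int(2e6, 120)),
                        neglog10p = sample(c(0, 5), 120, replace = TRUE,
                                           prob = c(0.8, 0.2)))
    ws <- window_scan(track, window_bp = 2e5, step_bp = 5e4,
                      threshold = 4, min_hits = 2)
    sig <- ws$windows[ws$windows$significant, ]
    if (nrow(sig) == 0) {
      expect_equal(nrow(ws$regions), 0)
      next
    }
    # brute-force union on a coarse bp grid
    covered <- rep(FALSE, 2e6 / 1e4 + 40)
    for (k in seq_len(nrow(sig))) {
      lo <- floor(sig$start_bp[k] / 1e4); hi <- ceiling(sig$end_bp[k] / 1e4)
      covered[lo:hi + 1] <- TRUE
    }
    runs <- rle(covered)
    expect_equal(nrow(ws$regions), sum(runs$values))
  }
})
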