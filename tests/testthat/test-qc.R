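test_that("HWE exact test matches full enumeration", {
  expect_equal(hwe_exact_p(25, 50, 25), oracle_hwe(25, 50, 25),
               tolerance = 1e-12)
  expect_lt(hwe_exact_p(50, 0, 50), 1e-4)
  expect_equal(hwe_exact_p(100, 0, 0), 1)
  expect_equal(hwe_exact_p(0, 0, 42), 1)
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(5:200, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact_p(nAA, nAa, naa), oracle_hwe(nAA, nAa, naa),
                 tolerance = 1e-12)
  }
})

test_that("qc_filter applies thresholds in order and logs removals", {
  # 6 individuals x 5 SNPs: SNP 2 monomorphic (below any MAF floor),
  # individual 3 missing 60% of calls
  g <- rbind(c(0, 0, 1, 2, 1),
             c(1, 0, 0, 1, 0),
             c(NA, NA, NA, 2, 1),
             c(2, 0, 1, 0, 2),
             c(1, 0, 2, 1, 1),
             c(0, 0, 1, 1, 0))
  rownames(g) <- sprintf("i%d", 1:6)
  v <- toy_variants(1:5 * 1000)
  s <- data.frame(sample_id = rownames(g), stringsAsFactors = FALSE)
  out <- qc_filter(g, v, s, snp_call = 0.95, ind_call = 0.90, maf = 0.01,
                   hwe_p = 0)
  expect_equal(nrow(out$geno), 5)
  expect_equal(ncol(out$geno), 4)
  rep <- out$report
  expect_equal(rep$removed[rep$filter == "individual_call_rate"], 1)
  expect_equal(rep$removed[rep$filter == "maf"], 1)
  # conservation on both axes
  expect_equal(rep$retained[rep$filter == "individual_call_rate"] +
                 rep$removed[rep$filter == "individual_call_rate"], 6)
  expect_equal(rep$retained[rep$filter == "maf"] +
                 rep$removed[rep$filter == "maf"], 5)
})

test_that("extreme thresholds pass everything through unchanged", {
  g <- hwe_geno(20, runif(50, 0.1, 0.9), seed = 12)
  g[sample(length(g), 30)] <- NA
  v <- toy_variants(seq_len(ncol(g)) * 500)
  s <- data.frame(sample_id = rownames(g), stringsAsFactors = FALSE)
  out <- qc_filter(g, v, s, snp_call = 0, ind_call = 0, maf = 0, hwe_p = 0)
  expect_identical(out$geno, g)
  expect_equal(sum(out$report$removed), 0)
})

test_that("qc_filter removal counts match an independent recount", {
  set.seed(13)
  g <- hwe_geno(80, runif(2000, 0.005, 0.5), seed = 13)
  g[runif(length(g)) < 0.05] <- NA
  v <- toy_variants(seq_len(ncol(g)) * 400)
  s <- data.frame(sample_id = rownames(g), stringsAsFactors = FALSE)
  out <- qc_filter(g, v, s)
  rep <- out$report
  # recount violations step by step with plain loops
  keep_i <- rowSums(!is.na(g)) / ncol(g) >= 0.90
  expect_equal(rep$removed[rep$filter == "individual_call_rate"],
               sum(!keep_i))
  g1 <- g[keep_i, ]
  keep_s <- colSums(!is.na(g1)) / nrow(g1) >= 0.95
  expect_equal(rep$removed[rep$filter == "snp_call_rate"], sum(!keep_s))
  g2 <- g1[, keep_s]
  p <- colMeans(g2, na.rm = TRUE) / 2
  keep_m <- pmin(p, 1 - p) >= 0.01
  expect_equal(rep$removed[rep$filter == "maf"], sum(!keep_m))
  g3 <- g2[, keep_m]
  keep_h <- vapply(seq_len(ncol(g3)), function(j)
    oracle_hwe(sum(g3[, j] == 0, na.rm = TRUE),
               sum(g3[, j] == 1, na.rm = TRUE),
               sum(g3[, j] == 2, na.rm = TRUE)) >= 1e-4, NA)
  expect_equal(rep$removed[rep$filter == "hwe"], sum(!keep_h))
  expect_equal(ncol(out$geno), sum(keep_h))
})

test_that("gencall filtering applies only when scores are supplied", {
  g <- hwe_geno(30, rep(0.5, 10), seed = 14)
  v <- toy_variants(1:10 * 1000)
  s <- data.frame(sample_id = rownames(g), stringsAsFactors = FALSE)
  scores <- c(rep(0.9, 8), 0.5, 0.6)
  out <- qc_filter(g, v, s, gencall_scores = scores, hwe_p = 0)
  expect_equal(out$report$removed[out$report$filter == "gencall_score"], 2)
  out2 <- qc_filter(g, v, s, hwe_p = 0)
  expect_match(out2$report$filter[3], "skipped")
})

test_that("PI_HAT recovers duplicates, unrelated pairs and parent-child", {
  freqs <- runif(10000, 0.1, 0.9)
  g <- hwe_geno(20, freqs, seed = 15)
  out <- degrade(g, n_duplicates = 1, n_parent_child = 1, seed = 16)
  ph <- ibd_pihat(out$geno)
  dup <- out$samples[out$samples$relation == "duplicate", ]
  chl <- out$samples[out$samples$relation == "child", ]
  pair_val <- function(a, b)
    ph$pihat[(ph$id1 == a & ph$id2 == b) | (ph$id1 == b & ph$id2 == a)]
  expect_gte(pair_val(dup$sample_id, dup$source_id), 0.95)
  expect_lt(abs(pair_val(chl$sample_id, chl$source_id) - 0.5), 0.1)
  unrel <- ph[ph$id1 == "ind_001" & ph$id2 == "ind_002", "pihat"]
  expect_lt(unrel, 0.1)
  # symmetric bounded table over all pairs
  expect_true(all(ph$pihat >= 0 & ph$pihat <= 1))
  expect_equal(nrow(ph), choose(22, 2))
})

test_that("pairs with too few informative SNPs are flagged unreliable", {
  g <- hwe_geno(4, runif(30, 0.3, 0.7), seed = 17)
  ph <- ibd_pihat(g, min_snps = 50)
  expect_true(all(ph$unreliable))
})

test_that("relatedness pruning removes the minimum necessary individuals", {
  tab <- data.frame(id1 = c("a", "x"), id2 = c("b", "y"),
                    pihat = c(0.9, 0.05))
  kept <- prune_related(tab, 0.18, sample_ids = c("a", "b", "x", "y"))
  expect_equal(sort(kept), c("a", "x", "y")) # drop the later-ID of the pair
  # nothing above threshold: all retained
  expect_equal(prune_related(tab[2, ], 0.18,
                             sample_ids = c("x", "y")), c("x", "y"))
  # 3-clique: two removals, matching the exhaustive minimum
  clique <- data.frame(id1 = c("a", "a", "b"), id2 = c("b", "c", "c"),
                       pihat = 0.5)
  kept3 <- prune_related(clique, 0.18, sample_ids = c("a", "b", "c"))
  expect_equal(length(kept3), 1)
  # exhaustive search over subsets on a random 8-individual graph
  set.seed(18)
  ids <- letters[1:8]
  pairs <- t(utils::combn(ids, 2))
  tabr <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2],
                     pihat = ifelse(runif(nrow(pairs)) < 0.25, 0.5, 0.01))
  keptr <- prune_related(tabr, 0.18, sample_ids = ids)
  edges <- tabr[tabr$pihat > 0.18, ]
  uncovered <- function(keep) !any(edges$id1 %in% keep & edges$id2 %in% keep)
  expect_true(uncovered(keptr))
  # no dropped individual can be restored without recreating a pair
  for (dropped in setdiff(ids, keptr))
    expect_false(uncovered(c(keptr, dropped)))
})

test_that("LD decay reports perfect correlation for duplicated SNPs", {
  set.seed(19)
  x <- rbinom(40, 2, 0.4)
  g <- cbind(x, x, rbinom(40, 2, 0.5))
  v <- toy_variants(c(1000, 51000, 141000))
  ld <- ld_decay(g, v, max_dist_bp = 2e5, n_bins = 4)
  # only the duplicated pair falls in bin 1
  expect_equal(ld$mean_r2[1], 1)
  expect_equal(ld$n_pairs, c(1L, 1L, 1L, 0L))
})

test_that("independent SNPs sit at the 1/(n-1) correlation floor", {
  n <- 50
  g <- hwe_geno(n, runif(400, 0.2, 0.8), seed = 20)
  v <- toy_variants(seq_len(ncol(g)) * 100)
  ld <- ld_decay(g, v, max_dist_bp = 5e4, n_bins = 1)
  expect_lt(abs(ld$mean_r2[1] - 1 / (n - 1)), 0.01)
})

test_that("LD decays with distance on recombining neutral simulations", {
  first <- numeric(0); last <- numeric(0)
  for (seed in 1:20) {
    d <- small_sim(seed = seed + 300, n = 25, N = 100, L = 5e5, mu = 2e-7,
                   r = 2e-7)
    ld <- ld_decay(haps_to_geno(d$haps), d$variants, max_dist_bp = 2e5,
                   n_bins = 4)
    first <- c(first, ld$mean_r2[1]); last <- c(last, ld$mean_r2[4])
  }
  expect_gt(mean(first, na.rm = TRUE), mean(last, na.rm = TRUE))
})
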