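#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact P value for deviation from Hardy-Weinberg proportions:
#' conditioning on the observed allele counts, the probabilities of all
#' heterozygote counts no more probable than the observed one are summed.
#' A site where one allele is absent returns P = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact P value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotypes")
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n_aa + n_Aa
  if (nA == 0 || nB == 0) return(1)
  # P(het = h | allele counts), h over the parity class of nA
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  lp <- lgamma(n + 1) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((nB - hs) / 2 + 1) + hs * log(2) +
    lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Apply the standard SNP-array QC chain
#'
#' Filters are applied in a fixed, logged order: individual call rate, SNP
#' call rate, (optional) per-SNP GenCall score, minor allele frequency, and
#' the exact Hardy-Weinberg test.
#'
#' @param geno samples x variants dosage matrix (0/1/2/NA).
#' @param variants,samples matching variant/sample tables.
#' @param snp_call minimum SNP call rate (default 0.95).
#' @param ind_call minimum individual call rate (default 0.90).
#' @param maf minimum minor allele frequency (default 0.01); SNPs strictly
#'   below are removed.
#' @param hwe_p minimum exact HWE P value (default 1e-4); SNPs strictly
#'   below are removed.
#' @param gencall_scores optional per-SNP score vector; when supplied, SNPs
#'   with score < `gencall_min` are removed (skipped and logged otherwise).
#' @param gencall_min GenCall score threshold (default 0.7).
#' @return list with filtered `geno`, `variants`, `samples` and a
#'   `qc_report` (ordered filter log with removal counts).
#' @export
qc_filter <- function(geno, variants, samples, snp_call = 0.95,
                      ind_call = 0.90, maf = 0.01, hwe_p = 1e-4,
                      gencall_scores = NULL, gencall_min = 0.7) {
  stopifnot(nrow(geno) == nrow(samples), ncol(geno) == nrow(variants))
  log <- list()
  note <- function(filter, axis, removed, retained)
    data.frame(filter = filter, axis = axis, removed = removed,
               retained = retained, stringsAsFactors = FALSE)

  keep_i <- rowMeans(!is.na(geno)) >= ind_call
  log[[1]] <- note("individual_call_rate", "sample", sum(!keep_i),
                   sum(keep_i))
  geno <- geno[keep_i, , drop = FALSE]
  samples <- samples[keep_i, , drop = FALSE]

  keep_s <- colMeans(!is.na(geno)) >= snp_call
  log[[2]] <- note("snp_call_rate", "snp", sum(!keep_s), sum(keep_s))
  geno <- geno[, keep_s, drop = FALSE]
  variants <- variants[keep_s, , drop = FALSE]
  if (!is.null(gencall_scores)) gencall_scores <- gencall_scores[keep_s]

  if (!is.null(gencall_scores)) {
    keep_g <- gencall_scores >= gencall_min
    log[[length(log) + 1]] <- note("gencall_score", "snp", sum(!keep_g),
                                   sum(keep_g))
    geno <- geno[, keep_g, drop = FALSE]
    variants <- variants[keep_g, , drop = FALSE]
  } else {
    log[[length(log) + 1]] <- note("gencall_score (skipped: no scores)",
                                   "snp", 0L, ncol(geno))
  }

  p <- colMeans(geno, na.rm = TRUE) / 2
  maf_obs <- pmin(p, 1 - p)
  keep_m <- !is.na(maf_obs) & maf_obs >= maf
  log[[length(log) + 1]] <- note("maf", "snp", sum(!keep_m), sum(keep_m))
  geno <- geno[, keep_m, drop = FALSE]
  variants <- variants[keep_m, , drop = FALSE]

  hw <- vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    hwe_exact_p(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
  }, 0)
  keep_h <- hw >= hwe_p
  log[[length(log) + 1]] <- note("hwe", "snp", sum(!keep_h), sum(keep_h))
  geno <- geno[, keep_h, drop = FALSE]
  variants <- variants[keep_h, , drop = FALSE]

  if (ncol(geno) == 0) stop("QC removed all SNPs")
  report <- do.call(rbind, log)
  class(report) <- c("qc_report", class(report))
  list(geno = geno, variants = variants, samples = samples, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC filter log (applied in order):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Pairwise identity-by-descent (PI_HAT) by method of moments
#'
#' Classic identity-by-state method-of-moments estimator: for each pair the
#' probabilities of sharing 0/1/2 alleles IBD are solved from the observed
#' IBS counts and their expectations under the sample allele frequencies;
#' `PI_HAT = P(IBD=2) + P(IBD=1)/2`, clamped to `[0, 1]`.  Missing
#' genotypes are excluded pairwise; pairs with fewer than `min_snps`
#' informative SNPs are flagged unreliable.
#'
#' @param geno samples x variants dosage matrix.
#' @param min_snps minimum informative SNPs per pair (default 50).
#' @return data frame with `id1`, `id2`, `pihat`, `n_snps`, `unreliable`.
#' @export
ibd_pihat <- function(geno, min_snps = 50) {
  n <- nrow(geno)
  if (n < 2) stop("need at least two individuals")
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("ind_%03d", seq_len(n))
  p <- colMeans(geno, na.rm = TRUE) / 2
  q <- 1 - p
  ok <- !is.na(p) & p > 0 & p < 1
  X <- geno[, ok, drop = FALSE]
  p <- p[ok]; q <- q[ok]
  M <- (!is.na(X)) * 1
  A0 <- (!is.na(X) & X == 0) * 1
  A1 <- (!is.na(X) & X == 1) * 1
  A2 <- (!is.na(X) & X == 2) * 1
  ibs0 <- A0 %*% t(A2) + A2 %*% t(A0)
  ibs2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  valid <- M %*% t(M)
  ibs1 <- valid - ibs0 - ibs2
  wsum <- function(w) M %*% t(sweep(M, 2, w, `*`)) # sum of w over shared SNPs
  e0_0 <- wsum(2 * p^2 * q^2)
  e1_0 <- wsum(4 * p^3 * q + 4 * p * q^3)
  e2_0 <- wsum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_1 <- wsum(2 * p * q)
  e2_1 <- wsum(1 - 2 * p * q)
  P0 <- ibs0 / e0_0
  P1 <- (ibs1 - P0 * e1_0) / e1_1
  P2 <- (ibs2 - P0 * e2_0 - P1 * e2_1) / valid
  P0 <- pmin(pmax(P0, 0), 1); P1 <- pmin(pmax(P1, 0), 1)
  P2 <- pmin(pmax(P2, 0), 1)
  tot <- P0 + P1 + P2
  pihat <- pmin(pmax((P2 + 0.5 * P1) / tot, 0), 1)
  ij <- which(upper.tri(pihat), arr.ind = TRUE)
  data.frame(id1 = ids[ij[, 1]], id2 = ids[ij[, 2]],
             pihat = pihat[ij], n_snps = valid[ij],
             unreliable = valid[ij] < min_snps, stringsAsFactors = FALSE)
}

#' Greedy relatedness pruning
#'
#' Repeatedly drops the individual involved in the most pairs with
#' `PI_HAT` above the threshold until no such pair remains.  Ties are
#' broken deterministically by dropping the individual latest in sample-ID
#' order.
#'
#' @param pihat_table output of [ibd_pihat()].
#' @param threshold PI_HAT cut-off; pairs strictly above are related
#'   (default 0.18).
#' @param sample_ids full sample-ID vector (defaults to IDs in the table).
#' @return character vector of retained sample IDs.
#' @export
prune_related <- function(pihat_table, threshold = 0.18, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sort(unique(c(pihat_table$id1, pihat_table$id2)))
  edges <- pihat_table[pihat_table$pihat > threshold, c("id1", "id2")]
  retained <- sample_ids
  while (nrow(edges) > 0) {
    deg <- table(c(edges$id1, edges$id2))
    worst <- names(deg)[deg == max(deg)]
    drop <- sort(worst, decreasing = TRUE)[1]
    retained <- setdiff(retained, drop)
    edges <- edges[edges$id1 != drop & edges$id2 != drop, , drop = FALSE]
  }
  retained
}

#' Linkage-disequilibrium decay summary
#'
#' Composite genotype-correlation r-squared for all intra-chromosome SNP
#' pairs within `max_dist_bp`, averaged in equal-width distance bins.
#' Zero-variance pairs are skipped.
#'
#' @param geno samples x variants dosage matrix.
#' @param variants variant table.
#' @param max_dist_bp maximum pair distance (default 1 Mb).
#' @param n_bins number of distance bins (default 20).
#' @return data frame with `bin_start`, `bin_end`, `n_pairs`, `mean_r2`.
#' @export
ld_decay <- function(geno, variants, max_dist_bp = 1e6, n_bins = 20) {
  width <- max_dist_bp / n_bins
  sums <- numeric(n_bins); counts <- integer(n_bins)
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    if (length(idx) < 2) next
    pos <- variants$pos_bp[idx]
    o <- order(pos); idx <- idx[o]; pos <- pos[o]
    G <- geno[, idx, drop = FALSE]
    sds <- apply(G, 2, stats::sd, na.rm = TRUE)
    for (i in seq_len(length(idx) - 1)) {
      if (is.na(sds[i]) || sds[i] == 0) next
      jmax <- findInterval(pos[i] + max_dist_bp, pos)
      if (jmax <= i) next
      js <- (i + 1):jmax
      js <- js[!is.na(sds[js]) & sds[js] > 0]
      if (!length(js)) next
      r <- suppressWarnings(
        stats::cor(G[, i], G[, js, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      d <- pos[js] - pos[i]
      b <- pmin(pmax(ceiling(d / width), 1L), n_bins)
      keep <- !is.na(r2)
      for (k in which(keep)) {
        sums[b[k]] <- sums[b[k]] + r2[k]
        counts[b[k]] <- counts[b[k]] + 1L
      }
    }
  }
  data.frame(bin_start = (seq_len(n_bins) - 1) * width,
             bin_end = seq_len(n_bins) * width,
             n_pairs = counts,
             mean_r2 = ifelse(counts > 0, sums / counts, NA_real_))
}
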