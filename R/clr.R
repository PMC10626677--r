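#' Empirical site frequency spectrum
#'
#' Normalised histogram of derived (or, folded, minor) allele counts across
#' all SNPs genome-wide; the null model of the composite likelihood ratio
#' scan.
#'
#' @param counts derived allele count per SNP (1..n-1).
#' @param n haplotype sample size.
#' @param folded fold to minor allele counts.
#' @return object of class `sfs`: list with `n`, `p` (probabilities for
#'   counts 1..n-1), `folded`.
#' @export
empirical_sfs <- function(counts, n, folded = FALSE) {
  counts <- counts[!is.na(counts)]
  if (!length(counts)) stop("no segregating sites")
  stopifnot(all(counts >= 1), all(counts <= n - 1))
  if (folded) counts <- pmin(counts, n - counts)
  p <- tabulate(counts, nbins = n - 1)
  p <- p / sum(p)
  structure(list(n = n, p = p, folded = folded), class = "sfs")
}

# P(i derived among m lineages drawn without replacement | background SFS),
# rows m = 1..n, columns i = 0..m (padded with NA).
downsample_sfs <- function(sfs) {
  n <- sfs$n
  Q <- matrix(NA_real_, n, n + 1)
  j <- seq_len(n - 1)
  for (m in seq_len(n)) {
    for (i in 0:m) {
      Q[m, i + 1] <- sum(sfs$p * stats::dhyper(i, j, n - j, m))
    }
  }
  Q
}

sweep_spectrum_impl <- function(sfs, p_e, Q = NULL) {
  n <- sfs$n
  if (is.null(Q)) Q <- downsample_sfs(sfs)
  pb <- numeric(n - 1)
  wk <- stats::dbinom(0:n, n, p_e)
  for (k in 0:n) {
    if (wk[k + 1] == 0) next
    if (k == n) { # all lineages escape: background spectrum
      pb <- pb + wk[k + 1] * sfs$p
      next
    }
    m <- k + 1
    for (i in 0:m) {
      qi <- Q[m, i + 1]
      if (qi == 0) next
      # the sweeping lineage is an exchangeable one of the m: derived w.p. i/m
      if (i > 0) {
        b1 <- (i - 1) + (n - k) # sweep lineage derived, expands to n-k copies
        if (b1 >= 1 && b1 <= n - 1)
          pb[b1] <- pb[b1] + wk[k + 1] * qi * i / m
      }
      if (i >= 1 && i <= n - 1)
        pb[i] <- pb[i] + wk[k + 1] * qi * (1 - i / m)
    }
  }
  pb / sum(pb)
}

#' Sweep-distorted allele frequency spectrum
#'
#' Hitchhiking model for the expected spectrum at a site a physical
#' distance `d_bp` from a just-completed sweep: each of the n lineages
#' escapes the sweep independently with probability
#' `p_e = 1 - exp(-alpha * d_bp)`; escapees carry frequencies drawn (without
#' replacement) from the background spectrum, non-escapees coalesce onto the
#' sweeping haplotype, and the result is renormalised over segregating
#' outcomes.
#'
#' @param background an [empirical_sfs()] object.
#' @param alpha sweep strength (per bp); larger alpha means a narrower
#'   footprint.
#' @param d_bp distance from the sweep site in bp.
#' @return probability vector over derived counts 1..n-1.
#' @export
sweep_spectrum <- function(background, alpha, d_bp) {
  stopifnot(inherits(background, "sfs"), alpha > 0, d_bp >= 0)
  p_e <- 1 - exp(-alpha * d_bp)
  sweep_spectrum_impl(background, p_e)
}

default_alpha_grid <- function(min_footprint_bp = 1e3) {
  # footprint half-widths (ln 2 / alpha) from ~10 Mb down to the
  # identifiability floor, plus a full-escape sentinel
  lo <- log(2) / 1e7
  hi <- max(log(2) / max(min_footprint_bp, 1e3), lo * 1.01)
  c(exp(seq(log(lo), log(hi), length.out = 40)), 1)
}

#' Composite likelihood ratio scan for selective sweeps
#'
#' SweepFinder-style scan: at each of `grid_size` evenly spaced test
#' positions per chromosome, the composite log likelihood of the observed
#' allele counts under the sweep-distorted spectrum (maximised over
#' `alpha_grid`) is compared with the background-spectrum null;
#' `lambda = 2 * (max_alpha l1 - l0)`, clamped at 0.
#'
#' @param variants variant table.
#' @param counts derived (or minor, if the background is folded) allele
#'   count per SNP.
#' @param background an [empirical_sfs()] built from the same dataset.
#' @param grid_size test positions per chromosome (default 10,000).
#' @param alpha_grid sweep-strength grid.  By default, 40 log-spaced
#'   values plus a full-escape sentinel, with footprint half-widths
#'   (`ln 2 / alpha`) spanning 10 Mb down to an identifiability floor of
#'   ten median inter-SNP spacings — a sweep footprint narrower than a
#'   few marker spacings cannot be distinguished from local noise on
#'   array-density data.
#' @param lr_factor likelihood-ratio convention factor (default 2).
#' @param new_mutation_weight mixture weight for the new-mutation
#'   adjustment: near the sweep a polymorphism may postdate the sweep and
#'   then follows the background spectrum rather than the escape model;
#'   each site's sweep likelihood is
#'   `(1 - w) * P_escape + w * P_background` (default 0.05).
#' @return data frame `chrom`, `grid_pos`, `lambda`, `alpha_hat`.
#' @export
clr_scan <- function(variants, counts, background, grid_size = 10000,
                     alpha_grid = NULL, lr_factor = 2,
                     new_mutation_weight = 0.05) {
  if (is.null(alpha_grid)) {
    spacing <- stats::median(unlist(lapply(
      split(variants$pos_bp, variants$chrom), diff)))
    alpha_grid <- default_alpha_grid(min_footprint_bp = 10 * spacing)
  }
  n <- background$n
  w_new <- new_mutation_weight
  # lookup table over x = alpha * d (p_e = 1 - exp(-x)); beyond x_max the
  # sweep spectrum is indistinguishable from the background
  x_max <- 13.8
  x_grid <- exp(seq(log(1e-6), log(x_max), length.out = 96))
  Q <- downsample_sfs(background)
  L <- t(vapply(x_grid, function(x) {
    ps <- sweep_spectrum_impl(background, 1 - exp(-x), Q)
    log(pmax((1 - w_new) * ps + w_new * background$p, 1e-300))
  }, numeric(n - 1)))
  log_p0 <- log(background$p)
  if (background$folded) counts <- pmin(counts, n - counts)
  out <- list()
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    if (!length(idx)) next
    pos <- variants$pos_bp[idx]
    b <- counts[idx]
    null_ll <- log_p0[b]
    grid_pos <- seq(min(pos), max(pos), length.out = grid_size)
    lam <- numeric(grid_size)
    ahat <- rep(NA_real_, grid_size)
    for (g in seq_len(grid_size)) {
      d <- abs(pos - grid_pos[g])
      best <- 0; best_a <- NA_real_
      for (a in alpha_grid) {
        x <- a * d
        inw <- which(x < x_max)
        if (!length(inw)) next
        x[inw] <- pmax(x[inw], x_grid[1])
        xi <- findInterval(x[inw], x_grid, all.inside = TRUE)
        x1 <- x_grid[xi]; x2 <- x_grid[xi + 1]
        w <- (x[inw] - x1) / (x2 - x1)
        cols <- cbind(xi, b[inw])
        cols2 <- cbind(xi + 1, b[inw])
        ll <- (1 - w) * L[cols] + w * L[cols2]
        delta <- sum(ll - null_ll[inw])
        if (delta > best) { best <- delta; best_a <- a }
      }
      lam[g] <- lr_factor * best
      ahat[g] <- best_a
    }
    out[[length(out) + 1L]] <-
      data.frame(chrom = ch, grid_pos = grid_pos, lambda = lam,
                 alpha_hat = ahat, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Empirical top-fraction threshold and regions
#'
#' The threshold is the `ceiling(top_fraction * n)`-th largest grid value
#' genome-wide (so exactly the top fraction of hits is selected when values
#' are distinct); contiguous runs of selected grid points are merged into
#' candidate regions.  A degenerate constant grid yields no regions.
#'
#' @param grid output of [clr_scan()].
#' @param top_fraction selected fraction of grid points (default 0.001).
#' @param method method label stamped on the regions.
#' @return list with `threshold` and `regions`.
#' @export
empirical_threshold <- function(grid, top_fraction = 0.001,
                                method = "CLR") {
  lam <- grid$lambda
  k <- ceiling(top_fraction * length(lam))
  if (top_fraction * length(lam) < 1) {
    warning("too few grid values for the requested top fraction; ",
            "threshold set to the maximum")
    k <- 1
  }
  threshold <- sort(lam, decreasing = TRUE)[k]
  regions <- list()
  if (diff(range(lam)) > 0) {
    for (ch in unique(grid$chrom)) {
      idx <- which(grid$chrom == ch)
      sel <- lam[idx] >= threshold
      r <- rle(sel)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (kk in which(r$values)) {
        regions[[length(regions) + 1L]] <-
          data.frame(chrom = ch,
                     start_bp = grid$grid_pos[idx[starts[kk]]],
                     end_bp = grid$grid_pos[idx[ends[kk]]],
                     method = method, stringsAsFactors = FALSE)
      }
    }
  }
  empty_r <- data.frame(chrom = character(0), start_bp = numeric(0),
                        end_bp = numeric(0), method = character(0))
  list(threshold = threshold,
       regions = if (length(regions)) do.call(rbind, regions) else empty_r)
}
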