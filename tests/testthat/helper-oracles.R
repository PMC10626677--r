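# Brute-force reference implementations used as independent oracles.
# Deliberately written as direct enumerations over pairs / intervals /
# configurations, sharing no code path with the package kernels.

# All-pairs EHH: fraction of carrier pairs identical on the interval
# between the focal SNP and each flanking SNP.
oracle_ehh <- function(haps, pos, focal, allele, max_gap = Inf) {
  carriers <- which(haps[, focal] == allele)
  S <- ncol(haps)
  out <- rep(NA_real_, S)
  if (length(carriers) < 2) return(out)
  pairs <- utils::combn(carriers, 2)
  npair <- ncol(pairs)
  out[focal] <- 1
  for (dir in c(-1, 1)) {
    j <- focal
    repeat {
      nj <- j + dir
      if (nj < 1 || nj > S) break
      if (abs(pos[nj] - pos[j]) > max_gap) break
      rng <- if (dir < 0) nj:focal else focal:nj
      same <- vapply(seq_len(npair), function(k)
        all(haps[pairs[1, k], rng] == haps[pairs[2, k], rng]), NA)
      out[nj] <- sum(same) / npair
      j <- nj
    }
  }
  out
}

# All-pairs mean shared extent in (gap-scaled) segregating-site units,
# focal site counted once per pair.
oracle_sl_mean <- function(haps, pos, focal, allele, max_gap = Inf,
                           gap_scale = Inf) {
  carriers <- which(haps[, focal] == allele)
  if (length(carriers) < 2) return(NA_real_)
  pairs <- utils::combn(carriers, 2)
  S <- ncol(haps)
  ext <- function(i1, i2, dir) {
    tot <- 0; j <- focal
    repeat {
      nj <- j + dir
      if (nj < 1 || nj > S) break
      gap <- abs(pos[nj] - pos[j])
      if (gap > max_gap) break
      if (haps[i1, nj] != haps[i2, nj]) break
      tot <- tot + if (gap > gap_scale) gap_scale / gap else 1
      j <- nj
    }
    tot
  }
  mean(vapply(seq_len(ncol(pairs)), function(k)
    1 + ext(pairs[1, k], pairs[2, k], -1) +
      ext(pairs[1, k], pairs[2, k], 1), 0))
}

# Enumerate all maximal intervals satisfying the run constraints, then
# apply the retention filters.
oracle_roh <- function(dosage, pos, params) {
  S <- length(pos)
  het <- cumsum(c(0, !is.na(dosage) & dosage == 1))
  mis <- cumsum(c(0, is.na(dosage)))
  hom <- cumsum(c(0, !is.na(dosage) & dosage != 1))
  badgap <- cumsum(c(0, 0, diff(pos) > params$max_gap_bp))
  valid <- function(i, j) {
    if (i < 1 || j > S || i > j) return(FALSE)
    if (badgap[j + 1] - badgap[i + 1] > 0) return(FALSE)
    het[j + 1] - het[i] <= params$max_het &&
      mis[j + 1] - mis[i] <= params$max_missing_in_run
  }
  out <- list()
  for (i in seq_len(S)) {
    for (j in i:S) {
      if (!valid(i, j)) next
      if (valid(i - 1, j) || valid(i, j + 1)) next
      n_hom <- hom[j + 1] - hom[i]
      len <- pos[j] - pos[i]
      if (n_hom >= params$min_snps && len >= params$min_length_bp &&
          n_hom / len >= params$min_density_snp_per_bp)
        out[[length(out) + 1L]] <-
          data.frame(start_bp = pos[i], end_bp = pos[j], n_snps = n_hom,
                     n_het = het[j + 1] - het[i], length_bp = len)
    }
  }
  if (!length(out))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), n_het = integer(0),
                      length_bp = numeric(0)))
  do.call(rbind, out)
}

# Exact HWE P by explicit enumeration with choose() products.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n - nA
  if (nA == 0 || nB == 0) return(1)
  hs <- seq(nA %% 2, min(nA, nB), by = 2)
  probs <- vapply(hs, function(h) {
    a <- (nA - h) / 2
    choose(n, a) * choose(n - a, h) * 2^h / choose(2 * n, nA)
  }, 0)
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Hypergeometric upper tail by direct summation.
oracle_hyper_tail <- function(obs, k_class, total, n_draw) {
  ks <- obs:min(k_class, n_draw)
  if (obs > min(k_class, n_draw)) return(0)
  sum(choose(k_class, ks) * choose(total - k_class, n_draw - ks)) /
    choose(total, n_draw)
}

# Sweep spectrum by exhaustive enumeration over escape configurations and
# ordered without-replacement type assignments (n small).
oracle_sweep_spectrum <- function(p_bg, n, p_e) {
  acc <- numeric(n - 1)
  for (j in seq_len(n - 1)) {
    pj <- p_bg[j]
    if (pj == 0) next
    for (cfg in 0:(2^n - 1)) {
      esc <- as.integer(intToBits(cfg))[seq_len(n)]
      k <- sum(esc)
      pcfg <- p_e^k * (1 - p_e)^(n - k)
      if (pcfg == 0) next
      if (k == n) { # no sweep lineage left: plain background draw
        if (j >= 1 && j <= n - 1) acc[j] <- acc[j] + pj * pcfg
        next
      }
      m <- k + 1 # escapees plus the sweeping lineage (drawn last)
      for (tcfg in 0:(2^m - 1)) {
        typ <- as.integer(intToBits(tcfg))[seq_len(m)]
        i <- sum(typ)
        if (i > j || (m - i) > (n - j)) next
        # sequential without-replacement draw probability
        der <- j; anc <- n - j; pool <- n; pt <- 1
        for (t in typ) {
          pt <- pt * (if (t == 1) der else anc) / pool
          if (t == 1) der <- der - 1 else anc <- anc - 1
          pool <- pool - 1
        }
        b <- sum(typ[seq_len(m - 1)]) + if (typ[m] == 1) n - k else 0
        if (b >= 1 && b <= n - 1) acc[b] <- acc[b] + pj * pcfg * pt
      }
    }
  }
  acc / sum(acc)
}

# Point-set interval overlap on small integer coordinates.
oracle_interval_overlap <- function(a, b) {
  length(intersect(seq(a[1], a[2]), seq(b[1], b[2]))) > 0
}
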