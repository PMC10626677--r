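#' Polarise a haplotype matrix so that 1 = derived allele
#'
#' Columns whose ancestral allele is allele b are flipped; where polarity is
#' unknown the major allele is treated as ancestral and the SNP is flagged.
#'
#' @param haps binary haplotype matrix (1 = allele b).
#' @param variants variant table with an `ancestral` column ("a", "b" or NA).
#' @return list with `haps` (1 = derived), `polarity_known` logical vector.
#' @export
polarize_haps <- function(haps, variants) {
  anc <- variants$ancestral
  known <- !is.na(anc) & anc %in% c("a", "b")
  flip <- logical(ncol(haps))
  flip[known] <- anc[known] == "b"
  if (any(!known)) {
    freq_b <- colMeans(haps[, !known, drop = FALSE])
    flip[!known] <- freq_b > 0.5 # major allele treated as ancestral
  }
  if (any(flip))
    haps[, flip] <- 1L - haps[, flip, drop = FALSE]
  list(haps = haps, polarity_known = known)
}

#' Extended haplotype homozygosity curve at one focal SNP
#'
#' EHH at flanking SNP x is the probability that two haplotypes drawn
#' without replacement from the carriers of the core allele are identical
#' at every SNP between the focal SNP and x.  The curve starts at 1 at the
#' focal SNP, is non-increasing outward, and is truncated when it falls
#' below `cutoff` or when an inter-SNP gap exceeds `max_gap_bp`.
#'
#' @param haps binary haplotype matrix over one chromosome.
#' @param pos_bp sorted SNP positions.
#' @param focal_idx focal SNP column index.
#' @param core_allele 0 or 1, the core allele defining the carrier set.
#' @param cutoff truncation threshold (default 0.05).
#' @param max_gap_bp maximum allowed inter-SNP gap (default 200 kb).
#' @return data frame `pos_bp`, `ehh` (NA outside the computed extent).
#' @export
ehh <- function(haps, pos_bp, focal_idx, core_allele, cutoff = 0.05,
                max_gap_bp = 2e5) {
  n_car <- sum(haps[, focal_idx] == core_allele)
  if (n_car < 2)
    stop("fewer than 2 carriers of the core allele at the focal SNP")
  vals <- ehh_curve_cpp(haps, as.numeric(pos_bp), focal_idx - 1L,
                        as.integer(core_allele), cutoff, max_gap_bp)
  data.frame(pos_bp = pos_bp, ehh = vals)
}

#' Raw (unstandardised) iHS scan
#'
#' For each polymorphic SNP the EHH curves of the ancestral and derived
#' carrier sets are integrated over physical distance (trapezoid rule, both
#' directions summed, truncated at EHH < `cutoff`); the raw statistic is
#' `ln(iHH_A / iHH_D)`.  Gaps larger than `gap_scale_bp` contribute at most
#' `gap_scale_bp` to the integral; extension stops at gaps > `max_gap_bp`.
#'
#' @param haps phased haplotype matrix, 1 = derived (see [polarize_haps()]).
#' @param variants variant table (single or multiple chromosomes).
#' @param maf_min minimum derived/ancestral allele frequency (default 0.05).
#' @param cutoff EHH integration cutoff (default 0.05).
#' @param max_gap_bp,gap_scale_bp gap handling parameters.
#' @return score track data frame: `chrom`, `pos_bp`, `snp_id`,
#'   `freq_derived`, `raw`, `skip_code` (0 ok, 1 frequency bounds,
#'   2 zero iHH).
#' @export
ihs_scan <- function(haps, variants, maf_min = 0.05, cutoff = 0.05,
                     max_gap_bp = 2e5, gap_scale_bp = 2e4) {
  out <- list()
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    m <- ihs_scan_cpp(haps[, idx, drop = FALSE],
                      as.numeric(variants$pos_bp[idx]), maf_min, cutoff,
                      max_gap_bp, gap_scale_bp)
    raw <- ifelse(m[, 4] == 0, log(m[, 2] / m[, 3]), NA_real_)
    out[[length(out) + 1L]] <-
      data.frame(chrom = ch, pos_bp = variants$pos_bp[idx],
                 snp_id = variants$snp_id[idx], freq_derived = m[, 1],
                 raw = raw, skip_code = as.integer(m[, 4]),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Raw (unstandardised) nSL scan
#'
#' For each SNP and carrier class, the mean over haplotype pairs of the
#' maximal interval (in segregating-site units, focal SNP included) over
#' which the pair is identical; the raw statistic is `ln(SL_A / SL_D)`.
#' Steps across gaps larger than `gap_scale_bp` are down-weighted by
#' `gap_scale_bp / gap`; extension stops at gaps > `max_gap_bp`.
#'
#' @inheritParams ihs_scan
#' @export
nsl_scan <- function(haps, variants, maf_min = 0.05, max_gap_bp = 2e5,
                     gap_scale_bp = 2e4) {
  out <- list()
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    m <- nsl_scan_cpp(haps[, idx, drop = FALSE],
                      as.numeric(variants$pos_bp[idx]), maf_min,
                      max_gap_bp, gap_scale_bp)
    raw <- ifelse(m[, 4] == 0, log(m[, 2] / m[, 3]), NA_real_)
    out[[length(out) + 1L]] <-
      data.frame(chrom = ch, pos_bp = variants$pos_bp[idx],
                 snp_id = variants$snp_id[idx], freq_derived = m[, 1],
                 raw = raw, skip_code = as.integer(m[, 4]),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Standardise raw scores within derived-allele-frequency bins
#'
#' Scores are pooled genome-wide, assigned to `n_bins` equal-width
#' derived-frequency bins, and z-scored within each bin (bin mean
#' subtracted, bin SD divided).  Bins with fewer than 2 scores or zero SD
#' yield missing standardised values.
#'
#' @param raw raw score vector.
#' @param freq derived allele frequency per score.
#' @param n_bins number of frequency bins (default 100).
#' @return standardised score vector.
#' @export
standardize_scores <- function(raw, freq, n_bins = 100) {
  bin <- pmin(pmax(ceiling(freq * n_bins), 1L), n_bins)
  std <- rep(NA_real_, length(raw))
  for (b in unique(bin[!is.na(raw)])) {
    idx <- which(bin == b & !is.na(raw))
    if (length(idx) < 2) next
    s <- stats::sd(raw[idx])
    if (is.na(s) || s == 0) next
    std[idx] <- (raw[idx] - mean(raw[idx])) / s
  }
  std
}

#' Two-tailed Gaussian tail transform
#'
#' Returns `-log10(2 * Phi(-|z|))`, the two-tailed P value of a
#' standardised score on the -log10 scale.
#'
#' @param z standardised score(s).
#' @export
neglog_two_tailed_p <- function(z) {
  -(log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
}

#' Sliding-window significance scan
#'
#' Windows of `window_bp` advanced by `step_bp` along each chromosome are
#' flagged significant when at least `min_hits` SNPs reach
#' `-log10 P >= threshold`; overlapping or touching flagged windows are
#' merged into candidate regions.
#'
#' @param track score track with `chrom`, `pos_bp`, `neglog10p` columns.
#' @param window_bp window size (default 0.5 Mb).
#' @param step_bp window step (default 10 kb).
#' @param threshold `-log10 P` threshold (default 4).
#' @param min_hits minimum extreme SNPs per significant window (default 3).
#' @param method method label stamped on the regions.
#' @return list with `windows` (per-window calls) and `regions` (merged
#'   significant regions).
#' @export
window_scan <- function(track, window_bp = 5e5, step_bp = 1e4,
                        threshold = 4, min_hits = 3, method = "IHS") {
  windows <- list(); regions <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch & !is.na(track$neglog10p))
    if (!length(idx)) next
    pos <- track$pos_bp[idx]
    hit_pos <- pos[track$neglog10p[idx] >= threshold]
    starts <- seq(1, max(pos), by = step_bp)
    ends <- starts + window_bp - 1
    n_hits <- vapply(seq_along(starts), function(k)
      sum(hit_pos >= starts[k] & hit_pos <= ends[k]), 0L)
    sig <- n_hits >= min_hits
    windows[[length(windows) + 1L]] <-
      data.frame(chrom = ch, start_bp = starts, end_bp = ends,
                 n_hits = n_hits, significant = sig,
                 stringsAsFactors = FALSE)
    if (any(sig)) {
      ws <- starts[sig]; we <- ends[sig]
      cur_s <- ws[1]; cur_e <- we[1]
      for (k in seq_along(ws)[-1]) {
        if (ws[k] <= cur_e + 1) cur_e <- max(cur_e, we[k])
        else {
          regions[[length(regions) + 1L]] <-
            data.frame(chrom = ch, start_bp = cur_s, end_bp = cur_e,
                       method = method, stringsAsFactors = FALSE)
          cur_s <- ws[k]; cur_e <- we[k]
        }
      }
      regions[[length(regions) + 1L]] <-
        data.frame(chrom = ch, start_bp = cur_s, end_bp = cur_e,
                   method = method, stringsAsFactors = FALSE)
    }
  }
  empty_r <- data.frame(chrom = character(0), start_bp = numeric(0),
                        end_bp = numeric(0), method = character(0))
  list(windows = if (length(windows)) do.call(rbind, windows) else NULL,
       regions = if (length(regions)) do.call(rbind, regions) else empty_r)
}

#' Full iHS or nSL pipeline stage
#'
#' Polarises, scans, standardises in 100 frequency bins, transforms to
#' two-tailed `-log10 P`, and calls significant windows.
#'
#' @param haps haplotype matrix (1 = allele b).
#' @param variants variant table.
#' @param stat `"ihs"` or `"nsl"`.
#' @param n_bins frequency bins for standardisation.
#' @param ... passed to [window_scan()].
#' @return list with `track` (scored SNP table) and the [window_scan()]
#'   output.
#' @export
haplo_stage <- function(haps, variants, stat = c("ihs", "nsl"),
                        n_bins = 100, ...) {
  stat <- match.arg(stat)
  pol <- polarize_haps(haps, variants)
  track <- if (stat == "ihs") ihs_scan(pol$haps, variants)
           else nsl_scan(pol$haps, variants)
  track$std <- standardize_scores(track$raw, track$freq_derived, n_bins)
  track$neglog10p <- neglog_two_tailed_p(track$std)
  scan <- window_scan(track, method = toupper(stat), ...)
  list(track = track, windows = scan$windows, regions = scan$regions)
}
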