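#' Parameters for consecutive-runs ROH detection
#'
#' Defaults follow standard recommendations for high-density SNP-array
#' data: minimum run length 1 Mb, at least 15 homozygous SNPs, at least one
#' SNP per 0.1 Mb, maximum inter-SNP gap 1 Mb, and one heterozygous call
#' allowed per run.
#'
#' @param min_length_bp minimum run length in bp.
#' @param min_snps minimum number of homozygous SNPs in a run.
#' @param min_density_snp_per_bp minimum homozygous-SNP density.
#' @param max_gap_bp maximum gap between consecutive SNPs inside a run.
#' @param max_het maximum heterozygous calls tolerated inside a run.
#' @param max_missing_in_run maximum missing calls tolerated inside a run.
#' @export
roh_params <- function(min_length_bp = 1e6, min_snps = 15,
                       min_density_snp_per_bp = 1 / 1e5, max_gap_bp = 1e6,
                       max_het = 1, max_missing_in_run = 0) {
  p <- list(min_length_bp = min_length_bp, min_snps = min_snps,
            min_density_snp_per_bp = min_density_snp_per_bp,
            max_gap_bp = max_gap_bp, max_het = max_het,
            max_missing_in_run = max_missing_in_run)
  stopifnot(p$min_length_bp > 0, p$min_snps > 0, p$max_gap_bp > 0,
            p$max_het >= 0, p$max_missing_in_run >= 0)
  class(p) <- "roh_params"
  p
}

#' Detect runs of homozygosity for one individual on one chromosome
#'
#' Windowless consecutive-runs detection: all maximal stretches of
#' consecutive calls containing at most `max_het` heterozygous and
#' `max_missing_in_run` missing calls, broken at inter-SNP gaps larger than
#' `max_gap_bp`, are enumerated; runs are then retained iff they contain at
#' least `min_snps` homozygous SNPs, span at least `min_length_bp`, and meet
#' the density requirement.  Run coordinates are the first/last SNP
#' positions.
#'
#' @param dosage one individual's dosages (0/1/2/NA) over one chromosome.
#' @param pos_bp sorted SNP positions.
#' @param params a [roh_params()] object.
#' @return data frame with `start_bp`, `end_bp`, `n_snps` (homozygous),
#'   `n_het`, `length_bp`.
#' @export
detect_roh <- function(dosage, pos_bp, params = roh_params()) {
  if (is.unsorted(pos_bp, strictly = TRUE)) stop("positions must be sorted")
  S <- length(pos_bp)
  empty <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), n_het = integer(0),
                      length_bp = numeric(0))
  if (S == 0) return(empty)
  het <- !is.na(dosage) & dosage == 1
  mis <- is.na(dosage)
  # split at big gaps, then two-pointer maximal valid intervals per segment
  breaks <- which(diff(pos_bp) > params$max_gap_bp)
  seg_start <- c(1L, breaks + 1L)
  seg_end <- c(breaks, S)
  out <- list()
  for (seg in seq_along(seg_start)) {
    a <- seg_start[seg]; b <- seg_end[seg]
    j <- a - 1L; nh <- 0L; nm <- 0L
    prev_jmax <- a - 1L
    for (i in a:b) {
      if (j < i - 1L) { j <- i - 1L; nh <- 0L; nm <- 0L }
      while (j < b) {
        nh2 <- nh + het[j + 1L]
        nm2 <- nm + mis[j + 1L]
        if (nh2 > params$max_het || nm2 > params$max_missing_in_run) break
        j <- j + 1L; nh <- nh2; nm <- nm2
      }
      if (j >= i && j > prev_jmax) {
        out[[length(out) + 1L]] <- c(i, j)
        prev_jmax <- j
      }
      nh <- nh - het[i]; nm <- nm - mis[i]
    }
  }
  if (!length(out)) return(empty)
  iv <- do.call(rbind, out)
  n_hom <- vapply(seq_len(nrow(iv)), function(k)
    sum(!het[iv[k, 1]:iv[k, 2]] & !mis[iv[k, 1]:iv[k, 2]]), 0L)
  n_het <- vapply(seq_len(nrow(iv)), function(k)
    sum(het[iv[k, 1]:iv[k, 2]]), 0L)
  len <- pos_bp[iv[, 2]] - pos_bp[iv[, 1]]
  keep <- n_hom >= params$min_snps & len >= params$min_length_bp &
    n_hom / len >= params$min_density_snp_per_bp
  data.frame(start_bp = pos_bp[iv[keep, 1]], end_bp = pos_bp[iv[keep, 2]],
             n_snps = n_hom[keep], n_het = n_het[keep],
             length_bp = len[keep])
}

#' Detect ROH for all individuals across all chromosomes
#'
#' @param geno samples x variants dosage matrix.
#' @param variants variant table.
#' @inheritParams detect_roh
#' @return data frame of runs with `sample_id` and `chrom` columns.
#' @export
detect_roh_all <- function(geno, variants, params = roh_params()) {
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("ind_%03d", seq_len(nrow(geno)))
  out <- list()
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    pos <- variants$pos_bp[idx]
    for (i in seq_len(nrow(geno))) {
      runs <- detect_roh(geno[i, idx], pos, params)
      if (nrow(runs)) {
        runs$sample_id <- ids[i]
        runs$chrom <- ch
        out[[length(out) + 1L]] <- runs
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), n_het = integer(0),
                      length_bp = numeric(0)))
  df <- do.call(rbind, out)
  df[, c("sample_id", "chrom", "start_bp", "end_bp", "n_snps", "n_het",
         "length_bp")]
}

#' Per-SNP ROH incidence
#'
#' Counts, for every SNP, the number of individuals with at least one run
#' covering its position (closed-interval inclusion).
#'
#' @param runs run table from [detect_roh_all()].
#' @param variants variant table.
#' @param n_individuals total number of individuals scanned.
#' @return data frame `chrom`, `pos_bp`, `count`.
#' @export
roh_incidence <- function(runs, variants, n_individuals) {
  count <- integer(nrow(variants))
  if (nrow(runs)) {
    for (ch in unique(runs$chrom)) {
      idx <- which(variants$chrom == ch)
      pos <- variants$pos_bp[idx]
      rch <- runs[runs$chrom == ch, , drop = FALSE]
      for (sid in unique(rch$sample_id)) {
        rs <- rch[rch$sample_id == sid, , drop = FALSE]
        covered <- rep(FALSE, length(idx))
        for (k in seq_len(nrow(rs)))
          covered <- covered | (pos >= rs$start_bp[k] & pos <= rs$end_bp[k])
        count[idx] <- count[idx] + covered
      }
    }
  }
  stopifnot(all(count <= n_individuals))
  data.frame(chrom = variants$chrom, pos_bp = variants$pos_bp,
             count = count)
}

#' Chromosome-normalised eROHi scores
#'
#' Per chromosome, incidence counts are z-scored against the chromosome
#' mean and standard deviation and converted to `-log10` of the right
#' Gaussian tail probability, so that extreme ROH islands are comparable
#' across chromosomes of different size.
#'
#' @param track incidence table from [roh_incidence()].
#' @return the track with `z` and `neglog10p` columns added.
#' @export
eroi_scores <- function(track) {
  track$z <- NA_real_
  track$neglog10p <- NA_real_
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    x <- track$count[idx]
    s <- stats::sd(x)
    if (length(idx) < 2 || is.na(s) || s == 0) {
      warning(sprintf("chromosome %s: zero incidence variance, no outliers",
                      ch))
      track$z[idx] <- 0
      track$neglog10p[idx] <- 0
      next
    }
    z <- (x - mean(x)) / s
    track$z[idx] <- z
    track$neglog10p[idx] <- -stats::pnorm(z, lower.tail = FALSE,
                                          log.p = TRUE) / log(10)
  }
  track
}

#' Call eROHi candidate regions
#'
#' Maximal stretches of at least `min_consecutive` adjacent outlier SNPs
#' (`-log10 P >= threshold`); each region is extended by `extension_bp` on
#' both sides (clipped at position 1).
#'
#' @param track scored track from [eroi_scores()].
#' @param threshold outlier threshold on `-log10 P` (default 4).
#' @param min_consecutive minimum adjacent outlier SNPs (default 2).
#' @param extension_bp flank added to each region (default 100 kb).
#' @return data frame `chrom`, `start_bp`, `end_bp`, `n_snps`, `method`.
#' @export
call_eroi_regions <- function(track, threshold = 4, min_consecutive = 2,
                              extension_bp = 1e5) {
  out <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    flag <- track$neglog10p[idx] >= threshold
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_consecutive)) {
      i1 <- idx[starts[k]]; i2 <- idx[ends[k]]
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch,
                   start_bp = max(1, track$pos_bp[i1] - extension_bp),
                   end_bp = track$pos_bp[i2] + extension_bp,
                   n_snps = ends[k] - starts[k] + 1L,
                   method = "ROHS", stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      method = character(0)))
  do.call(rbind, out)
}

#' Classify runs by length
#'
#' Left-closed, right-open classes in Mb: 1-2, 2-4, 4-8, 8-16, >16.
#'
#' @param runs run table.
#' @return named integer vector of class counts.
#' @export
roh_length_classes <- function(runs) {
  mb <- runs$length_bp / 1e6
  cls <- cut(mb, breaks = c(1, 2, 4, 8, 16, Inf), right = FALSE,
             labels = c("1-2", "2-4", "4-8", "8-16", ">16"))
  table(cls)
}
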