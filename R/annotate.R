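#' Read gene intervals from a GFF3 file
#'
#' @param path GFF3 path (1-based coordinates).
#' @param feature_type feature type to keep (default "gene").
#' @return feature table: `chrom`, `start_bp`, `end_bp`, `feature_id`,
#'   `feature_class`.
#' @export
read_gff_features <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path)
  if ("type" %in% colnames(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) == feature_type]
  meta <- S4Vectors::mcols(gr)
  id <- if ("Name" %in% colnames(meta)) as.character(meta$Name)
        else if ("ID" %in% colnames(meta)) as.character(meta$ID)
        else sprintf("feature_%d", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             feature_id = id, feature_class = id,
             stringsAsFactors = FALSE)
}

#' Read feature intervals from a BED file
#'
#' BED input is 0-based half-open; coordinates are converted to the
#' package's 1-based inclusive convention.
#'
#' @param path BED path.
#' @export
read_bed_features <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  id <- if (!is.null(gr$name)) as.character(gr$name)
        else sprintf("feature_%d", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             feature_id = id, feature_class = id,
             stringsAsFactors = FALSE)
}

#' Read a QTL interval table
#'
#' Tab-separated export with columns chrom, start, end, trait, class (an
#' Animal QTLdb style dump).
#'
#' @param path TSV path.
#' @export
read_qtl_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:5] <- c("chrom", "start_bp", "end_bp", "trait", "class")
  df$chrom <- as.character(df$chrom)
  df$feature_id <- if (is.null(df$qtl_id)) sprintf("qtl_%d", seq_len(nrow(df)))
                   else df$qtl_id
  df$feature_class <- df$class
  df[, c("chrom", "start_bp", "end_bp", "feature_id", "feature_class",
         "trait")]
}

#' Overlap features with candidate regions
#'
#' Every (region, feature) pair with closed-interval overlap on the same
#' chromosome; a feature may hit several regions.  Features on chromosomes
#' absent from the region table are skipped with a warning.
#'
#' @param regions region table (`chrom`, `start_bp`, `end_bp`).
#' @param features feature table (`chrom`, `start_bp`, `end_bp`,
#'   `feature_id`, `feature_class`).
#' @return overlap table with region index/coordinates and feature fields.
#' @export
features_in_regions <- function(regions, features) {
  empty <- data.frame(region_idx = integer(0), chrom = character(0),
                      region_start = numeric(0), region_end = numeric(0),
                      feature_id = character(0), feature_class = character(0))
  if (nrow(regions) == 0 || nrow(features) == 0) return(empty)
  unknown <- !(features$chrom %in% regions$chrom)
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start_bp,
                                                  regions$end_bp))
  gr_f <- GenomicRanges::GRanges(features$chrom,
                                 IRanges::IRanges(features$start_bp,
                                                  features$end_bp))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, gr_f))
  ri <- S4Vectors::queryHits(hits); fi <- S4Vectors::subjectHits(hits)
  if (!length(ri)) return(empty)
  data.frame(region_idx = ri, chrom = regions$chrom[ri],
             region_start = regions$start_bp[ri],
             region_end = regions$end_bp[ri],
             feature_id = features$feature_id[fi],
             feature_class = features$feature_class[fi],
             stringsAsFactors = FALSE)
}

#' QTL-class enrichment in candidate regions
#'
#' For each QTL class, the observed count is the number of distinct QTLs of
#' that class overlapping any candidate region; the expected count is the
#' class total times the overall fraction of QTLs overlapping regions
#' within the scope; the richness factor is observed/expected.  P values
#' come from the hypergeometric upper tail (drawing the overlapping set
#' from the scope's QTL population) and are Benjamini-Hochberg adjusted
#' across classes.
#'
#' @param regions candidate region table.
#' @param qtl QTL table from [read_qtl_table()].
#' @param scope `"genome"` or `"chromosome"`.
#' @return data frame with `scope_unit`, `feature_class`, `observed`,
#'   `expected`, `richness`, `p`, `fdr`.
#' @export
qtl_enrichment <- function(regions, qtl, scope = c("genome", "chromosome")) {
  scope <- match.arg(scope)
  units <- if (scope == "genome") list(all = qtl)
           else split(qtl, qtl$chrom)
  rows <- list()
  for (u in names(units)) {
    qu <- units[[u]]
    ru <- if (scope == "genome") regions
          else regions[regions$chrom == u, , drop = FALSE]
    total <- nrow(qu)
    if (total == 0) next
    ov <- features_in_regions(ru, qu)
    ov_ids <- unique(ov$feature_id) # a QTL counted once even if multi-hit
    n_ov <- length(ov_ids)
    for (cl in unique(qu$feature_class)) {
      k_total <- sum(qu$feature_class == cl)
      if (k_total == 0) next
      obs <- sum(qu$feature_id %in% ov_ids & qu$feature_class == cl)
      expected <- k_total * n_ov / total
      p <- if (n_ov == 0) 1
           else stats::phyper(obs - 1, k_total, total - k_total, n_ov,
                              lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(scope_unit = u, feature_class = cl, observed = obs,
                   expected = expected,
                   richness = if (expected > 0) obs / expected else NA_real_,
                   p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(scope_unit = character(0), feature_class = character(0),
                      observed = integer(0), expected = numeric(0),
                      richness = numeric(0), p = numeric(0), fdr = numeric(0)))
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res
}

#' Per-class QTL composition of candidate regions
#'
#' @param overlap_table output of [features_in_regions()].
#' @return data frame `feature_class`, `count`, `percent`.
#' @export
classify_regions_by_qtl <- function(overlap_table) {
  if (nrow(overlap_table) == 0)
    return(data.frame(feature_class = character(0), count = integer(0),
                      percent = numeric(0)))
  tab <- table(overlap_table$feature_class)
  data.frame(feature_class = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
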