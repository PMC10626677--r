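#' Closed-interval region overlap
#'
#' Two regions on the same chromosome overlap iff
#' `a.start <= b.end && b.start <= a.end` (1-based inclusive coordinates;
#' a shared endpoint counts as overlap).  Vectorised over `b`.
#'
#' @param a single region (list/row with `chrom`, `start_bp`, `end_bp`).
#' @param b region(s), same fields.
#' @return logical vector.
#' @export
regions_overlap <- function(a, b) {
  a$chrom == b$chrom & a$start_bp <= b$end_bp & b$start_bp <= a$end_bp
}

#' Region length in Mb
#'
#' `(end - start) / 1e6`, half-up rounded to 3 decimals (the convention of
#' printed candidate-region tables).
#'
#' @param start_bp,end_bp region bounds, `end_bp > start_bp`.
#' @export
region_length_mb <- function(start_bp, end_bp) {
  stopifnot(all(end_bp > start_bp))
  floor((end_bp - start_bp) / 1e6 * 1000 + 0.5) / 1000
}

#' Multi-method consensus candidate regions
#'
#' Builds the cross-method overlap graph of all per-method regions and
#' emits each connected component supported by at least `min_methods`
#' distinct methods as one consensus region (start = min start, end = max
#' end, methods = union), sorted by chromosome and start.
#'
#' @param region_list list of per-method region data frames, each with
#'   `chrom`, `start_bp`, `end_bp`, `method` columns.
#' @param min_methods minimum distinct contributing methods (default 2).
#' @return data frame `chrom`, `start_bp`, `end_bp`, `length_mb`,
#'   `methods` (hyphen-joined), `n_methods`.
#' @export
build_consensus <- function(region_list, min_methods = 2) {
  all_r <- do.call(rbind, lapply(region_list, function(x)
    x[, c("chrom", "start_bp", "end_bp", "method")]))
  empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), length_mb = numeric(0),
                      methods = character(0), n_methods = integer(0))
  if (is.null(all_r) || nrow(all_r) == 0) return(empty)
  n <- nrow(all_r)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (all_r$chrom[i] == all_r$chrom[j] &&
          all_r$start_bp[i] <= all_r$end_bp[j] &&
          all_r$start_bp[j] <= all_r$end_bp[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  out <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    methods <- sort(unique(all_r$method[members]))
    if (length(methods) < min_methods) next
    s <- min(all_r$start_bp[members]); e <- max(all_r$end_bp[members])
    out[[length(out) + 1L]] <-
      data.frame(chrom = all_r$chrom[members[1]], start_bp = s, end_bp = e,
                 length_mb = region_length_mb(s, e),
                 methods = paste(methods, collapse = "-"),
                 n_methods = length(methods), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  chrom_key <- suppressWarnings(as.numeric(res$chrom))
  if (any(is.na(chrom_key))) chrom_key <- rank(res$chrom)
  res <- res[order(chrom_key, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}
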