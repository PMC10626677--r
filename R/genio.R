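#' Write a simulated dataset to VCF and PLINK text formats
#'
#' Emits a VCF 4.2 with phased GT fields and an `AA` (ancestral allele) INFO
#' tag, PLINK `.ped`/`.map` files, and (when `truth` is supplied) a
#' tab-separated truth sidecar recording the sweep site.
#'
#' @param haps 2n x S binary haplotype matrix (1 = allele b).
#' @param variants variant table (`chrom`, `pos_bp`, `snp_id`, `allele_a`,
#'   `allele_b`, `ancestral`).
#' @param samples data frame with a `sample_id` column.
#' @param out_prefix path prefix for the output files.
#' @param formats any of `"vcf"`, `"plink"`.
#' @param truth optional truth record (or list of per-chromosome records)
#'   from the simulator.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(haps, variants, samples, out_prefix,
                          formats = c("vcf", "plink"), truth = NULL) {
  stopifnot(ncol(haps) == nrow(variants),
            nrow(haps) == 2 * nrow(samples))
  paths <- character(0)
  if ("vcf" %in% formats) {
    path <- paste0(out_prefix, ".vcf")
    write_vcf_file(haps, variants, samples, path)
    paths <- c(paths, path)
  }
  if ("plink" %in% formats) {
    geno <- haps_to_geno(haps)
    write_plink_ped(geno, variants, samples, out_prefix)
    paths <- c(paths, paste0(out_prefix, c(".ped", ".map")))
  }
  if (!is.null(truth)) {
    recs <- if (!is.null(truth$chrom)) list(truth) else truth
    df <- do.call(rbind, lapply(recs, function(t)
      data.frame(chrom = t$chrom, sweep_pos_bp = t$sweep_pos_bp, s = t$s,
                 realized_freq = t$realized_freq)))
    path <- paste0(out_prefix, ".truth.tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

write_vcf_file <- function(haps, variants, samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sweepstack",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  for (ch in unique(variants$chrom))
    writeLines(sprintf("##contig=<ID=%s>", ch), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples$sample_id), collapse = "\t"),
             con)
  n <- nrow(samples)
  h1 <- haps[seq(1, 2 * n, 2), , drop = FALSE]
  h2 <- haps[seq(2, 2 * n, 2), , drop = FALSE]
  aa <- ifelse(variants$ancestral == "b", variants$allele_b,
               variants$allele_a)
  for (j in seq_len(nrow(variants))) {
    gt <- paste0(h1[, j], "|", h2[, j])
    writeLines(paste(c(variants$chrom[j], format(variants$pos_bp[j],
                                                 scientific = FALSE),
                       variants$snp_id[j], variants$allele_a[j],
                       variants$allele_b[j], ".", "PASS",
                       paste0("AA=", aa[j]), "GT", gt), collapse = "\t"),
               con)
  }
  invisible(path)
}

write_plink_ped <- function(geno, variants, samples, out_prefix) {
  map <- data.frame(chrom = variants$chrom, snp_id = variants$snp_id,
                    cm = 0, pos_bp = format(variants$pos_bp,
                                            scientific = FALSE, trim = TRUE))
  utils::write.table(map, paste0(out_prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(geno); S <- ncol(geno)
  a <- variants$allele_a; b <- variants$allele_b
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- geno[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, b, a))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, b, a))
    lines[i] <- paste(c(samples$sample_id[i], samples$sample_id[i],
                        "0", "0", "0", "-9", rbind(a1, a2)), collapse = " ")
  }
  writeLines(lines, paste0(out_prefix, ".ped"))
  invisible(out_prefix)
}

#' Write PLINK binary (bed/bim/fam) files
#'
#' The `.bim` allele-1 column is the allele-b (dosage-counted) allele, the
#' SNP-major `.bed` layout follows the PLINK 1 specification.
#'
#' @param geno samples x variants allele-b dosage matrix.
#' @inheritParams write_dataset
#' @export
write_plink_bed <- function(geno, variants, samples, out_prefix) {
  bim <- data.frame(variants$chrom, variants$snp_id, 0,
                    format(variants$pos_bp, scientific = FALSE, trim = TRUE),
                    variants$allele_b, variants$allele_a)
  utils::write.table(bim, paste0(out_prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(samples$sample_id, samples$sample_id, 0, 0, 0, -9)
  utils::write.table(fam, paste0(out_prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(geno)
  codes <- c(`2` = 0L, `1` = 2L, `0` = 3L) # hom A1, het, hom A2
  con <- file(paste0(out_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  nb <- ceiling(n / 4)
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    code <- ifelse(is.na(g), 1L, codes[as.character(g)])
    code <- c(code, rep(0L, nb * 4 - n))
    byte <- code[seq(1, length(code), 4)] +
      bitwShiftL(code[seq(2, length(code), 4)], 2) +
      bitwShiftL(code[seq(3, length(code), 4)], 4) +
      bitwShiftL(code[seq(4, length(code), 4)], 6)
    writeBin(as.raw(byte), con)
  }
  invisible(out_prefix)
}

#' Read a VCF into the package's data model
#'
#' Phased haplotypes are returned iff every non-missing GT field uses the
#' `|` separator; half-missing genotypes are treated as missing.
#' Multiallelic records are skipped (counted in `n_multiallelic_skipped`).
#'
#' @param path VCF file path.
#' @return list with `geno` (allele-b a.k.a. ALT dosage), `haps` (or NULL if
#'   unphased), `variants`, `samples`, `n_multiallelic_skipped`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    warning(sprintf("skipped %d multiallelic site(s)", n_multi))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  aa <- tryCatch(vcfR::extract.info(v, "AA"), error = function(e) NULL)
  samples <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  S <- nrow(fix); n <- ncol(gt)
  ancestral <- rep(NA_character_, S)
  if (!is.null(aa)) {
    ancestral[!is.na(aa) & aa == fix$REF] <- "a"
    ancestral[!is.na(aa) & aa == fix$ALT] <- "b"
  }
  variants <- data.frame(chrom = fix$CHROM, pos_bp = as.numeric(fix$POS),
                         snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                         sprintf("snp%06d", seq_len(S)),
                                         fix$ID),
                         allele_a = fix$REF, allele_b = fix$ALT,
                         ancestral = ancestral, stringsAsFactors = FALSE)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = S)
  gt[gt == "."] <- NA
  phased <- all(grepl("|", gt[!is.na(gt)], fixed = TRUE)) && any(!is.na(gt))
  al1 <- substr(gt, 1, 1); al2 <- substr(gt, 3, 3)
  al1[al1 == "."] <- NA; al2[al2 == "."] <- NA
  d1 <- matrix(suppressWarnings(as.integer(al1)), nrow = S)
  d2 <- matrix(suppressWarnings(as.integer(al2)), nrow = S)
  geno <- t(d1 + d2) # half-missing propagates NA
  dimnames(geno) <- list(samples$sample_id, variants$snp_id)
  haps <- NULL
  if (phased) {
    haps <- matrix(0L, nrow = 2 * n, ncol = S)
    haps[seq(1, 2 * n, 2), ] <- t(d1)
    haps[seq(2, 2 * n, 2), ] <- t(d2)
    rownames(haps) <- paste0(rep(samples$sample_id, each = 2), c("_1", "_2"))
  }
  list(geno = geno, haps = haps, variants = variants, samples = samples,
       n_multiallelic_skipped = n_multi)
}

#' Read PLINK text (`.ped`/`.map`) or binary (`.bed`/`.bim`/`.fam`) data
#'
#' For `.ped`/`.map` input the dosage-counted allele (allele b) of each SNP
#' is the minor allele observed in the file (ties broken alphabetically),
#' matching the PLINK A1 = minor convention; for binary input it is the
#' `.bim` allele-1 column.  `0 0` genotypes are missing.
#'
#' @param prefix path prefix (without extension).
#' @return list with `geno`, `variants`, `samples`.
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".ped")))
    read_plink_ped(prefix)
  else if (file.exists(paste0(prefix, ".bed")))
    read_plink_bed(prefix)
  else stop("no .ped/.map or .bed/.bim/.fam files at prefix: ", prefix)
}

read_plink_ped <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           stringsAsFactors = FALSE)
  colnames(map) <- c("chrom", "snp_id", "cm", "pos_bp")[seq_len(ncol(map))]
  S <- nrow(map)
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6 + 2 * S)
    stop(sprintf("ped/map dimension mismatch: %d allele columns for %d SNPs",
                 ncol(ped) - 6, S))
  samples <- data.frame(sample_id = ped[[2]], stringsAsFactors = FALSE)
  n <- nrow(ped)
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  al[al == "0"] <- NA
  a1 <- al[, seq(1, 2 * S, 2), drop = FALSE]
  a2 <- al[, seq(2, 2 * S, 2), drop = FALSE]
  geno <- matrix(NA_integer_, n, S)
  allele_a <- allele_b <- character(S)
  for (j in seq_len(S)) {
    obs <- c(a1[, j], a2[, j])
    tab <- sort(table(obs))
    lev <- names(tab)
    if (length(lev) == 1) lev <- c(lev, NA)
    # minor allele first; ties broken alphabetically
    if (length(tab) == 2 && tab[1] == tab[2]) lev <- sort(lev)
    allele_b[j] <- lev[1]; allele_a[j] <- lev[2]
    geno[, j] <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
  }
  variants <- data.frame(chrom = as.character(map$chrom),
                         pos_bp = as.numeric(map$pos_bp),
                         snp_id = map$snp_id, allele_a = allele_a,
                         allele_b = allele_b, ancestral = NA_character_,
                         stringsAsFactors = FALSE)
  dimnames(geno) <- list(samples$sample_id, variants$snp_id)
  list(geno = geno, variants = variants, samples = samples)
}

read_plink_bed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  S <- nrow(bim); n <- nrow(fam)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * S)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  body <- as.integer(raw[-(1:3)])
  nb <- ceiling(n / 4)
  codes <- matrix(0L, nb * 4, S)
  m <- matrix(body, nb, S)
  codes[seq(1, nb * 4, 4), ] <- bitwAnd(m, 3L)
  codes[seq(2, nb * 4, 4), ] <- bitwAnd(bitwShiftR(m, 2L), 3L)
  codes[seq(3, nb * 4, 4), ] <- bitwAnd(bitwShiftR(m, 4L), 3L)
  codes[seq(4, nb * 4, 4), ] <- bitwAnd(bitwShiftR(m, 6L), 3L)
  codes <- codes[seq_len(n), , drop = FALSE]
  geno <- matrix(NA_integer_, n, S)
  geno[codes == 0L] <- 2L
  geno[codes == 2L] <- 1L
  geno[codes == 3L] <- 0L
  variants <- data.frame(chrom = as.character(bim[[1]]),
                         pos_bp = as.numeric(bim[[4]]), snp_id = bim[[2]],
                         allele_a = as.character(bim[[6]]),
                         allele_b = as.character(bim[[5]]),
                         ancestral = NA_character_, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = as.character(fam[[2]]),
                        stringsAsFactors = FALSE)
  dimnames(geno) <- list(samples$sample_id, variants$snp_id)
  list(geno = geno, variants = variants, samples = samples)
}
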