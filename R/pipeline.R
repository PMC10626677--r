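#' Pipeline configuration
#'
#' Bundles every stage's parameters with the standard defaults of a
#' high-density within-population selection scan (1 Mb / 15-SNP ROH,
#' outlier threshold 4, 0.5 Mb windows with at least 3 extreme SNPs, 100
#' standardisation bins, CLR grid of 10,000 per chromosome, top 0.1%
#' threshold, IBD pruning at PI_HAT 0.18), so the zero-argument
#' configuration reproduces the canonical scan.
#'
#' @param vcf path to a phased VCF (alternative: pass an in-memory dataset
#'   to [run_pipeline()] directly).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param qc list of [qc_filter()] thresholds plus `ibd` (PI_HAT cut-off).
#' @param roh [roh_params()] list.
#' @param scan iHS/nSL window parameters.
#' @param clr CLR parameters (`grid_size`, `top_fraction`, `folded`).
#' @param min_methods consensus support requirement.
#' @param gff,qtl optional annotation inputs.
#' @export
pipeline_config <- function(vcf = NULL, out_dir = tempfile("sweepstack_"),
                            seed = 1L,
                            qc = list(snp_call = 0.95, ind_call = 0.90,
                                      maf = 0.01, hwe_p = 1e-4, ibd = 0.18),
                            roh = roh_params(),
                            scan = list(window_bp = 5e5, step_bp = 1e4,
                                        threshold = 4, min_hits = 3,
                                        n_bins = 100),
                            clr = list(grid_size = 10000,
                                       top_fraction = 0.001,
                                       folded = FALSE),
                            min_methods = 2, gff = NULL, qtl = NULL) {
  cfg <- list(vcf = vcf, out_dir = out_dir, seed = as.integer(seed),
              qc = qc, roh = roh, scan = scan, clr = clr,
              min_methods = min_methods, gff = gff, qtl = qtl)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- pipeline_config()
  for (nm in names(y)) {
    if (is.list(base[[nm]]) && is.list(y[[nm]])) {
      for (k in names(y[[nm]])) base[[nm]][[k]] <- y[[nm]][[k]]
    } else base[[nm]] <- y[[nm]]
  }
  base
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full selection-signature pipeline
#'
#' Executes qc -> (roh, ihs, nsl, clr) -> consensus -> annotate on a phased
#' dataset, writing each stage's plot-ready TSV plus a JSON manifest of
#' parameters, input hashes, and row counts.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional in-memory dataset (list with `haps`, `variants`,
#'   `samples`) overriding `config$vcf`.
#' @return the manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- "input"
  manifest <- list(seed = config$seed,
                   parameters = lapply(config[c("qc", "roh", "scan", "clr",
                                                "min_methods")], unclass),
                   stages = list())
  res <- tryCatch({
    if (is.null(dataset)) {
      if (is.null(config$vcf)) stop("no input: set config$vcf or pass dataset")
      dataset <- read_vcf(config$vcf)
      manifest$input <- list(vcf = config$vcf,
                             md5 = unname(tools::md5sum(config$vcf)))
    }
    if (is.null(dataset$haps))
      stop("phased haplotypes required (all GT fields must use '|')")
    if (is.null(dataset$geno)) dataset$geno <- haps_to_geno(dataset$haps)

    stage <- "qc"
    qc <- qc_filter(dataset$geno, dataset$variants, dataset$samples,
                    snp_call = config$qc$snp_call,
                    ind_call = config$qc$ind_call,
                    maf = config$qc$maf, hwe_p = config$qc$hwe_p)
    keep_snp <- match(qc$variants$snp_id, dataset$variants$snp_id)
    keep_ind <- match(qc$samples$sample_id, dataset$samples$sample_id)
    if (!is.null(config$qc$ibd) && nrow(qc$geno) >= 2) {
      ph <- ibd_pihat(qc$geno)
      retained <- prune_related(ph, threshold = config$qc$ibd,
                                sample_ids = qc$samples$sample_id)
      pruned <- setdiff(qc$samples$sample_id, retained)
      keep <- qc$samples$sample_id %in% retained
      qc$geno <- qc$geno[keep, , drop = FALSE]
      qc$samples <- qc$samples[keep, , drop = FALSE]
      keep_ind <- keep_ind[keep]
      qc$report <- rbind(qc$report,
                         data.frame(filter = "ibd_pihat", axis = "sample",
                                    removed = length(pruned),
                                    retained = sum(keep)))
    }
    hap_rows <- as.vector(rbind(2 * keep_ind - 1, 2 * keep_ind))
    haps <- dataset$haps[hap_rows, keep_snp, drop = FALSE]
    variants <- qc$variants
    write_tsv(qc$report, file.path(config$out_dir, "qc_report.tsv"))
    write_tsv(ld_decay(qc$geno, variants),
              file.path(config$out_dir, "ld_decay.tsv"))
    manifest$stages$qc <- list(n_snps = ncol(qc$geno),
                               n_samples = nrow(qc$geno))

    stage <- "roh"
    runs <- detect_roh_all(qc$geno, variants, config$roh)
    inc <- eroi_scores(roh_incidence(runs, variants, nrow(qc$geno)))
    roh_regions <- call_eroi_regions(inc, threshold = config$scan$threshold)
    write_tsv(runs, file.path(config$out_dir, "roh_runs.tsv"))
    write_tsv(inc, file.path(config$out_dir, "roh_incidence.tsv"))
    write_tsv(roh_regions, file.path(config$out_dir, "roh_regions.tsv"))
    manifest$stages$roh <- list(n_runs = nrow(runs),
                                n_regions = nrow(roh_regions))

    scan_args <- config$scan
    stage <- "ihs"
    ihs <- haplo_stage(haps, variants, "ihs", n_bins = scan_args$n_bins,
                       window_bp = scan_args$window_bp,
                       step_bp = scan_args$step_bp,
                       threshold = scan_args$threshold,
                       min_hits = scan_args$min_hits)
    write_tsv(ihs$track, file.path(config$out_dir, "ihs_track.tsv"))
    write_tsv(ihs$regions, file.path(config$out_dir, "ihs_regions.tsv"))
    manifest$stages$ihs <- list(n_scored = sum(!is.na(ihs$track$std)),
                                n_regions = nrow(ihs$regions))

    stage <- "nsl"
    nsl <- haplo_stage(haps, variants, "nsl", n_bins = scan_args$n_bins,
                       window_bp = scan_args$window_bp,
                       step_bp = scan_args$step_bp,
                       threshold = scan_args$threshold,
                       min_hits = scan_args$min_hits)
    write_tsv(nsl$track, file.path(config$out_dir, "nsl_track.tsv"))
    write_tsv(nsl$regions, file.path(config$out_dir, "nsl_regions.tsv"))
    manifest$stages$nsl <- list(n_scored = sum(!is.na(nsl$track$std)),
                                n_regions = nrow(nsl$regions))

    stage <- "clr"
    pol <- polarize_haps(haps, variants)
    counts <- colSums(pol$haps)
    seg <- counts >= 1 & counts <= nrow(pol$haps) - 1
    sfs <- empirical_sfs(counts[seg], nrow(pol$haps),
                         folded = isTRUE(config$clr$folded))
    grid <- clr_scan(variants[seg, , drop = FALSE], counts[seg], sfs,
                     grid_size = config$clr$grid_size)
    thr <- empirical_threshold(grid, config$clr$top_fraction)
    write_tsv(grid, file.path(config$out_dir, "clr_grid.tsv"))
    write_tsv(thr$regions, file.path(config$out_dir, "clr_regions.tsv"))
    manifest$stages$clr <- list(threshold = thr$threshold,
                                n_regions = nrow(thr$regions))

    stage <- "consensus"
    cons <- build_consensus(list(roh_regions, ihs$regions, nsl$regions,
                                 thr$regions),
                            min_methods = config$min_methods)
    write_tsv(cons, file.path(config$out_dir, "consensus_regions.tsv"))
    manifest$stages$consensus <- list(n_regions = nrow(cons))

    if (!is.null(config$qtl)) {
      stage <- "annotate"
      qtl <- read_qtl_table(config$qtl)
      enr <- qtl_enrichment(cons, qtl, scope = "genome")
      ov <- features_in_regions(cons, qtl)
      write_tsv(enr, file.path(config$out_dir, "qtl_enrichment.tsv"))
      write_tsv(classify_regions_by_qtl(ov),
                file.path(config$out_dir, "qtl_classes.tsv"))
      manifest$stages$annotate <- list(n_classes = nrow(enr))
    }
    if (!is.null(config$gff)) {
      stage <- "annotate_genes"
      genes <- read_gff_features(config$gff)
      write_tsv(features_in_regions(cons, genes),
                file.path(config$out_dir, "genes_in_regions.tsv"))
    }
    list(qc = qc, runs = runs, incidence = inc, roh_regions = roh_regions,
         ihs = ihs, nsl = nsl, clr_grid = grid, clr = thr, consensus = cons)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  outs <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$outputs <- lapply(stats::setNames(nm = basename(outs)),
                             function(f) {
    p <- file.path(config$out_dir, f)
    list(md5 = unname(tools::md5sum(p)),
         n_rows = length(readLines(p)) - 1L)
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(res, list(manifest = manifest, out_dir = config$out_dir)))
}

#' Plot-ready Manhattan table
#'
#' One row per SNP with its score, an extremeness flag, and whether it lies
#' inside a multi-method consensus region — sufficient to redraw a
#' Manhattan plot of any of the four scans.
#'
#' @param track score track with `chrom`, `pos_bp` and a value column.
#' @param value_col name of the value column (e.g. "neglog10p").
#' @param threshold extremeness threshold on the value column.
#' @param regions optional consensus region table.
#' @export
manhattan_table <- function(track, value_col = "neglog10p", threshold = 4,
                            regions = NULL) {
  out <- data.frame(chrom = track$chrom, pos = track$pos_bp,
                    value = track[[value_col]], stringsAsFactors = FALSE)
  out$is_extreme <- !is.na(out$value) & out$value >= threshold
  out$in_confirmed_region <- FALSE
  if (!is.null(regions) && nrow(regions) > 0) {
    for (k in seq_len(nrow(regions))) {
      hit <- out$chrom == regions$chrom[k] &
        out$pos >= regions$start_bp[k] & out$pos <= regions$end_bp[k]
      out$in_confirmed_region <- out$in_confirmed_region | hit
    }
  }
  out
}
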