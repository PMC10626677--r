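mk_features <- function(chrom, s, e, id = NULL, class = NULL) {
  n <- length(s)
  data.frame(chrom = as.character(chrom), start_bp = s, end_bp = e,
             feature_id = if (is.null(id)) sprintf("f%d", seq_len(n)) else id,
             feature_class = if (is.null(class)) "gene" else class,
             stringsAsFactors = FALSE)
}

mk_regions <- function(chrom, s, e)
  data.frame(chrom = as.character(chrom), start_bp = s, end_bp = e,
             stringsAsFactors = FALSE)

test_that("feature overlap respects chromosome and closed intervals", {
  regions <- mk_regions(1, 1000, 2000)
  inside <- mk_features(1, 1200, 1800, id = "g1")
  other_chrom <- mk_features(2, 1200, 1800, id = "g2")
  ov <- features_in_regions(regions, rbind(inside, other_chrom))
  expect_equal(ov$feature_id, "g1")
  # shared endpoint counts
  edge <- mk_features(1, 2000, 2500, id = "g3")
  expect_equal(nrow(features_in_regions(regions, edge)), 1)
  expect_equal(nrow(features_in_regions(regions,
                                        mk_features(1, 2001, 2500))), 0)
})

test_that("feature overlap matches a brute-force all-pairs scan", {
  set.seed(81)
  for (rep in 1:20) {
    rs <- sample.int(5000, 5)
    regions <- mk_regions(sample(1:2, 5, TRUE), rs, rs + sample.int(800, 5))
    fs <- sample.int(5000, 30)
    features <- mk_features(sample(1:2, 30, TRUE), fs,
                            fs + sample.int(300, 30),
                            id = sprintf("f%d", 1:30))
    ov <- features_in_regions(regions, features)
    brute <- 0
    for (i in seq_len(nrow(regions))) {
      for (j in seq_len(nrow(features))) {
        if (regions$chrom[i] == features$chrom[j] &&
            regions$start_bp[i] <= features$end_bp[j] &&
            features$start_bp[j] <= regions$end_bp[i]) {
          brute <- brute + 1
          expect_true(any(ov$region_idx == i & ov$feature_id ==
                            features$feature_id[j]))
        }
      }
    }
    expect_equal(nrow(ov), brute)
  }
})

test_that("a class comprising all QTLs has unit richness and P = 1", {
  qtl <- mk_features(1, 1:20 * 100, 1:20 * 100 + 50, class = "Milk")
  qtl$trait <- "milk yield"
  regions <- mk_regions(1, 500, 1200)
  enr <- qtl_enrichment(regions, qtl, scope = "genome")
  expect_equal(enr$richness, 1)
  expect_equal(enr$p, 1)
})

test_that("richness and hypergeometric P match the worked enumeration", {
  # 100 QTLs, 20 in the class; 10 overlap regions, 8 of them in the class
  set.seed(82)
  cls <- rep(c("Meat_and_Carcass", "Other"), c(20, 80))
  start <- numeric(100)
  start[1:8] <- 1000 + 1:8 * 10        # class members inside the region
  start[21:22] <- 1000 + 9:10 * 10     # two non-class inside
  start[c(9:20, 23:100)] <- 1e6 + seq_len(90) * 1000 # everything else out
  qtl <- mk_features(1, start, start + 5,
                     id = sprintf("q%d", 1:100), class = cls)
  qtl$trait <- cls
  regions <- mk_regions(1, 900, 1300)
  enr <- qtl_enrichment(regions, qtl, scope = "genome")
  row <- enr[enr$feature_class == "Meat_and_Carcass", ]
  expect_equal(row$observed, 8)
  expect_equal(row$richness, 8 / (10 * 0.2))
  expect_equal(row$p, oracle_hyper_tail(8, 20, 100, 10), tolerance = 1e-12)
  other <- enr[enr$feature_class == "Other", ]
  expect_equal(other$p, oracle_hyper_tail(2, 80, 100, 10),
               tolerance = 1e-12)
})

test_that("hypergeometric P matches enumeration on small random scopes", {
  set.seed(83)
  for (rep in 1:30) {
    total <- sample(10:30, 1)
    k_class <- sample(1:total, 1)
    n_draw <- sample(1:total, 1)
    obs <- sample(0:min(k_class, n_draw), 1)
    expect_equal(stats::phyper(obs - 1, k_class, total - k_class, n_draw,
                               lower.tail = FALSE),
                 oracle_hyper_tail(obs, k_class, total, n_draw),
                 tolerance = 1e-12)
  }
})

test_that("FDR adjustment reproduces a hand Benjamini-Hochberg", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.30)
  # step-up: p * 5 / rank, cumulative minimum from the largest rank
  hand <- c(0.005, 0.020, 0.05125, 0.05125, 0.30)
  expect_equal(stats::p.adjust(p, "BH"), hand, tolerance = 1e-12)
  # and the enrichment table carries BH-adjusted values
  cls <- rep(c("A", "B", "C"), c(5, 5, 90))
  start <- c(1:10 * 10 + 1000, 1e6 + 1:90 * 1000)
  qtl <- mk_features(1, start, start + 5, id = sprintf("q%d", 1:100),
                     class = cls)
  qtl$trait <- cls
  enr <- qtl_enrichment(mk_regions(1, 1000, 1200), qtl, scope = "genome")
  expect_equal(enr$fdr, stats::p.adjust(enr$p, "BH"))
  expect_true(all(enr$fdr >= enr$p - 1e-12))
})

test_that("a constructed 3x overrepresented class recovers richness 3", {
  # 200 QTLs, class A 40 of them; 40 QTLs overlap regions, 24 in class A:
  # expected A = 40 * 40/200 = 8, observed 24 -> richness 3.0
  cls <- rep(c("A", "B"), c(40, 160))
  start <- numeric(200)
  start[1:24] <- 1000 + 1:24 * 10          # class A inside
  start[41:56] <- 1500 + 1:16 * 10         # class B inside (16)
  start[c(25:40, 57:200)] <- 1e6 + seq_len(160) * 1000
  qtl <- mk_features(1, start, start + 5, id = sprintf("q%d", 1:200),
                     class = cls)
  qtl$trait <- cls
  enr <- qtl_enrichment(mk_regions(1, 900, 1700), qtl, scope = "genome")
  a <- enr[enr$feature_class == "A", ]
  expect_equal(a$richness, 3)
  expect_lt(a$fdr, 0.01)
})

test_that("per-class composition percentages are conserved", {
  ov <- data.frame(region_idx = c(1, 1, 2, 2), chrom = "1",
                   region_start = 1, region_end = 2,
                   feature_id = sprintf("q%d", 1:4),
                   feature_class = c("Milk", "Meat", "Meat", "Meat"))
  cl <- classify_regions_by_qtl(ov)
  expect_equal(cl$percent[cl$feature_class == "Meat"], 75)
  expect_equal(cl$percent[cl$feature_class == "Milk"], 25)
  expect_equal(sum(cl$count), nrow(ov))
  single <- classify_regions_by_qtl(ov[1, ])
  expect_equal(single$percent, 100)
})

test_that("GFF3 and BED readers land on 1-based inclusive coordinates", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\ttest\tgene\t1001\t2000\t.\t+\t.\tID=gene1;Name=ABC1",
               "1\ttest\texon\t1001\t1500\t.\t+\t.\tID=exon1"), gff)
  g <- read_gff_features(gff)
  expect_equal(nrow(g), 1) # exon filtered out
  expect_equal(g$start_bp, 1001)
  expect_equal(g$end_bp, 2000)
  expect_equal(g$feature_id, "ABC1")
  bed <- tempfile(fileext = ".bed")
  writeLines("1\t1000\t2000\tqtlA", bed)
  b <- read_bed_features(bed)
  expect_equal(b$start_bp, 1001) # 0-based half-open converted
  expect_equal(b$end_bp, 2000)
  expect_equal(b$feature_id, "qtlA")
})

test_that("QTL table reader maps the expected columns", {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(chrom = c(1, 2), start = c(100, 200),
                                end = c(150, 260), trait = c("t1", "t2"),
                                class = c("Milk", "Wool")),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  q <- read_qtl_table(f)
  expect_equal(q$feature_class, c("Milk", "Wool"))
  expect_equal(q$start_bp, c(100, 200))
})
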