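test_that("annotation filters remove repeat, CNV and indel-flank markers", {
  cand <- mk_markers(c(150, 505, 511, 900))
  tracks <- annotation_tracks(
    repeats = data.table(chrom = "chr1", start = 100L, end = 200L),
    cnvs = data.table(chrom = "chr1", start = 700L, end = 800L),
    indel_positions = data.table(chrom = "chr1", pos = 500L))
  out <- filter_by_annotation(cand, tracks, indel_flank_bp = 10)
  expect_equal(out$markers$pos, c(511L, 900L))   # |511-500| = 11 > 10
  expect_equal(out$filter_log[pos == 150, reason], "repeat")
  expect_equal(out$filter_log[pos == 505, reason], "indel_flank")
  ## every candidate in exactly one of markers / filter_log
  expect_equal(sort(c(out$markers$pos, out$filter_log$pos)), sort(cand$pos))
})

test_that("empty tracks keep all candidates; unknown chromosomes warn", {
  cand <- mk_markers(c(10, 20, 30))
  expect_equal(filter_by_annotation(cand, annotation_tracks())$markers,
               as_marker_table(cand))
  tracks <- annotation_tracks(repeats = data.table(chrom = "chr2",
                                                   start = 0L, end = 50L))
  expect_warning(out <- filter_by_annotation(cand, tracks), "absent")
  expect_equal(nrow(out$markers), 3L)
})

test_that("depth-deviation filter uses strict inequalities on the chromosome median", {
  ## depth table: 9 positions of depth 30 plus the marker sites -> median 30
  mk <- mk_markers(c(11, 12, 13, 14))
  dp <- data.table(chrom = "chr1", pos = 1:14,
                   depth = c(rep(30L, 10), 46L, 45L, 14L, 15L))
  tracks <- annotation_tracks(depth = dp)
  out <- filter_by_depth_deviation(mk, tracks)
  expect_equal(out$markers$pos, c(12L, 14L))      # 45 and 15 are boundary
  expect_equal(out$filter_log$pos, c(11L, 13L))   # 46 > 45, 14 < 15
  expect_true(all(out$filter_log$reason == "depth_deviation"))
})

test_that("all-zero-depth chromosomes lose their markers with a warning", {
  mk <- mk_markers(c(5, 6))
  tracks <- annotation_tracks(depth = data.table(chrom = "chr1", pos = 1:10,
                                                 depth = 0L))
  expect_warning(out <- filter_by_depth_deviation(mk, tracks), "all-zero")
  expect_equal(nrow(out$markers), 0L)
  expect_equal(nrow(out$filter_log), 2L)
})

test_that("annotation and depth filters commute", {
  set.seed(5)
  cand <- mk_markers(sort(sample(1:1000, 60)))
  tracks <- annotation_tracks(
    repeats = data.table(chrom = "chr1", start = c(100L, 600L),
                         end = c(220L, 650L)),
    indel_positions = data.table(chrom = "chr1", pos = c(400L, 800L)),
    depth = data.table(chrom = "chr1", pos = 1:1000,
                       depth = sample(c(10L, 30L, 60L), 1000, replace = TRUE,
                                      prob = c(.2, .6, .2))))
  ab <- filter_by_depth_deviation(filter_by_annotation(cand, tracks), tracks)
  ba <- filter_by_annotation(filter_by_depth_deviation(cand, tracks), tracks)
  expect_equal(ab$markers, ba$markers)
})

test_that("reciprocal filter keeps only allele-consistent counterparts", {
  cmap <- coordinate_map(data.table(
    chrom_a = "chr1", pos_a = c(100L, 200L, 300L, 400L),
    chrom_b = "chrB", pos_b = c(1100L, 1200L, 1300L, 1400L)))
  a <- data.table(chrom = "chr1", pos = c(100L, 200L, 300L),
                  p1_allele = "A", p2_allele = "G")
  b <- data.table(chrom = "chrB", pos = c(1100L, 1300L),
                  p1_allele = c("A", "G"), p2_allele = c("G", "A"))
  out <- reciprocal_filter(a, b, cmap)
  expect_equal(out$markers$pos, 100L)             # 200 unmatched, 300 swapped
  expect_setequal(out$filter_log$reason, "not_reciprocal")
})

test_that("reciprocal filter drops ambiguously mapped positions", {
  cmap <- coordinate_map(data.table(chrom_a = "chr1", pos_a = c(100L, 100L),
                                    chrom_b = "chrB", pos_b = c(900L, 901L)))
  a <- data.table(chrom = "chr1", pos = 100L, p1_allele = "A",
                  p2_allele = "G")
  b <- data.table(chrom = "chrB", pos = c(900L, 901L), p1_allele = "A",
                  p2_allele = "G")
  out <- reciprocal_filter(a, b, cmap)
  expect_equal(nrow(out$markers), 0L)
  expect_equal(out$filter_log$reason, "ambiguous_mapping")
})

test_that("reciprocal filter is symmetric across the two directions", {
  cmap <- coordinate_map(data.table(
    chrom_a = "chr1", pos_a = c(100L, 200L, 300L),
    chrom_b = "chrB", pos_b = c(150L, 250L, 350L)))
  inv <- coordinate_map(data.table(chrom_a = cmap$chrom_b, pos_a = cmap$pos_b,
                                   chrom_b = cmap$chrom_a, pos_b = cmap$pos_a))
  a <- data.table(chrom = "chr1", pos = c(100L, 200L),
                  p1_allele = c("A", "C"), p2_allele = c("G", "T"))
  b <- data.table(chrom = "chrB", pos = c(150L, 350L),
                  p1_allele = c("A", "C"), p2_allele = c("G", "T"))
  ab <- reciprocal_filter(a, b, cmap)$markers
  ba <- reciprocal_filter(b, a, inv)$markers
  ## same marker set expressed in the other coordinate system
  expect_equal(ab$pos, 100L)
  expect_equal(ba$pos, 150L)
  expect_equal(ab[, .(p1_allele, p2_allele)], ba[, .(p1_allele, p2_allele)])
})

test_that("consensus intersection requires presence in all three sets", {
  cmap <- coordinate_map(data.table(
    chrom_a = "chr1", pos_a = c(10L, 20L, 30L),
    chrom_b = "chrB", pos_b = c(110L, 120L, 130L)))
  aln <- data.table(chrom = "chr1", pos = c(10L, 20L, 30L),
                    p1_allele = "A", p2_allele = "G",
                    source = "genome_alignment")
  m1 <- data.table(chrom = "chr1", pos = c(10L, 30L), p1_allele = "A",
                   p2_allele = "G")
  m2 <- data.table(chrom = "chrB", pos = c(110L, 120L), p1_allele = "A",
                   p2_allele = "G")
  out <- intersect_consensus(aln, m1, m2, cmap)
  expect_equal(out$markers$pos, 10L)
  expect_equal(out$markers$source, "consensus")
  ## consensus is a subset of every input set
  expect_true(all(out$markers$pos %in% aln$pos))
  expect_true(all(out$markers$pos %in% m1$pos))
  expect_warning(
    intersect_consensus(aln[0], m1, m2, cmap), "empty consensus")
})

test_that("marker stats report per-chromosome distances and degenerate cases", {
  st <- marker_stats(mk_markers(c(100, 200, 400)))
  expect_equal(st[chrom == "chr1", mean_dist], 150)
  expect_equal(st[chrom == "chr1", median_dist], 150)
  expect_equal(st[chrom == "total", n], 3L)
  st1 <- marker_stats(mk_markers(42))
  expect_equal(st1[chrom == "chr1", n], 1L)
  expect_true(is.na(st1[chrom == "chr1", mean_dist]))
})

test_that("marker tables reject malformed input", {
  expect_error(as_marker_table(mk_markers(10, p1 = "A", p2 = "A")), "differ")
  expect_error(as_marker_table(data.table(chrom = "c", pos = c(5L, 5L),
                                          p1_allele = "A", p2_allele = "G")),
               "duplicate")
  expect_error(as_marker_table(mk_markers(10, p1 = "N")), "A/C/G/T")
})

test_that("marker catalogs round-trip through TSV", {
  cand <- mk_markers(c(150, 900))
  tracks <- annotation_tracks(repeats = data.table(chrom = "chr1",
                                                   start = 100L, end = 200L))
  cat0 <- filter_by_annotation(cand, tracks)
  f <- tempfile(fileext = ".tsv")
  write_marker_catalog(cat0, f)
  back <- read_marker_catalog(f)
  expect_equal(back$markers, cat0$markers)
})

test_that("VCF and BED adapters enforce marker preconditions", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "p.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=500000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P2", sep = "\t"),
    "chr1\t150\t.\tA\tG\t60\tPASS\t.\tGT\t1/1",
    "chr1\t300\t.\tC\tT\t60\tPASS\t.\tGT\t0/1",
    "chr1\t900\t.\tTA\tT\t60\tPASS\t.\tGT\t1/1"), vcf)
  snv <- read_snv_vcf(vcf)
  expect_equal(snv$pos, 150L)          # het and indel records excluded
  expect_equal(snv[, .(p1_allele, p2_allele)],
               data.table(p1_allele = "A", p2_allele = "G"))
  ind <- read_indel_positions(vcf)
  expect_equal(ind$pos, 900L)

  bed <- file.path(dir, "r.bed")
  writeLines("chr1\t100\t200", bed)
  expect_equal(read_bed_track(bed),
               data.table(chrom = "chr1", start = 100L, end = 200L))
})
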