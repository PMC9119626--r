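library(data.table)

## small marker table on one or two chromosomes
mk_markers <- function(pos, chrom = "chr1", p1 = "A", p2 = "G") {
  data.table(chrom = chrom, pos = as.integer(pos),
             p1_allele = p1, p2_allele = p2, source = "reference_mapping")
}

## one allele-observation row from per-base (count, quality-per-read) pairs
mk_obs <- function(sample, chrom, pos, counts = c(A = 0, C = 0, G = 0, T = 0),
                   qual_per_read = 30) {
  bases <- c("A", "C", "G", "T")
  cnt <- setNames(rep(0L, 4), bases)
  cnt[names(counts)] <- as.integer(counts)
  row <- data.table(sample = sample, chrom = chrom, pos = as.integer(pos))
  row[, (paste0("count_", bases)) := as.list(cnt)]
  row[, (paste0("qualsum_", bases)) := as.list(as.numeric(cnt) * qual_per_read)]
  row
}

## long genotype table from a wide call matrix (rows = markers)
mk_calls <- function(mat, pos = NULL, chrom = "chr1") {
  gam <- c("a", "b", "c", "d")
  if (is.null(pos)) pos <- seq_len(nrow(mat)) * 100L
  rbindlist(lapply(1:4, function(i) {
    data.table(sample = gam[i], chrom = chrom, pos = as.integer(pos),
               call = mat[, i], qnet = 60, purity = 1,
               status = ifelse(is.na(mat[, i]), "no_data", "called"))
  }))
}

## wide integer genotype matrix (1/2) -> long call table
mk_calls_int <- function(G, pos = NULL, chrom = "chr1") {
  M <- matrix(ifelse(G == 1L, "P1", "P2"), ncol = 4)
  mk_calls(M, pos = pos, chrom = chrom)
}

## default yeast-scale fixture shared across tests (built once per run)
.fix_env <- new.env()
yeast_fixture <- function(n_markers = 50000L) {
  key <- paste0("cat", n_markers)
  if (is.null(.fix_env[[key]])) {
    cl <- yeast_chromosome_lengths()
    .fix_env[[key]] <- list(chrom_lengths = cl,
                            catalog = simulate_marker_catalog(cl, n_markers,
                                                              seed = 11))
  }
  .fix_env[[key]]
}
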