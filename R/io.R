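## TSV writers carry a commented provenance header; readers skip it.
.write_tsv <- function(dt, path, params = NULL) {
  hdr <- sprintf("# tetrarec %s%s",
                 as.character(utils::packageVersion("tetrarec")),
                 if (is.null(params)) "" else paste0(" | ", params))
  writeLines(hdr, path)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  first <- readLines(path, n = 50L)
  skip <- sum(cumprod(startsWith(first, "#")))
  fread(path, sep = "\t", skip = skip, header = TRUE)
}

#' Read candidate parental SNV markers from a VCF
#'
#' Keeps biallelic SNV records (single-base REF and ALT). When a genotype
#' (GT) field is present, only homozygous-ALT calls are kept and
#' heterozygous calls are excluded — variant calling itself happens
#' upstream; this reader only enforces the homozygosity precondition.
#' REF becomes the P1 allele and ALT the P2 allele.
#'
#' @param path VCF file (plain text or gzipped).
#' @param source marker source label (default `"reference_mapping"`).
#' @return marker data.table (`chrom`, `pos`, `p1_allele`, `p2_allele`,
#'   `source`).
#' @export
read_snv_vcf <- function(path, source = "reference_mapping") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.table(vcfR::getFIX(v))
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (nrow(v@gt) && ncol(v@gt) >= 2L) {
    gt <- vcfR::extract.gt(v, element = "GT")[, 1L]
    gt <- gsub("|", "/", gt, fixed = TRUE)
    keep <- keep & !is.na(gt) & gt %in% c("1/1", "1")
  }
  fix <- fix[keep]
  data.table(chrom = fix$CHROM, pos = as.integer(fix$POS),
             p1_allele = fix$REF, p2_allele = fix$ALT, source = source)
}

#' Read indel anchor positions from a VCF
#'
#' Returns the POS anchors of records whose REF or ALT is longer than one
#' base, for use as the indel track of [annotation_tracks()].
#'
#' @param path VCF file.
#' @return data.table with `chrom`, `pos`.
#' @export
read_indel_positions <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.table(vcfR::getFIX(v))
  ind <- fix[nchar(REF) > 1L | nchar(ALT) > 1L]
  data.table(chrom = ind$CHROM, pos = as.integer(ind$POS))
}

#' Read an interval track from a BED file
#'
#' @param path BED file (0-based half-open intervals).
#' @return data.table with `chrom`, `start`, `end` in the BED convention.
#' @export
read_bed_track <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr))
  } else {
    bed <- fread(path, header = FALSE, sep = "\t")
    data.table(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
               end = as.integer(bed[[3]]))
  }
}

#' Read a per-site depth table
#'
#' Three tab-separated columns without header (chrom, 1-based position,
#' depth), the `samtools depth -aa` layout.
#'
#' @param path depth file.
#' @return data.table with `chrom`, `pos`, `depth`.
#' @export
read_depth_table <- function(path) {
  d <- fread(path, header = FALSE, sep = "\t")
  setnames(d, 1:3, c("chrom", "pos", "depth"))
  d[, .(chrom = as.character(chrom), pos = as.integer(pos),
        depth = as.integer(depth))]
}

#' Read a coordinate anchor table
#'
#' Tab-separated with header `chrom_a`, `pos_a`, `chrom_b`, `pos_b`.
#'
#' @param path anchor TSV.
#' @return a [coordinate_map()].
#' @export
read_coordinate_map <- function(path) {
  coordinate_map(.read_tsv(path))
}

#' Read a chromosome length table
#'
#' Tab-separated, two columns (chrom, length), header optional.
#'
#' @param path length TSV.
#' @return named integer vector.
#' @export
read_chrom_lengths <- function(path) {
  d <- fread(path, header = FALSE, sep = "\t")
  if (is.na(suppressWarnings(as.integer(d[[2]][1])))) d <- d[-1]
  setNames(as.integer(as.character(d[[2]])), as.character(d[[1]]))
}

#' Write / read a marker catalog as TSV
#'
#' @param catalog a [marker_catalog()].
#' @param path output marker TSV; the filter log goes to
#'   `<path>.filtered.tsv` when `log_path` is not given.
#' @param log_path optional filter-log path (NULL = derive from `path`).
#' @param params provenance string for the commented header.
#' @return `write_marker_catalog()` returns `path` invisibly;
#'   `read_marker_catalog()` returns a `marker_catalog`.
#' @export
write_marker_catalog <- function(catalog, path, log_path = NULL,
                                 params = NULL) {
  stopifnot(inherits(catalog, "marker_catalog"))
  .write_tsv(catalog$markers, path, params)
  if (is.null(log_path)) log_path <- paste0(path, ".filtered.tsv")
  .write_tsv(catalog$filter_log, log_path, params)
  invisible(path)
}

#' @rdname write_marker_catalog
#' @export
read_marker_catalog <- function(path) {
  marker_catalog(.read_tsv(path))
}

#' Write / read an allele-observation table as TSV
#'
#' @param obs observation table (see [simulate_observations()]).
#' @param path TSV path.
#' @param params provenance string.
#' @export
write_observations <- function(obs, path, params = NULL) {
  .write_tsv(as.data.table(obs), path, params)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  o <- .read_tsv(path)
  o[, `:=`(sample = as.character(sample), chrom = as.character(chrom),
           pos = as.integer(pos))]
  o[]
}

#' Write / read a genotype table as TSV
#'
#' @param calls genotype table from [genotype_gametes()].
#' @param path TSV path.
#' @param params provenance string.
#' @export
write_genotypes <- function(calls, path, params = NULL) {
  .write_tsv(as.data.table(calls), path, params)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  g <- .read_tsv(path)
  g[, `:=`(sample = as.character(sample), chrom = as.character(chrom),
           pos = as.integer(pos), call = as.character(call),
           status = as.character(status))]
  g[call == "", call := NA_character_]
  g[]
}

#' Read a tetrad manifest
#'
#' Tab-separated with header: `tetrad_id`, `gamete` (one of a/b/c/d),
#' `sample_id`, `observation_path`. Every tetrad must have 3 or 4 distinct
#' gamete labels; a 3-gamete tetrad is processed with its fourth gamete
#' all-NA and recovered by inference where the 2:2 ratio forces it.
#'
#' @param path manifest TSV.
#' @return validated data.table.
#' @export
read_manifest <- function(path) {
  m <- .read_tsv(path)
  need <- c("tetrad_id", "gamete", "sample_id", "observation_path")
  if (!all(need %in% names(m)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  m[, gamete := as.character(gamete)]
  bad <- m[, .(ok = all(gamete %in% c("a", "b", "c", "d")) &
                 uniqueN(gamete) == .N & .N %in% c(3L, 4L)),
           by = tetrad_id][ok == FALSE]
  if (nrow(bad))
    stop("invalid gamete labels for tetrad(s): ",
         paste(bad$tetrad_id, collapse = ", "))
  m
}
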