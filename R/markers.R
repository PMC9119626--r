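#' Marker tables and catalogs
#'
#' A *marker* is a biallelic SNV segregating between the two crossing parents:
#' one row with columns `chrom`, `pos` (1-based), `p1_allele`, `p2_allele`
#' (distinct bases in A/C/G/T) and `source` (one of `"reference_mapping"`,
#' `"genome_alignment"`, `"consensus"`). A *marker catalog* couples the
#' surviving markers with a filter log that records, for every removed
#' candidate, the first filter that removed it; every input candidate ends up
#' in exactly one of the two tables.
#'
#' @param markers data.frame of markers (see above); coerced and validated.
#' @param filter_log data.frame with marker columns plus `reason`.
#' @return `marker_catalog()` returns an object of class `marker_catalog`:
#'   a list with elements `markers` (sorted, duplicate-free data.table) and
#'   `filter_log`.
#' @export
marker_catalog <- function(markers, filter_log = NULL) {
  mk <- as_marker_table(markers)
  if (is.null(filter_log)) {
    filter_log <- data.table(chrom = character(), pos = integer(),
                             p1_allele = character(), p2_allele = character(),
                             source = character(), reason = character())
  } else {
    filter_log <- as.data.table(filter_log)
  }
  structure(list(markers = mk, filter_log = filter_log),
            class = "marker_catalog")
}

#' @param x a `marker_catalog`.
#' @param ... unused.
#' @rdname marker_catalog
#' @export
print.marker_catalog <- function(x, ...) {
  cat(sprintf("marker_catalog: %d markers on %d chromosome(s); %d filtered\n",
              nrow(x$markers), length(unique(x$markers$chrom)),
              nrow(x$filter_log)))
  if (nrow(x$filter_log))
    print(x$filter_log[, .N, by = reason])
  invisible(x)
}

#' @rdname marker_catalog
#' @export
as_marker_table <- function(markers) {
  mk <- as.data.table(markers)
  need <- c("chrom", "pos", "p1_allele", "p2_allele")
  if (!all(need %in% names(mk)))
    stop("markers need columns: ", paste(need, collapse = ", "))
  if (!"source" %in% names(mk)) mk[, source := "reference_mapping"]
  mk <- mk[, c(need, "source"), with = FALSE]
  mk[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
            p1_allele = toupper(p1_allele), p2_allele = toupper(p2_allele))]
  bases <- c("A", "C", "G", "T")
  if (any(!mk$p1_allele %in% bases) || any(!mk$p2_allele %in% bases))
    stop("parental alleles must be A/C/G/T")
  if (any(mk$p1_allele == mk$p2_allele))
    stop("p1_allele and p2_allele must differ at every marker")
  if (any(mk$pos < 1L)) stop("marker pos must be >= 1")
  setorder(mk, chrom, pos)
  if (anyDuplicated(mk, by = c("chrom", "pos")))
    stop("duplicate (chrom, pos) in marker table")
  mk[]
}

## accept a marker_catalog or a bare marker table
.markers_of <- function(x) {
  if (inherits(x, "marker_catalog")) x$markers else as_marker_table(x)
}
.log_of <- function(x) {
  if (inherits(x, "marker_catalog")) x$filter_log else NULL
}

#' Annotation tracks used by the marker filters
#'
#' Bundles the genomic annotation consumed by [filter_by_annotation()] and
#' [filter_by_depth_deviation()]. Interval tracks (`repeats`, `cnvs`) use the
#' BED convention: 0-based, half-open `[start, end)`. Indel positions and the
#' depth table are 1-based. Conversion to 1-based closed intervals happens
#' here, at the boundary.
#'
#' @param repeats,cnvs data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), or NULL for an empty track.
#' @param indel_positions data.frame with `chrom`, `pos` (1-based VCF POS
#'   anchors), or NULL.
#' @param depth data.frame with `chrom`, `pos`, `depth` covering every
#'   position of the chromosomes it annotates, or NULL.
#' @return object of class `annotation_tracks`.
#' @export
annotation_tracks <- function(repeats = NULL, cnvs = NULL,
                              indel_positions = NULL, depth = NULL) {
  iv <- function(x) {
    if (is.null(x)) return(data.table(chrom = character(), start = integer(),
                                      end = integer()))
    x <- as.data.table(x)[, .(chrom = as.character(chrom),
                              start = as.integer(start),
                              end = as.integer(end))]
    if (any(x$start >= x$end)) stop("intervals must have start < end")
    x
  }
  ip <- if (is.null(indel_positions)) {
    data.table(chrom = character(), pos = integer())
  } else {
    as.data.table(indel_positions)[, .(chrom = as.character(chrom),
                                       pos = as.integer(pos))]
  }
  dp <- if (is.null(depth)) {
    data.table(chrom = character(), pos = integer(), depth = integer())
  } else {
    as.data.table(depth)[, .(chrom = as.character(chrom),
                             pos = as.integer(pos),
                             depth = as.integer(depth))]
  }
  structure(list(repeats = iv(repeats), cnvs = iv(cnvs),
                 indel_positions = ip, depth = dp),
            class = "annotation_tracks")
}

## positions of markers (1-based) falling inside 0-based half-open intervals
.in_intervals <- function(mk, intervals) {
  if (nrow(intervals) == 0L || nrow(mk) == 0L)
    return(rep(FALSE, nrow(mk)))
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L,
                                                intervals$end))
  pts <- GenomicRanges::GRanges(mk$chrom, IRanges::IRanges(mk$pos, mk$pos))
  suppressWarnings(IRanges::overlapsAny(pts, gr))
}

#' Filter candidate markers by repeat, CNV and indel-flank annotation
#'
#' Removes candidates whose position lies inside any repeat interval, any CNV
#' interval, or within `indel_flank_bp` of an indel position (inclusive, both
#' sides, using the indel's VCF POS anchor). The first matching filter (in
#' the order repeat, cnv, indel_flank) is logged as the removal reason.
#' Candidates on chromosomes absent from all tracks are kept, with a warning.
#'
#' @param candidates marker table or `marker_catalog` of biallelic SNVs
#'   (heterozygous calls must already be excluded upstream).
#' @param tracks an [annotation_tracks()] object.
#' @param indel_flank_bp flank half-width in bp (default 10).
#' @return a [marker_catalog()].
#' @export
filter_by_annotation <- function(candidates, tracks, indel_flank_bp = 10L) {
  mk <- .markers_of(candidates)
  prev_log <- .log_of(candidates)
  stopifnot(inherits(tracks, "annotation_tracks"))

  track_chroms <- unique(c(tracks$repeats$chrom, tracks$cnvs$chrom,
                           tracks$indel_positions$chrom))
  unknown <- setdiff(unique(mk$chrom), track_chroms)
  if (length(track_chroms) && length(unknown))
    warning("candidate chromosome(s) absent from annotation tracks, kept ",
            "unfiltered: ", paste(unknown, collapse = ", "))

  why <- rep(NA_character_, nrow(mk))
  why[.in_intervals(mk, tracks$repeats)] <- "repeat"
  hit_cnv <- .in_intervals(mk, tracks$cnvs)
  why[is.na(why) & hit_cnv] <- "cnv"
  if (nrow(tracks$indel_positions)) {
    flank <- tracks$indel_positions[, .(chrom,
                                        start = pos - as.integer(indel_flank_bp) - 1L,
                                        end = pos + as.integer(indel_flank_bp))]
    flank[, start := pmax(start, 0L)]
    hit_ind <- .in_intervals(mk, flank)
    why[is.na(why) & hit_ind] <- "indel_flank"
  }

  removed <- mk[!is.na(why)]
  removed[, reason := why[!is.na(why)]]
  marker_catalog(mk[is.na(why)], rbind(prev_log, removed, fill = TRUE))
}

#' Filter markers whose mapping depth deviates from the chromosome median
#'
#' A marker is removed iff its per-site depth is strictly greater than
#' `high_factor` times, or strictly less than `low_factor` times, the
#' chromosome-wide median depth (computed over every position present in the
#' depth table for that chromosome, zeros included). Boundary values are
#' retained. A chromosome whose depth is all zero has all its markers
#' removed, with a warning. Marker positions missing from the depth table are
#' treated as depth 0.
#'
#' @param catalog marker table or `marker_catalog`.
#' @param tracks an [annotation_tracks()] with a `depth` table covering the
#'   marker chromosomes.
#' @param high_factor,low_factor multiples of the chromosome-wide median
#'   (defaults 1.5 and 0.5).
#' @return a [marker_catalog()].
#' @export
filter_by_depth_deviation <- function(catalog, tracks,
                                      high_factor = 1.5, low_factor = 0.5) {
  mk <- .markers_of(catalog)
  prev_log <- .log_of(catalog)
  stopifnot(inherits(tracks, "annotation_tracks"))
  dp <- tracks$depth
  med <- dp[, .(med = as.numeric(median(depth))), by = chrom]

  mk2 <- copy(mk)
  mk2[, depth := dp[mk2, on = c("chrom", "pos"), x.depth]]
  mk2[is.na(depth), depth := 0L]
  mk2[, med := med[mk2, on = "chrom", x.med]]

  zero_chr <- med[med == 0, chrom]
  if (length(zero_chr) && any(mk2$chrom %in% zero_chr))
    warning("all-zero depth on chromosome(s): ",
            paste(intersect(zero_chr, unique(mk2$chrom)), collapse = ", "),
            "; their markers were removed")

  drop <- (!is.na(mk2$med)) &
    (mk2$depth > high_factor * mk2$med |
       mk2$depth < low_factor * mk2$med |
       mk2$med == 0)
  removed <- mk[drop][, reason := "depth_deviation"]
  marker_catalog(mk[!drop], rbind(prev_log, removed, fill = TRUE))
}

#' Coordinate map between two parental coordinate systems
#'
#' An anchor table pairing positions of parent A's coordinate system with
#' parent B's. Must be injective in each direction where defined.
#'
#' @param map data.frame with columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b`.
#' @return validated data.table of class `coordinate_map`.
#' @export
coordinate_map <- function(map) {
  m <- as.data.table(map)
  need <- c("chrom_a", "pos_a", "chrom_b", "pos_b")
  if (!all(need %in% names(m)))
    stop("coordinate map needs columns: ", paste(need, collapse = ", "))
  m <- m[, .(chrom_a = as.character(chrom_a), pos_a = as.integer(pos_a),
             chrom_b = as.character(chrom_b), pos_b = as.integer(pos_b))]
  setattr(m, "class", c("coordinate_map", class(m)))
  m[]
}

## markers expressed in B coordinates -> A coordinates (NA where unmapped;
## positions hit by multiple anchors are flagged ambiguous)
.map_b_to_a <- function(mk_b, cmap) {
  amb <- cmap[, .N, by = .(chrom_b, pos_b)][N > 1L]
  out <- copy(mk_b)
  out[, ambiguous := FALSE]
  if (nrow(amb))
    out[amb, on = c(chrom = "chrom_b", pos = "pos_b"), ambiguous := TRUE]
  uni <- cmap[!amb, on = c("chrom_b", "pos_b")]
  out[, `:=`(chrom_a = uni[out, on = c(chrom_b = "chrom", pos_b = "pos"), x.chrom_a],
             pos_a   = uni[out, on = c(chrom_b = "chrom", pos_b = "pos"), x.pos_a])]
  out
}

#' Retain markers recovered reciprocally in both comparison directions
#'
#' Parent-based SNV calling is directional (A-to-B vs B-to-A); this filter
#' retains a marker iff a counterpart with the identical `(p1_allele,
#' p2_allele)` pair exists in the other direction at the position given by
#' the coordinate map. The result is expressed in the A coordinate system.
#' Markers whose position maps to multiple counterparts are dropped and
#' logged as `ambiguous`.
#'
#' @param set_a_to_b markers called in direction A-to-B, in A coordinates.
#' @param set_b_to_a markers called in direction B-to-A, in B coordinates.
#' @param cmap a [coordinate_map()] (A positions vs B positions).
#' @return a [marker_catalog()] in A coordinates.
#' @export
reciprocal_filter <- function(set_a_to_b, set_b_to_a, cmap) {
  a <- .markers_of(set_a_to_b)
  b <- .markers_of(set_b_to_a)
  stopifnot(inherits(cmap, "coordinate_map"))

  amb_a <- cmap[, .N, by = .(chrom_a, pos_a)][N > 1L]
  a2 <- copy(a)[, ambiguous := FALSE]
  if (nrow(amb_a))
    a2[amb_a, on = c(chrom = "chrom_a", pos = "pos_a"), ambiguous := TRUE]

  bm <- .map_b_to_a(b, cmap)
  bm <- bm[ambiguous == FALSE & !is.na(pos_a)]
  a2[, has_counterpart := FALSE]
  if (nrow(bm))
    a2[bm, on = c(chrom = "chrom_a", pos = "pos_a",
                  p1_allele = "p1_allele", p2_allele = "p2_allele"),
       has_counterpart := TRUE]

  keep <- a2$has_counterpart & !a2$ambiguous
  why <- ifelse(a2$ambiguous, "ambiguous_mapping", "not_reciprocal")
  removed <- a[!keep]
  removed[, reason := why[!keep]]
  marker_catalog(a[keep], rbind(.log_of(set_a_to_b), removed, fill = TRUE))
}

#' Consensus of alignment-based and reciprocal mapping-based marker sets
#'
#' A marker enters the consensus iff it is present, with the identical allele
#' pair, in the genome-alignment set and in both cross-parent mapping sets
#' (the P2-space set compared through the coordinate map). A final reciprocal
#' filter makes the result strictly symmetric relative to the two parents.
#' Output is in the A (P1) coordinate system with `source = "consensus"`.
#'
#' @param alignment_set genome-alignment-derived markers, A coordinates.
#' @param mapping_set_on_p1 read-mapping-derived markers in P1 (A) space.
#' @param mapping_set_on_p2 read-mapping-derived markers in P2 (B) space.
#' @param cmap a [coordinate_map()].
#' @return a [marker_catalog()]; empty (with a warning) if the intersection
#'   is empty.
#' @export
intersect_consensus <- function(alignment_set, mapping_set_on_p1,
                                mapping_set_on_p2, cmap) {
  aln <- .markers_of(alignment_set)
  m1 <- .markers_of(mapping_set_on_p1)
  m2 <- .markers_of(mapping_set_on_p2)

  ## consensus = alignment set confirmed in both mapping spaces
  step1 <- reciprocal_filter(aln, m2, cmap)          # confirmed in P2 space
  in_m1 <- copy(step1$markers)[, hit := FALSE]
  in_m1[m1, on = c("chrom", "pos", "p1_allele", "p2_allele"), hit := TRUE]
  removed <- step1$markers[!in_m1$hit][, reason := "absent_from_p1_mapping"]
  cons <- step1$markers[in_m1$hit]
  if (nrow(cons)) cons[, source := "consensus"]
  if (nrow(cons) == 0L) warning("empty consensus marker set")
  marker_catalog(cons, rbind(step1$filter_log, removed, fill = TRUE))
}

#' Marker catalog summary statistics
#'
#' Per-chromosome and total marker counts with mean and median inter-marker
#' distance (between consecutive markers on the same chromosome only).
#' Chromosomes with fewer than two markers contribute no distances and report
#' NA; the `total` row pools distances over all chromosomes.
#'
#' @param catalog marker table or `marker_catalog`.
#' @return data.table with columns `chrom`, `n`, `mean_dist`, `median_dist`.
#' @export
marker_stats <- function(catalog) {
  mk <- .markers_of(catalog)
  per <- mk[, {
    d <- if (.N >= 2L) diff(pos) else integer()
    .(n = .N,
      mean_dist = if (length(d)) mean(d) else NA_real_,
      median_dist = if (length(d)) as.numeric(median(d)) else NA_real_)
  }, by = chrom]
  alld <- mk[, if (.N >= 2L) .(d = diff(pos)), by = chrom]$d
  tot <- data.table(chrom = "total", n = nrow(mk),
                    mean_dist = if (length(alld)) mean(alld) else NA_real_,
                    median_dist = if (length(alld)) as.numeric(median(alld)) else NA_real_)
  rbind(per, tot)
}
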