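#' Score a marker site from its allele observations
#'
#' The *major base* is the base with maximal summed base quality. The Q_net
#' score is the cumulative quality difference between the major base and all
#' other bases (`qualsum[major] - sum(qualsum[others])`); *base purity* is
#' the fraction of reads supporting the major base. An exact qualsum tie
#' leaves the major base undefined (NA downstream).
#'
#' @param obs one allele-observation row: a list/data.frame with
#'   `count_A`..`count_T` and `qualsum_A`..`qualsum_T`.
#' @return list with `major_base` (NA on a tie or zero coverage), `qnet`,
#'   `purity`, and logicals `tie`, `no_data`.
#' @export
score_site <- function(obs) {
  obs <- as.data.table(as.list(obs))
  sc <- .score_observations(obs)
  list(major_base = sc$major[1], qnet = sc$qnet[1], purity = sc$purity[1],
       tie = sc$tie[1], no_data = sc$no_data[1])
}

## vectorized scoring over an observation table
.score_observations <- function(obs) {
  bases <- c("A", "C", "G", "T")
  Q <- as.matrix(obs[, paste0("qualsum_", bases), with = FALSE])
  C <- as.matrix(obs[, paste0("count_", bases), with = FALSE])
  storage.mode(Q) <- "double"
  storage.mode(C) <- "double"
  tot_q <- rowSums(Q)
  tot_c <- rowSums(C)
  maj <- max.col(Q, ties.method = "first")
  qmax <- Q[cbind(seq_len(nrow(Q)), maj)]
  tie <- rowSums(Q == qmax) > 1L
  no_data <- tot_c == 0
  out <- data.table(major = bases[maj],
                    qnet = 2 * qmax - tot_q,
                    purity = C[cbind(seq_len(nrow(C)), maj)] / tot_c,
                    tie = tie, no_data = no_data)
  out[no_data | tie, major := NA_character_]
  out[no_data == TRUE, `:=`(qnet = NA_real_, purity = NA_real_)]
  out
}

#' Call the genotype of one gamete at one marker
#'
#' A genotype is assigned only when the major base matches one of the two
#' parental alleles and both Q_net and base purity meet their cutoffs
#' (defaults 50 and 0.9). All failure modes are expressed as statuses:
#' `no_data` (zero coverage), `admixed` (qualsum tie, or purity below cutoff
#' with both parental alleles observed), `conflict` (major base matches
#' neither parental allele), `low_qnet`, `low_purity`.
#'
#' @param obs one allele-observation row (see [score_site()]).
#' @param marker one marker row with `p1_allele`, `p2_allele`.
#' @param qnet_cutoff,purity_cutoff assignment cutoffs.
#' @return list with `call` ("P1", "P2" or NA), `qnet`, `purity`, `status`.
#' @export
call_genotype <- function(obs, marker, qnet_cutoff = 50, purity_cutoff = 0.9) {
  obs <- as.data.table(as.list(obs))
  mk <- as.data.table(as.list(marker))
  sc <- .score_observations(obs)
  res <- .call_from_scores(sc, mk$p1_allele, mk$p2_allele,
                           obs[, paste0("count_", c("A", "C", "G", "T")),
                               with = FALSE],
                           qnet_cutoff, purity_cutoff)
  list(call = res$call[1], qnet = res$qnet[1], purity = res$purity[1],
       status = res$status[1])
}

.call_from_scores <- function(sc, p1, p2, counts, qnet_cutoff, purity_cutoff) {
  bases <- c("A", "C", "G", "T")
  counts <- as.matrix(counts)
  n <- nrow(sc)
  c_p1 <- counts[cbind(seq_len(n), match(p1, bases))]
  c_p2 <- counts[cbind(seq_len(n), match(p2, bases))]
  status <- rep("called", n)
  call <- ifelse(sc$major == p1, "P1",
                 ifelse(sc$major == p2, "P2", NA_character_))
  status[sc$purity < purity_cutoff] <- "low_purity"
  status[sc$purity < purity_cutoff & c_p1 > 0 & c_p2 > 0] <- "admixed"
  status[sc$qnet < qnet_cutoff] <- "low_qnet"
  status[!is.na(sc$major) & sc$major != p1 & sc$major != p2] <- "conflict"
  status[sc$tie] <- "admixed"
  status[sc$no_data] <- "no_data"
  call[status != "called"] <- NA_character_
  data.table(call = call, qnet = sc$qnet, purity = sc$purity, status = status)
}

#' Genotype gametes at every catalog marker
#'
#' Applies [call_genotype()] logic, vectorized, to every (gamete, marker)
#' cell. Markers without an observation row for a gamete are reported as
#' `no_data`. When `report_admixed = TRUE` the sites with admixed genotype
#' signals (candidate post-meiotic segregation sites) are attached as the
#' `"admixed_sites"` attribute.
#'
#' @param obs allele-observation table (`sample`, `chrom`, `pos`,
#'   `count_A`..`count_T`, `qualsum_A`..`qualsum_T`).
#' @param catalog marker table or `marker_catalog`.
#' @param qnet_cutoff,purity_cutoff assignment cutoffs (defaults 50, 0.9).
#' @param samples gamete sample ids to genotype; default: all samples in
#'   `obs`.
#' @param report_admixed attach the admixed-site report.
#' @return data.table with one row per (sample, marker): `sample`, `chrom`,
#'   `pos`, `call`, `qnet`, `purity`, `status`.
#' @export
genotype_gametes <- function(obs, catalog, qnet_cutoff = 50,
                             purity_cutoff = 0.9, samples = NULL,
                             report_admixed = FALSE) {
  mk <- .markers_of(catalog)
  obs <- as.data.table(obs)
  if (is.null(samples)) samples <- sort(unique(obs$sample))
  grid <- CJ(sample = samples, marker_row = seq_len(nrow(mk)))
  cells <- cbind(grid[, .(sample)], mk[grid$marker_row,
                                       .(chrom, pos, p1_allele, p2_allele)])
  qc_cols <- c(paste0("count_", c("A", "C", "G", "T")),
               paste0("qualsum_", c("A", "C", "G", "T")))
  cells <- merge(cells, obs[, c("sample", "chrom", "pos", qc_cols),
                            with = FALSE],
                 by = c("sample", "chrom", "pos"), all.x = TRUE)
  for (cc in qc_cols) set(cells, which(is.na(cells[[cc]])), cc, 0)
  sc <- .score_observations(cells)
  res <- .call_from_scores(sc, cells$p1_allele, cells$p2_allele,
                           cells[, paste0("count_", c("A", "C", "G", "T")),
                                 with = FALSE],
                           qnet_cutoff, purity_cutoff)
  out <- cbind(cells[, .(sample, chrom, pos)], res)
  setorder(out, sample, chrom, pos)
  if (report_admixed)
    setattr(out, "admixed_sites", out[status == "admixed"])
  out[]
}

#' Sites with admixed genotype signals (candidate PMS sites)
#'
#' @param calls genotype table from [genotype_gametes()].
#' @return the subset of rows with `status == "admixed"`.
#' @export
admixed_sites <- function(calls) {
  as.data.table(calls)[status == "admixed"]
}

#' Mask genotypes inside gamete-specific CNV regions
#'
#' Calls at markers falling inside a gamete's CNV intervals are set to NA
#' with status `cnv_masked`; other gametes are unaffected. Intervals are
#' 0-based half-open (BED convention), so a marker exactly at an interval
#' `end` is not masked.
#'
#' @param calls genotype table from [genotype_gametes()].
#' @param gamete_cnvs named list (by sample id) of data.frames with `chrom`,
#'   `start`, `end`.
#' @return masked copy of `calls`.
#' @export
mask_cnv <- function(calls, gamete_cnvs) {
  out <- copy(as.data.table(calls))
  for (g in names(gamete_cnvs)) {
    iv <- as.data.table(gamete_cnvs[[g]])
    if (nrow(iv) == 0L) next
    for (r in seq_len(nrow(iv))) {
      out[sample == g & chrom == iv$chrom[r] &
            pos > iv$start[r] & pos <= iv$end[r],
          `:=`(call = NA_character_, status = "cnv_masked")]
    }
  }
  out
}

#' Cross-validate genotype calls made in the two parental coordinate spaces
#'
#' Parent-based analysis genotypes each gamete twice, once per parental
#' genome space. Markers where both spaces call a genotype but disagree are
#' voided (`NA`, status `conflict`) in both mirrored outputs; where exactly
#' one space calls, that call is kept in both; markers absent from one
#' space's catalog count as NA there.
#'
#' @param calls_p1 genotype table in the P1 (A) coordinate space.
#' @param calls_p2 genotype table in the P2 (B) coordinate space.
#' @param cmap a [coordinate_map()] pairing the two marker spaces.
#' @return list with reconciled tables `p1` and `p2`, each in its own
#'   coordinate space.
#' @export
reconcile_parent_spaces <- function(calls_p1, calls_p2, cmap) {
  stopifnot(inherits(cmap, "coordinate_map"))
  a <- copy(as.data.table(calls_p1))
  b <- copy(as.data.table(calls_p2))
  ## express the p2-space calls in A coordinates
  b[, `:=`(chrom_a = cmap[b, on = c(chrom_b = "chrom", pos_b = "pos"), x.chrom_a],
           pos_a   = cmap[b, on = c(chrom_b = "chrom", pos_b = "pos"), x.pos_a])]
  bm <- b[!is.na(pos_a)]
  a[, other_call := bm[a, on = c(sample = "sample", chrom_a = "chrom",
                                 pos_a = "pos"), x.call]]
  was_na <- is.na(a$call)
  conflict <- !is.na(a$call) & !is.na(a$other_call) & a$call != a$other_call
  a[, call := fifelse(conflict, NA_character_,
                      fifelse(is.na(call), other_call, call))]
  a[conflict, status := "conflict"]
  a[was_na & !is.na(call), status := "called"]   # adopted from the other space
  a[, other_call := NULL]

  ## mirror back into B coordinates
  akey <- a[, .(sample, chrom, pos, rcall = call, rconflict = conflict)]
  b[, `:=`(rcall = akey[b, on = c(sample = "sample", chrom = "chrom_a",
                                  pos = "pos_a"), x.rcall],
           rconflict = akey[b, on = c(sample = "sample", chrom = "chrom_a",
                                      pos = "pos_a"), x.rconflict])]
  mapped <- !is.na(b$pos_a) & !is.na(b$rconflict)
  b_was_na <- is.na(b$call)
  b[mapped == TRUE, call := rcall]
  b[mapped & rconflict == TRUE, status := "conflict"]
  b[mapped & b_was_na & !is.na(call), status := "called"]
  b[, c("chrom_a", "pos_a", "rcall", "rconflict") := NULL]
  list(p1 = a[], p2 = b[])
}

#' Infer missing genotypes from the tetrad-wide 2:2 segregation ratio
#'
#' At each marker, with `(n1, n2)` the counts of called P1/P2 genotypes over
#' the four gametes, NA cells are filled (status `inferred`) only when the
#' 2:2 ratio forces them uniquely: one NA with `(2,1)` becomes P2 and with
#' `(1,2)` becomes P1; two NAs with `(2,0)` both become P2 and with `(0,2)`
#' both become P1. Every other pattern (including `(3,0)`/`(0,3)`, which may
#' mark a gene-conversion site) is left untouched. The input (raw) table is
#' not modified.
#'
#' @param calls genotype table covering exactly four gametes.
#' @return a new genotype table with forced fills applied; inferred cells
#'   have NA `qnet`/`purity`.
#' @export
infer_missing <- function(calls) {
  out <- copy(as.data.table(calls))
  if (length(unique(out$sample)) != 4L)
    stop("infer_missing needs exactly 4 gametes, got ",
         length(unique(out$sample)))
  seg <- out[, .(n1 = sum(call == "P1", na.rm = TRUE),
                 n2 = sum(call == "P2", na.rm = TRUE),
                 nNA = sum(is.na(call))), by = .(chrom, pos)]
  seg[, fill := fcase(nNA == 1L & n1 == 2L & n2 == 1L, "P2",
                      nNA == 1L & n1 == 1L & n2 == 2L, "P1",
                      nNA == 2L & n1 == 2L & n2 == 0L, "P2",
                      nNA == 2L & n1 == 0L & n2 == 2L, "P1",
                      default = NA_character_)]
  out[, fill := seg[out, on = c("chrom", "pos"), x.fill]]
  out[is.na(call) & !is.na(fill),
      `:=`(call = fill, status = "inferred",
           qnet = NA_real_, purity = NA_real_)]
  out[, fill := NULL]
  out[]
}

#' Parental and missing allele frequencies along the genome
#'
#' Pools the genotype calls of one or more tetrads genotyped against the
#' same marker catalog and reports, per marker, the fraction of P1, P2 and
#' NA cells.
#'
#' @param matrices a genotype table or list of genotype tables sharing one
#'   marker grid.
#' @return data.table with `chrom`, `pos`, `freq_P1`, `freq_P2`, `freq_NA`
#'   (summing to 1).
#' @export
summarize_allele_frequencies <- function(matrices) {
  if (is.data.frame(matrices)) matrices <- list(matrices)
  grids <- lapply(matrices, function(m)
    unique(as.data.table(m)[, .(chrom, pos)]))
  for (g in grids[-1])
    if (!identical(setorder(copy(grids[[1]]), chrom, pos),
                   setorder(copy(g), chrom, pos)))
      stop("genotype tables use different marker catalogs")
  all <- rbindlist(lapply(matrices, as.data.table), use.names = TRUE,
                   fill = TRUE)
  freq <- all[, .(freq_P1 = mean(!is.na(call) & call == "P1"),
                  freq_P2 = mean(!is.na(call) & call == "P2"),
                  freq_NA = mean(is.na(call))), by = .(chrom, pos)]
  setorder(freq, chrom, pos)
  freq[]
}

#' Genotyping error rate against simulated ground truth
#'
#' Compares non-NA genotype calls with the true chromatid genotypes of a
#' simulated tetrad. The error rate is the fraction of mismatched calls
#' among all non-NA calls.
#'
#' @param calls genotype table for gametes a-d.
#' @param truth a `tetrad_truth`.
#' @return list with `n_cells`, `n_called`, `n_wrong`, `error_rate` (NaN
#'   when nothing is called).
#' @export
genotyping_error_rate <- function(calls, truth) {
  stopifnot(inherits(truth, "tetrad_truth"))
  tl <- melt(truth$genotypes, id.vars = c("chrom", "pos"),
             variable.name = "sample", value.name = "true_geno",
             variable.factor = FALSE)
  tl[, true_call := ifelse(true_geno == 1L, "P1", "P2")]
  x <- as.data.table(calls)[tl, on = c("sample", "chrom", "pos")]
  n_called <- sum(!is.na(x$call))
  n_wrong <- sum(!is.na(x$call) & x$call != x$true_call)
  list(n_cells = nrow(x), n_called = n_called, n_wrong = n_wrong,
       error_rate = n_wrong / n_called)
}
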