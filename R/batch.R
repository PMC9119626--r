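#' Batch tetrad analysis driven by a sample manifest
#'
#' Runs genotyping, missing-genotype inference and recombination profiling
#' for every tetrad of a manifest and writes per-tetrad reports under
#' `outdir/<tetrad_id>/` (`genotypes/` with raw and inferred tables,
#' `events/` with segregation records, linkage blocks and classified
#' events for both). A tetrad that fails is reported and skipped; the batch
#' continues. When all tetrads share the same marker grid a batch-level
#' allele-frequency summary is written as well.
#'
#' @param manifest data.table from [read_manifest()] (columns `tetrad_id`,
#'   `gamete`, `sample_id`, `observation_path`). Observation files are
#'   TSVs as written by [write_observations()]; the `sample` column is
#'   replaced by the manifest's gamete label.
#' @param catalog marker table or `marker_catalog`.
#' @param outdir output directory (created if needed).
#' @param chrom_lengths named vector for block bound extension (optional).
#' @param qnet_cutoff,purity_cutoff genotyping cutoffs.
#' @param min_markers,min_size_bp,merging_range_bp profiler parameters.
#' @param gamete_cnvs optional named list (gamete label -> CNV intervals)
#'   applied to every tetrad via [mask_cnv()].
#' @param report_admixed also write the admixed-site (candidate PMS) report.
#' @return list with `summary` (per-tetrad status and counts),
#'   `allele_freq` (batch allele-frequency table or NULL), and `failures`.
#' @export
run_batch <- function(manifest, catalog, outdir,
                      chrom_lengths = NULL,
                      qnet_cutoff = 50, purity_cutoff = 0.9,
                      min_markers = 1L, min_size_bp = 1L,
                      merging_range_bp = 0L,
                      gamete_cnvs = NULL, report_admixed = FALSE) {
  manifest <- as.data.table(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- sprintf("qnet=%s purity=%s min_markers=%d min_size=%d merge=%d",
                    qnet_cutoff, purity_cutoff, as.integer(min_markers),
                    as.integer(min_size_bp), as.integer(merging_range_bp))
  summaries <- list()
  failures <- character(0)
  inferred_list <- list()

  for (tid in unique(manifest$tetrad_id)) {
    res <- tryCatch({
      rows <- manifest[tetrad_id == tid]
      obs <- rbindlist(lapply(seq_len(nrow(rows)), function(r) {
        o <- read_observations(rows$observation_path[r])
        o[, sample := rows$gamete[r]]
        o
      }))
      tdir <- file.path(outdir, tid)
      dir.create(file.path(tdir, "genotypes"), recursive = TRUE,
                 showWarnings = FALSE)
      dir.create(file.path(tdir, "events"), showWarnings = FALSE)

      raw <- genotype_gametes(obs, catalog, qnet_cutoff, purity_cutoff,
                              samples = c("a", "b", "c", "d"),
                              report_admixed = report_admixed)
      if (!is.null(gamete_cnvs)) raw <- mask_cnv(raw, gamete_cnvs)
      inf <- infer_missing(raw)
      write_genotypes(raw, file.path(tdir, "genotypes", "raw.tsv"), params)
      write_genotypes(inf, file.path(tdir, "genotypes", "inferred.tsv"),
                      params)
      if (report_admixed)
        write_genotypes(admixed_sites(raw),
                        file.path(tdir, "genotypes", "admixed_sites.tsv"),
                        params)

      n_events <- integer(0)
      for (tag in c("raw", "inferred")) {
        gt <- if (tag == "raw") raw else inf
        rec <- classify_segregation(gt)
        bl <- build_blocks(rec, chrom_lengths, min_markers, min_size_bp)
        evd <- classify_events(bl, merging_range_bp)
        .write_tsv(rec[, .(chrom, pos, pattern, ratio)],
                   file.path(tdir, "events",
                             sprintf("segregation_%s.tsv", tag)), params)
        .write_tsv(bl, file.path(tdir, "events",
                                 sprintf("blocks_%s.tsv", tag)), params)
        .write_tsv(evd, file.path(tdir, "events",
                                  sprintf("events_%s.tsv", tag)), params)
        n_events[tag] <- nrow(evd)
      }
      inferred_list[[tid]] <- inf
      data.table(tetrad_id = tid, status = "ok",
                 n_gametes = nrow(rows),
                 n_called = sum(!is.na(raw$call)),
                 n_na = sum(is.na(raw$call)),
                 n_events_raw = n_events[["raw"]],
                 n_events_inferred = n_events[["inferred"]])
    }, error = function(e) {
      warning("tetrad ", tid, " failed: ", conditionMessage(e))
      data.table(tetrad_id = tid, status = paste("failed:",
                                                 conditionMessage(e)),
                 n_gametes = NA_integer_, n_called = NA_integer_,
                 n_na = NA_integer_, n_events_raw = NA_integer_,
                 n_events_inferred = NA_integer_)
    })
    if (res$status[1] != "ok") failures <- c(failures, tid)
    summaries[[tid]] <- res
  }

  summary <- rbindlist(summaries)
  .write_tsv(summary, file.path(outdir, "batch_summary.tsv"), params)
  allele_freq <- NULL
  if (length(inferred_list) >= 1L) {
    allele_freq <- tryCatch(
      summarize_allele_frequencies(unname(inferred_list)),
      error = function(e) NULL)
    if (!is.null(allele_freq))
      .write_tsv(allele_freq, file.path(outdir, "allele_frequencies.tsv"),
                 params)
  }
  list(summary = summary, allele_freq = allele_freq, failures = failures)
}
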