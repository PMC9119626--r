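#' Simulation configuration for recombinant tetrads
#'
#' Bundles the parameters of the tetrad simulator. Defaults follow gene
#' conversion tract size distributions estimated from real budding yeast
#' tetrads: Type 1 (NCO-associated) tracts ~ Normal(2250, 2200) bp, Type 2
#' (CO-associated) tracts ~ Normal(2500, 2000) bp, both truncated to
#' [100, 5000] bp.
#'
#' @param n_co number of crossover events (each carries one Type 2 GC tract).
#' @param n_nco number of non-crossover events (each is one Type 1 GC tract).
#' @param gc1_mean,gc1_sd Type 1 GC tract size mean / sd (bp).
#' @param gc2_mean,gc2_sd Type 2 GC tract size mean / sd (bp).
#' @param gc_min,gc_max truncation bounds for tract sizes (bp).
#' @param depth mean per-marker read depth for simulated observations.
#' @param base_error per-base miscall probability (a miscalled read reports a
#'   uniformly random other base).
#' @param base_quality Phred quality attributed to every simulated base.
#' @param seed RNG seed (NULL = use the current RNG state).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_co = 90L, n_nco = 65L,
                              gc1_mean = 2250, gc1_sd = 2200,
                              gc2_mean = 2500, gc2_sd = 2000,
                              gc_min = 100, gc_max = 5000,
                              depth = 8, base_error = 1e-3,
                              base_quality = 30, seed = NULL) {
  stopifnot(n_co >= 0, n_nco >= 0,
            gc_min > 0, gc_min <= gc_max,
            gc1_sd >= 0, gc2_sd >= 0,
            depth >= 0, base_error >= 0, base_error < 1,
            base_quality >= 2)
  structure(list(n_co = as.integer(n_co), n_nco = as.integer(n_nco),
                 gc1_mean = gc1_mean, gc1_sd = gc1_sd,
                 gc2_mean = gc2_mean, gc2_sd = gc2_sd,
                 gc_min = gc_min, gc_max = gc_max,
                 depth = depth, base_error = base_error,
                 base_quality = base_quality,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

#' Nuclear chromosome lengths of the budding yeast reference genome
#'
#' The 16 nuclear chromosomes of the *S. cerevisiae* R64 reference assembly
#' (~12.07 Mb), used as a realistic coordinate system for yeast-scale
#' simulations.
#'
#' @return named integer vector of chromosome lengths (bp).
#' @export
yeast_chromosome_lengths <- function() {
  c(chrI = 230218L, chrII = 813184L, chrIII = 316620L, chrIV = 1531933L,
    chrV = 576874L, chrVI = 270161L, chrVII = 1090940L, chrVIII = 562643L,
    chrIX = 439888L, chrX = 745751L, chrXI = 666816L, chrXII = 1078177L,
    chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L, chrXVI = 948066L)
}

#' Simulate a marker catalog on a set of chromosomes
#'
#' Places `n_markers` biallelic SNV markers uniformly at random (without
#' replacement within a chromosome) across chromosomes, with per-chromosome
#' counts proportional to length, and draws two distinct parental alleles per
#' marker.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_markers total number of markers.
#' @param seed RNG seed (NULL = current RNG state).
#' @return a [marker_catalog()] with `source = "consensus"`.
#' @export
simulate_marker_catalog <- function(chrom_lengths, n_markers = 50000L,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 1))
  n_per <- round(as.numeric(n_markers) *
                   chrom_lengths / sum(as.numeric(chrom_lengths)))
  n_per[1] <- n_per[1] + (n_markers - sum(n_per))
  bases <- c("A", "C", "G", "T")
  mk <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    n <- n_per[[ch]]
    if (n <= 0L) return(NULL)
    p1 <- sample(bases, n, replace = TRUE)
    p2 <- bases[(match(p1, bases) - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
    data.table(chrom = ch,
               pos = sort(sample.int(chrom_lengths[[ch]], n)),
               p1_allele = p1, p2_allele = p2, source = "consensus")
  }))
  marker_catalog(mk)
}

## truncated normal by rejection, rounded to integer bp
.rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(integer())
  out <- numeric(0)
  for (i in seq_len(10000L)) {
    x <- rnorm(max(n * 2L, 10L), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
    if (length(out) >= n) return(as.integer(round(out[seq_len(n)])))
  }
  stop("truncated-normal sampling failed: bounds [", lo, ", ", hi,
       "] capture too little probability mass")
}

#' Project parental markers onto a template genome
#'
#' Produces the two parental genomes by substituting, at every marker
#' position, the P1 allele (for parent 1) and the P2 allele (for parent 2)
#' into the template sequence. The template base at each marker position must
#' equal one of the two parental alleles.
#'
#' @param template a [Biostrings::DNAStringSet] named by chromosome.
#' @param catalog marker table or `marker_catalog`.
#' @return list with elements `p1` and `p2`, each a `DNAStringSet` of the
#'   same lengths as the template.
#' @export
project_parental_genomes <- function(template, catalog) {
  mk <- .markers_of(catalog)
  stopifnot(inherits(template, "DNAStringSet"))
  missing_chr <- setdiff(unique(mk$chrom), names(template))
  if (length(missing_chr))
    stop("marker chromosome(s) absent from template: ",
         paste(missing_chr, collapse = ", "))
  p1 <- template
  p2 <- template
  for (ch in unique(mk$chrom)) {
    sub <- mk[chrom == ch]
    if (any(sub$pos > Biostrings::nchar(template[[ch]])))
      stop("marker position beyond end of ", ch)
    ref <- as.character(Biostrings::extractAt(
      template[[ch]], IRanges::IRanges(sub$pos, sub$pos)))
    bad <- which(ref != sub$p1_allele & ref != sub$p2_allele)
    if (length(bad))
      stop("template base matches neither parental allele at ",
           ch, ":", sub$pos[bad[1]], " (template ", ref[bad[1]],
           ", alleles ", sub$p1_allele[bad[1]], "/", sub$p2_allele[bad[1]], ")")
    at <- rep(FALSE, Biostrings::nchar(template[[ch]]))
    at[sub$pos] <- TRUE
    p1[[ch]] <- Biostrings::replaceLetterAt(template[[ch]], at, sub$p1_allele)
    p2[[ch]] <- Biostrings::replaceLetterAt(template[[ch]], at, sub$p2_allele)
  }
  list(p1 = p1, p2 = p2)
}

## does the open interval (lo, hi) contain at least one marker position?
.marker_between <- function(pos_vec, lo, hi) {
  any(pos_vec > lo & pos_vec < hi)
}

#' Simulate a recombinant tetrad with full ground truth
#'
#' Simulates the four chromatids of one meiosis on a four-chromatid model:
#' gametes a and b start as P1 copies, c and d as P2 copies. Each CO picks,
#' at its breakpoint `x`, one chromatid currently carrying P1 downstream and
#' one carrying P2, and swaps their genotypes for all positions > `x`; a Type
#' 2 GC tract (size from the Type 2 truncated normal) abuts the breakpoint on
#' one side (chosen uniformly) on one of the two recombining chromatids
#' (chosen uniformly) and converts it to the other parent within the tract.
#' Each NCO converts one uniformly chosen chromatid within a Type 1 tract.
#' Chromosomes are chosen proportional to length and positions uniformly;
#' placements are rejected (up to 1000 retries per event) unless every pair
#' of event footprints on a chromosome is disjoint *and* separated by at
#' least one catalog marker, so that each event owns a distinct linkage
#' signal.
#'
#' Outside all GC tracts every marker segregates exactly 2:2 across the four
#' chromatids; inside a tract exactly one chromatid deviates (3:1 or 1:3).
#'
#' @param config a [simulation_config()]; `config$seed`, when non-NULL, seeds
#'   the RNG for reproducible output.
#' @param catalog marker table or `marker_catalog`.
#' @param chrom_lengths named vector of chromosome lengths (bp) covering all
#'   marker chromosomes.
#' @return object of class `tetrad_truth`: list with `genotypes` (data.table
#'   `chrom`, `pos`, `a`..`d`, values 1 = P1, 2 = P2), `events` (data.table
#'   with type "CO"/"NCO", breakpoint, tract bounds, involved chromatids,
#'   tract carrier and side), `chrom_lengths`, and `config`.
#' @export
simulate_tetrad <- function(config, catalog, chrom_lengths) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  mk <- .markers_of(catalog)
  stopifnot(!is.null(names(chrom_lengths)))
  missing_chr <- setdiff(unique(mk$chrom), names(chrom_lengths))
  if (length(missing_chr))
    stop("marker chromosome(s) without length: ",
         paste(missing_chr, collapse = ", "))
  chrom_lengths <- round(chrom_lengths)

  n_ev <- config$n_co + config$n_nco
  ev_type <- c(rep("CO", config$n_co), rep("NCO", config$n_nco))
  sizes <- integer(n_ev)
  sizes[ev_type == "CO"] <- .rtruncnorm_int(config$n_co, config$gc2_mean,
                                            config$gc2_sd, config$gc_min,
                                            config$gc_max)
  sizes[ev_type == "NCO"] <- .rtruncnorm_int(config$n_nco, config$gc1_mean,
                                             config$gc1_sd, config$gc_min,
                                             config$gc_max)

  if (n_ev == 0L) {
    G0 <- matrix(rep(c(1L, 1L, 2L, 2L), each = nrow(mk)), ncol = 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
    ev0 <- data.table(event_id = character(), type = character(),
                      chrom = character(), breakpoint = integer(),
                      tract_start = integer(), tract_end = integer(),
                      side = character(), chromatids = character(),
                      gc_carrier = character())
    return(structure(list(genotypes = cbind(mk[, .(chrom, pos)],
                                            as.data.table(G0)),
                          events = ev0, chrom_lengths = chrom_lengths,
                          config = config),
                     class = "tetrad_truth"))
  }

  marker_pos <- split(mk$pos, mk$chrom)
  chroms <- names(chrom_lengths)
  placed <- vector("list", n_ev)
  footprints <- lapply(setNames(chroms, chroms),
                       function(ch) matrix(numeric(0), ncol = 2))

  for (k in seq_len(n_ev)) {
    s <- sizes[k]
    ok <- FALSE
    for (try in seq_len(1000L)) {
      ch <- sample(chroms, 1L, prob = chrom_lengths)
      L <- chrom_lengths[[ch]]
      if (ev_type[k] == "CO") {
        side <- sample(c("left", "right"), 1L)
        if (side == "left") {
          if (L - 1L < s) next
          x <- sample(seq.int(s, L - 1L), 1L)
          tract <- c(x - s + 1L, x)
          fp <- c(tract[1], x)
        } else {
          if (L - s < 1L) next
          x <- sample(seq.int(1L, L - s), 1L)
          tract <- c(x + 1L, x + s)
          fp <- c(x, tract[2])
        }
      } else {
        side <- NA_character_
        x <- NA_integer_
        if (L - s + 1L < 1L) next
        t0 <- sample.int(L - s + 1L, 1L)
        tract <- c(t0, t0 + s - 1L)
        fp <- tract
      }
      ## disjoint from, and marker-separated from, all accepted footprints
      prev <- footprints[[ch]]
      mp <- marker_pos[[ch]]
      if (is.null(mp)) mp <- numeric(0)
      clash <- FALSE
      if (nrow(prev)) {
        for (r in seq_len(nrow(prev))) {
          lo <- prev[r, 1]; hi <- prev[r, 2]
          if (fp[1] <= hi && fp[2] >= lo) { clash <- TRUE; break }
          gap <- if (fp[1] > hi) c(hi, fp[1]) else c(fp[2], lo)
          if (!.marker_between(mp, gap[1], gap[2])) { clash <- TRUE; break }
        }
      }
      if (clash) next
      footprints[[ch]] <- rbind(prev, fp)
      placed[[k]] <- list(type = ev_type[k], chrom = ch, breakpoint = x,
                          tract_start = tract[1], tract_end = tract[2],
                          side = side)
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place event ", k, " after 1000 retries; ",
           "use fewer events or longer chromosomes")
  }

  ev <- rbindlist(lapply(placed, as.data.table))
  ev[, event_id := sprintf("ev%03d", .I)]

  ## genotype paths: a,b start P1 (1); c,d start P2 (2)
  gam <- c("a", "b", "c", "d")
  geno <- mk[, .(chrom, pos)]
  G <- matrix(rep(c(1L, 1L, 2L, 2L), each = nrow(geno)), ncol = 4)
  colnames(G) <- gam

  ev[, `:=`(chromatid_1 = NA_character_, chromatid_2 = NA_character_,
            gc_carrier = NA_character_)]
  for (ch in unique(ev$chrom)) {
    rows <- which(geno$chrom == ch)
    state <- c(1L, 1L, 2L, 2L)
    co_idx <- ev[, .I[chrom == ch & type == "CO"]]
    co_idx <- co_idx[order(ev$breakpoint[co_idx])]
    for (k in co_idx) {
      x <- ev$breakpoint[k]
      i <- sample(which(state == 1L), 1L)
      j <- sample(which(state == 2L), 1L)
      dn <- rows[geno$pos[rows] > x]
      tmp <- G[dn, i]
      G[dn, i] <- G[dn, j]
      G[dn, j] <- tmp
      state[c(i, j)] <- state[c(j, i)]
      set(ev, k, "chromatid_1", gam[i])
      set(ev, k, "chromatid_2", gam[j])
      set(ev, k, "gc_carrier", sample(gam[c(i, j)], 1L))
    }
  }
  ## NCO carriers, then apply all GC tracts as local flips
  nco_idx <- which(ev$type == "NCO")
  if (length(nco_idx))
    for (k in nco_idx) {
      carrier <- sample(gam, 1L)
      set(ev, k, "chromatid_1", carrier)
      set(ev, k, "gc_carrier", carrier)
    }
  for (k in seq_len(nrow(ev))) {
    rows <- which(geno$chrom == ev$chrom[k] &
                    geno$pos >= ev$tract_start[k] &
                    geno$pos <= ev$tract_end[k])
    if (length(rows)) {
      ci <- match(ev$gc_carrier[k], gam)
      G[rows, ci] <- 3L - G[rows, ci]
    }
  }

  geno <- cbind(geno, as.data.table(G))
  ev[, chromatids := ifelse(type == "CO",
                            paste(pmin(chromatid_1, chromatid_2),
                                  pmax(chromatid_1, chromatid_2), sep = ","),
                            chromatid_1)]
  ev <- ev[, .(event_id, type, chrom, breakpoint, tract_start, tract_end,
               side, chromatids, gc_carrier)]

  structure(list(genotypes = geno, events = ev,
                 chrom_lengths = chrom_lengths, config = config),
            class = "tetrad_truth")
}

#' @param x a `tetrad_truth`.
#' @param ... unused.
#' @rdname simulate_tetrad
#' @export
print.tetrad_truth <- function(x, ...) {
  cat(sprintf("tetrad_truth: %d markers, %d CO + %d NCO events on %d chromosome(s)\n",
              nrow(x$genotypes), sum(x$events$type == "CO"),
              sum(x$events$type == "NCO"), length(x$chrom_lengths)))
  invisible(x)
}

#' Flag which simulated events are detectable given the marker positions
#'
#' A gene-conversion tract is detectable iff at least one marker lies inside
#' it. A CO is detectable iff at least one marker lies on each side of its
#' breakpoint *outside its own GC tract* (a tract-interior marker carries a
#' 3:1 signal and cannot witness the reciprocal 2:2 switch). A Type 2 GC
#' (CO-associated tract) is detectable iff its tract contains a marker and
#' its CO is detectable; a CO-associated tract whose CO is invisible presents
#' exactly as an NCO signal.
#'
#' @param truth a `tetrad_truth` from [simulate_tetrad()].
#' @param catalog marker table or `marker_catalog`.
#' @return the `tetrad_truth` with event columns `tract_markers`,
#'   `co_detectable` (NA for NCO) and `gc_detectable` added.
#' @export
annotate_detectability <- function(truth, catalog) {
  stopifnot(inherits(truth, "tetrad_truth"))
  mk <- .markers_of(catalog)
  marker_pos <- split(mk$pos, mk$chrom)
  ev <- copy(truth$events)
  ev[, tract_markers := 0L]
  ev[, co_detectable := NA]
  ev[, gc_detectable := NA]
  for (k in seq_len(nrow(ev))) {
    mp <- marker_pos[[ev$chrom[k]]]
    if (is.null(mp)) mp <- numeric(0)
    in_tract <- mp >= ev$tract_start[k] & mp <= ev$tract_end[k]
    set(ev, k, "tract_markers", sum(in_tract))
    if (ev$type[k] == "CO") {
      x <- ev$breakpoint[k]
      left <- any(mp <= x & !in_tract)
      right <- any(mp > x & !in_tract)
      set(ev, k, "co_detectable", left && right)
      set(ev, k, "gc_detectable", (sum(in_tract) >= 1L) && left && right)
    } else {
      set(ev, k, "gc_detectable", sum(in_tract) >= 1L)
    }
  }
  truth$events <- ev
  truth
}

#' Census of simulated recombination events by observable type
#'
#' Translates the simulated event list into the four-type taxonomy: every CO
#' counts as a Type 2 CO with a linked Type 2 GC (by construction every
#' simulated CO carries a tract), and every NCO as a Type 1 GC.
#'
#' @param truth a `tetrad_truth`.
#' @return named integer vector with entries `CO_T2`, `GC_T2`, `GC_T1`.
#' @export
truth_event_census <- function(truth) {
  stopifnot(inherits(truth, "tetrad_truth"))
  n_co <- sum(truth$events$type == "CO")
  c(CO_T2 = n_co, GC_T2 = n_co,
    GC_T1 = sum(truth$events$type == "NCO"))
}

#' Expected observable events for a simulated tetrad
#'
#' Derives, from the ground truth and the marker positions, the event list a
#' perfect profiler would report: a detectable CO with a detectable tract
#' appears as CO_T2 plus a linked GC_T2 (both attributed to the two
#' recombining gametes, since the tract carrier is unidentifiable from
#' genotypes alone); a detectable CO with an undetectable tract appears as
#' CO_T1; an undetectable CO whose tract still contains markers appears as a
#' GC_T1 on the tract carrier; a detectable NCO appears as GC_T1.
#'
#' @param truth a `tetrad_truth` (detectability annotated on the fly if
#'   absent).
#' @param catalog marker table or `marker_catalog`.
#' @return data.table with columns `truth_id`, `type`, `chrom`, `start`,
#'   `end`, `gametes`.
#' @export
expected_events <- function(truth, catalog) {
  stopifnot(inherits(truth, "tetrad_truth"))
  if (!"gc_detectable" %in% names(truth$events))
    truth <- annotate_detectability(truth, catalog)
  ev <- truth$events
  out <- list()
  for (k in seq_len(nrow(ev))) {
    e <- ev[k]
    if (e$type == "CO") {
      if (isTRUE(e$co_detectable)) {
        if (isTRUE(e$gc_detectable)) {
          out[[length(out) + 1L]] <- data.table(
            truth_id = e$event_id, type = "CO_T2", chrom = e$chrom,
            start = e$breakpoint, end = e$breakpoint, gametes = e$chromatids)
          out[[length(out) + 1L]] <- data.table(
            truth_id = e$event_id, type = "GC_T2", chrom = e$chrom,
            start = e$tract_start, end = e$tract_end, gametes = e$chromatids)
        } else {
          out[[length(out) + 1L]] <- data.table(
            truth_id = e$event_id, type = "CO_T1", chrom = e$chrom,
            start = e$breakpoint, end = e$breakpoint, gametes = e$chromatids)
        }
      } else if (e$tract_markers >= 1L) {
        out[[length(out) + 1L]] <- data.table(
          truth_id = e$event_id, type = "GC_T1", chrom = e$chrom,
          start = e$tract_start, end = e$tract_end, gametes = e$gc_carrier)
      }
    } else if (isTRUE(e$gc_detectable)) {
      out[[length(out) + 1L]] <- data.table(
        truth_id = e$event_id, type = "GC_T1", chrom = e$chrom,
        start = e$tract_start, end = e$tract_end, gametes = e$gc_carrier)
    }
  }
  if (!length(out))
    return(data.table(truth_id = character(), type = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), gametes = character()))
  rbindlist(out)
}

#' Simulate per-marker allele observations for the four gametes
#'
#' For every (gamete, marker) cell, the read count is drawn
#' Poisson(`config$depth`); each read reports the gamete's true parental
#' allele with probability `1 - config$base_error`, otherwise a uniformly
#' chosen other base; every read contributes `config$base_quality` Phred
#' units to the summed base quality of the base it reports.
#'
#' @param truth a `tetrad_truth`.
#' @param catalog marker table or `marker_catalog` (must match the truth's
#'   marker grid).
#' @param config a [simulation_config()].
#' @param seed RNG seed; defaults to an offset of `config$seed` so that
#'   observation noise is reproducible yet decoupled from event placement
#'   (NULL = current RNG state).
#' @return data.table with one row per (gamete, marker): `sample`, `chrom`,
#'   `pos`, `count_A`..`count_T`, `qualsum_A`..`qualsum_T` (zero-coverage
#'   cells included, with all-zero counts).
#' @export
simulate_observations <- function(truth, catalog, config,
                                  seed = if (is.null(config$seed)) NULL
                                         else config$seed + 104729L) {
  stopifnot(inherits(truth, "tetrad_truth"),
            inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  mk <- .markers_of(catalog)
  geno <- truth$genotypes
  if (nrow(mk) != nrow(geno) ||
      !all(mk$chrom == geno$chrom & mk$pos == geno$pos))
    stop("catalog does not match the truth's marker grid")

  bases <- c("A", "C", "G", "T")
  gam <- c("a", "b", "c", "d")
  long <- rbindlist(lapply(gam, function(g) {
    data.table(sample = g, chrom = geno$chrom, pos = geno$pos,
               true_allele = ifelse(geno[[g]] == 1L, mk$p1_allele,
                                    mk$p2_allele))
  }))
  N <- nrow(long)
  n_reads <- rpois(N, config$depth)
  n_err <- rbinom(N, n_reads, config$base_error)
  n_ok <- n_reads - n_err

  counts <- matrix(0L, nrow = N, ncol = 4, dimnames = list(NULL, bases))
  tb <- match(long$true_allele, bases)
  counts[cbind(seq_len(N), tb)] <- n_ok
  err_cells <- which(n_err > 0L)
  if (length(err_cells)) {
    cell <- rep(err_cells, n_err[err_cells])
    shift <- sample.int(3L, length(cell), replace = TRUE)
    eb <- (tb[cell] - 1L + shift) %% 4L + 1L
    add <- data.table(cell = cell, eb = eb)[, .N, by = .(cell, eb)]
    counts[cbind(add$cell, add$eb)] <- counts[cbind(add$cell, add$eb)] + add$N
  }
  qual <- counts * config$base_quality
  obs <- data.table(sample = long$sample, chrom = long$chrom, pos = long$pos)
  obs[, (paste0("count_", bases)) := as.data.table(counts)]
  obs[, (paste0("qualsum_", bases)) := as.data.table(qual)]
  setorder(obs, sample, chrom, pos)
  obs[]
}
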