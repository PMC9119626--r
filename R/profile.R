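## position indices at which two 4-character genotype patterns differ
.pat_diff <- function(p, q) {
  which(strsplit(p, "")[[1]] != strsplit(q, "")[[1]])
}

.ratio_of <- function(pattern) {
  n1 <- nchar(gsub("2", "", pattern))
  c("R04", "R13", "R22", "R31", "R40")[n1 + 1L]
}

#' Tetrad-wide segregation records
#'
#' Scans the genotype table at every marker and, for markers where all four
#' gametes have a non-NA call, records the 4-gamete genotype pattern and its
#' parental segregation ratio (2:2, 3:1, 1:3, 4:0 or 0:4). Markers with any
#' NA call are excluded (they are ignored when building linkage blocks and do
#' not split them).
#'
#' @param calls genotype table for exactly four gametes (long format, from
#'   [genotype_gametes()] or [infer_missing()]).
#' @return data.table with `chrom`, `pos`, one call column per gamete,
#'   `pattern` (4 characters over 1 = P1 / 2 = P2, gametes in sorted sample
#'   order) and `ratio` (`R22`, `R31`, `R13`, `R40`, `R04`). The gamete
#'   order is attached as attribute `"gametes"`.
#' @export
classify_segregation <- function(calls) {
  dt <- as.data.table(calls)
  gam <- sort(unique(dt$sample))
  if (length(gam) != 4L)
    stop("expected exactly 4 gametes, got ", length(gam))
  wide <- dcast(dt, chrom + pos ~ sample, value.var = "call")
  setorder(wide, chrom, pos)
  complete <- stats::complete.cases(wide[, gam, with = FALSE])
  rec <- wide[complete]
  code <- function(v) fifelse(v == "P1", "1", "2")
  rec[, pattern := do.call(paste0, lapply(.SD, code)), .SDcols = gam]
  rec[, ratio := vapply(pattern, .ratio_of, character(1))]
  setattr(rec, "gametes", gam)
  rec[]
}

#' Build linkage blocks from segregation records
#'
#' Groups maximal runs of consecutive informative markers sharing the same
#' full 4-gamete genotype pattern into preliminary blocks (grouping is by
#' pattern, not ratio class alone: two adjacent 2:2 runs with different
#' patterns — a crossover — are distinct blocks). NA markers never split a
#' block. Blocks with fewer than `min_markers` supporting markers or an
#' inner span below `min_size_bp` are dissolved: their markers are discarded
#' and flanking same-pattern blocks merge; the rule is re-applied until
#' stable. Final outer bounds are the midpoints between a block's outermost
#' markers and the nearest informative markers of the neighboring blocks;
#' the first and last blocks of a chromosome extend to position 1 and the
#' chromosome end, so the final blocks tile each chromosome exactly.
#'
#' @param records output of [classify_segregation()].
#' @param chrom_lengths named vector of chromosome lengths; when NULL the
#'   last block ends at the last informative marker.
#' @param min_markers minimal supporting marker count (default 1).
#' @param min_size_bp minimal inner span in bp (default 1).
#' @return data.table of blocks: `chrom`, `block_id`, `pattern`, `ratio`,
#'   `n_markers`, `inner_start`, `inner_end`, `outer_start`, `outer_end`,
#'   with the gamete order attribute passed through.
#' @export
build_blocks <- function(records, chrom_lengths = NULL,
                         min_markers = 1L, min_size_bp = 1L) {
  rec <- copy(as.data.table(records))
  gam <- attr(records, "gametes")
  if (nrow(rec) == 0L) {
    out <- data.table(chrom = character(), block_id = integer(),
                      pattern = character(), ratio = character(),
                      n_markers = integer(), inner_start = numeric(),
                      inner_end = numeric(), outer_start = numeric(),
                      outer_end = numeric())
    setattr(out, "gametes", gam)
    return(out)
  }
  setorder(rec, chrom, pos)
  blocks_per_chrom <- lapply(split(rec, by = "chrom"), function(rc) {
    ## preliminary blocks: runs of identical pattern
    runs <- rle(rc$pattern)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    bl <- data.table(pattern = runs$values,
                     n_markers = runs$lengths,
                     inner_start = as.numeric(rc$pos[starts]),
                     inner_end = as.numeric(rc$pos[ends]))
    ## dissolve sub-threshold blocks, re-merging flanks, until stable
    repeat {
      bad <- bl$n_markers < min_markers |
        (bl$inner_end - bl$inner_start + 1) < min_size_bp
      if (!any(bad) || all(bad)) break
      bl <- bl[!bad]
      ## merge adjacent blocks that now share a pattern
      grp <- cumsum(c(TRUE, bl$pattern[-1] != bl$pattern[-nrow(bl)]))
      bl <- bl[, .(pattern = pattern[1], n_markers = sum(n_markers),
                   inner_start = min(inner_start),
                   inner_end = max(inner_end)), by = .(grp)][, grp := NULL]
    }
    if (all(bl$n_markers < min_markers |
            (bl$inner_end - bl$inner_start + 1) < min_size_bp))
      return(bl[0])
    bl[, ratio := vapply(pattern, .ratio_of, character(1))]
    ## outer bounds by flanking midpoints
    n <- nrow(bl)
    mid <- if (n > 1) (bl$inner_end[-n] + bl$inner_start[-1]) / 2 else numeric()
    chrom_end <- if (!is.null(chrom_lengths) &&
                     rc$chrom[1] %in% names(chrom_lengths))
      as.numeric(chrom_lengths[[rc$chrom[1]]]) else bl$inner_end[n]
    bl[, outer_start := c(1, mid)]
    bl[, outer_end := c(mid, chrom_end)]
    bl[, chrom := rc$chrom[1]]
    bl
  })
  out <- rbindlist(blocks_per_chrom, use.names = TRUE)
  out[, block_id := seq_len(.N)]
  setcolorder(out, c("chrom", "block_id", "pattern", "ratio", "n_markers",
                     "inner_start", "inner_end", "outer_start", "outer_end"))
  setattr(out, "gametes", gam)
  out[]
}

.empty_events <- function() {
  data.table(event_id = character(), type = character(), chrom = character(),
             start = numeric(), end = numeric(), breakpoint = numeric(),
             gametes = character(), n_markers = integer(),
             linked_event = character(), context = character())
}

#' Classify recombination events from adjacent linkage blocks
#'
#' Applies a decision table to the genotype switch patterns between adjacent
#' linkage blocks along each chromosome:
#'
#' * two adjacent 2:2 blocks differing by a reciprocal two-gamete switch →
#'   a Type 1 crossover (`CO_T1`) at the block boundary;
#' * a 3:1/1:3 block whose two flanking 2:2 blocks share the same pattern,
#'   with a single gamete switching in and back → a Type 1 gene conversion
#'   (`GC_T1`) spanning the block, attributed to the deviating gamete;
#' * a 3:1/1:3 block whose flanking 2:2 blocks differ by a reciprocal
#'   two-gamete switch, the middle block deviating from each flank by one of
#'   those two gametes → a Type 2 crossover (`CO_T2`) with a linked Type 2
#'   gene conversion (`GC_T2`) spanning the block; both are attributed to
#'   the two recombining gametes (the tract carrier is not identifiable from
#'   genotypes alone);
#' * a terminal 3:1/1:3 block whose single 2:2 flank differs by exactly one
#'   gamete → `GC_T1` truncated at the chromosome end;
#' * 4:0/0:4 blocks, three-or-more-gamete switches and any other chain →
#'   `COMPLEX`, reported with its full pattern context, never dropped.
#'
#' @param blocks output of [build_blocks()].
#' @param merging_range_bp passed on to [merge_events()] (default 0 = no
#'   merging).
#' @return data.table of events: `event_id`, `type`, `chrom`, `start`,
#'   `end`, `breakpoint` (CO events), `gametes` (comma-joined), `n_markers`
#'   (tract-supporting markers for GC events), `linked_event` (GC_T2 and
#'   CO_T2 are linked pairwise), `context` (pattern chain).
#' @export
classify_events <- function(blocks, merging_range_bp = 0L) {
  bl <- as.data.table(blocks)
  gam <- attr(blocks, "gametes")
  if (is.null(gam)) gam <- c("a", "b", "c", "d")
  if (nrow(bl) == 0L) return(.empty_events())
  evs <- list()
  eid <- 0L
  new_id <- function() sprintf("E%03d", eid)
  add <- function(type, chrom, start, end, breakpoint, gametes, n_markers,
                  linked = NA_character_, context = NA_character_) {
    eid <<- eid + 1L
    evs[[length(evs) + 1L]] <<- data.table(
      event_id = new_id(), type = type, chrom = chrom,
      start = as.numeric(start), end = as.numeric(end),
      breakpoint = as.numeric(breakpoint),
      gametes = gametes, n_markers = as.integer(n_markers),
      linked_event = linked, context = context)
    new_id()
  }

  for (ch in unique(bl$chrom)) {
    cb <- bl[chrom == ch]
    n <- nrow(cb)
    ## crossovers between directly adjacent 2:2 blocks
    if (n > 1) {
      for (i in seq_len(n - 1L)) {
        if (cb$ratio[i] == "R22" && cb$ratio[i + 1L] == "R22") {
          d <- .pat_diff(cb$pattern[i], cb$pattern[i + 1L])
          ctx <- paste(cb$pattern[i], cb$pattern[i + 1L], sep = ">")
          bp <- (cb$inner_end[i] + cb$inner_start[i + 1L]) / 2
          if (length(d) == 2L) {
            add("CO_T1", ch, cb$inner_end[i], cb$inner_start[i + 1L], bp,
                paste(gam[d], collapse = ","), 0L, context = ctx)
          } else {
            ## simultaneous 4-strand switch or other non-reciprocal change
            add("COMPLEX", ch, cb$inner_end[i], cb$inner_start[i + 1L], bp,
                NA_character_, 0L, context = ctx)
          }
        }
      }
    }
    ## non-2:2 blocks
    for (i in seq_len(n)) {
      if (cb$ratio[i] == "R22") next
      left <- if (i > 1L) cb[i - 1L] else NULL
      right <- if (i < n) cb[i + 1L] else NULL
      ctx <- paste(c(if (!is.null(left)) left$pattern, cb$pattern[i],
                     if (!is.null(right)) right$pattern), collapse = ">")
      if (cb$ratio[i] %in% c("R40", "R04")) {
        add("COMPLEX", ch, cb$outer_start[i], cb$outer_end[i], NA,
            NA_character_, cb$n_markers[i], context = ctx)
        next
      }
      if (!is.null(left) && !is.null(right) &&
          left$ratio == "R22" && right$ratio == "R22") {
        dl <- .pat_diff(cb$pattern[i], left$pattern)
        dr <- .pat_diff(cb$pattern[i], right$pattern)
        df <- .pat_diff(left$pattern, right$pattern)
        if (length(df) == 0L && length(dl) == 1L) {
          add("GC_T1", ch, cb$outer_start[i], cb$outer_end[i], NA,
              gam[dl], cb$n_markers[i], context = ctx)
        } else if (length(df) == 2L && length(dl) == 1L &&
                   length(dr) == 1L && dl != dr &&
                   setequal(c(dl, dr), df)) {
          pair <- paste(gam[sort(df)], collapse = ",")
          span <- c(left$inner_end, right$inner_start)
          co_id <- add("CO_T2", ch, span[1], span[2], mean(span),
                       pair, cb$n_markers[i], context = ctx)
          gc_id <- add("GC_T2", ch, cb$outer_start[i], cb$outer_end[i], NA,
                       pair, cb$n_markers[i], linked = co_id, context = ctx)
          evs[[length(evs) - 1L]][, linked_event := gc_id]
        } else {
          add("COMPLEX", ch, cb$outer_start[i], cb$outer_end[i], NA,
              NA_character_, cb$n_markers[i], context = ctx)
        }
      } else {
        ## terminal block (or flanked by another non-2:2 block)
        flank <- if (!is.null(left)) left else right
        if (!is.null(flank) && flank$ratio == "R22" &&
            (is.null(left) || is.null(right))) {
          d <- .pat_diff(cb$pattern[i], flank$pattern)
          if (length(d) == 1L) {
            add("GC_T1", ch, cb$outer_start[i], cb$outer_end[i], NA,
                gam[d], cb$n_markers[i], context = ctx)
            next
          }
        }
        add("COMPLEX", ch, cb$outer_start[i], cb$outer_end[i], NA,
            NA_character_, cb$n_markers[i], context = ctx)
      }
    }
  }
  out <- if (length(evs)) rbindlist(evs) else .empty_events()
  setorder(out, chrom, start, end)
  merge_events(out, merging_range_bp)
}

#' Merge recombination events in close adjacency
#'
#' Events on the same chromosome that share at least one involved gamete and
#' whose intervals lie within `merging_range_bp` of each other are merged
#' into a single event spanning their union; the type escalates to `COMPLEX`
#' when the merged events differ in type. With `merging_range_bp = 0` the
#' input is returned unchanged.
#'
#' @param events event table from [classify_events()].
#' @param merging_range_bp non-negative merging distance in bp.
#' @return merged event table.
#' @export
merge_events <- function(events, merging_range_bp = 0L) {
  stopifnot(merging_range_bp >= 0)
  ev <- copy(as.data.table(events))
  if (merging_range_bp == 0L || nrow(ev) < 2L) return(ev)
  repeat {
    merged <- FALSE
    setorder(ev, chrom, start, end)
    for (i in seq_len(nrow(ev) - 1L)) {
      for (j in (i + 1L):nrow(ev)) {
        if (ev$chrom[i] != ev$chrom[j]) next
        gap <- max(0, max(ev$start[i], ev$start[j]) -
                     min(ev$end[i], ev$end[j]))
        if (gap > merging_range_bp) next
        if (is.na(ev$gametes[i]) || is.na(ev$gametes[j])) next
        gi <- strsplit(ev$gametes[i], ",")[[1]]
        gj <- strsplit(ev$gametes[j], ",")[[1]]
        if (!length(intersect(gi, gj))) next
        new <- data.table(
          event_id = ev$event_id[i],
          type = if (ev$type[i] == ev$type[j]) ev$type[i] else "COMPLEX",
          chrom = ev$chrom[i],
          start = min(ev$start[i], ev$start[j]),
          end = max(ev$end[i], ev$end[j]),
          breakpoint = NA_real_,
          gametes = paste(sort(union(gi, gj)), collapse = ","),
          n_markers = ev$n_markers[i] + ev$n_markers[j],
          linked_event = NA_character_,
          context = paste(ev$context[i], ev$context[j], sep = "|"))
        ev <- rbind(ev[-c(i, j)], new)
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  setorder(ev, chrom, start, end)
  ev[]
}

#' Compare called events with simulated ground truth
#'
#' Derives the expected observable event list from the ground truth via
#' [expected_events()] (which accounts for marker-limited detectability and
#' type degradation), then matches called events to expected events
#' requiring identical chromosome, event type and involved gametes, and
#' overlapping intervals (the called interval extended by `tolerance_bp` on
#' each side). Each expected event is matched to at most one called event
#' and vice versa.
#'
#' @param events called event table from [classify_events()].
#' @param truth a `tetrad_truth`.
#' @param catalog marker table or `marker_catalog`.
#' @param tolerance_bp slack added to called intervals before the overlap
#'   test (default 0).
#' @return list with `summary` (per-type expected/matched/missed/spurious
#'   counts), `matches` (expected-to-called pairing), `recall` and
#'   `precision` over the expected (detectable) events.
#' @export
compare_to_truth <- function(events, truth, catalog, tolerance_bp = 0L) {
  exp_ev <- expected_events(truth, catalog)
  called <- copy(as.data.table(events))
  called[, matched := FALSE]
  pairs <- list()
  for (k in seq_len(nrow(exp_ev))) {
    e <- exp_ev[k]
    cand <- called[matched == FALSE & chrom == e$chrom & type == e$type &
                     gametes == e$gametes &
                     start - tolerance_bp <= e$end &
                     end + tolerance_bp >= e$start]
    if (nrow(cand)) {
      cand[, dist := abs((start + end) / 2 - (e$start + e$end) / 2)]
      hit <- cand[which.min(dist)]
      called[event_id == hit$event_id, matched := TRUE]
      pairs[[length(pairs) + 1L]] <- data.table(
        truth_id = e$truth_id, type = e$type, event_id = hit$event_id)
    }
  }
  matches <- if (length(pairs)) rbindlist(pairs) else
    data.table(truth_id = character(), type = character(),
               event_id = character())
  types <- sort(unique(c(exp_ev$type, called$type)))
  summary <- rbindlist(lapply(types, function(tp) {
    data.table(type = tp,
               n_expected = sum(exp_ev$type == tp),
               n_matched = sum(matches$type == tp),
               n_missed = sum(exp_ev$type == tp) - sum(matches$type == tp),
               n_spurious = sum(called$type == tp & !called$matched))
  }))
  list(summary = summary, matches = matches,
       recall = if (nrow(exp_ev)) nrow(matches) / nrow(exp_ev) else NaN,
       precision = if (nrow(called)) sum(called$matched) / nrow(called)
                   else NaN)
}
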