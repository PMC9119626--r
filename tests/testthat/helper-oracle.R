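## Brute-force recombination-event classifier used as the independent
## oracle: walks the per-marker pattern strings of a complete genotype
## matrix directly (no linkage-block objects, no interval arithmetic) and
## enumerates every run transition.

oracle_classify <- function(patterns, gam = c("a", "b", "c", "d")) {
  stopifnot(all(nchar(patterns) == 4L))
  r <- rle(patterns)
  k <- length(r$values)
  chars <- strsplit(r$values, "")
  ones <- vapply(chars, function(v) sum(v == "1"), integer(1))
  wdiff <- function(i, j) which(chars[[i]] != chars[[j]])
  out <- list()
  emit <- function(type, gametes, n_markers) {
    out[[length(out) + 1L]] <<- data.table(type = type, gametes = gametes,
                                           n_markers = as.integer(n_markers))
  }
  ## crossovers between directly adjacent 2:2 runs
  for (i in seq_len(max(k - 1L, 0L))) {
    if (ones[i] == 2L && ones[i + 1L] == 2L) {
      d <- wdiff(i, i + 1L)
      if (length(d) == 2L)
        emit("CO_T1", paste(sort(gam[d]), collapse = ","), 0L)
      else
        emit("COMPLEX", NA_character_, 0L)
    }
  }
  ## non-2:2 runs
  for (i in seq_len(k)) {
    if (ones[i] == 2L) next
    n_i <- r$lengths[i]
    if (ones[i] %in% c(0L, 4L)) { emit("COMPLEX", NA_character_, n_i); next }
    left22 <- i > 1L && ones[i - 1L] == 2L
    right22 <- i < k && ones[i + 1L] == 2L
    if (left22 && right22) {
      dl <- wdiff(i, i - 1L)
      dr <- wdiff(i, i + 1L)
      df <- wdiff(i - 1L, i + 1L)
      if (length(df) == 0L && length(dl) == 1L) {
        emit("GC_T1", gam[dl], n_i)
      } else if (length(df) == 2L && length(dl) == 1L &&
                 length(dr) == 1L && dl != dr && setequal(c(dl, dr), df)) {
        pair <- paste(gam[sort(df)], collapse = ",")
        emit("CO_T2", pair, n_i)
        emit("GC_T2", pair, n_i)
      } else {
        emit("COMPLEX", NA_character_, n_i)
      }
    } else if ((i == 1L || i == k) && (left22 || right22)) {
      fl <- if (left22) i - 1L else i + 1L
      d <- wdiff(i, fl)
      if (length(d) == 1L) emit("GC_T1", gam[d], n_i)
      else emit("COMPLEX", NA_character_, n_i)
    } else {
      emit("COMPLEX", NA_character_, n_i)
    }
  }
  if (!length(out))
    return(data.table(type = character(), gametes = character(),
                      n_markers = integer()))
  res <- rbindlist(out)
  setorder(res, type, gametes, n_markers, na.last = TRUE)
  res
}

## random complete genotype matrix built from a 2:2 base plus random
## crossover-like, conversion-like and arbitrary perturbations
oracle_random_matrix <- function(n_markers) {
  base <- sample(list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1),
                      c(2, 2, 1, 1), c(2, 1, 2, 1), c(2, 1, 1, 2)), 1)[[1]]
  G <- matrix(rep(base, each = n_markers), ncol = 4)
  for (e in seq_len(sample(0:4, 1))) {
    kind <- sample(c("co", "gc", "wild"), 1, prob = c(0.4, 0.4, 0.2))
    if (kind == "co") {
      p <- sample.int(n_markers, 1)
      ij <- sample.int(4, 2)
      G[p:n_markers, ij] <- 3L - G[p:n_markers, ij]
    } else if (kind == "gc") {
      p <- sort(sample.int(n_markers, 2))
      g <- sample.int(4, 1)
      G[p[1]:p[2], g] <- 3L - G[p[1]:p[2], g]
    } else {
      p <- sample.int(n_markers, 1)
      G[p, ] <- sample(1:2, 4, replace = TRUE)
    }
  }
  G
}

## run the package pipeline on a wide integer matrix, reduce to the
## oracle's comparison view
pipeline_classify <- function(G, pos = NULL, chrom_len = NULL) {
  calls <- mk_calls_int(G, pos = pos)
  rec <- classify_segregation(calls)
  cl <- if (is.null(chrom_len)) NULL else c(chr1 = chrom_len)
  bl <- build_blocks(rec, cl)
  ev <- classify_events(bl)
  res <- ev[, .(type, gametes, n_markers)]
  setorder(res, type, gametes, n_markers, na.last = TRUE)
  res
}
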