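test_that("segregation records classify complete rows and skip NA rows", {
  mat <- rbind(c("P1", "P1", "P2", "P2"),
               c("P1", "P1", "P1", "P2"),
               c("P1", NA, "P2", "P2"),
               c("P2", "P2", "P2", "P2"))
  rec <- classify_segregation(mk_calls(mat))
  expect_equal(nrow(rec), 3L)                       # NA row dropped
  expect_equal(rec$ratio, c("R22", "R31", "R04"))
  expect_equal(rec$pattern, c("1122", "1112", "2222"))
  expect_equal(attr(rec, "gametes"), c("a", "b", "c", "d"))
})

test_that("block bounds are flanking-marker midpoints extended to chromosome ends", {
  mat <- rbind(matrix(c("P1", "P1", "P2", "P2"), 3, 4, byrow = TRUE),
               matrix(c("P1", "P2", "P1", "P2"), 2, 4, byrow = TRUE))
  calls <- mk_calls(mat, pos = c(100, 120, 140, 200, 220))
  rec <- classify_segregation(calls)
  bl <- build_blocks(rec, c(chr1 = 1000))
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$outer_end[1], 170)                 # (140+200)/2
  expect_equal(bl$outer_start[2], 170)
  expect_equal(bl$outer_start[1], 1)
  expect_equal(bl$outer_end[2], 1000)

  ## inner block flanked by neighbors at 50 and 260
  mat2 <- rbind(c("P1", "P1", "P2", "P2"),
                matrix(c("P1", "P2", "P1", "P2"), 3, 4, byrow = TRUE),
                c("P2", "P1", "P2", "P1"))
  calls2 <- mk_calls(mat2, pos = c(50, 100, 150, 200, 260))
  bl2 <- build_blocks(classify_segregation(calls2), c(chr1 = 500))
  expect_equal(bl2[2, .(outer_start, outer_end)],
               data.table(outer_start = 75, outer_end = 230))
})

test_that("NA markers never split a block", {
  mat <- rbind(c("P1", "P1", "P2", "P2"),
               c("P1", NA, "P2", "P2"),
               c("P1", "P1", "P2", "P2"))
  bl <- build_blocks(classify_segregation(mk_calls(mat)), c(chr1 = 400))
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$n_markers, 2L)
})

test_that("sub-threshold blocks dissolve and same-pattern flanks merge", {
  mat <- rbind(matrix("P1", 2, 4),
               c("P1", "P1", "P1", "P2"),                 # 1-marker island
               matrix("P1", 2, 4))
  mat[1:2, 3:4] <- "P2"; mat[4:5, 3:4] <- "P2"
  calls <- mk_calls(mat, pos = c(100, 200, 300, 400, 500))
  bl1 <- build_blocks(classify_segregation(calls), c(chr1 = 600),
                      min_markers = 1)
  expect_equal(nrow(bl1), 3L)
  bl2 <- build_blocks(classify_segregation(calls), c(chr1 = 600),
                      min_markers = 2)
  expect_equal(nrow(bl2), 1L)
  expect_equal(bl2$n_markers, 4L)                    # island marker ignored
  expect_equal(bl2$pattern, "1122")
})

test_that("final blocks tile each chromosome without gaps or overlaps", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    G <- oracle_random_matrix(n)
    pos <- sort(sample(1:5000, n))
    bl <- build_blocks(classify_segregation(mk_calls_int(G, pos = pos)),
                       c(chr1 = 6000))
    expect_equal(bl$outer_start[1], 1)
    expect_equal(bl$outer_end[nrow(bl)], 6000)
    if (nrow(bl) > 1)
      expect_equal(bl$outer_start[-1], bl$outer_end[-nrow(bl)])
  }
})

test_that("adjacent-block transitions classify into the event taxonomy", {
  ## reciprocal 2-gamete switch between 2:2 blocks: Type 1 CO
  mat <- rbind(matrix(c("P1", "P1", "P2", "P2"), 2, 4, byrow = TRUE),
               matrix(c("P1", "P2", "P1", "P2"), 2, 4, byrow = TRUE))
  ev <- classify_events(build_blocks(classify_segregation(mk_calls(mat)),
                                     c(chr1 = 500)))
  expect_equal(ev$type, "CO_T1")
  expect_equal(ev$gametes, "b,c")
  expect_equal(ev$breakpoint, 250)                  # midpoint of 200 | 300

  ## 3:1 island with identical flanks: Type 1 GC on the deviant gamete
  mat <- rbind(c("P1", "P1", "P2", "P2"),
               c("P1", "P1", "P1", "P2"),
               c("P1", "P1", "P2", "P2"))
  ev <- classify_events(build_blocks(classify_segregation(mk_calls(mat)),
                                     c(chr1 = 500)))
  expect_equal(ev$type, "GC_T1")
  expect_equal(ev$gametes, "c")
  expect_equal(ev$n_markers, 1L)

  ## 3:1 island between reciprocally differing flanks: CO_T2 + linked GC_T2
  mat <- rbind(c("P1", "P1", "P2", "P2"),
               c("P1", "P1", "P1", "P2"),
               c("P1", "P2", "P1", "P2"))
  ev <- classify_events(build_blocks(classify_segregation(mk_calls(mat)),
                                     c(chr1 = 500)))
  expect_setequal(ev$type, c("CO_T2", "GC_T2"))
  expect_equal(unique(ev$gametes), "b,c")
  expect_equal(ev[type == "CO_T2", linked_event], ev[type == "GC_T2", event_id])
  expect_equal(ev[type == "GC_T2", linked_event], ev[type == "CO_T2", event_id])

  ## 4:0 block and >=3-gamete switches go to COMPLEX
  mat <- rbind(c("P1", "P1", "P2", "P2"),
               c("P1", "P1", "P1", "P1"),
               c("P1", "P1", "P2", "P2"))
  ev <- classify_events(build_blocks(classify_segregation(mk_calls(mat)),
                                     c(chr1 = 500)))
  expect_equal(ev$type, "COMPLEX")
  expect_false(is.na(ev$context))

  ## terminal 3:1 block: GC truncated at the chromosome end
  mat <- rbind(c("P1", "P2", "P1", "P2"),
               c("P1", "P2", "P2", "P2"))
  ev <- classify_events(build_blocks(classify_segregation(mk_calls(mat)),
                                     c(chr1 = 500)))
  expect_equal(ev$type, "GC_T1")
  expect_equal(ev$gametes, "c")
})

test_that("event merging is gated on range, chromosome and shared gametes", {
  ev <- data.table(
    event_id = c("E1", "E2", "E3"),
    type = c("GC_T1", "GC_T1", "CO_T1"),
    chrom = "chr1",
    start = c(1000, 1250, 5000), end = c(1200, 1400, 5002),
    breakpoint = NA_real_, gametes = c("b", "b", "b,c"),
    n_markers = c(3L, 2L, 0L), linked_event = NA_character_,
    context = NA_character_)
  expect_equal(merge_events(ev, 0), ev)              # identity at range 0
  m <- merge_events(ev, 100)
  expect_equal(nrow(m), 2L)
  expect_equal(m[gametes == "b", .(type, start, end, n_markers)],
               data.table(type = "GC_T1", start = 1000, end = 1400,
                          n_markers = 5L))
  ## different types escalate to COMPLEX
  ev2 <- copy(ev)[2, `:=`(type = "CO_T1", gametes = "b,c")]
  m2 <- merge_events(ev2, 100)
  expect_equal(nrow(m2), 2L)
  expect_true("COMPLEX" %in% m2$type)
})

test_that("truth comparison matches on type, gametes and location", {
  fx <- yeast_fixture(5000)
  cfg <- simulation_config(n_co = 10, n_nco = 8, depth = 20, base_error = 0,
                           seed = 3)
  tr <- simulate_tetrad(cfg, fx$catalog, fx$chrom_lengths)
  obs <- simulate_observations(tr, fx$catalog, cfg)
  calls <- genotype_gametes(obs, fx$catalog, qnet_cutoff = 50)
  ev <- classify_events(build_blocks(classify_segregation(calls),
                                     fx$chrom_lengths))
  cmp <- compare_to_truth(ev, tr, fx$catalog)
  expect_equal(cmp$recall, 1)
  expect_equal(cmp$precision, 1)

  ## empty call set: everything missed
  cmp0 <- compare_to_truth(ev[0], tr, fx$catalog)
  expect_equal(cmp0$recall, 0)
  expect_equal(sum(cmp0$summary$n_missed), sum(cmp0$summary$n_expected))

  ## wrong involved gamete: spurious call plus missed truth
  ev2 <- copy(ev)
  g1 <- ev2[type == "GC_T1"][1]
  ev2[event_id == g1$event_id,
      gametes := setdiff(c("a", "b", "c", "d"), g1$gametes)[1]]
  cmp2 <- compare_to_truth(ev2, tr, fx$catalog)
  expect_equal(cmp2$summary[type == "GC_T1", n_missed], 1L)
  expect_equal(cmp2$summary[type == "GC_T1", n_spurious], 1L)
})

test_that("block building and classification agree with the brute-force oracle", {
  set.seed(77)
  for (i in 1:80) {
    n <- sample(2:20, 1)
    G <- oracle_random_matrix(n)
    o <- oracle_classify(apply(G, 1, paste, collapse = ""))
    p <- pipeline_classify(G)
    expect_equal(p, o, ignore_attr = TRUE)
  }
})
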