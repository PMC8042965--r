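test_that("classify_junction follows the shift and inversion rules", {
  p <- hotspot_params()
  L <- 100000L
  # same strand, ref gap 500 vs read gap 10: shift of 490, an event
  a <- mk_seg(read_start = 0L, read_end = 1000L, ref_start = 0L,
              ref_end = 1000L)
  b <- mk_seg(read_start = 1010L, read_end = 2010L, ref_start = 1500L,
              ref_end = 2500L)
  ev <- classify_junction(a, b, L, TRUE, p)
  expect_equal(ev$kind, "shift")
  expect_equal(ev$magnitude, 490)
  expect_equal(c(ev$lo, ev$hi), c(1000L, 1500L))

  # magnitude 150 stays below the strict 200-bp threshold: no event
  b2 <- mk_seg(read_start = 1000L, read_end = 2000L, ref_start = 1150L,
               ref_end = 2150L)
  expect_null(classify_junction(a, b2, L, TRUE, p))
  # magnitude exactly 200: still no event; 201 is one
  b3 <- mk_seg(read_start = 1000L, read_end = 2000L, ref_start = 1200L,
               ref_end = 2200L)
  expect_null(classify_junction(a, b3, L, TRUE, p))
  b4 <- mk_seg(read_start = 1000L, read_end = 2000L, ref_start = 1201L,
               ref_end = 2201L)
  expect_equal(classify_junction(a, b4, L, TRUE, p)$magnitude, 201)

  # strand flip between 300/400 bp segments is an inversion event
  a5 <- mk_seg(read_start = 0L, read_end = 300L, ref_start = 5000L,
               ref_end = 5300L)
  b5 <- mk_seg(read_start = 300L, read_end = 700L, ref_start = 5300L,
               ref_end = 5700L, strand = "-")
  ev5 <- classify_junction(a5, b5, L, TRUE, p)
  expect_equal(ev5$kind, "inversion")
  expect_equal(ev5$magnitude, 300)

  # circular wrap: a ends at 99,900, b starts at 150, read gap 50:
  # minimal-arc displacement 250, magnitude exactly 200, no event
  a6 <- mk_seg(read_start = 0L, read_end = 900L, ref_start = 99000L,
               ref_end = 99900L)
  b6 <- mk_seg(read_start = 950L, read_end = 1950L, ref_start = 150L,
               ref_end = 1150L)
  expect_null(classify_junction(a6, b6, L, TRUE, p))
  # one bp less of read gap makes it an event of magnitude 201,
  # localized across the origin as two intervals
  b7 <- mk_seg(read_start = 949L, read_end = 1949L, ref_start = 150L,
               ref_end = 1150L)
  ev7 <- classify_junction(a6, b7, L, TRUE, p)
  expect_equal(unique(ev7$magnitude), 201)
  expect_equal(nrow(ev7), 2)
  expect_setequal(ev7$lo, c(99900L, 0L))
  # on a linear genome the same pair is a huge leftward shift
  evlin <- classify_junction(a6, b7, L, FALSE, p)
  expect_equal(unique(evlin$magnitude), abs((150 - 99900) - (949 - 900)))

  # segments from different reads violate the contract
  expect_error(classify_junction(a, mk_seg(read_id = "zz"), L, TRUE, p),
               "different reads")
})

test_that("detect_events enumerates consecutive junctions per chain", {
  p <- hotspot_params()
  expect_equal(nrow(detect_events(mk_seg(), 50000L, TRUE, p)), 0)

  # three segments with strands +,-,+ give two inversion events
  ch <- mk_chain(
    mk_seg(read_start = 0L, read_end = 1000L, ref_start = 2000L,
           ref_end = 3000L),
    mk_seg(read_start = 1000L, read_end = 1500L, ref_start = 3000L,
           ref_end = 3500L, strand = "-"),
    mk_seg(read_start = 1500L, read_end = 2500L, ref_start = 3500L,
           ref_end = 4500L))
  ev <- detect_events(ch, 50000L, TRUE, p)
  expect_equal(ev$kind, c("inversion", "inversion"))
  expect_equal(ev$junction, c(1L, 2L))

  # collinear adjacent segments (equal ref and read gaps) are silent
  ch2 <- mk_chain(
    mk_seg(read_start = 0L, read_end = 1000L, ref_start = 0L,
           ref_end = 1000L),
    mk_seg(read_start = 1300L, read_end = 2300L, ref_start = 1300L,
           ref_end = 2300L))
  expect_equal(nrow(detect_events(ch2, 50000L, TRUE, p)), 0)
})

test_that("detect_events matches a brute-force enumerator on random chains", {
  set.seed(77)
  p <- hotspot_params()
  for (i in 1:300) {
    ch <- random_chain(sprintf("r%04d", i), genome_len = 10000L)
    got <- detect_events(ch, 10000L, TRUE, p)
    want <- brute_force_events(ch, 10000L, TRUE)
    got1 <- unique(got[, c("junction", "kind", "magnitude")])
    expect_equal(nrow(got1), nrow(want), info = sprintf("chain %d", i))
    expect_equal(got1$kind, want$kind, info = sprintf("chain %d", i))
    expect_equal(got1$magnitude, want$magnitude,
                 info = sprintf("chain %d", i))
    # linear classification must agree too
    got_lin <- unique(detect_events(ch, 10000L, FALSE,
                                    p)[, c("junction", "kind", "magnitude")])
    want_lin <- brute_force_events(ch, 10000L, FALSE)
    expect_equal(got_lin$magnitude, want_lin$magnitude,
                 info = sprintf("linear chain %d", i))
  }
})

test_that("hotspots need strictly more than min_reads distinct reads", {
  p <- hotspot_params()
  L <- 20000L
  # 9 distinct reads with junctions inside [3000, 4000): one hotspot
  ev9 <- mk_events_at(sprintf("r%d", 1:9), 3200L, 3300L)
  hs <- call_hotspots(ev9, L, p)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$start, 3000L)
  expect_equal(hs$n_reads, 9L)
  expect_equal(sort(strsplit(hs$read_ids, ",")[[1]]),
               sort(sprintf("r%d", 1:9)))

  # 8 distinct reads, each with two events there: still no hotspot
  ev8 <- rbind(mk_events_at(sprintf("r%d", 1:8), 3200L, 3300L),
               mk_events_at(sprintf("r%d", 1:8), 3400L, 3500L))
  expect_equal(nrow(call_hotspots(ev8, L, p)), 0)
  # histograms count each read once per touched window
  expect_equal(hotspot_histogram(ev8, L, p)[4], 8L)

  # no events, no hotspots; histogram has one slot per window
  none <- call_hotspots(ev9[0, ], L, p)
  expect_equal(nrow(none), 0)
  expect_equal(hotspot_histogram(ev9[0, ], L, p), integer(20))
})

test_that("junction intervals spanning window boundaries touch every window", {
  p <- hotspot_params()
  ev <- mk_events_at("r1", 1990L, 2010L)
  h <- hotspot_histogram(ev, 10000L, p)
  expect_equal(h, c(0L, 1L, 1L, rep(0L, 7L)))

  # single event confined to one window increments exactly that window
  h2 <- hotspot_histogram(mk_events_at("r1", 5100L, 5200L), 10000L, p)
  expect_equal(which(h2 == 1L), 6L)
  expect_equal(sum(h2), 1L)

  # a translocation-like jump spanning most of the genome is truncated
  # to its two window-sized flanks instead of painting everything
  wide <- mk_events_at(sprintf("r%d", 1:10), 2000L, 52000L)
  h3 <- hotspot_histogram(wide, 60000L, p)
  expect_equal(which(h3 > 0), c(3L, 52L))
})

test_that("hotspot calls are monotone in min_reads and min_shift", {
  sc <- toy_scenario(seed = 41L, n_reads = 500L)
  L <- sc$sim$genome$length
  kept <- filter_alignments(sc$alns, filter_thresholds())
  chains <- build_chains(kept)
  hs_by_reads <- lapply(c(2, 8, 20), function(mr) {
    call_hotspots(detect_events_all(chains, L, TRUE, hotspot_params()),
                  L, hotspot_params(min_reads = mr))$window_index
  })
  expect_true(all(hs_by_reads[[2]] %in% hs_by_reads[[1]]))
  expect_true(all(hs_by_reads[[3]] %in% hs_by_reads[[2]]))

  hs_by_shift <- lapply(c(100, 200, 1000), function(ms) {
    p <- hotspot_params(min_shift = ms)
    call_hotspots(detect_events_all(chains, L, TRUE, p), L, p)$window_index
  })
  expect_true(all(hs_by_shift[[2]] %in% hs_by_shift[[1]]))
  expect_true(all(hs_by_shift[[3]] %in% hs_by_shift[[2]]))

  # an absurd threshold removes everything
  p_inf <- hotspot_params(min_reads = 1e6)
  expect_equal(nrow(call_hotspots(detect_events_all(chains, L, TRUE,
                                                    hotspot_params()),
                                  L, p_inf)), 0)
})

test_that("hotspot calls rotate with the reference on circular genomes", {
  sc <- toy_scenario(seed = 51L, n_reads = 400L)
  L <- sc$sim$genome$length
  r <- 7000L
  alns <- filter_alignments(sc$alns, filter_thresholds())
  # drop reads with any segment that would straddle the origin after
  # rotation, so coordinates rotate without re-splitting
  shifted <- alns
  shifted$ref_start <- (alns$ref_start + r) %% L
  shifted$ref_end <- ((alns$ref_end - 1L + r) %% L) + 1L
  bad_reads <- unique(shifted$read_id[shifted$ref_end <= shifted$ref_start])
  alns <- alns[!alns$read_id %in% bad_reads, ]
  shifted <- shifted[!shifted$read_id %in% bad_reads, ]

  p <- hotspot_params()
  hs0 <- call_hotspots(detect_events_all(build_chains(alns), L, TRUE, p),
                       L, p)
  hs1 <- call_hotspots(detect_events_all(build_chains(shifted), L, TRUE, p),
                       L, p)
  expect_equal(sort((hs0$window_index * p$window + r) %% L),
               sort(hs1$window_index * p$window))
})
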