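test_that("simulated genomes have the requested length, composition and loci", {
  sim <- simulate_genome(100000, gc = 0.43, n_loci = 3,
                         locus_len_range = c(500, 2000), seed = 1)
  expect_equal(sim$genome$length, 100000)
  expect_equal(nchar(sim$genome$sequence), 100000)
  expect_equal(nrow(sim$loci), 3)
  expect_true(all(sim$loci$end - sim$loci$start >= 500))
  expect_true(all(sim$loci$end - sim$loci$start <= 2000))
  # loci are non-overlapping and at least one window apart
  expect_true(all(sim$loci$start[-1] - sim$loci$end[-3] >= 1000))

  # oracle: realized G+C by direct base counting
  tab <- table(strsplit(sim$genome$sequence, "", fixed = TRUE)[[1]])
  gc <- (tab[["G"]] + tab[["C"]]) / sum(tab)
  expect_lt(abs(gc - 0.43), 0.01)
})

test_that("simulate_genome is deterministic and reports infeasible placement", {
  a <- simulate_genome(50000, n_loci = 2, locus_len_range = c(500, 900),
                       seed = 42)
  b <- simulate_genome(50000, n_loci = 2, locus_len_range = c(500, 900),
                       seed = 42)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$loci, b$loci)
  expect_error(
    simulate_genome(25000, n_loci = 10, locus_len_range = c(2100, 2400),
                    seed = 1),
    "could not place")
})

test_that("a genome without invertible loci yields no hotspots", {
  sim <- simulate_genome(40000, n_loci = 0, seed = 3)
  expect_equal(nrow(sim$loci), 0)
  pop <- build_population(sim$genome, sim$loci, n_variants = 10, seed = 3)
  rd <- simulate_reads(pop, n_reads = 200, seed = 3)
  expect_false(any(rd$reads$truth_discordant))
  scan <- scan_alignments(emit_truth_alignments(rd), sim$genome$length)
  expect_equal(nrow(scan$hotspots), 0)
  expect_equal(length(scan$discordant_reads), 0)
})

test_that("population inversion is an involution and matches its binomial rate", {
  sim <- simulate_genome(30000, n_loci = 2, locus_len_range = c(300, 600),
                         inverted_fraction = 1, seed = 5)
  pop1 <- build_population(sim$genome, sim$loci, n_variants = 3, seed = 5)
  expect_true(all(pop1$orientations))
  v1 <- variant_sequence(pop1, 1)
  expect_false(identical(v1, sim$genome$sequence))
  # invert every locus again: back to the reference
  g2 <- reference_genome("twice", v1, circular = TRUE)
  pop2 <- build_population(g2, sim$loci, n_variants = 1, seed = 6)
  expect_identical(variant_sequence(pop2, 1), sim$genome$sequence)

  # fraction 0 leaves every variant identical to the reference
  loci0 <- sim$loci
  loci0$inverted_fraction <- 0
  pop0 <- build_population(sim$genome, loci0, n_variants = 4, seed = 7)
  expect_identical(variant_sequence(pop0, 2), sim$genome$sequence)

  # realized inversion counts are binomial around n * fraction
  loci3 <- sim$loci
  loci3$inverted_fraction <- 0.3
  pop3 <- build_population(sim$genome, loci3, n_variants = 1000, seed = 8)
  sd3 <- sqrt(1000 * 0.3 * 0.7)
  expect_true(all(abs(pop3$realized_counts - 300) <= 3 * sd3))
})

test_that("origin segments map bijectively onto read coordinates", {
  sc <- toy_scenario()
  segs <- split(sc$reads$segments, sc$reads$segments$read_id)
  lens <- setNames(sc$reads$reads$length, sc$reads$reads$read_id)
  for (id in names(segs)) {
    s <- segs[[id]]
    s <- s[order(s$read_start), ]
    expect_equal(sum(s$read_end - s$read_start), unname(lens[[id]]))
    expect_equal(s$read_start, c(0L, s$read_end[-nrow(s)]))
  }
  # read sequences have the stated lengths
  expect_equal(unname(nchar(sc$reads$sequences)),
               sc$reads$reads$length)
})

test_that("a read across a fully inverted locus is discordant with a +,-,+ path", {
  sim <- simulate_genome(30000, n_loci = 1, locus_len_range = c(500, 500),
                         inverted_fraction = 1, seed = 9)
  locus <- sim$loci
  pop <- build_population(sim$genome, sim$loci, n_variants = 2, seed = 9)
  # place one read deterministically so that it fully spans the locus
  segs <- invertonscan:::origin_segments(locus$start - 1000L, 2500L,
                                         sim$genome$length, TRUE,
                                         locus)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$strand, c("+", "-", "+"))
  expect_equal(segs[2, c("ref_start", "ref_end")],
               data.frame(ref_start = locus$start, ref_end = locus$end),
               ignore_attr = TRUE)
  tr <- invertonscan:::truth_from_segments(segs, sim$genome$length, TRUE,
                                           200L, 200L)
  expect_true(tr$discordant)

  # a read wholly inside a never-inverted region stays concordant
  far <- (locus$end + 5000L) %% (sim$genome$length - 3000L)
  segs1 <- invertonscan:::origin_segments(far, 2000L, sim$genome$length,
                                          TRUE, locus[0, ])
  expect_equal(nrow(segs1), 1)
  expect_false(invertonscan:::truth_from_segments(
    segs1, sim$genome$length, TRUE, 200L, 200L)$discordant)
})

test_that("simulate_reads honours counts, clamping and linear-reference limits", {
  sc <- toy_scenario(n_reads = 500L)
  expect_equal(nrow(sc$reads$reads), 500)
  expect_true(all(sc$reads$reads$length >= 1001))

  lin <- reference_genome("short", strrep("ACGT", 500), circular = FALSE)
  pop <- build_population(lin, data.frame(start = integer(0),
                                          end = integer(0),
                                          inverted_fraction = numeric(0)),
                          n_variants = 2, seed = 1)
  expect_error(simulate_reads(pop, n_reads = 20, min_len = 3000, seed = 1),
               "longer than the linear reference")
})

test_that("oracle alignments tile each read and round-trip through PAF and BLAST", {
  sc <- toy_scenario(n_reads = 120L)
  alns <- sc$alns
  expect_true(all(alns$identity_pct == 100))
  expect_true(all(alns$evalue == 0))
  by_read <- split(alns, alns$read_id)
  for (id in names(by_read)[1:20]) {
    a <- by_read[[id]][order(by_read[[id]]$read_start), ]
    expect_equal(a$read_start[1], 0L)
    expect_equal(a$read_end[nrow(a)], a$read_len[1])
    if (nrow(a) > 1) expect_equal(a$read_start[-1], a$read_end[-nrow(a)])
  }

  paf <- tempfile(fileext = ".paf")
  write_paf(alns, sc$sim$genome, paf)
  back <- read_paf(paf)
  cols <- c("read_id", "read_len", "read_start", "read_end",
            "ref_start", "ref_end", "strand", "aln_len")
  expect_equal(back[cols], alns[cols], ignore_attr = TRUE)
  expect_true(all(is.na(back$evalue)))

  bl <- tempfile(fileext = ".tsv")
  write_blast_tab(alns, sc$sim$genome, bl)
  lens <- setNames(sc$reads$reads$length, sc$reads$reads$read_id)
  back2 <- read_blast_tab(bl, lens)
  expect_equal(back2[cols], alns[cols], ignore_attr = TRUE)
  expect_equal(back2$evalue, rep(0, nrow(alns)))
})

test_that("identical seeds reproduce identical read sets", {
  a <- toy_scenario(seed = 21L, n_reads = 100L)
  b <- toy_scenario(seed = 21L, n_reads = 100L)
  expect_identical(a$reads$sequences, b$reads$sequences)
  expect_identical(a$reads$segments, b$reads$segments)
  expect_identical(a$reads$reads, b$reads$reads)
})
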