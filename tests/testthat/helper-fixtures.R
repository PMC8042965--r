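# Shared fixture builders and independent oracles. Everything is
# generated in code; no binary fixtures.

# One alignment-table row with sane defaults.
mk_seg <- function(read_id = "r1", read_start = 0L, read_end = 1000L,
                   ref_start = 0L, ref_end = 1000L, strand = "+",
                   read_len = 5000L, identity_pct = 100, evalue = NA_real_,
                   aln_len = read_end - read_start) {
  data.frame(read_id = read_id, read_len = read_len,
             read_start = read_start, read_end = read_end,
             ref_start = ref_start, ref_end = ref_end, strand = strand,
             identity_pct = identity_pct, evalue = evalue,
             aln_len = aln_len)
}

mk_chain <- function(...) {
  df <- do.call(rbind, list(...))
  df[order(df$read_start), , drop = FALSE]
}

# Independent brute-force junction enumerator used as the oracle for
# detect_events. Circular displacement is found by explicitly trying the
# three linear unwrappings (d, d - L, d + L) and keeping the smallest
# |displacement| (preferring the non-negative one on exact ties), rather
# than the modular arithmetic the implementation uses.
brute_force_events <- function(chain, genome_len, circular,
                               min_shift = 200, min_inversion_len = 0) {
  kinds <- character(0)
  mags <- numeric(0)
  n <- nrow(chain)
  if (n >= 2) {
    for (j in seq_len(n - 1)) {
      a <- chain[j, ]
      b <- chain[j + 1, ]
      if (a$strand != b$strand) {
        m <- min(a$ref_end - a$ref_start, b$ref_end - b$ref_start)
        if (m > min_inversion_len) {
          kinds <- c(kinds, "inversion")
          mags <- c(mags, m)
        }
        next
      }
      fa <- if (a$strand == "+") a$ref_end else a$ref_start
      fb <- if (b$strand == "+") b$ref_start else b$ref_end
      raw <- if (a$strand == "+") fb - fa else fa - fb
      cands <- if (circular) c(raw, raw - genome_len, raw + genome_len) else raw
      best <- cands[order(abs(cands), cands < 0)][1]
      m <- abs(best - (b$read_start - a$read_end))
      if (m > min_shift) {
        kinds <- c(kinds, "shift")
        mags <- c(mags, m)
      }
    }
  }
  data.frame(kind = kinds, magnitude = mags)
}

# Random chain of up to max_segs segments over a toy reference.
random_chain <- function(read_id, genome_len = 10000L, max_segs = 4L) {
  n <- sample.int(max_segs, 1L)
  seg_len <- sample(201:800, n, replace = TRUE)
  gaps <- sample(0:300, n, replace = TRUE)
  read_start <- cumsum(gaps) + c(0L, cumsum(seg_len))[seq_len(n)]
  ref_start <- sample.int(genome_len - max(seg_len), n, replace = TRUE) - 1L
  do.call(rbind, lapply(seq_len(n), function(i) {
    mk_seg(read_id = read_id,
           read_start = read_start[i], read_end = read_start[i] + seg_len[i],
           ref_start = ref_start[i], ref_end = ref_start[i] + seg_len[i],
           strand = sample(c("+", "-"), 1L),
           read_len = max(read_start + seg_len) + 1500L)
  }))
}

# Small simulated scenario reused across tests (kept modest so the whole
# suite stays fast).
toy_scenario <- function(seed = 11L, n_loci = 2L, inverted_fraction = 0.4,
                         n_reads = 400L, genome_len = 60000L,
                         n_variants = 60L) {
  sim <- simulate_genome(genome_len, gc = 0.43, n_loci = n_loci,
                         locus_len_range = c(500L, 1500L),
                         inverted_fraction = inverted_fraction,
                         circular = TRUE, seed = seed)
  pop <- build_population(sim$genome, sim$loci, n_variants = n_variants,
                          seed = seed + 1L)
  reads <- simulate_reads(pop, n_reads = n_reads, seed = seed + 2L)
  list(sim = sim, pop = pop, reads = reads,
       alns = emit_truth_alignments(reads))
}

# Events table with one junction per read, all inside [lo, hi).
mk_events_at <- function(read_ids, lo, hi) {
  data.frame(read_id = read_ids, junction = 1L, kind = "inversion",
             magnitude = hi - lo, lo = lo, hi = hi)
}

write_fixture_gff <- function(path,
                              seqid = "chr",
                              rows = NULL) {
  header <- "##gff-version 3"
  if (is.null(rows)) {
    rows <- c(
      gff_row(seqid, "gene", 101, 200, "+", "g_plain", "hypothetical protein"),
      gff_row(seqid, "CDS", 1001, 2000, "+", "g_int",
              "site-specific integrase"),
      gff_row(seqid, "CDS", 2501, 3500, "+", "g_cap",
              "capsule biosynthesis protein"),
      gff_row(seqid, "CDS", 9001, 9800, "-", "g_tonb",
              "TonB-dependent receptor"),
      gff_row(seqid, "CDS", 12001, 12900, "+", "g_rec",
              "tyrosine-type recombinase/integrase"))
  }
  writeLines(c(header, rows), path)
  path
}

gff_row <- function(seqid, type, start, end, strand, id, product) {
  sprintf("%s\tfixture\t%s\t%d\t%d\t.\t%s\t.\tID=%s;product=%s",
          seqid, type, start, end, strand, id, product)
}
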