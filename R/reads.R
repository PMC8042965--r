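#' Simulate nanopore-like reads from a phase-variable population
#'
#' Read lengths are log-normal (the default log-mean 8.5 / log-sd 0.6 gives
#' a median near 4.9 kb) clamped to `min_len`; start positions are uniform
#' on the variant genome, wrapping across the origin when the replicon is
#' circular. Reads are error-free by default: the detection pipeline
#' consumes aligner output, not raw signal, so exact reads keep the oracle
#' alignments exact. Each read carries its origin segments in reference
#' coordinates (split at every inverted-locus boundary it crosses, and at
#' the origin) plus a truth label saying whether the read's alignment
#' structure is discordant with the reference.
#'
#' The truth label mirrors the published detection rule: origin segments
#' shorter than `truth_min_seg_len` bp are ignored (they would not survive
#' the segment-length filter), and a read is discordant iff two consecutive
#' surviving segments differ in strand or are displaced from collinearity
#' by more than `truth_min_shift` bp.
#'
#' @param population A [build_population()] result.
#' @param n_reads Number of reads to draw.
#' @param len_meanlog,len_sdlog Log-normal read-length parameters.
#' @param min_len Minimum read length in bp (lengths are clamped up to it).
#'   The default 1001 keeps every simulated read above the strict >1000 nt
#'   read filter.
#' @param error_rate Uniform substitution rate applied to read sequences
#'   (default 0; truth alignments assume error-free reads).
#' @param seed Integer seed.
#' @param truth_min_seg_len,truth_min_shift Thresholds (bp) used for the
#'   truth label, matching the published segment-length and shift filters.
#' @return Object of class `simulated_reads`: list with `reads` (data.frame:
#'   `read_id`, `length`, `variant`, `start`, `n_segments`,
#'   `truth_discordant`), `segments` (data.frame of origin segments in read
#'   order: `read_id`, `read_start`, `read_end`, `ref_start`, `ref_end`,
#'   `strand`, `origin_adjacent`), `sequences` (named character),
#'   `truth_junctions` (named list of reference positions), and `genome`.
#' @examples
#' sim <- simulate_genome(50000, n_loci = 1, locus_len_range = c(500, 800),
#'                        inverted_fraction = 1, seed = 1)
#' pop <- build_population(sim$genome, sim$loci, n_variants = 5, seed = 1)
#' rd <- simulate_reads(pop, n_reads = 10, seed = 1)
#' table(rd$reads$truth_discordant)
#' @export
simulate_reads <- function(population, n_reads,
                           len_meanlog = 8.5, len_sdlog = 0.6,
                           min_len = 1001L, error_rate = 0,
                           seed = NULL,
                           truth_min_seg_len = 200L,
                           truth_min_shift = 200L) {
  stopifnot(inherits(population, "genome_population"),
            n_reads >= 1, min_len >= 1, error_rate >= 0, error_rate < 1)
  genome <- population$genome
  L <- genome$length

  with_seed(seed, {
    lens <- pmax(as.integer(round(rlnorm(n_reads, len_meanlog, len_sdlog))),
                 as.integer(min_len))
    if (genome$circular) {
      lens <- pmin(lens, L)
      starts <- sample.int(L, n_reads, replace = TRUE) - 1L
    } else {
      if (any(lens > L))
        stopf("read longer than the linear reference (%d > %d bp); cannot place it",
              max(lens), L)
      starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L,
                       integer(1))
    }
    variants <- sample.int(nrow(population$orientations), n_reads,
                           replace = TRUE)

    seg_list <- vector("list", n_reads)
    seqs <- character(n_reads)
    discordant <- logical(n_reads)
    junctions <- vector("list", n_reads)
    ids <- sprintf("read_%05d", seq_len(n_reads))

    for (i in seq_len(n_reads)) {
      inv <- population$loci[population$orientations[variants[i], ], ,
                             drop = FALSE]
      segs <- origin_segments(starts[i], lens[i], L, genome$circular, inv)
      segs$read_id <- ids[i]
      seg_list[[i]] <- segs
      seqs[i] <- read_sequence_from_segments(genome$sequence, segs)
      tr <- truth_from_segments(segs, L, genome$circular,
                                truth_min_seg_len, truth_min_shift)
      discordant[i] <- tr$discordant
      junctions[[i]] <- tr$junctions
    }

    if (error_rate > 0) seqs <- vapply(seqs, mutate_seq, character(1),
                                       rate = error_rate, USE.NAMES = FALSE)

    segments <- do.call(rbind, seg_list)
    segments <- segments[, c("read_id", "read_start", "read_end",
                             "ref_start", "ref_end", "strand",
                             "origin_adjacent")]
    rownames(segments) <- NULL
    structure(
      list(reads = data.frame(read_id = ids, length = lens,
                              variant = variants, start = starts,
                              n_segments = vapply(seg_list, nrow, integer(1)),
                              truth_discordant = discordant),
           segments = segments,
           sequences = setNames(seqs, ids),
           truth_junctions = setNames(junctions, ids),
           genome = genome),
      class = "simulated_reads")
  })
}

#' @export
print.simulated_reads <- function(x, ...) {
  cat(sprintf("<simulated_reads> %d reads from %s (%d discordant)\n",
              nrow(x$reads), x$genome$id, sum(x$reads$truth_discordant)))
  invisible(x)
}

# Split the variant interval [start, start+len) into origin segments in
# reference coordinates. Inversions are in-place and length-preserving, so
# variant and reference coordinates coincide outside inverted loci; inside
# an inverted locus [a, b) a variant position p maps to a + b - 1 - p on
# the minus strand. `inv` holds only the loci inverted in THIS variant.
origin_segments <- function(start, len, genome_len, circular, inv) {
  parts <- if (start + len <= genome_len) {
    list(c(start, start + len))
  } else {
    stopifnot(circular)
    list(c(start, genome_len), c(0L, start + len - genome_len))
  }
  out <- list()
  read_pos <- 0L
  for (pi in seq_along(parts)) {
    u <- parts[[pi]][1]; v <- parts[[pi]][2]
    bp <- c(u, v)
    for (k in seq_len(nrow(inv))) {
      a <- inv$start[k]; b <- inv$end[k]
      if (a < v && b > u) bp <- c(bp, max(u, a), min(v, b))
    }
    bp <- sort(unique(bp))
    for (j in seq_len(length(bp) - 1L)) {
      p <- bp[j]; q <- bp[j + 1L]
      k <- which(inv$start <= p & inv$end >= q)
      if (length(k) == 1L) {
        a <- inv$start[k]; b <- inv$end[k]
        seg <- data.frame(read_start = read_pos, read_end = read_pos + (q - p),
                          ref_start = a + b - q, ref_end = a + b - p,
                          strand = "-",
                          origin_adjacent = FALSE)
      } else {
        seg <- data.frame(read_start = read_pos, read_end = read_pos + (q - p),
                          ref_start = p, ref_end = q, strand = "+",
                          origin_adjacent = length(parts) == 2L)
      }
      out[[length(out) + 1L]] <- seg
      read_pos <- read_pos + (q - p)
    }
  }
  do.call(rbind, out)
}

read_sequence_from_segments <- function(refseq, segs) {
  pieces <- character(nrow(segs))
  for (j in seq_len(nrow(segs))) {
    s <- subseq0(refseq, segs$ref_start[j], segs$ref_end[j])
    pieces[j] <- if (segs$strand[j] == "-") revcomp(s) else s
  }
  paste(pieces, collapse = "")
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(runif(n) < rate)
  if (length(hit) == 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

# Truth label for one read: evaluate consecutive surviving origin segments
# for strand discordance or displacement from collinearity. Kept separate
# from the detection module on purpose (the pipeline is checked against
# these labels, so they must not be produced by the code under test).
truth_from_segments <- function(segs, genome_len, circular,
                                min_seg_len, min_shift) {
  keep <- (segs$read_end - segs$read_start) > min_seg_len
  s <- segs[keep, , drop = FALSE]
  junctions <- integer(0)
  disc <- FALSE
  if (nrow(s) >= 2) {
    for (j in seq_len(nrow(s) - 1L)) {
      a <- s[j, ]; b <- s[j + 1L, ]
      fa <- if (a$strand == "+") a$ref_end else a$ref_start
      fb <- if (b$strand == "+") b$ref_start else b$ref_end
      if (a$strand != b$strand) {
        disc <- TRUE
        junctions <- c(junctions, fa, fb)
      } else {
        d <- if (a$strand == "+") fb - fa else fa - fb
        if (circular) d <- circ_signed_min(d, genome_len)
        read_gap <- b$read_start - a$read_end
        if (abs(d - read_gap) > min_shift) {
          disc <- TRUE
          junctions <- c(junctions, fa, fb)
        }
      }
    }
  }
  list(discordant = disc, junctions = unique(junctions))
}

#' Emit exact oracle alignments for simulated reads
#'
#' One local alignment per origin segment, with 100% identity and e-value
#' 0: the alignment structure an exact aligner would report for error-free
#' reads. Stands in for the external aligner so the whole detection
#' pipeline can be exercised without one.
#'
#' @param reads A [simulate_reads()] result.
#' @param genome The [reference_genome()] the reads were simulated from.
#' @return Alignment data.frame with columns `read_id`, `read_len`,
#'   `read_start`, `read_end`, `ref_start`, `ref_end`, `strand`,
#'   `identity_pct`, `evalue`, `aln_len` (coordinates 0-based half-open).
#' @export
emit_truth_alignments <- function(reads, genome = reads$genome) {
  stopifnot(inherits(reads, "simulated_reads"))
  if (!identical(genome$id, reads$genome$id))
    stopf("reads were simulated against %s, not %s", reads$genome$id,
          genome$id)
  segs <- reads$segments
  read_len <- setNames(reads$reads$length, reads$reads$read_id)
  data.frame(read_id = segs$read_id,
             read_len = as.integer(read_len[segs$read_id]),
             read_start = segs$read_start, read_end = segs$read_end,
             ref_start = segs$ref_start, ref_end = segs$ref_end,
             strand = segs$strand,
             identity_pct = 100,
             evalue = 0,
             aln_len = segs$read_end - segs$read_start,
             row.names = NULL)
}

#' Write simulated reads as FASTA or FASTQ
#'
#' FASTQ qualities are constant Q40 (the simulator has no error model to
#' encode).
#'
#' @param reads A [simulate_reads()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  stopifnot(inherits(reads, "simulated_reads"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reads$sequences), path)
  invisible(path)
}

#' @rdname write_reads_fasta
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "simulated_reads"))
  ids <- names(reads$sequences)
  qual <- vapply(nchar(reads$sequences),
                 function(n) paste(rep("I", n), collapse = ""), character(1))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads$sequences),
                           "+", unname(qual)))
  writeLines(lines, path)
  invisible(path)
}

#' Write the simulation truth sidecar as JSON
#'
#' Per-read discordance labels and per-locus realized inversion counts, for
#' downstream benchmarking against pipeline output.
#'
#' @param reads A [simulate_reads()] result.
#' @param population The [build_population()] the reads came from.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(reads, population, path) {
  stopifnot(inherits(reads, "simulated_reads"),
            inherits(population, "genome_population"))
  obj <- list(
    genome = list(id = reads$genome$id, length = reads$genome$length,
                  circular = reads$genome$circular),
    n_variants = nrow(population$orientations),
    loci = cbind(population$loci,
                 realized_inverted = as.integer(population$realized_counts)),
    reads = reads$reads[, c("read_id", "length", "truth_discordant")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
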