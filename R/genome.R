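#' Reference genome container
#'
#' A minimal container for the coordinate system every other computation
#' lives in: one sequence plus a circularity flag. All coordinates in this
#' package are 0-based half-open on the forward strand of this sequence.
#'
#' @param id Sequence identifier (used as the seqname in all outputs).
#' @param sequence Character scalar over A/C/G/T (upper case).
#' @param circular Is the replicon circular?
#' @return An object of class `reference_genome` with fields `id`,
#'   `sequence`, `circular` and `length`.
#' @examples
#' g <- reference_genome("toy", "ACGTACGT", circular = TRUE)
#' g$length
#' @export
reference_genome <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L, is.logical(circular))
  if (grepl("[^ACGT]", sequence))
    stopf("reference_genome: sequence contains characters outside A/C/G/T")
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         length = nchar(sequence)),
    class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Extract [lo, hi) (0-based half-open) from a genome sequence.
subseq0 <- function(seq, lo, hi) substr(seq, lo + 1L, hi)

#' Simulate a genome with invertible loci
#'
#' Draws an i.i.d. random sequence at a target G+C fraction and places
#' `n_loci` non-overlapping invertible loci, each longer than 200 bp (so
#' inversions survive the segment-length filter) and separated from its
#' neighbours and the origin by at least one hotspot window (1000 bp), so
#' that each locus maps to its own window(s) in downstream hotspot calls.
#'
#' @param length Genome length in bp.
#' @param gc Target G+C fraction in (0, 1).
#' @param n_loci Number of invertible loci to place.
#' @param locus_len_range Length-2 integer vector, inclusive range of locus
#'   lengths in bp; minimum must exceed 200.
#' @param inverted_fraction Fraction of the cell population carrying each
#'   locus inverted; recycled to `n_loci`.
#' @param circular Simulate a circular replicon?
#' @param seed Integer seed; fixed seed gives identical output.
#' @param min_separation Minimum bp between placed loci (and from both
#'   genome ends). Default one hotspot window.
#' @return List with `genome` (a [reference_genome()]) and `loci`, a
#'   data.frame with columns `locus_id`, `start`, `end` (0-based half-open)
#'   and `inverted_fraction`.
#' @examples
#' sim <- simulate_genome(50000, gc = 0.43, n_loci = 2,
#'                        locus_len_range = c(500, 1500), seed = 1)
#' sim$loci
#' @export
simulate_genome <- function(length, gc = 0.43, n_loci = 3,
                            locus_len_range = c(500, 2000),
                            inverted_fraction = 0.3,
                            circular = TRUE, seed = NULL,
                            min_separation = 1000L) {
  stopifnot(length >= 1, gc > 0, gc < 1, n_loci >= 0,
            length(locus_len_range) == 2L,
            locus_len_range[1] <= locus_len_range[2])
  if (n_loci > 0 && locus_len_range[1] <= 200)
    stopf("locus_len_range minimum must exceed 200 bp (segment-length filter)")
  if (length < 10 * max(locus_len_range))
    stopf("genome length %d too short for loci up to %d bp", length,
          max(locus_len_range))
  inverted_fraction <- rep_len(inverted_fraction, max(n_loci, 1L))
  stopifnot(all(inverted_fraction >= 0), all(inverted_fraction <= 1))

  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    sequence <- paste(bases, collapse = "")
    loci <- place_loci(length, n_loci, locus_len_range, min_separation)
    loci$inverted_fraction <- if (n_loci > 0) inverted_fraction[seq_len(n_loci)] else numeric(0)
    list(genome = reference_genome("sim_chromosome", sequence, circular),
         loci = loci)
  })
}

# Rejection-sample non-overlapping locus placements separated by >= min_sep
# from each other and from the sequence ends (loci never span the origin).
place_loci <- function(genome_len, n_loci, len_range, min_sep,
                       max_tries = 10000L) {
  empty <- data.frame(locus_id = character(0), start = integer(0),
                      end = integer(0))
  if (n_loci == 0) return(empty)
  placed_start <- integer(0)
  placed_end <- integer(0)
  cand <- seq(len_range[1], len_range[2])
  lens <- cand[sample.int(length(cand), n_loci, replace = TRUE)]
  for (i in seq_len(n_loci)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      start <- sample.int(genome_len - lens[i] - 2L * min_sep, 1L) + min_sep
      end <- start + lens[i]
      if (all(start - placed_end >= min_sep | placed_start - end >= min_sep)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stopf("could not place locus %d of %d without overlap (genome %d bp, min separation %d bp)",
            i, n_loci, genome_len, min_sep)
    placed_start <- c(placed_start, start)
    placed_end <- c(placed_end, end)
  }
  ord <- order(placed_start)
  data.frame(locus_id = sprintf("locus_%02d", seq_len(n_loci)),
             start = as.integer(placed_start[ord]),
             end = as.integer(placed_end[ord]))
}

#' Write a genome to FASTA
#'
#' @param genome A [reference_genome()].
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  dna <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$id))
  Biostrings::writeXStringSet(dna, path, width = width)
  invisible(path)
}

#' Read the first sequence of a FASTA file as a reference genome
#'
#' @param path FASTA path (plain or gzipped).
#' @param circular Circularity flag to attach (FASTA does not carry one).
#' @return A [reference_genome()].
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0) stopf("no sequences in %s", path)
  id <- sub("\\s.*$", "", names(dna)[1])
  reference_genome(id, as.character(dna[[1]]), circular = circular)
}

#' Write truth loci as BED
#'
#' 0-based half-open BED4 with the inverted fraction in the score column.
#'
#' @param loci Locus data.frame from [simulate_genome()].
#' @param genome The [reference_genome()] the loci live on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, genome, path) {
  df <- data.frame(chrom = rep(genome$id, nrow(loci)),
                   start = loci$start, end = loci$end,
                   name = loci$locus_id,
                   score = loci$inverted_fraction)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
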