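#' Build a phase-variable population of genome variants
#'
#' Each variant equals the reference except that each invertible locus is
#' independently reverse-complemented in place with probability
#' `inverted_fraction`. Variants are stored as orientation flags against
#' the shared reference (inversions are length-preserving, so variant and
#' reference coordinates coincide); [variant_sequence()] materializes a
#' full sequence on demand.
#'
#' @param genome A [reference_genome()].
#' @param loci Locus data.frame (`start`, `end`, `inverted_fraction`), as
#'   from [simulate_genome()].
#' @param n_variants Number of cells/genome variants to draw.
#' @param seed Integer seed.
#' @return Object of class `genome_population`: list with `genome`, `loci`,
#'   `orientations` (n_variants x n_loci logical matrix; TRUE = inverted)
#'   and `realized_counts` (per-locus number of inverted variants).
#' @examples
#' sim <- simulate_genome(50000, n_loci = 2, locus_len_range = c(500, 1000),
#'                        inverted_fraction = 0.5, seed = 1)
#' pop <- build_population(sim$genome, sim$loci, n_variants = 20, seed = 2)
#' pop$realized_counts
#' @export
build_population <- function(genome, loci, n_variants, seed = NULL) {
  stopifnot(inherits(genome, "reference_genome"), n_variants >= 1)
  validate_loci(loci, genome)
  n_loci <- nrow(loci)
  orientations <- with_seed(seed, {
    matrix(runif(n_variants * n_loci) < rep(loci$inverted_fraction,
                                            each = n_variants),
           nrow = n_variants, ncol = n_loci)
  })
  if (n_loci > 0) colnames(orientations) <- loci$locus_id
  structure(
    list(genome = genome, loci = loci, orientations = orientations,
         realized_counts = setNames(as.integer(colSums(orientations)),
                                    loci$locus_id)),
    class = "genome_population")
}

validate_loci <- function(loci, genome) {
  stopifnot(is.data.frame(loci),
            all(c("start", "end") %in% names(loci)))
  if (nrow(loci) == 0) return(invisible(loci))
  if (any(loci$start < 0) || any(loci$end > genome$length) ||
      any(loci$start >= loci$end))
    stopf("invalid locus coordinates for genome of length %d", genome$length)
  o <- order(loci$start)
  if (any(loci$start[o][-1] < loci$end[o][-length(o)]))
    stopf("invertible loci must be pairwise non-overlapping")
  invisible(loci)
}

#' @export
print.genome_population <- function(x, ...) {
  cat(sprintf("<genome_population> %d variants of %s (%d invertible loci)\n",
              nrow(x$orientations), x$genome$id, nrow(x$loci)))
  invisible(x)
}

#' Materialize the full sequence of one population variant
#'
#' @param population A [build_population()] result.
#' @param i Variant index.
#' @return Character scalar: the variant's genome sequence.
#' @export
variant_sequence <- function(population, i) {
  stopifnot(inherits(population, "genome_population"),
            i >= 1, i <= nrow(population$orientations))
  seq <- population$genome$sequence
  loci <- population$loci
  for (k in seq_len(nrow(loci))) {
    if (population$orientations[i, k]) {
      lo <- loci$start[k]; hi <- loci$end[k]
      substr(seq, lo + 1L, hi) <- revcomp(subseq0(seq, lo, hi))
    }
  }
  seq
}
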