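#' G+C content of a sequence
#'
#' 100 * (G + C) / (A + C + G + T), case-insensitive; IUPAC ambiguity
#' codes are excluded from numerator and denominator.
#'
#' @param seq Character scalar, a [reference_genome()] or a
#'   `Biostrings::DNAString`.
#' @return G+C content as a percentage (mol%).
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(seq) {
  dna <- as_dnastring(seq)
  if (length(dna) == 0) stopf("gc_content: empty sequence")
  f <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T"))
  denom <- sum(f)
  if (denom == 0) stopf("gc_content: no unambiguous bases")
  as.numeric(100 * (f[["G"]] + f[["C"]]) / denom)
}

as_dnastring <- function(seq) {
  if (inherits(seq, "reference_genome")) seq <- seq$sequence
  if (is.character(seq)) {
    stopifnot(length(seq) == 1L)
    return(Biostrings::DNAString(toupper(seq)))
  }
  if (inherits(seq, "DNAString")) return(seq)
  stopf("unsupported sequence type: %s", class(seq)[1])
}

new_track <- function(kind, window, values, genome_len) {
  structure(list(kind = kind, window = as.integer(window),
                 values = unname(values),
                 genome_len = as.integer(genome_len)),
            class = "genome_track")
}

#' @export
print.genome_track <- function(x, ...) {
  cat(sprintf("<genome_track> %s: %d windows of %d bp\n", x$kind,
              length(x$values), x$window))
  invisible(x)
}

#' @export
as.data.frame.genome_track <- function(x, ...) {
  n <- length(x$values)
  start <- (seq_len(n) - 1L) * x$window
  data.frame(start = start, end = pmin(start + x$window, x$genome_len),
             value = x$values)
}

window_views <- function(dna, window) {
  n <- length(dna)
  starts <- seq(1L, n, by = window)
  Biostrings::Views(dna, start = starts, end = pmin(starts + window - 1L, n))
}

#' Windowed G+C content track
#'
#' @param seq Sequence (see [gc_content()]).
#' @param window Window size in bp.
#' @return A `genome_track` of per-window G+C percentages.
#' @export
gc_content_track <- function(seq, window = 1000L) {
  dna <- as_dnastring(seq)
  v <- window_views(dna, window)
  f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  vals <- ifelse(denom == 0, 0, 100 * (f[, "G"] + f[, "C"]) / denom)
  new_track("gc_content", window, vals, length(dna))
}

#' Windowed GC skew track
#'
#' (G - C) / (G + C) per window; windows without G or C are 0 by
#' convention. Sign changes along a bacterial chromosome typically mark
#' the replication origin and terminus.
#'
#' @param seq Sequence (see [gc_content()]).
#' @param window Window size in bp.
#' @return A `genome_track` of per-window skew values in [-1, 1].
#' @examples
#' gc_skew("GGGGCCCC", window = 4)$values
#' @export
gc_skew <- function(seq, window = 1000L) {
  dna <- as_dnastring(seq)
  v <- window_views(dna, window)
  f <- Biostrings::letterFrequency(v, c("G", "C"))
  denom <- f[, "G"] + f[, "C"]
  vals <- ifelse(denom == 0, 0, (f[, "G"] - f[, "C"]) / denom)
  new_track("gc_skew", window, vals, length(dna))
}

#' Windowed alignment coverage track
#'
#' Mean per-base depth per window from the reference intervals of
#' (typically post-filter) alignments. Intervals are taken as given;
#' origin-spanning alignments should already be split at the origin, as
#' both the simulator and the supported input formats do.
#'
#' @param alns Alignment data.frame (`ref_start`, `ref_end`).
#' @param genome_len Reference length in bp.
#' @param window Window size in bp.
#' @return A `genome_track` of mean depths.
#' @export
coverage_track <- function(alns, genome_len, window = 1000L) {
  n_win <- ceiling(genome_len / window)
  if (nrow(alns) == 0)
    return(new_track("coverage", window, numeric(n_win), genome_len))
  if (any(alns$ref_end > genome_len))
    stopf("alignment reference interval exceeds genome length %d", genome_len)
  cov <- IRanges::coverage(IRanges::IRanges(start = alns$ref_start + 1L,
                                            end = alns$ref_end),
                           width = genome_len)
  starts <- seq(1L, genome_len, by = window)
  means <- IRanges::viewMeans(
    IRanges::Views(cov, start = starts,
                   end = pmin(starts + window - 1L, genome_len)))
  new_track("coverage", window, as.numeric(means), genome_len)
}

#' Write a genome track as bedGraph
#'
#' @param track A `genome_track`.
#' @param genome A [reference_genome()] (seqname).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, genome, path) {
  write_bedgraph(track$values, genome, track$window, path)
}
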