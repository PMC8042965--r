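#' Hotspot-calling parameters
#'
#' Published defaults: non-overlapping 1000-bp windows anchored at
#' coordinate 0, a hotspot needs strictly more than 8 distinct discordant
#' reads in a window, and a coordinate shift must exceed 200 bp to count
#' as a recombination event.
#'
#' @param window Window size in bp.
#' @param min_reads Distinct-discordant-read threshold (exclusive): a
#'   window is a hotspot iff its count is strictly greater.
#' @param min_shift Shift-magnitude threshold in bp (exclusive).
#' @param min_inversion_len Optional minimum inverted-segment length (bp,
#'   exclusive) for an inversion junction to count as an event. Default 0:
#'   inversions are events whenever both flanking segments survive the
#'   segment-length filter, reading the published >200 nt threshold as a
#'   shift-displacement gate (the alternative reading is available by
#'   raising this).
#' @param max_junction_span Junction intervals wider than
#'   `max_junction_span * window` bp are truncated to their two flanking
#'   window-sized ends before window counting, so a single
#'   translocation-like jump cannot paint half the genome. Heuristic;
#'   set to `Inf` to disable.
#' @return A `hotspot_params` list.
#' @export
hotspot_params <- function(window = 1000L, min_reads = 8L, min_shift = 200L,
                           min_inversion_len = 0L, max_junction_span = 10) {
  stopifnot(window >= 1, min_reads >= 0, min_shift >= 0,
            min_inversion_len >= 0, max_junction_span > 0)
  structure(list(window = as.integer(window), min_reads = min_reads,
                 min_shift = min_shift,
                 min_inversion_len = min_inversion_len,
                 max_junction_span = max_junction_span),
            class = "hotspot_params")
}

empty_events <- function() {
  data.frame(read_id = character(0), junction = integer(0),
             kind = character(0), magnitude = numeric(0),
             lo = integer(0), hi = integer(0))
}

#' Classify the junction between two consecutive segments of one read
#'
#' A strand flip between consecutive segments is an inversion event. For
#' same-strand segments the shift is the displacement from collinearity:
#' the signed reference gap between the two segments' facing ends, taken
#' in the strand's direction of travel (reversed for minus-strand pairs)
#' minus the read gap. On a circular genome the reference gap uses the arc
#' direction with the smaller absolute displacement. A shift is an event
#' iff its magnitude strictly exceeds `p$min_shift`.
#'
#' The junction is localized to the reference span between the two facing
#' ends (0-based half-open, normalized lo <= hi); when the minimal arc
#' wraps the origin the span is split into two intervals, hence the
#' returned data.frame can have two rows for one event.
#'
#' @param a,b Single-row segment data.frames, consecutive in read order
#'   (`a$read_start <= b$read_start`).
#' @param genome_len Reference length in bp.
#' @param circular Is the reference circular?
#' @param p A [hotspot_params()].
#' @return `NULL` (no event) or a data.frame with columns `kind`
#'   (`"inversion"`/`"shift"`), `magnitude` (bp), `lo`, `hi` — one row per
#'   junction interval piece.
#' @export
classify_junction <- function(a, b, genome_len, circular = TRUE,
                              p = hotspot_params()) {
  if (!identical(a$read_id, b$read_id))
    stopf("classify_junction: segments belong to different reads (%s vs %s)",
          a$read_id, b$read_id)
  fa <- if (a$strand == "+") a$ref_end else a$ref_start
  fb <- if (b$strand == "+") b$ref_start else b$ref_end
  if (a$strand != b$strand) {
    magnitude <- min(a$ref_end - a$ref_start, b$ref_end - b$ref_start)
    if (magnitude <= p$min_inversion_len) return(NULL)
    iv <- junction_interval(fa, fb, genome_len, circular)
    return(cbind(data.frame(kind = "inversion", magnitude = magnitude),
                 iv))
  }
  read_gap <- b$read_start - a$read_end
  d <- if (a$strand == "+") fb - fa else fa - fb
  if (circular) d <- circ_signed_min(d, genome_len)
  magnitude <- abs(d - read_gap)
  if (magnitude <= p$min_shift) return(NULL)
  iv <- junction_interval(fa, fb, genome_len, circular)
  cbind(data.frame(kind = "shift", magnitude = magnitude), iv)
}

# Reference span between two facing endpoints along the minimal arc,
# normalized to 0-based half-open rows; wraps split at the origin. A
# zero-width junction (abutting endpoints) is widened to 1 bp so it still
# lands in a window.
junction_interval <- function(fa, fb, genome_len, circular) {
  lo <- min(fa, fb); hi <- max(fa, fb)
  direct <- hi - lo
  if (circular && (genome_len - direct) < direct) {
    # minimal arc crosses the origin
    rows <- data.frame(lo = c(hi, 0L), hi = c(genome_len, lo))
    rows <- rows[rows$hi > rows$lo, , drop = FALSE]
    if (nrow(rows) == 0) rows <- data.frame(lo = 0L, hi = 1L)
    rownames(rows) <- NULL
    return(rows)
  }
  if (hi == lo) {
    lo <- max(0L, min(lo, genome_len - 1L))
    hi <- lo + 1L
  }
  data.frame(lo = lo, hi = hi)
}

#' Detect recombination events along one read chain
#'
#' Evaluates every consecutive segment pair of the chain with
#' [classify_junction()]; an n-segment chain yields at most n-1 events,
#' and a read is "inconsistent" iff it has at least one.
#'
#' @param chain One read's ordered segment data.frame (an element of
#'   [build_chains()] output).
#' @inheritParams classify_junction
#' @return Event data.frame (`read_id`, `junction`, `kind`, `magnitude`,
#'   `lo`, `hi`), possibly empty; one row per junction interval piece.
#' @export
detect_events <- function(chain, genome_len, circular = TRUE,
                          p = hotspot_params()) {
  n <- nrow(chain)
  if (n < 2) return(empty_events())
  out <- vector("list", n - 1L)
  for (j in seq_len(n - 1L)) {
    ev <- classify_junction(chain[j, ], chain[j + 1L, ], genome_len,
                            circular, p)
    if (!is.null(ev))
      out[[j]] <- cbind(data.frame(read_id = chain$read_id[1],
                                   junction = j),
                        ev)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_events())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect events for every chain
#'
#' @param chains A [build_chains()] result.
#' @inheritParams classify_junction
#' @return One event data.frame over all reads.
#' @export
detect_events_all <- function(chains, genome_len, circular = TRUE,
                              p = hotspot_params()) {
  evs <- lapply(chains, detect_events, genome_len = genome_len,
                circular = circular, p = p)
  evs <- evs[vapply(evs, nrow, integer(1)) > 0]
  if (length(evs) == 0) return(empty_events())
  res <- do.call(rbind, evs)
  rownames(res) <- NULL
  res
}

# Distinct discordant reads per fixed window. A read is counted once in
# every window any of its (possibly truncated) junction intervals
# overlaps, regardless of how many of its events fall there.
window_read_counts <- function(events, genome_len, p) {
  n_win <- as.integer(ceiling(genome_len / p$window))
  counts <- integer(n_win)
  if (nrow(events) == 0) return(counts)
  iv <- truncate_junctions(events, p)
  win_start <- (seq_len(n_win) - 1L) * p$window
  win_end <- pmin(win_start + p$window, genome_len)
  hits <- GenomicRanges::findOverlaps(
    IRanges::IRanges(start = iv$lo + 1L, end = pmax(iv$hi, iv$lo + 1L)),
    IRanges::IRanges(start = win_start + 1L, end = win_end))
  if (length(hits) == 0) return(counts)
  df <- unique(data.frame(read = iv$read_id[S4Vectors::queryHits(hits)],
                          win = S4Vectors::subjectHits(hits)))
  tab <- table(df$win)
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

truncate_junctions <- function(events, p) {
  span_cap <- p$max_junction_span * p$window
  wide <- which((events$hi - events$lo) > span_cap)
  if (length(wide) == 0) return(events)
  keep <- events[-wide, c("read_id", "lo", "hi")]
  w <- events[wide, ]
  flanks <- data.frame(
    read_id = rep(w$read_id, 2L),
    lo = c(w$lo, w$hi - p$window),
    hi = c(w$lo + p$window, w$hi))
  rbind(keep, flanks)
}

#' Call windowed recombination hotspots
#'
#' Partitions the reference into consecutive non-overlapping windows
#' anchored at coordinate 0 (the last window may be short) and reports
#' every window whose distinct-discordant-read count strictly exceeds
#' `p$min_reads`.
#'
#' @param events Event data.frame from [detect_events_all()].
#' @param genome_len Reference length in bp.
#' @param p A [hotspot_params()].
#' @return Hotspot data.frame sorted by window: `window_index` (0-based),
#'   `start`, `end` (0-based half-open), `n_reads` and `read_ids`
#'   (comma-separated supporting reads).
#' @export
call_hotspots <- function(events, genome_len, p = hotspot_params()) {
  counts <- window_read_counts(events, genome_len, p)
  idx <- which(counts > p$min_reads)
  ids <- character(length(idx))
  if (length(idx) > 0 && nrow(events) > 0) {
    iv <- truncate_junctions(events, p)
    for (k in seq_along(idx)) {
      w0 <- (idx[k] - 1L) * p$window
      w1 <- min(w0 + p$window, genome_len)
      touch <- iv$lo < w1 & pmax(iv$hi, iv$lo + 1L) > w0
      ids[k] <- paste(sort(unique(iv$read_id[touch])), collapse = ",")
    }
  }
  data.frame(window_index = idx - 1L,
             start = (idx - 1L) * p$window,
             end = pmin(idx * p$window, genome_len),
             n_reads = counts[idx],
             read_ids = ids)
}

#' Per-window discordant-read histogram
#'
#' The dense per-window counterpart of [call_hotspots()]: the number of
#' distinct discordant reads whose junction intervals touch each window.
#' Because one read can touch several windows, the histogram total can
#' exceed the number of discordant reads.
#'
#' @inheritParams call_hotspots
#' @return Integer vector of length `ceiling(genome_len / p$window)`.
#' @export
hotspot_histogram <- function(events, genome_len, p = hotspot_params()) {
  window_read_counts(events, genome_len, p)
}

#' Write events as TSV
#'
#' @param events Event data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write hotspots as BED6
#'
#' Score column carries the discordant read count.
#'
#' @param hotspots [call_hotspots()] output.
#' @param genome A [reference_genome()] (seqname).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotspots_bed <- function(hotspots, genome, path) {
  df <- data.frame(chrom = rep(genome$id, nrow(hotspots)),
                   start = hotspots$start, end = hotspots$end,
                   name = sprintf("hotspot_%d", hotspots$window_index),
                   score = hotspots$n_reads,
                   strand = rep(".", nrow(hotspots)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a hotspot BED file back into a hotspot table
#'
#' @param path BED path (>= 3 columns; score column, when present, is the
#'   discordant read count).
#' @param window Window size the BED was produced with.
#' @return Hotspot data.frame (without supporting read ids).
#' @export
read_hotspots_bed <- function(path, window = 1000L) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), window_index = integer(0),
                      start = integer(0), end = integer(0),
                      n_reads = integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(f, `[[`, character(1), 1),
             window_index = as.integer(
               as.numeric(vapply(f, `[[`, character(1), 2)) %/% window),
             start = as.integer(as.numeric(vapply(f, `[[`, character(1), 2))),
             end = as.integer(as.numeric(vapply(f, `[[`, character(1), 3))),
             n_reads = vapply(f, function(x)
               if (length(x) >= 5) as.integer(as.numeric(x[5])) else NA_integer_,
               integer(1)))
}

#' Write a per-window vector as bedGraph
#'
#' @param values Numeric vector, one value per window.
#' @param genome A [reference_genome()].
#' @param window Window size in bp.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(values, genome, window, path) {
  n <- length(values)
  start <- (seq_len(n) - 1L) * window
  end <- pmin(start + window, genome$length)
  df <- data.frame(rep(genome$id, n), start, end, values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
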