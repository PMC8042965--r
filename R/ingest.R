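#' Alignment filter thresholds
#'
#' The published read- and segment-level filters, all strict inequalities:
#' reads longer than 1000 nt; segments above 90% identity, below e-value
#' 1e-20 (when an e-value is present) and longer than 200 nt.
#'
#' @param min_read_len Keep a segment only if its read is longer than this
#'   (bp, exclusive).
#' @param min_identity_pct Keep segments with identity strictly above this.
#' @param max_evalue Keep segments with e-value strictly below this;
#'   segments without an e-value (PAF) pass.
#' @param min_aln_len Keep segments strictly longer than this (bp).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_read_len = 1000, min_identity_pct = 90,
                              max_evalue = 1e-20, min_aln_len = 200) {
  stopifnot(min_read_len > 0, min_identity_pct > 0, max_evalue > 0,
            min_aln_len > 0)
  structure(list(min_read_len = min_read_len,
                 min_identity_pct = min_identity_pct,
                 max_evalue = max_evalue,
                 min_aln_len = min_aln_len),
            class = "filter_thresholds")
}

#' Filter local alignments
#'
#' Applies [filter_thresholds()] to an alignment table. The read-length
#' test removes every segment of a short read (it is a read-level
#' exclusion); the other three act per segment. Row order is preserved.
#'
#' @param alns Alignment data.frame.
#' @param thresholds A [filter_thresholds()].
#' @return The surviving rows, in their original order.
#' @export
filter_alignments <- function(alns, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (nrow(alns) == 0) return(alns)
  keep <- alns$read_len > thresholds$min_read_len &
    alns$identity_pct > thresholds$min_identity_pct &
    alns$aln_len > thresholds$min_aln_len &
    (is.na(alns$evalue) | alns$evalue < thresholds$max_evalue)
  out <- alns[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble per-read alignment chains
#'
#' Groups filtered segments by read, drops any segment whose read interval
#' is fully contained in another segment of the same read (ties between
#' identical intervals are broken by larger identity x length, then by
#' smaller reference start), and orders survivors by read start. Partial
#' overlaps on the read are retained: inversion junctions commonly produce
#' small overlaps, and overlap alone never generates an event.
#'
#' @param alns Filtered alignment data.frame.
#' @return A list of class `read_chains`; each element is one read's
#'   segment data.frame ordered by `read_start`, named by `read_id`.
#' @export
build_chains <- function(alns) {
  if (nrow(alns) == 0)
    return(structure(list(), class = "read_chains"))
  chains <- lapply(split(alns, alns$read_id), function(g) {
    g <- prune_contained(g)
    g <- g[order(g$read_start, g$ref_start), , drop = FALSE]
    rownames(g) <- NULL
    g
  })
  structure(chains, class = "read_chains")
}

# Drop read-interval-contained segments. A segment is dropped when another
# segment of the same read strictly contains its read interval; identical
# intervals keep only the tie-break winner (larger identity_pct * aln_len,
# then smaller ref_start, then input order). Maximal intervals always
# survive, so containment chains resolve to their outermost segment.
prune_contained <- function(g) {
  n <- nrow(g)
  if (n <= 1) return(g)
  score <- g$identity_pct * g$aln_len
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (!(g$read_start[j] <= g$read_start[i] &&
            g$read_end[i] <= g$read_end[j])) next
      identical_iv <- g$read_start[j] == g$read_start[i] &&
        g$read_end[j] == g$read_end[i]
      if (!identical_iv ||
          score[j] > score[i] ||
          (score[j] == score[i] && g$ref_start[j] < g$ref_start[i]) ||
          (score[j] == score[i] && g$ref_start[j] == g$ref_start[i] && j < i)) {
        drop[i] <- TRUE
        break
      }
    }
  }
  g[!drop, , drop = FALSE]
}

#' @export
print.read_chains <- function(x, ...) {
  ns <- vapply(x, nrow, integer(1))
  cat(sprintf("<read_chains> %d reads (%d with >1 segment)\n",
              length(x), sum(ns > 1)))
  invisible(x)
}
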