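#' Run the full hotspot-detection pipeline on an alignment table
#'
#' Convenience wrapper: filter alignments, build chains, detect events,
#' and call windowed hotspots in one step with the published defaults.
#'
#' @param alns Alignment data.frame (from [read_paf()],
#'   [read_blast_tab()] or [emit_truth_alignments()]).
#' @param genome_len Reference length in bp.
#' @param circular Is the reference circular?
#' @param thresholds A [filter_thresholds()].
#' @param params A [hotspot_params()].
#' @return List of class `hotspot_scan`: `chains`, `events`, `hotspots`,
#'   `histogram` (per-window counts), `discordant_reads` (character
#'   vector) and `summary` (named counts: reads_in, reads_kept,
#'   discordant_reads, events, hotspots).
#' @examples
#' sim <- simulate_genome(50000, n_loci = 1, locus_len_range = c(500, 900),
#'                        inverted_fraction = 0.5, seed = 7)
#' pop <- build_population(sim$genome, sim$loci, n_variants = 30, seed = 7)
#' rd <- simulate_reads(pop, n_reads = 300, seed = 7)
#' scan <- scan_alignments(emit_truth_alignments(rd), sim$genome$length)
#' scan$summary
#' @export
scan_alignments <- function(alns, genome_len, circular = TRUE,
                            thresholds = filter_thresholds(),
                            params = hotspot_params()) {
  reads_in <- length(unique(alns$read_id))
  kept <- filter_alignments(alns, thresholds)
  chains <- build_chains(kept)
  events <- detect_events_all(chains, genome_len, circular, params)
  hotspots <- call_hotspots(events, genome_len, params)
  histogram <- hotspot_histogram(events, genome_len, params)
  discordant <- sort(unique(events$read_id))
  structure(
    list(chains = chains, events = events, hotspots = hotspots,
         histogram = histogram, discordant_reads = discordant,
         summary = c(reads_in = reads_in, reads_kept = length(chains),
                     discordant_reads = length(discordant),
                     events = nrow(events), hotspots = nrow(hotspots))),
    class = "hotspot_scan")
}

#' @export
print.hotspot_scan <- function(x, ...) {
  cat("<hotspot_scan>\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-17s %d\n", nm, x$summary[[nm]]))
  invisible(x)
}

#' Benchmark hotspot calls against simulated truth loci
#'
#' Scores a hotspot set against the simulator's truth: a locus is
#' recovered when at least one hotspot overlaps it, and a hotspot is a
#' true positive when it lies within `slack_windows` windows of a truth
#' locus.
#'
#' @param hotspots [call_hotspots()] output.
#' @param loci Truth locus data.frame (`start`, `end`).
#' @param window Window size in bp.
#' @param slack_windows Allowed distance, in windows, between a hotspot
#'   and the nearest truth locus for the hotspot to count as true.
#' @return List: `recall` (loci recovered / loci), `precision` (true
#'   hotspots / hotspots; 1 when there are no hotspots and no loci),
#'   `loci_recovered`, `n_loci`, `true_hotspots`, `n_hotspots`.
#' @export
benchmark_hotspots <- function(hotspots, loci, window = 1000L,
                               slack_windows = 1L) {
  n_loci <- nrow(loci)
  n_hot <- nrow(hotspots)
  recovered <- 0L
  if (n_loci > 0 && n_hot > 0) {
    for (k in seq_len(n_loci)) {
      if (any(hotspots$start < loci$end[k] & loci$start[k] < hotspots$end))
        recovered <- recovered + 1L
    }
  }
  true_hot <- 0L
  if (n_hot > 0 && n_loci > 0) {
    slack <- slack_windows * window
    for (h in seq_len(n_hot)) {
      gap <- interval_gap(hotspots$start[h], hotspots$end[h],
                          loci$start, loci$end)
      if (any(gap <= slack)) true_hot <- true_hot + 1L
    }
  }
  list(recall = if (n_loci > 0) recovered / n_loci else 1,
       precision = if (n_hot > 0) true_hot / n_hot else 1,
       loci_recovered = recovered, n_loci = n_loci,
       true_hotspots = true_hot, n_hotspots = n_hot)
}
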