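#' Default functional-category keyword table
#'
#' Maps product descriptions to the categories the colocalization scan
#' uses: site-specific recombination machinery (recombinase, integrase,
#' invertase, transposase) and phase-variation-prone surface genes
#' (Sus/TonB nutrient uptake, capsule/LPS biosynthesis). The table ships
#' as an editable YAML file; categories are tried in order and the first
#' matching (case-insensitive) regular expression wins.
#'
#' @param path YAML file mapping category names to character vectors of
#'   regular expressions. Defaults to the table shipped with the package.
#' @return Named list of character vectors, in match-priority order.
#' @export
feature_categories <- function(path = system.file("extdata",
                                                  "feature_categories.yaml",
                                                  package = "invertonscan")) {
  tab <- yaml::read_yaml(path)
  stopifnot(is.list(tab), length(tab) > 0, !is.null(names(tab)))
  lapply(tab, as.character)
}

anchor_categories <- c("recombinase", "integrase", "invertase")
target_categories <- c("sus_tonB", "capsule_lps")

#' Assign a functional category to product descriptions
#'
#' @param product Character vector of product/Name strings.
#' @param categories Keyword table from [feature_categories()].
#' @return Character vector of category names; unmatched products get
#'   `"other"`.
#' @export
categorize_product <- function(product, categories = feature_categories()) {
  out <- rep("other", length(product))
  product[is.na(product)] <- ""
  for (cat in rev(names(categories))) {
    pattern <- paste(categories[[cat]], collapse = "|")
    hit <- grepl(pattern, product, ignore.case = TRUE, perl = TRUE)
    out[hit] <- cat
  }
  out
}

#' Parse gene features from GFF3
#'
#' Reads a GFF3 file through `rtracklayer`, keeps gene/CDS features,
#' converts the 1-based inclusive coordinates to the package's 0-based
#' half-open convention, and assigns functional categories from the
#' product (falling back to Name/gene) attributes.
#'
#' @param path GFF3 path.
#' @param categories Keyword table ([feature_categories()]).
#' @param types Feature types to keep.
#' @return data.frame: `feature_id`, `seqname`, `start`, `end` (0-based
#'   half-open), `strand`, `category`, `product`.
#' @export
parse_gff <- function(path, categories = feature_categories(),
                      types = c("gene", "CDS")) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stopf("malformed GFF3 in %s: %s", path, conditionMessage(e)))
  gr <- gr[as.character(gr$type) %in% types]
  mc <- S4Vectors::mcols(gr)
  pick <- function(nm) if (nm %in% names(mc)) as.character(mc[[nm]]) else
    rep(NA_character_, length(gr))
  product <- pick("product")
  alt <- pick("Name")
  product <- ifelse(is.na(product) | product == "", alt, product)
  id <- pick("ID")
  id <- ifelse(is.na(id) | id == "", pick("locus_tag"), id)
  id <- ifelse(is.na(id) | id == "",
               sprintf("feature_%06d", seq_along(gr)), id)
  df <- data.frame(feature_id = id,
                   seqname = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   product = ifelse(is.na(product), "", product))
  df$category <- categorize_product(df$product, categories)
  df
}

#' Relate hotspots to annotated features
#'
#' For each hotspot, reports every feature overlapping its interval
#' (relation `overlap`, distance 0) and every disjoint feature whose gap
#' to the hotspot is at most `flank` bp (relation `within_flank`).
#' Rows are ordered by (hotspot start, distance, feature_id).
#'
#' @param hotspots Hotspot data.frame (`start`, `end`; e.g.
#'   [call_hotspots()] or [read_hotspots_bed()] output).
#' @param features Feature data.frame from [parse_gff()].
#' @param flank Maximum gap in bp for proximity reporting.
#' @return data.frame: hotspot interval, feature columns, `relation`,
#'   `distance`.
#' @export
hotspot_overlap_report <- function(hotspots, features, flank = 1000L) {
  stopifnot(flank >= 0)
  empty <- data.frame(hotspot_start = integer(0), hotspot_end = integer(0),
                      feature_id = character(0), category = character(0),
                      product = character(0), relation = character(0),
                      distance = integer(0))
  if (nrow(hotspots) == 0 || nrow(features) == 0) return(empty)
  rows <- list()
  for (h in seq_len(nrow(hotspots))) {
    gap <- interval_gap(hotspots$start[h], hotspots$end[h],
                        features$start, features$end)
    overlap <- features$start < hotspots$end[h] &
      hotspots$start[h] < features$end
    keep <- which(overlap | gap <= flank)
    if (length(keep) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      hotspot_start = hotspots$start[h], hotspot_end = hotspots$end[h],
      feature_id = features$feature_id[keep],
      category = features$category[keep],
      product = features$product[keep],
      relation = ifelse(overlap[keep], "overlap", "within_flank"),
      distance = as.integer(ifelse(overlap[keep], 0L, gap[keep])))
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$hotspot_start, out$distance, out$feature_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for recombinase genes near phase-variable surface genes
#'
#' Pairs every recombination-machinery gene (category recombinase,
#' integrase or invertase) with every surface-structure gene (Sus/TonB or
#' capsule/LPS) whose gap is at most `max_dist` bp, using the minimal arc
#' on circular genomes. Each pair is reported once with its minimal
#' distance (0 when the intervals overlap).
#'
#' @param features Feature data.frame from [parse_gff()].
#' @param max_dist Maximum gap in bp (the paper never quantifies "in
#'   proximity"; 5000 bp is this package's default).
#' @param circular Treat the genome as circular?
#' @param genome_len Genome length (required when `circular`).
#' @return data.frame: anchor/target feature columns and `distance`,
#'   ordered by (distance, anchor, target).
#' @export
colocalization_scan <- function(features, max_dist = 5000L,
                                circular = TRUE, genome_len = NULL) {
  anchors <- features[features$category %in% anchor_categories, ,
                      drop = FALSE]
  targets <- features[features$category %in% target_categories, ,
                      drop = FALSE]
  empty <- data.frame(anchor_id = character(0), anchor_category = character(0),
                      target_id = character(0), target_category = character(0),
                      distance = integer(0))
  if (nrow(anchors) == 0 || nrow(targets) == 0) return(empty)
  if (circular && is.null(genome_len))
    stopf("colocalization_scan: genome_len is required for circular genomes")
  rows <- list()
  for (i in seq_len(nrow(anchors))) {
    d <- if (circular) {
      circ_interval_gap(anchors$start[i], anchors$end[i],
                        targets$start, targets$end, genome_len)
    } else {
      interval_gap(anchors$start[i], anchors$end[i],
                   targets$start, targets$end)
    }
    keep <- which(d <= max_dist)
    if (length(keep) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      anchor_id = anchors$feature_id[i],
      anchor_category = anchors$category[i],
      target_id = targets$feature_id[keep],
      target_category = targets$category[keep],
      distance = as.integer(d[keep]))
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$distance, out$anchor_id, out$target_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
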