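# PAF and BLAST outfmt-6 readers/writers. Internal coordinates are always
# 0-based half-open on the forward reference strand; conversions happen
# only here, at the serialization boundary.

paf_required_cols <- 12L

#' Read local alignments from PAF
#'
#' Parses minimap2-style PAF (>= 12 mandatory columns; extra SAM-like tags
#' are ignored). PAF coordinates are already 0-based half-open on the
#' forward strands of query and target. Percent identity is derived as
#' 100 * residue matches / alignment block length (columns 10-11). PAF
#' carries no e-value, so `evalue` is `NA`; the e-value filter treats
#' absent values as passing (that filter exists to drop spurious BLAST
#' hits, and long-read mappers do their own mapping-quality filtering).
#'
#' @param path Path to a PAF file (plain or gzipped) or a connection.
#' @return Alignment data.frame (see [emit_truth_alignments()] for the
#'   column contract).
#' @export
read_paf <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < paf_required_cols))
    stopf("malformed PAF line %d: %d columns (need >= %d)",
          which(n < paf_required_cols)[1], min(n), paf_required_cols)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(x))
      stopf("malformed PAF line %d: non-numeric %s", which(is.na(x))[1], what)
    x
  }
  strand <- get(5)
  if (!all(strand %in% c("+", "-")))
    stopf("malformed PAF line %d: strand must be + or -",
          which(!strand %in% c("+", "-"))[1])
  aln <- data.frame(read_id = get(1),
                    read_len = as.integer(num(2, "query length")),
                    read_start = as.integer(num(3, "query start")),
                    read_end = as.integer(num(4, "query end")),
                    ref_start = as.integer(num(8, "target start")),
                    ref_end = as.integer(num(9, "target end")),
                    strand = strand,
                    identity_pct = 100 * num(10, "matches") / num(11, "block length"),
                    evalue = NA_real_,
                    aln_len = as.integer(num(11, "block length")))
  bad <- which(aln$read_start < 0 | aln$read_start >= aln$read_end |
                 aln$read_end > aln$read_len |
                 aln$ref_start < 0 | aln$ref_start >= aln$ref_end |
                 aln$aln_len < 1)
  if (length(bad))
    stopf("malformed PAF line %d: negative or inverted coordinates", bad[1])
  aln
}

empty_alignments <- function() {
  data.frame(read_id = character(0), read_len = integer(0),
             read_start = integer(0), read_end = integer(0),
             ref_start = integer(0), ref_end = integer(0),
             strand = character(0), identity_pct = numeric(0),
             evalue = numeric(0), aln_len = integer(0))
}

#' Write local alignments as PAF
#'
#' @param alns Alignment data.frame.
#' @param genome A [reference_genome()] (target name and length).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(alns, genome, path) {
  nmatch <- as.integer(round(alns$aln_len * alns$identity_pct / 100))
  df <- data.frame(alns$read_id, alns$read_len, alns$read_start,
                   alns$read_end, alns$strand, genome$id, genome$length,
                   alns$ref_start, alns$ref_end, nmatch, alns$aln_len,
                   255L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read local alignments from BLAST tabular output
#'
#' Parses 12-column `-outfmt 6` rows (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). BLAST coordinates are
#' 1-based inclusive and the subject-coordinate order encodes strand:
#' `sstart > send` means the query matched the minus strand, and the
#' coordinates are swapped before conversion to 0-based half-open. BLAST
#' rows do not carry the query length, so it must be supplied.
#'
#' @param path Path (plain or gzipped) or connection.
#' @param read_lengths Read lengths: a named numeric vector, a two-column
#'   data.frame/TSV path (read_id, length), or a FASTA path (lengths are
#'   computed).
#' @return Alignment data.frame.
#' @export
read_blast_tab <- function(path, read_lengths) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 12L))
    stopf("malformed BLAST tabular row %d: %d columns (need 12)",
          which(n < 12L)[1], min(n))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(x))
      stopf("malformed BLAST tabular row %d: non-numeric %s",
            which(is.na(x))[1], what)
    x
  }
  lens <- resolve_read_lengths(read_lengths)
  read_id <- get(1)
  missing <- setdiff(unique(read_id), names(lens))
  if (length(missing))
    stopf("no read length supplied for read '%s'", missing[1])
  qstart <- num(7, "qstart"); qend <- num(8, "qend")
  sstart <- num(9, "sstart"); send <- num(10, "send")
  if (any(qstart > qend))
    stopf("malformed BLAST tabular row %d: qstart > qend",
          which(qstart > qend)[1])
  minus <- sstart > send
  data.frame(read_id = read_id,
             read_len = as.integer(lens[read_id]),
             read_start = as.integer(qstart - 1),
             read_end = as.integer(qend),
             ref_start = as.integer(ifelse(minus, send, sstart) - 1),
             ref_end = as.integer(ifelse(minus, sstart, send)),
             strand = ifelse(minus, "-", "+"),
             identity_pct = num(3, "pident"),
             evalue = num(11, "evalue"),
             aln_len = as.integer(num(4, "length")),
             row.names = NULL)
}

resolve_read_lengths <- function(read_lengths) {
  if (is.numeric(read_lengths) && !is.null(names(read_lengths)))
    return(read_lengths)
  if (is.data.frame(read_lengths)) {
    stopifnot(ncol(read_lengths) >= 2)
    return(setNames(as.numeric(read_lengths[[2]]),
                    as.character(read_lengths[[1]])))
  }
  if (is.character(read_lengths) && length(read_lengths) == 1L) {
    if (grepl("\\.(fa|fasta|fna|fa\\.gz|fasta\\.gz|fna\\.gz)$", read_lengths)) {
      w <- Biostrings::fasta.seqlengths(read_lengths)
      names(w) <- sub("\\s.*$", "", names(w))
      return(w)
    }
    df <- read.table(read_lengths, sep = "\t", header = FALSE,
                     col.names = c("read_id", "length"),
                     colClasses = c("character", "numeric"))
    return(setNames(df$length, df$read_id))
  }
  stopf("read_lengths must be a named vector, data.frame, TSV path or FASTA path")
}

#' Write local alignments as 12-column BLAST tabular
#'
#' Inverse of [read_blast_tab()]: coordinates go back to 1-based inclusive
#' and minus-strand hits get swapped subject coordinates. Mismatch and gap
#' columns are derived from identity assuming gapless segments; bitscore
#' is a nominal 2 bits per aligned base.
#'
#' @param alns Alignment data.frame.
#' @param genome A [reference_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(alns, genome, path) {
  minus <- alns$strand == "-"
  mism <- as.integer(round(alns$aln_len * (100 - alns$identity_pct) / 100))
  evalue <- ifelse(is.na(alns$evalue), 0, alns$evalue)
  df <- data.frame(alns$read_id, genome$id,
                   formatC(alns$identity_pct, format = "f", digits = 3),
                   alns$aln_len, mism, 0L,
                   alns$read_start + 1L, alns$read_end,
                   ifelse(minus, alns$ref_end, alns$ref_start + 1L),
                   ifelse(minus, alns$ref_start + 1L, alns$ref_end),
                   format(evalue, scientific = TRUE),
                   2L * alns$aln_len)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read alignments with format auto-detection
#'
#' PAF is recognized by a `+`/`-` in column 5 with >= 12 columns; anything
#' else 12-column numeric is treated as BLAST tabular.
#'
#' @param path Alignment path.
#' @param format `"auto"`, `"paf"` or `"blast"`.
#' @param read_lengths Required for BLAST tabular (see [read_blast_tab()]).
#' @return Alignment data.frame.
#' @export
read_alignments <- function(path, format = c("auto", "paf", "blast"),
                            read_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    con <- open_text(path)
    first <- readLines(con, n = 1L)
    close(con)
    if (length(first) == 0) return(empty_alignments())
    f <- strsplit(first, "\t", fixed = TRUE)[[1]]
    format <- if (length(f) >= 12 && f[5] %in% c("+", "-")) "paf" else "blast"
  }
  if (format == "paf") return(read_paf(path))
  if (is.null(read_lengths))
    stopf("BLAST tabular input needs read_lengths (table or FASTA)")
  read_blast_tab(path, read_lengths)
}
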