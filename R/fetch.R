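#' Fetch a nucleotide sequence from NCBI as FASTA
#'
#' Thin wrapper over the NCBI E-utilities `efetch` endpoint, for the
#' optional accession-backed checks (genome lengths and G+C content of
#' published replicons). Requires network access; fails with a clear
#' error when offline.
#'
#' @param accession GenBank nucleotide accession (e.g. `"MN917146"`).
#' @param dest Destination FASTA path (default: tempfile).
#' @param timeout Download timeout in seconds.
#' @return The path to the downloaded FASTA.
#' @export
fetch_genbank_fasta <- function(accession, dest = tempfile(fileext = ".fa"),
                                timeout = 60) {
  stopifnot(is.character(accession), length(accession) == 1L)
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=", accession)
  old <- options(timeout = timeout)
  on.exit(options(old))
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                 error = function(e) -1L, warning = function(w) -1L)
  if (!identical(ok, 0L) || !file.exists(dest) || file.size(dest) < 10)
    stopf("could not fetch %s from NCBI (offline or unreachable)", accession)
  first <- readLines(dest, n = 1L)
  if (!startsWith(first, ">"))
    stopf("NCBI response for %s is not FASTA", accession)
  dest
}
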