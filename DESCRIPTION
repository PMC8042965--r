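Package: invertonscan
Title: Detection of Dynamic Recombination Hotspots and Invertible Loci
    from Long-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects candidate phase-variable loci (invertons) in bacterial
    genomes from long-read local alignments. Reads are parsed from PAF or
    BLAST tabular output, filtered on read length, identity, e-value and
    alignment length, and assembled into per-read chains; internal strand
    flips and coordinate shifts between consecutive segments are classified
    as recombination events and aggregated into fixed 1-kb windowed
    hotspots. Includes genome-track computations (G+C content, GC skew,
    alignment coverage), annotation overlap and recombinase/surface-gene
    colocalization reports from GFF3, and a seeded simulator of circular
    genomes with invertible loci, phase-variable populations, nanopore-like
    reads with per-read truth labels, and exact oracle alignments, so the
    whole pipeline is testable without external data or an aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
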