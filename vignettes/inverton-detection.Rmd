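---
title: "Detecting phase-variable loci from long-read alignment structure"
author: "invertonscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phase-variable loci from long-read alignment structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invertonscan)
```

## The problem and the model

Bacteroidetes such as *Bacteroides xylanisolvens* switch surface
phenotypes by site-specific DNA inversion: a recombinase flips a
promoter-bearing segment (an inverton) between two inverted repeats, so
at any moment the cell population is a mixture of both orientations.
The assembled reference genome necessarily records one orientation.
Long reads sequenced from the population therefore disagree with the
reference precisely at invertible loci, and the disagreement has a
characteristic *local-alignment structure*:

* a read spanning an inverted segment aligns as (at least) three local
  segments whose middle segment maps to the opposite strand — an
  **inversion** junction;
* deletions, insertions or translocation-like rearrangements displace
  consecutive same-strand segments from collinearity — a **shift**
  junction.

`invertonscan` detects loci by counting, per fixed genomic window, how
many distinct reads exhibit such junctions. No statistical model is
attached to the count: following the original procedure this package
implements, a window is a hotspot when the count exceeds a fixed
threshold. The method assumes (i) alignments are local and may split a
read into several segments; (ii) read depth is roughly uniform, so a
fixed count threshold has comparable meaning along the genome; and
(iii) the reference is a single replicon, circular by default.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_read_len` | 1000 | bp | reads must be **strictly longer** to be used at all |
| `min_identity_pct` | 90 | % | per-segment identity, strict |
| `max_evalue` | 1e−20 | — | per-segment e-value, strict upper bound; absent e-values (PAF) pass |
| `min_aln_len` | 200 | bp | per-segment length, strict |
| `min_shift` | 200 | bp | shift magnitude must strictly exceed this to be an event |
| `min_inversion_len` | 0 | bp | optional length gate on inversion events (see below) |
| `window` | 1000 | bp | fixed, non-overlapping windows anchored at coordinate 0 |
| `min_reads` | 8 | reads | hotspot iff distinct discordant reads per window is **> 8** |
| `max_junction_span` | 10 | windows | junction intervals wider than this are truncated to their two flanking windows |

All four filter thresholds and both event thresholds are strict
inequalities, read literally from the procedure being implemented
("longer than 1000 nt", "above 90% identity", "below 1e−20", "longer
than 200 nt", "more than 200 nt", "more than 8 reads"). A read of
exactly 1000 bp, a segment of exactly 200 bp, a shift of exactly 200 bp
and a window with exactly 8 discordant reads are all *excluded*; the
boundary tests pin each of these down.

## Junction classification in detail

For consecutive segments $a$, $b$ of one read (ordered by query start),
with *facing ends* $f_a$ ($a$'s reference coordinate at its query end —
`ref_end` on `+`, `ref_start` on `−`) and $f_b$ (symmetrically at $b$'s
query start):

* **strands differ** → inversion. Its magnitude is defined as the
  smaller of the two flanking segments' reference spans; since the
  procedure defines no inversion magnitude and only gates *shifts* at
  200 nt, inversions count as events whenever both flanking segments
  survive the 200-nt segment filter (`min_inversion_len = 0`). The
  stricter reading — gating inversions on length too — is available by
  raising `min_inversion_len`.
* **strands equal** → shift magnitude $|\Delta_{ref} - \Delta_{read}|$,
  where $\Delta_{read}$ is the query gap and $\Delta_{ref}$ the signed
  displacement from $f_a$ to $f_b$ in the direction of travel (reversed
  on `−`). The displacement is measured from collinearity on purpose: a
  long reference gap matched by an equally long read gap (an unaligned
  repeat, a low-complexity hole) is *not* a rearrangement and produces
  no event.

On circular genomes $\Delta_{ref}$ takes the arc with the smaller
absolute displacement; exact ties ($|\Delta| = L/2$) resolve to the
positive arc. The junction is localized to the reference span between
$f_a$ and $f_b$ along that arc, split in two at the origin when the arc
wraps, and widened to 1 bp when the facing ends coincide so the
junction still lands in a window.

Three more conventions matter for window counting:

* a read is counted **once per window** touched by any of its junction
  intervals — not once globally, and not once per event — which is the
  only counting that keeps the per-window histogram well defined when a
  read has several events;
* windows are fixed bins anchored at 0, never sliding; a junction
  interval overlapping two windows increments both;
* a junction interval wider than `max_junction_span` windows (a single
  translocation-like jump across the genome) is truncated to its two
  flanking windows before counting. This is a declared heuristic: it
  keeps one aberrant read from painting hundreds of windows, at the
  cost of not flagging the interior of truly enormous junctions.

All coordinates are 0-based half-open on the forward reference strand
everywhere inside the package; conversions to and from 1-based
inclusive conventions (BLAST tabular, GFF3) happen only at the parse
and serialize boundaries. Within a read, segments whose query interval
is contained in another's are pruned (ties between identical intervals:
larger identity × length, then smaller reference start); partial query
overlaps are kept, because inversion junctions routinely produce small
overlaps and overlap alone never generates an event.

## What the simulator emulates — and what it does not

The generator produces the study conditions end to end: a circular
random genome at a target G+C (default 0.43, the host-genome range), a
small set of invertible loci (500–2000 bp, each > 200 bp so inversions
are detectable under the segment filter, pairwise separated by at least
one window so each locus maps to its own hotspot windows), a population
of `n_variants` genomes in which each locus is independently inverted
with probability `inverted_fraction` (default 0.3), and `n_reads` reads
with log-normal lengths (log-mean 8.5, log-sd 0.6 ≈ median 4.9 kb, the
nanopore-like regime) starting uniformly on the circle.

Reads are **error-free by default** (an optional uniform substitution
rate exists but defaults to 0): the detection procedure consumes aligner
output, not raw signal, and exact reads make the oracle alignments
exact — one `LocalAlignment` per origin segment at 100% identity,
e-value 0. Read lengths are clamped to a minimum of 1001 bp so that the
strict >1000 nt read filter is never triggered by the point mass the
clamp creates at its boundary; this keeps the simulator's truth labels
and the pipeline's verdicts comparable read for read.

Each read's truth label mirrors the detection definition — segments
≤ 200 bp ignored, then any consecutive pair differing in strand or
displaced by > 200 bp marks the read discordant — but is computed by
the simulator's own small checker over the true origin segments,
independently of the detection code, so end-to-end agreement is a real
test, not a tautology.

The simulator does **not** model nanopore error profiles (homopolymer
errors, quality strings), basecalling, chimeric reads, or inverted
repeats at locus boundaries. Passing tests therefore demonstrate the
*logic* of filtering, chaining, classification and windowing — they do
not certify behaviour on noisy real alignments, where identity and
e-value filtering carry the load the simulator bypasses.

```{r example}
sim <- simulate_genome(60000, n_loci = 2, locus_len_range = c(500, 1500),
                       inverted_fraction = 0.3, seed = 11)
pop <- build_population(sim$genome, sim$loci, n_variants = 60, seed = 12)
reads <- simulate_reads(pop, n_reads = 400, seed = 13)
scan <- scan_alignments(emit_truth_alignments(reads), sim$genome$length)
scan$summary
benchmark_hotspots(scan$hotspots, sim$loci)[c("recall", "precision")]
```

## Numerical and design choices

* **PAF without e-values.** PAF carries no e-value; such segments pass
  the e-value filter. The filter exists to drop spurious BLAST hits,
  and long-read mappers apply their own mapping-quality filtering;
  rejecting PAF outright would exclude the format the long-read
  ecosystem actually uses. Identity for PAF is derived as
  100 × matches / alignment block length.
* **G+C conventions.** `gc_content()` excludes ambiguity codes from
  numerator and denominator; GC skew is (G−C)/(G+C) per window with 0
  for windows without G or C. Reported mol% values round half-even to
  2 decimals.
* **Degenerate inputs.** Empty alignment sets, empty event sets and
  empty hotspot sets flow through every stage as empty tables; an empty
  sequence is an error. Infeasible locus placement (loci cannot be
  placed non-overlapping at the required separation) raises an explicit
  error rather than silently placing fewer.
* **Determinism.** Every stochastic operation takes a seed and restores
  the caller's RNG state; identical parameters and seed give
  byte-identical FASTA/FASTQ/PAF/BED/JSON outputs. Run manifests record
  parameters and seeds but no timestamps.
* **Proximity defaults.** The colocalization scan pairs
  recombinase/integrase/invertase genes with Sus/TonB and capsule/LPS
  genes within `max_dist = 5000` bp (minimal arc on circular genomes);
  the overlap report uses a 1000-bp flank. Neither cutoff is prescribed
  by the procedure this implements; both are package defaults and
  every report is monotone in them. The product-keyword table that
  assigns categories ships as an editable YAML file
  (`inst/extdata/feature_categories.yaml`).

## Problem sizes used by the test suite

The reference verification scenario is a 100-kb circular genome with 3
loci, 200 population variants and 2000 reads (about 100× depth), on
which locus recall and precision are both 1 and the detected
discordant-read set equals the truth set exactly. Unit and property
tests run smaller scenarios (40–60 kb, 100–500 reads) plus 1300 random
chains against a brute-force junction enumerator; the whole suite
completes in well under a minute on one core. These sizes are chosen so
the binomial signal at each locus (tens of discordant reads against a
threshold of 8) is overwhelming, which is what makes exact
recall/precision assertions meaningful rather than flaky.

## Known limitations

* No significance model for hotspot counts; the fixed `> 8 reads /
  1 kb` rule inherits its meaning from the original depth and does not
  adapt to coverage.
* Single-replicon analysis: alignments are assumed to target one
  reference sequence; plasmids are analysed one at a time.
* No SAM/BAM ingestion and no alignment computation — production
  alignments come from an external aligner (BLASTn or minimap2).
* No inverted-repeat motif search at hotspot boundaries, and no calling
  of which orientation is ancestral.
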