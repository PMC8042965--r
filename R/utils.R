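# internal helpers: seeded RNG scoping and circular-coordinate arithmetic

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. seed = NULL runs the code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Signed displacement with the smaller |.| of the two arc directions on a
# circle of size `len`; ties (|d| == len/2) resolve to the positive arc.
# Vectorised over d.
circ_signed_min <- function(d, len) {
  fwd <- d %% len
  bwd <- fwd - len
  ifelse(abs(fwd) <= abs(bwd), fwd, bwd)
}

# Gap (0 if overlapping/adjacent-overlap) between 0-based half-open intervals.
interval_gap <- function(a_lo, a_hi, b_lo, b_hi) {
  pmax(0L, pmax(b_lo - a_hi, a_lo - b_hi))
}

# Minimal gap between two intervals on a circular genome of length len:
# min of the linear gap and the gap going the other way round the origin.
circ_interval_gap <- function(a_lo, a_hi, b_lo, b_hi, len) {
  lin <- interval_gap(a_lo, a_hi, b_lo, b_hi)
  wrap <- pmax(0L, len - (pmax(a_hi, b_hi) - pmin(a_lo, b_lo)))
  overlap <- (a_lo < b_hi) & (b_lo < a_hi)
  ifelse(overlap, 0L, pmin(lin, wrap))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Open a (possibly gzipped) path or pass a connection through.
open_text <- function(x) {
  if (inherits(x, "connection")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("\\.gz$", x)) gzfile(x, "rt") else file(x, "rt")
}
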