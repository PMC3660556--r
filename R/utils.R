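# Internal helpers shared across modules.

# BED half-open [start, end) -> 1-based inclusive [start + 1, end].
bed_to_inclusive <- function(start, end) {
  list(start = start + 1L, end = end)
}

# 1-based inclusive [start, end] -> BED half-open [start - 1, end).
inclusive_to_bed <- function(start, end) {
  list(start = start - 1L, end = end)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

stop_if_missing_cols <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(x)
}

# Warn about and drop columns not in the documented schema.
keep_known_cols <- function(x, cols, what) {
  extra <- setdiff(names(x), cols)
  if (length(extra) > 0) {
    warn(sprintf("%s: ignoring unknown column(s): %s",
                 what, paste(extra, collapse = ", ")))
  }
  x[intersect(cols, names(x))]
}

# Which positions fall inside any interval of `regions` (1-based inclusive,
# same chromosome naming)? Vectorized over positions via IRanges.
positions_in_regions <- function(chrom, pos, regions) {
  stopifnot(length(chrom) == length(pos))
  hit <- logical(length(pos))
  if (length(pos) == 0 || nrow(regions) == 0) return(hit)
  for (cur in unique(regions$chrom)) {
    qi <- which(chrom == cur)
    if (length(qi) == 0) next
    ri <- regions[regions$chrom == cur, , drop = FALSE]
    q <- IRanges::IRanges(start = pos[qi], width = 1L)
    s <- IRanges::IRanges(start = ri$start, end = ri$end)
    hit[qi] <- IRanges::overlapsAny(q, s)
  }
  hit
}
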