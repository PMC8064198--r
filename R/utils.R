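# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific child seed from a run seed (kept below 2^31).
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 7919) %% 2147483647
}

# Luminance (ITU-R BT.601) of an RGB intensity triple / array.
luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

# Pixel offsets of a filled disc of radius r (integer offsets around 0,0).
disc_offsets <- function(r) {
  s <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dr = s, dc = s)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Stamp TRUE into `mask` at center (row, col) for the given offsets,
# returning the affected linear indices (assumes offsets fit in-bounds).
offset_index <- function(nrow_m, row, col, offsets) {
  (col + offsets$dc - 1L) * nrow_m + (row + offsets$dr)
}
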