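# Internal helpers shared across modules.

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `code` with a temporary RNG seed, restoring global RNG state afterwards.
# Keeps all package randomness flowing from explicit seeds.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Shift a logical matrix by (dr, dc), filling vacated cells with FALSE.
shift_logical <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
  out
}

# Union of the four lateral (up/down/left/right) shifts of a logical matrix.
neighbour4_any <- function(m) {
  shift_logical(m, 1L, 0L) | shift_logical(m, -1L, 0L) |
    shift_logical(m, 0L, 1L) | shift_logical(m, 0L, -1L)
}

# Trapezoid-rule integral of y over a uniform grid x.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

stop_fw <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
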