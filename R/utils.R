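# Internal helpers shared across modules.

# Run expr with a private RNG stream, restoring the caller's stream after.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  force(expr)
}

# Draw replicate child seeds from a master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Linear index of (row, col) in an H x W matrix, vectorised.
rc_idx <- function(row, col, H) (col - 1L) * H + row

# 4-neighbour linear indices of linear index i in an H x W matrix.
# Returns a list in fixed order N, E, S, W (N = row - 1) with NA off-grid.
vn_neighbors <- function(i, H, W) {
  row <- ((i - 1L) %% H) + 1L
  col <- ((i - 1L) %/% H) + 1L
  list(
    N = ifelse(row > 1L, i - 1L, NA_integer_),
    E = ifelse(col < W, i + H, NA_integer_),
    S = ifelse(row < H, i + 1L, NA_integer_),
    W = ifelse(col > 1L, i - H, NA_integer_)
  )
}

# Moore neighbourhood offsets in the package's fixed tie-break order:
# N, E, S, W, NE, SE, SW, NW (dx = column step, dy = row step).
moore_order <- function() {
  cbind(
    dx = c(0L, 1L, 0L, -1L, 1L, 1L, -1L, -1L),
    dy = c(-1L, 0L, 1L, 0L, -1L, 1L, 1L, -1L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
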