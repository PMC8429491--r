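# Secreted-factor pools and fields.
#
# Five factors are tracked as global pools with per-hour secretion rates
# driven by the cell census (anti-inflammatory macrophages AM, neutrophils
# N, pro-inflammatory macrophages PM, fibroblasts Fb, damaged ECM DE):
#
#   dIGF1/dt = 2 * (8.8e-5 * AM)
#   dTNFa/dt = 3.21e-12 + 5.8e-12 * N + 1.25e-9 * PM + 4.9e-18 * Fb
#   dTGFb/dt = 8.75e-3 * AM
#   dHGF/dt  = 1.49e-7 * DE
#   dIL6/dt  = 2.91e-12 + 1.25e-12 * N + 1.25e-12 * PM
#
# Rates are used as printed in their source literature; their absolute
# scales differ by orders of magnitude and no unit conversion is attempted
# because only signs, gradients, and arg-max comparisons feed the agent
# rules. Global pools drive temporal gates (positive-gradient checks);
# per-pixel local fields (deposited at damage contact sites) drive spatial
# chemotaxis.

CYTOKINES <- c("IGF1", "TNFa", "TGFb", "HGF", "IL6")

#' Create a cytokine state
#'
#' @param height,width Grid dimensions for the local fields; omit both for a
#'   pools-only state.
#' @return A `cytokine_state`: global pools (all zero), previous-tick
#'   snapshot (absent until the first update), and per-pixel local fields
#'   for IL6 and TGFb when dimensions are given.
#' @export
cytokine_state <- function(height = NULL, width = NULL) {
  local <- NULL
  if (!is.null(height) && !is.null(width)) {
    local <- list(IL6 = matrix(0, height, width),
                  TGFb = matrix(0, height, width))
  }
  structure(
    list(pools = setNames(numeric(5), CYTOKINES), prev = NULL, local = local),
    class = "cytokine_state"
  )
}

#' Per-hour secretion rates for a cell census
#'
#' @param census Named list/vector with nonnegative counts `N`, `PM`, `AM`,
#'   `Fb`, `DE`.
#' @return A tibble with columns `factor` and `rate` (units per hour).
#' @export
cytokine_rates <- function(census) {
  tibble::tibble(factor = CYTOKINES, rate = unname(cytokine_rates_vec(census)))
}

# Fast path used every tick: plain named numeric vector of the printed
# per-hour rates.
cytokine_rates_vec <- function(census) {
  for (f in c("N", "PM", "AM", "Fb", "DE")) {
    v <- census[[f]]
    if (is.null(v) || is.na(v) || v < 0) stop_("census field ", f, " must be nonnegative")
  }
  setNames(c(
    2 * (8.8e-5 * census$AM),
    3.21e-12 + 5.8e-12 * census$N + 1.25e-9 * census$PM + 4.9e-18 * census$Fb,
    8.75e-3 * census$AM,
    1.49e-7 * census$DE,
    2.91e-12 + 1.25e-12 * census$N + 1.25e-12 * census$PM
  ), CYTOKINES)
}

#' Advance cytokine pools by one time step
#'
#' Increments each global pool by its census-driven secretion rate times
#' `dt_hours`, snapshots the previous pools for gradient checks, optionally
#' applies first-order decay after secretion, and optionally diffuses the
#' local fields with a mass-conserving 4-neighbor kernel.
#'
#' @param state A `cytokine_state`.
#' @param census Named counts (`N`, `PM`, `AM`, `Fb`, `DE`).
#' @param dt_hours Time step, hours (> 0).
#' @param decay First-order decay rate per hour (default 0: factors
#'   accumulate, as in the source equations).
#' @param diffusion Local-field smoothing weight in [0, 1] (share of each
#'   pixel's content spread to its 4 neighbors per step).
#' @return The updated `cytokine_state`.
#' @export
cytokines_update <- function(state, census, dt_hours = 1, decay = 0,
                             diffusion = 0) {
  stopifnot(dt_hours > 0, decay >= 0, diffusion >= 0, diffusion <= 1)
  rates <- cytokine_rates_vec(census)
  state$prev <- state$pools
  state$pools <- state$pools + rates * dt_hours
  if (decay > 0) state$pools <- state$pools * exp(-decay * dt_hours)
  if (!is.null(state$local) && diffusion > 0) {
    state$local <- lapply(state$local, diffuse4, w = diffusion)
  }
  state
}

# Mass-conserving 4-neighbor smoothing: each pixel sends w/4 of its content
# to each existing neighbor; shares toward the boundary reflect back.
diffuse4 <- function(m, w) {
  H <- nrow(m); W <- ncol(m)
  received <- matrix(0, H, W)
  received[-H, ] <- received[-H, ] + m[-1, ]   # from below
  received[-1, ] <- received[-1, ] + m[-H, ]   # from above
  received[, -W] <- received[, -W] + m[, -1]   # from right
  received[, -1] <- received[, -1] + m[, -W]   # from left
  missing_nb <- matrix(0, H, W)
  missing_nb[1, ] <- missing_nb[1, ] + 1
  missing_nb[H, ] <- missing_nb[H, ] + 1
  missing_nb[, 1] <- missing_nb[, 1] + 1
  missing_nb[, W] <- missing_nb[, W] + 1
  (1 - w) * m + (w / 4) * (received + missing_nb * m)
}

#' Deposit an amount of a factor at a pixel
#'
#' Adds `amount` to the local field at (x, y) and to the global pool.
#'
#' @param state A `cytokine_state` with local fields.
#' @param x,y 0-based pixel coordinates.
#' @param factor `"IL6"` or `"TGFb"`.
#' @param amount Nonnegative amount.
#' @return The updated `cytokine_state`.
#' @export
deposit_local <- function(state, x, y, factor = c("IL6", "TGFb"), amount) {
  factor <- match.arg(factor)
  stopifnot(amount >= 0)
  if (is.null(state$local)) stop_("cytokine state has no local fields")
  H <- nrow(state$local[[factor]]); W <- ncol(state$local[[factor]])
  if (any(x < 0 | x >= W | y < 0 | y >= H)) stop_("pixel outside grid")
  idx <- rc_idx(y + 1L, x + 1L, H)
  state$local[[factor]][idx] <- state$local[[factor]][idx] + amount
  state$pools[[factor]] <- state$pools[[factor]] + sum(amount)
  state
}

#' Is a factor's global pool increasing?
#'
#' Compares the current pool with the previous-tick snapshot. Before the
#' first update (no snapshot) the gradient is treated as non-positive.
#'
#' @param state A `cytokine_state`.
#' @param factor One of `r paste(CYTOKINES, collapse = ", ")`.
#' @return `TRUE` if the pool strictly increased over the last step.
#' @export
gradient_positive <- function(state, factor) {
  if (is.null(state$prev)) return(FALSE)
  (state$pools[[factor]] - state$prev[[factor]]) > 0
}

#' Moore-neighborhood arg-max of a local field
#'
#' Returns the neighboring pixel (or the pixel itself) with the highest
#' local concentration. Ties are broken by a fixed neighbor order
#' (N, E, S, W, NE, SE, SW, NW, then self), so a uniform field sends the
#' searcher north.
#'
#' @param state A `cytokine_state` with local fields.
#' @param factor `"IL6"` or `"TGFb"`.
#' @param x,y 0-based pixel coordinates of the searcher.
#' @return A list with the chosen `x` and `y`.
#' @export
local_max_neighbor <- function(state, factor = c("IL6", "TGFb"), x, y) {
  factor <- match.arg(factor)
  if (is.null(state$local)) stop_("cytokine state has no local fields")
  field <- state$local[[factor]]
  H <- nrow(field); W <- ncol(field)
  off <- moore_order()
  cx <- c(x + off[, "dx"], x)
  cy <- c(y + off[, "dy"], y)
  ok <- cx >= 0 & cx < W & cy >= 0 & cy < H
  cx <- cx[ok]; cy <- cy[ok]
  v <- field[rc_idx(cy + 1L, cx + 1L, H)]
  j <- which.max(v) # first index wins ties: fixed neighbor order
  list(x = cx[j], y = cy[j])
}
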