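# Hourly-tick agent scheduler.
#
# One tick advances, in fixed order: cytokine update -> neutrophils ->
# macrophages -> satellite cells/myoblasts -> fibroblasts -> border
# re-formation & hypertrophy -> census log. The fixed order (and a single
# seeded RNG stream stored in the state) makes whole runs bit-reproducible.
#
# State is an environment holding the grid matrices, the cytokine state,
# and one vector-of-attributes block per agent class; all per-tick rules
# are vectorised over agents. Agents may share pixels (cells in a 50 um
# slice are not volume-filling at this resolution) and traverse any canvas
# pixel; targeting uses a capped subsample of target pixels for direction
# finding.

# --- RNG plumbing -----------------------------------------------------------

with_state_rng <- function(state, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", state$rng, envir = globalenv())
  on.exit({
    state$rng <- get(".Random.seed", envir = globalenv())
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  force(expr)
}

# --- Initialization ---------------------------------------------------------

#' Initialize a simulation state
#'
#' Places agents on a (possibly pre-damaged) grid: satellite cells on
#' border fibrils (fibril pixels 4-adjacent to ECM), neutrophils,
#' macrophages and fibroblasts uniformly at random on ECM pixels.
#'
#' @param grid A `tissue_grid`, typically with damage already applied via
#'   [apply_damage()].
#' @param config A [sim_config()].
#' @param seed Integer seed for the run's RNG stream.
#' @return A simulation state (environment of class `sim_state`).
#' @export
sim_init <- function(grid, config = sim_config(), seed = 1) {
  state <- new.env(parent = emptyenv())
  state$cfg <- config
  state$label <- grid$label
  state$owner <- grid$owner
  state$collagen <- grid$collagen
  state$damaged <- grid$damaged
  state$needs_repair <- grid$needs_repair
  state$H <- nrow(grid$label); state$W <- ncol(grid$label)
  state$n_fibers <- grid$n_fibers
  state$pixel_area <- grid$pixel_area
  state$slice_thickness <- grid$slice_thickness
  state$tick <- 0L
  state$initial_fibrils <- sum(is_fibril(grid$label))
  state$damage_tick <- if (any(grid$damaged)) 1L else NA_integer_
  state$damage_seen <- any(grid$damaged)
  state$clocked <- FALSE
  state$m_clocked <- FALSE
  state$ever_AM <- FALSE
  state$cy <- cytokine_state(state$H, state$W)

  local_seed(seed, {
    H <- state$H
    ecm_idx <- which(state$label == ECM_CODE)
    if (!length(ecm_idx)) stop_("grid has no ECM pixels to seed cells on")
    border <- border_fibrils(state)
    n_sc <- initial_sc_count(config, grid)
    if (n_sc > 0 && !length(border)) stop_("no border fibrils to place SCs on")
    sc_px <- if (n_sc > 0) border[sample.int(length(border), n_sc,
      replace = n_sc > length(border))] else integer(0)
    state$s_x <- (sc_px - 1L) %/% H
    state$s_y <- (sc_px - 1L) %% H
    state$s_state <- rep(0L, n_sc) # 0 quiescent, 1 active
    state$s_div <- rep(0L, n_sc)
    state$s_age <- rep(0L, n_sc)

    place <- function(n) {
      px <- if (n > 0) ecm_idx[sample.int(length(ecm_idx), n, replace = TRUE)] else integer(0)
      list(x = (px - 1L) %/% H, y = (px - 1L) %% H)
    }
    np <- place(config$n_neutrophils)
    state$n_x <- np$x; state$n_y <- np$y
    state$n_death <- rep(Inf, config$n_neutrophils)
    mp <- place(config$n_macrophages)
    state$m_x <- mp$x; state$m_y <- mp$y
    state$m_phen <- rep(1L, config$n_macrophages)
    state$m_death <- rep(Inf, config$n_macrophages)
    fp <- place(initial_fb_count(config, grid))
    state$f_x <- fp$x; state$f_y <- fp$y
    state$f_act <- rep(FALSE, length(fp$x))
    state$b_x <- integer(0); state$b_y <- integer(0); state$b_death <- numeric(0)
    state$rng <- get(".Random.seed", envir = globalenv())
  })

  state$log <- matrix(NA_real_, config$ticks + 1L, length(CENSUS_COLS),
                      dimnames = list(NULL, CENSUS_COLS))
  state$log[1L, ] <- unlist(sim_census(state))[CENSUS_COLS]
  state$log[1L, "tick"] <- 0
  class(state) <- c("sim_state", "environment")
  state
}

CENSUS_COLS <- c("tick", "N", "PM", "AM", "Fb", "SC_q", "SC_a", "MB",
                 "DE", "DF", "fibril_count", "ecm_count")

# Fibril pixels 4-adjacent to ECM.
border_fibrils <- function(state) {
  label <- state$label
  H <- state$H; W <- state$W
  fib <- is_fibril(label)
  ecm <- label == ECM_CODE
  nb_ecm <- matrix(FALSE, H, W)
  nb_ecm[-H, ] <- nb_ecm[-H, ] | ecm[-1, ]
  nb_ecm[-1, ] <- nb_ecm[-1, ] | ecm[-H, ]
  nb_ecm[, -W] <- nb_ecm[, -W] | ecm[, -1]
  nb_ecm[, -1] <- nb_ecm[, -1] | ecm[, -W]
  which(fib & nb_ecm)
}

#' Census of a simulation state
#'
#' @param state A `sim_state`.
#' @return Named list of agent counts, damaged-object counts (`DE`, `DF`)
#'   and grid tallies for the current tick.
#' @export
sim_census <- function(state) {
  fib <- is_fibril(state$label)
  list(
    tick = state$tick,
    N = length(state$n_x),
    PM = sum(state$m_phen == 1L),
    AM = sum(state$m_phen == 2L),
    Fb = length(state$f_x),
    SC_q = sum(state$s_state == 0L),
    SC_a = sum(state$s_state == 1L),
    MB = length(state$b_x),
    DE = sum(state$damaged & state$label == ECM_CODE),
    DF = sum(state$damaged & fib),
    fibril_count = sum(fib),
    ecm_count = sum(state$label == ECM_CODE)
  )
}

#' Extract a simulation state's grid
#'
#' @param state A `sim_state`.
#' @return A `tissue_grid` snapshot of the current lattice.
#' @export
sim_grid <- function(state) {
  new_tissue_grid(state$label, state$owner, state$collagen, state$damaged,
                  state$needs_repair, state$n_fibers, state$pixel_area,
                  state$slice_thickness)
}

# --- Movement helpers -------------------------------------------------------

# Exact city-block distance transform to the TRUE pixels of `mask`
# (two-pass chamfer; the within-row recursion is vectorised with the
# cummin trick: min_{c'<=c} v[c'] + (c - c') = cummin(v - c) + c).
dist4 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- seq_len(W)
  dt <- matrix(1e7, H, W)
  dt[mask] <- 0
  for (r in seq_len(H)) {
    if (r > 1L) dt[r, ] <- pmin(dt[r, ], dt[r - 1L, ] + 1)
    dt[r, ] <- cummin(dt[r, ] - idx) + idx
  }
  for (r in rev(seq_len(H))) {
    if (r < H) dt[r, ] <- pmin(dt[r, ], dt[r + 1L, ] + 1)
    dt[r, ] <- rev(cummin(rev(dt[r, ]) - idx) + idx)
  }
  dt
}

# Move agents `speed` greedy descent steps down a distance transform: each
# agent walks toward its own nearest target, so crowds spread over the
# whole damage frontier instead of converging on a single pixel. Agents
# already on a target (distance 0) stay put.
dt_step <- function(dt, x, y, speed, W, H) {
  n <- length(x)
  if (!n) return(list(x = x, y = y))
  off <- rbind(c(0L, 0L), moore_order()) # stay, then fixed Moore order
  for (s in seq_len(speed)) {
    vals <- matrix(Inf, n, nrow(off))
    for (k in seq_len(nrow(off))) {
      cx <- x + off[k, 1L]; cy <- y + off[k, 2L]
      ok <- cx >= 0L & cx < W & cy >= 0L & cy < H
      if (any(ok)) vals[ok, k] <- dt[rc_idx(cy[ok] + 1L, cx[ok] + 1L, H)]
    }
    # random tie-breaking between equidistant directions: a deterministic
    # tie-break herds whole crowds along identical paths; the jitter (< 1,
    # below the integer distance spacing) spreads them over the frontier
    vals <- vals + matrix(runif(n * nrow(off), 0, 0.5), n)
    best <- max.col(-vals, ties.method = "first")
    x <- pmin(pmax(x + off[best, 1L], 0L), W - 1L)
    y <- pmin(pmax(y + off[best, 2L], 0L), H - 1L)
  }
  list(x = x, y = y)
}

# Exact-nearest beeline for small agent groups (fibroblasts).
beeline <- function(x, y, tx, ty, speed, W, H) {
  d2 <- outer(x, tx, "-")^2 + outer(y, ty, "-")^2
  j <- max.col(-d2, ties.method = "first")
  dx <- tx[j] - x; dy <- ty[j] - y
  nx <- x + sign(dx) * pmin(abs(dx), speed)
  ny <- y + sign(dy) * pmin(abs(dy), speed)
  list(x = pmin(pmax(nx, 0L), W - 1L), y = pmin(pmax(ny, 0L), H - 1L))
}

# Positions for newly recruited immune cells: random ECM pixels (influx
# from the vasculature arrives across the tissue, not at the work site).
recruit_positions <- function(state, k) {
  ecm_idx <- which(state$label == ECM_CODE)
  if (!length(ecm_idx)) ecm_idx <- which(state$label != EMPTY_CODE)
  px <- ecm_idx[sample.int(length(ecm_idx), k, replace = TRUE)]
  list(x = (px - 1L) %/% state$H, y = (px - 1L) %% state$H)
}

# Greedy one-to-one matching of agents to adjacent TRUE pixels of `mask`
# (self, then von Neumann neighbors in fixed order): every matched agent
# claims a DISTINCT pixel, so a crowd on a damage frontier works as many
# pixels in parallel as are reachable.
match_contacts <- function(x, y, mask, H, W, moore = FALSE) {
  n <- length(x)
  out <- rep(NA_integer_, n)
  claimed <- matrix(FALSE, H, W)
  offs <- if (moore) rbind(c(0L, 0L), moore_order()) else
    rbind(c(0L, 0L), c(0L, -1L), c(1L, 0L), c(0L, 1L), c(-1L, 0L))
  for (k in seq_len(nrow(offs))) {
    cx <- x + offs[k, 1L]; cy <- y + offs[k, 2L]
    ok <- is.na(out) & cx >= 0L & cx < W & cy >= 0L & cy < H
    if (!any(ok)) next
    oki <- which(ok)
    idx <- rc_idx(cy[oki] + 1L, cx[oki] + 1L, H)
    hit <- mask[idx] & !claimed[idx]
    if (!any(hit)) next
    idxh <- idx[hit]
    keep <- !duplicated(idxh)
    agents <- oki[hit][keep]
    out[agents] <- idxh[keep]
    claimed[idxh[keep]] <- TRUE
  }
  out
}

random_walk <- function(x, y, W, H) {
  nx <- x + sample(c(-1L, 0L, 1L), length(x), replace = TRUE)
  ny <- y + sample(c(-1L, 0L, 1L), length(y), replace = TRUE)
  list(x = pmin(pmax(nx, 0L), W - 1L), y = pmin(pmax(ny, 0L), H - 1L))
}

# For each agent, the first pixel in fixed order (self, N, E, S, W) whose
# mask entry is TRUE; NA when none. `mask` is an H x W logical matrix.
contact_pixel <- function(x, y, mask, H, W) {
  n <- length(x)
  out <- rep(NA_integer_, n)
  offs <- rbind(c(0L, 0L), c(0L, -1L), c(1L, 0L), c(0L, 1L), c(-1L, 0L))
  for (k in seq_len(nrow(offs))) {
    cx <- x + offs[k, 1L]; cy <- y + offs[k, 2L]
    ok <- is.na(out) & cx >= 0L & cx < W & cy >= 0L & cy < H
    if (!any(ok)) next
    idx <- rc_idx(cy[ok] + 1L, cx[ok] + 1L, H)
    hit <- mask[idx]
    out[which(ok)[hit]] <- idx[hit]
  }
  out
}

# Moore-neighborhood (incl. self) contact against a mask, same return as
# contact_pixel but scanning all 8 neighbors in the fixed Moore order.
contact_pixel_moore <- function(x, y, mask, H, W) {
  n <- length(x)
  out <- rep(NA_integer_, n)
  off <- rbind(c(0L, 0L), moore_order())
  for (k in seq_len(nrow(off))) {
    cx <- x + off[k, 1L]; cy <- y + off[k, 2L]
    ok <- is.na(out) & cx >= 0L & cx < W & cy >= 0L & cy < H
    if (!any(ok)) next
    idx <- rc_idx(cy[ok] + 1L, cx[ok] + 1L, H)
    hit <- mask[idx]
    out[which(ok)[hit]] <- idx[hit]
  }
  out
}

# Step along the local IL-6 arg-max (Moore, fixed tie-break order, self
# last); agents seeing a flat zero field take a random-walk step.
il6_argmax_step <- function(field, x, y, W, H) {
  n <- length(x)
  off <- rbind(moore_order(), c(0L, 0L))
  vals <- matrix(-1, n, nrow(off))
  for (k in seq_len(nrow(off))) {
    cx <- x + off[k, 1L]; cy <- y + off[k, 2L]
    ok <- cx >= 0L & cx < W & cy >= 0L & cy < H
    if (any(ok)) vals[ok, k] <- field[rc_idx(cy[ok] + 1L, cx[ok] + 1L, H)]
  }
  best <- max.col(vals, ties.method = "first")
  flat <- vals[cbind(seq_len(n), best)] <= 0
  nx <- x + off[best, 1L]; ny <- y + off[best, 2L]
  if (any(flat)) {
    rw <- random_walk(x[flat], y[flat], W, H)
    nx[flat] <- rw$x; ny[flat] <- rw$y
  }
  list(x = pmin(pmax(nx, 0L), W - 1L), y = pmin(pmax(ny, 0L), H - 1L))
}

# Clear damaged pixels: label -> EMPTY, flags reset, collagen lost.
# needs_repair persists so repair agents can find the site.
clear_pixels <- function(state, px) {
  if (!length(px)) return(invisible())
  state$label[px] <- EMPTY_CODE
  state$damaged[px] <- FALSE
  state$collagen[px] <- 0
  invisible()
}

# --- Per-class steps --------------------------------------------------------

neutrophil_step <- function(state, t) {
  cfg <- state$cfg
  n <- length(state$n_x)
  if (n == 0 && !state$damage_seen) return(invisible())
  H <- state$H; W <- state$W
  dmg <- which(state$damaged)
  if (!state$clocked && state$damage_seen) {
    # damage detection starts the neutrophils' lifespan clocks
    state$n_death <- t + rexp(n, 1 / cfg$neutrophil_lifespan_h)
    state$clocked <- TRUE
  }
  if (n > 0 && length(dmg)) {
    # act first, move second: agents touching damage work in place, each
    # claiming its own damaged pixel
    tgt <- match_contacts(state$n_x, state$n_y, state$damaged, H, W)
    in_contact <- !is.na(tgt)
    if (any(in_contact)) {
      px <- tgt[in_contact] # distinct pixels by construction
      state$needs_repair[px] <- TRUE
      state$cy$local$IL6[px] <- state$cy$local$IL6[px] + cfg$il6_deposit
      state$cy$pools[["IL6"]] <- state$cy$pools[["IL6"]] +
        cfg$il6_deposit * length(px)
      # proliferation/recruitment (window-limited, capped): new neutrophils
      # extravasate at random ECM sites
      if ((t - state$damage_tick) <= cfg$neutrophil_window_h) {
        k <- min(sum(runif(length(px)) < cfg$neutrophil_spawn_p),
                 cfg$neutrophil_recruit_max,
                 cfg$neutrophil_cap - length(state$n_x))
        if (k > 0) {
          sp <- recruit_positions(state, k)
          state$n_x <- c(state$n_x, sp$x)
          state$n_y <- c(state$n_y, sp$y)
          state$n_death <- c(state$n_death, t + rexp(k, 1 / cfg$neutrophil_lifespan_h))
        }
      }
      # breakdown of damaged objects
      cpx <- px[runif(length(px)) < cfg$neutrophil_clear_p]
      clear_pixels(state, cpx)
    }
    # phagocytes keep crawling as they consume: everyone repositions by
    # descending the distance field toward their nearest damaged object
    if (any(state$damaged)) {
      dt <- dist4(state$damaged)
      mv <- dt_step(dt, state$n_x[seq_len(n)], state$n_y[seq_len(n)],
                    cfg$n_speed, W, H)
      state$n_x[seq_len(n)] <- mv$x; state$n_y[seq_len(n)] <- mv$y
      state$dt_dmg <- dt
    }
  } else if (n > 0) {
    mv <- random_walk(state$n_x, state$n_y, W, H)
    state$n_x <- mv$x; state$n_y <- mv$y
  }
  keep <- state$n_death > t
  if (!all(keep)) {
    state$n_x <- state$n_x[keep]; state$n_y <- state$n_y[keep]
    state$n_death <- state$n_death[keep]
  }
  invisible()
}

macrophage_step <- function(state, t) {
  cfg <- state$cfg
  m <- length(state$m_x)
  H <- state$H; W <- state$W
  dmg <- which(state$damaged)
  # phenotype switch: once damage has occurred and all damaged objects are
  # cleared, every M1 becomes an anti-inflammatory M2
  if (state$damage_seen && !length(dmg)) {
    m1 <- state$m_phen == 1L
    if (any(m1)) {
      state$m_phen[m1] <- 2L
      # M2 persist for a fixed resolution phase (small spread): the
      # anti-inflammatory era ends ~m2_lifespan_h after the switch, which
      # pins the IGF-1/TGF-beta signalling window
      state$m_death[m1] <- t + cfg$m2_lifespan_h + runif(sum(m1), 0, 6)
      state$ever_AM <- TRUE
    }
  }
  if (m > 0) {
    engaged <- state$damage_seen &&
      (t - state$damage_tick) >= cfg$macrophage_delay_h &&
      ((t - state$damage_tick) <= cfg$inflammation_resolution_h ||
         length(dmg) <= cfg$chronic_debris)
    is_m1 <- state$m_phen == 1L
    if (engaged && length(dmg) && any(is_m1)) {
      if (!state$m_clocked) {
        # engagement starts the resident M1 lifespan clocks (founders are
        # not consumed while waiting out the infiltration delay)
        state$m_death[is_m1] <- t + rexp(sum(is_m1), 1 / cfg$m1_lifespan_h)
        state$m_clocked <- TRUE
      }
      # act first: M1 touching a damaged object phagocytose in place, each
      # claiming its own damaged pixel
      m1_idx <- which(is_m1)
      tgt <- rep(NA_integer_, m)
      tgt[m1_idx] <- match_contacts(state$m_x[m1_idx], state$m_y[m1_idx],
                                    state$damaged, H, W)
      in_contact <- !is.na(tgt)
      # recruitment: a baseline monocyte influx while damage persists plus
      # phagocytosis-driven proliferation, jointly ceiling-limited; new M1
      # extravasate at random ECM sites
      if ((t - state$damage_tick) <= cfg$macrophage_window_h) {
        k <- min(cfg$macrophage_influx +
                   sum(runif(sum(in_contact)) < cfg$macrophage_spawn_p),
                 cfg$macrophage_recruit_max,
                 cfg$macrophage_cap - length(state$m_x))
        if (k > 0) {
          sp <- recruit_positions(state, k)
          state$m_x <- c(state$m_x, sp$x)
          state$m_y <- c(state$m_y, sp$y)
          state$m_phen <- c(state$m_phen, rep(1L, k))
          state$m_death <- c(state$m_death, t + rexp(k, 1 / cfg$m1_lifespan_h))
        }
      }
      if (any(in_contact)) {
        px <- tgt[in_contact] # distinct pixels by construction
        state$needs_repair[px] <- TRUE
        cpx <- px[runif(length(px)) < cfg$macrophage_clear_p]
        clear_pixels(state, cpx)
      }
      # all M1 take an angular step toward remaining damage; M2 wander
      m1i <- which(is_m1)
      if (any(state$damaged) && length(m1i)) {
        dt <- dist4(state$damaged)
        mv <- dt_step(dt, state$m_x[m1i], state$m_y[m1i], cfg$m_speed, W, H)
        state$m_x[m1i] <- mv$x; state$m_y[m1i] <- mv$y
      }
      m2 <- which(!is_m1)
      if (length(m2)) {
        rw <- random_walk(state$m_x[m2], state$m_y[m2], W, H)
        state$m_x[m2] <- rw$x; state$m_y[m2] <- rw$y
      }
    } else {
      # pre-engagement (or no damage): climb the local IL-6 field if any,
      # otherwise random walk
      mv <- il6_argmax_step(state$cy$local$IL6, state$m_x, state$m_y, W, H)
      state$m_x <- mv$x; state$m_y <- mv$y
    }
  }
  keep <- state$m_death > t
  if (!all(keep)) {
    state$m_x <- state$m_x[keep]; state$m_y <- state$m_y[keep]
    state$m_phen <- state$m_phen[keep]; state$m_death <- state$m_death[keep]
  }
  invisible()
}

#' Satellite-cell division probability chain
#'
#' The chance of division decreases 20% after each of the first three
#' divisions and 40% at the fourth and later:
#' `p(d) = base_p * 0.8^min(d, 3) * (0.6 if d >= 4 else 1)`.
#'
#' @param d Completed divisions (vectorised).
#' @param base_p Base division probability per eligible hour.
#' @return Division probabilities.
#' @export
sc_division_prob <- function(d, base_p) {
  base_p * 0.8^pmin(d, 3) * ifelse(d >= 4, 0.6, 1)
}

satellite_step <- function(state, t) {
  cfg <- state$cfg
  H <- state$H; W <- state$W
  ns <- length(state$s_x)
  # myoblast expiry
  bkeep <- state$b_death > t
  if (!all(bkeep)) {
    state$b_x <- state$b_x[bkeep]; state$b_y <- state$b_y[bkeep]
    state$b_death <- state$b_death[bkeep]
  }
  if (ns == 0) return(invisible())
  # activation requires HGF (released by damaged ECM)
  if (state$cy$pools[["HGF"]] > cfg$hgf_threshold) {
    q <- state$s_state == 0L
    state$s_state[q] <- 1L
    state$s_age[q] <- 0L
  }
  active <- state$s_state == 1L
  state$s_age[active] <- state$s_age[active] + 1L
  igf_up <- gradient_positive(state$cy, "IGF1")

  repaired_any <- rep(FALSE, ns)
  if (any(active)) {
    # repair passes: each adjacent active SC restores up to
    # sc_repairs_per_tick cleared fibril pixels (myoblast fusion), working
    # in place; the repairable mask is refreshed between passes
    for (pass in seq_len(cfg$sc_repairs_per_tick)) {
      repairable <- state$needs_repair & state$label == EMPTY_CODE &
        is_fibril(state$owner)
      if (!any(repairable)) break
      tgt <- rep(NA_integer_, ns)
      tgt[active] <- match_contacts(state$s_x[active], state$s_y[active],
                                    repairable, H, W, moore = TRUE)
      cand <- which(!is.na(tgt) & runif(ns) < cfg$sc_repair_p)
      if (!length(cand)) break
      px <- tgt[cand] # distinct by construction
      n_mb <- length(state$b_x)
      n_fix <- if (cfg$repair_requires_myoblast) min(length(px), n_mb) else length(px)
      if (n_fix == 0) break
      px <- px[seq_len(n_fix)]
      state$label[px] <- state$owner[px]
      state$needs_repair[px] <- FALSE
      repaired_any[cand] <- TRUE
      used <- min(n_fix, n_mb) # fusion consumes myoblasts FIFO
      if (used > 0) {
        state$b_x <- state$b_x[-seq_len(used)]
        state$b_y <- state$b_y[-seq_len(used)]
        state$b_death <- state$b_death[-seq_len(used)]
      }
    }
    # active SCs migrate along the remaining repair sites
    repairable <- state$needs_repair & state$label == EMPTY_CODE &
      is_fibril(state$owner)
    acti <- which(active)
    if (any(repairable) && length(acti)) {
      mv <- dt_step(dist4(repairable), state$s_x[acti], state$s_y[acti],
                    cfg$sc_speed, W, H)
      state$s_x[acti] <- mv$x; state$s_y[acti] <- mv$y
    }
  }
  # division
  active <- state$s_state == 1L
  if (igf_up && any(active)) {
    eligible <- active & state$s_age >= cfg$sc_division_min_age_h
    p <- sc_division_prob(state$s_div, cfg$sc_division_base_p)
    div <- which(eligible & runif(ns) < p)
    if (length(div)) {
      type <- sample(c("sym_sc", "sym_mb", "asym"), length(div),
                     replace = TRUE, prob = cfg$sc_division_probs)
      state$s_div[div] <- state$s_div[div] + 1L
      # daughters disperse to border fibrils (transit-amplifying progeny
      # circulate along the basal lamina rather than stacking on the parent)
      border <- border_fibrils(state)
      daughter_pos <- function(k) {
        if (!length(border)) {
          list(x = integer(0), y = integer(0))
        } else {
          px <- border[sample.int(length(border), k, replace = TRUE)]
          list(x = (px - 1L) %/% H, y = (px - 1L) %% H)
        }
      }
      sym_sc <- div[type == "sym_sc"]
      if (length(sym_sc)) { # two active SCs
        dp <- daughter_pos(length(sym_sc))
        state$s_x <- c(state$s_x, dp$x)
        state$s_y <- c(state$s_y, dp$y)
        state$s_state <- c(state$s_state, rep(1L, length(dp$x)))
        state$s_div <- c(state$s_div, state$s_div[sym_sc][seq_along(dp$x)])
        state$s_age <- c(state$s_age, rep(0L, length(dp$x)))
      }
      asym <- div[type == "asym"]
      if (length(asym)) { # one active (parent) + one quiescent daughter
        dp <- daughter_pos(length(asym))
        state$s_x <- c(state$s_x, dp$x)
        state$s_y <- c(state$s_y, dp$y)
        state$s_state <- c(state$s_state, rep(0L, length(dp$x)))
        state$s_div <- c(state$s_div, state$s_div[asym][seq_along(dp$x)])
        state$s_age <- c(state$s_age, rep(0L, length(dp$x)))
      }
      sym_mb <- div[type == "sym_mb"]
      if (length(sym_mb)) { # parent differentiates into two myoblasts
        state$b_x <- c(state$b_x, rep(state$s_x[sym_mb], each = 2L))
        state$b_y <- c(state$b_y, rep(state$s_y[sym_mb], each = 2L))
        state$b_death <- c(state$b_death,
                           rep(t + cfg$myoblast_lifespan_h, 2L * length(sym_mb)))
        drop <- rep(FALSE, length(state$s_x))
        drop[sym_mb] <- TRUE
        state$s_x <- state$s_x[!drop]; state$s_y <- state$s_y[!drop]
        state$s_state <- state$s_state[!drop]
        state$s_div <- state$s_div[!drop]; state$s_age <- state$s_age[!drop]
      }
    }
  }
  # pool exit: once the IGF-1 gradient is no longer positive in the
  # post-acute phase, active SCs leave the pool under a hazard; residual
  # SCs linger longer (gentler hazard) once all repair work is done
  if (!igf_up && state$damage_seen &&
      (t - state$damage_tick) >= cfg$sc_exit_after_h) {
    work_left <- any(state$damaged) ||
      any(state$needs_repair & state$label == EMPTY_CODE & is_fibril(state$owner))
    p_exit <- if (work_left) cfg$sc_exit_p else cfg$sc_exit_post_p
    ns2 <- length(state$s_x)
    out <- state$s_state == 1L & runif(ns2) < p_exit
    if (any(out)) {
      state$s_x <- state$s_x[!out]; state$s_y <- state$s_y[!out]
      state$s_state <- state$s_state[!out]
      state$s_div <- state$s_div[!out]; state$s_age <- state$s_age[!out]
    }
  }
  invisible()
}

fibroblast_step <- function(state, t) {
  cfg <- state$cfg
  nf <- length(state$f_x)
  if (nf == 0) return(invisible())
  H <- state$H; W <- state$W
  if (gradient_positive(state$cy, "TGFb")) state$f_act[] <- TRUE
  empty_idx <- which(state$label == EMPTY_CODE & state$owner != EMPTY_CODE)
  if (!length(empty_idx)) {
    mv <- random_walk(state$f_x, state$f_y, W, H)
    state$f_x <- mv$x; state$f_y <- mv$y
    return(invisible())
  }
  sc_total <- length(state$s_x)
  fallback <- sc_total == 0L
  if (!fallback) {
    # collagen deposition targets cleared ECM-owned pixels at ECM edges
    ecm_adj <- matrix(FALSE, H, W)
    ecm <- state$label == ECM_CODE
    ecm_adj[-H, ] <- ecm_adj[-H, ] | ecm[-1, ]
    ecm_adj[-1, ] <- ecm_adj[-1, ] | ecm[-H, ]
    ecm_adj[, -W] <- ecm_adj[, -W] | ecm[, -1]
    ecm_adj[, -1] <- ecm_adj[, -1] | ecm[, -W]
    cand_mask <- state$label == EMPTY_CODE & state$owner == ECM_CODE & ecm_adj
  } else {
    cand_mask <- state$label == EMPTY_CODE & state$owner != EMPTY_CODE
  }
  cand_idx <- which(cand_mask)
  act <- which(state$f_act)
  if (length(cand_idx) && length(act)) {
    mv <- beeline(state$f_x[act], state$f_y[act],
                  (cand_idx - 1L) %/% H, (cand_idx - 1L) %% H,
                  cfg$fb_speed, W, H)
    state$f_x[act] <- mv$x; state$f_y[act] <- mv$y
    if (!fallback) {
      tgt <- contact_pixel_moore(state$f_x[act], state$f_y[act], cand_mask, H, W)
      dep <- !is.na(tgt) & runif(length(act)) < cfg$fb_deposit_p
      px <- unique(tgt[dep])
      if (length(px)) {
        state$label[px] <- ECM_CODE
        state$owner[px] <- ECM_CODE
        state$collagen[px] <- 1.0
        state$needs_repair[px] <- FALSE
      }
      # collagen competition: myofibroblasts occasionally claim cleared
      # fibril-owned pixels at ECM edges before myoblasts reach them, so
      # longer repair phases lose more fiber territory to matrix
      if (cfg$fb_claim_fibril_p > 0) {
        fib_mask <- state$label == EMPTY_CODE & is_fibril(state$owner) & ecm_adj
        if (any(fib_mask)) {
          tgt2 <- contact_pixel_moore(state$f_x[act], state$f_y[act], fib_mask, H, W)
          claim <- !is.na(tgt2) & runif(length(act)) < cfg$fb_claim_fibril_p
          px2 <- unique(tgt2[claim])
          if (length(px2)) {
            state$label[px2] <- ECM_CODE
            state$owner[px2] <- ECM_CODE
            state$collagen[px2] <- 1.0
            state$needs_repair[px2] <- FALSE
          }
        }
      }
    } else {
      # fibrosis fallback: with no SCs left in the muscle, fibroblasts fill
      # any remaining cleared space (including former fibril space)
      k <- min(length(cand_idx), length(act) * cfg$fb_fallback_rate)
      if (k > 0) {
        px <- sort(cand_idx)[seq_len(k)]
        state$label[px] <- ECM_CODE
        state$owner[px] <- ECM_CODE
        state$collagen[px] <- 1.0
        state$needs_repair[px] <- FALSE
      }
    }
  } else {
    mv <- random_walk(state$f_x, state$f_y, W, H)
    state$f_x <- mv$x; state$f_y <- mv$y
  }
  invisible()
}

hypertrophy_step <- function(state, t) {
  cfg <- state$cfg
  if (!state$damage_seen) return(invisible())
  n_act <- sum(state$s_state == 1L)
  if (n_act == 0) return(invisible())
  # border re-formation / hypertrophy only after the injury is resolved:
  # all damaged objects cleared and every repairable site either repaired
  # or fibrosed (or the count already restored)
  if (any(state$damaged)) return(invisible())
  repairable <- any(state$needs_repair & state$label == EMPTY_CODE &
                      is_fibril(state$owner))
  fib_count <- sum(is_fibril(state$label))
  if (repairable && fib_count < state$initial_fibrils) return(invisible())
  k <- stats::rbinom(1L, min(n_act, cfg$hypertrophy_sc_cap), cfg$hypertrophy_p)
  if (k == 0) return(invisible())
  H <- state$H; W <- state$W
  label <- state$label
  # border ECM pixels adjacent to exactly one fiber, interior to the canvas
  ecm_idx <- which(label == ECM_CODE)
  if (!length(ecm_idx)) return(invisible())
  nb <- vn_neighbors(ecm_idx, H, W)
  nb_lab <- vapply(nb, function(d) {
    out <- rep(-1L, length(d))
    out[!is.na(d)] <- label[d[!is.na(d)]]
    out
  }, integer(length(ecm_idx)))
  if (is.null(dim(nb_lab))) nb_lab <- matrix(nb_lab, nrow = 1L)
  fib_nb <- nb_lab
  fib_nb[!(fib_nb >= 1L & fib_nb < ECM_CODE)] <- 0L
  n_ids <- apply(fib_nb, 1L, function(v) length(unique(v[v > 0L])))
  interior <- rowSums(nb_lab == -1L | nb_lab == EMPTY_CODE) == 0
  cand <- which(n_ids == 1L & interior)
  if (!length(cand)) return(invisible())
  pick <- cand[sample.int(length(cand), min(k, length(cand)))]
  added <- 0L
  for (j in pick) {
    px <- ecm_idx[j]
    fid <- fib_nb[j, ][fib_nb[j, ] > 0L][1L]
    nbp <- vn_neighbors(px, H, W)
    nbl <- state$label[unlist(nbp)[!is.na(unlist(nbp))]]
    # septum guard: never place a fibril 4-adjacent to a different fiber
    if (any(nbl >= 1L & nbl < ECM_CODE & nbl != fid)) next
    state$label[px] <- fid
    state$owner[px] <- fid
    state$collagen[px] <- 0
    added <- added + 1L
  }
  invisible()
}

# --- Tick driver ------------------------------------------------------------

#' Advance a simulation by one tick
#'
#' Applies the fixed update order (cytokines, neutrophils, macrophages,
#' satellite cells, fibroblasts, border/hypertrophy) and logs the census.
#'
#' @param state A `sim_state` from [sim_init()].
#' @return The state, invisibly (modified in place).
#' @export
sim_step <- function(state) {
  t <- state$tick + 1L
  with_state_rng(state, {
    # the census entering the cytokine update is last tick's post-step
    # census (cached by the previous call)
    cen <- state$cen_cache %||% sim_census(state)
    # local-field diffusion matters only while macrophages can read it
    diff_w <- if (length(state$m_x)) state$cfg$il6_diffusion else 0
    state$cy <- cytokines_update(state$cy, cen, dt_hours = 1,
                                 decay = state$cfg$cytokine_decay,
                                 diffusion = diff_w)
    neutrophil_step(state, t)
    macrophage_step(state, t)
    satellite_step(state, t)
    fibroblast_step(state, t)
    hypertrophy_step(state, t)
  })
  state$tick <- t
  cen_post <- sim_census(state)
  state$cen_cache <- cen_post
  if (t + 1L <= nrow(state$log)) {
    state$log[t + 1L, ] <- unlist(cen_post)[CENSUS_COLS]
  }
  invisible(state)
}

# TRUE when nothing can change the grid or census any more: no damage, no
# cleared tissue, and no mobile agents except (immortal) fibroblasts with
# nothing to deposit.
sim_quiescent <- function(state) {
  length(state$n_x) == 0L && length(state$m_x) == 0L &&
    length(state$s_x) == 0L && length(state$b_x) == 0L &&
    !any(state$damaged) &&
    !any(state$label == EMPTY_CODE & state$owner != EMPTY_CODE)
}
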