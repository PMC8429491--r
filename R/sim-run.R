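# Whole-run drivers and census time-series metrics.

#' Seed strain-based damage into a grid
#'
#' Computes a strain field (surrogate by default, or an imported field),
#' selects the highest-strain fibril pixels as damage seeds, expands them
#' into a necrosis halo, and applies the marks.
#'
#' @param grid A `tissue_grid`.
#' @param config A [sim_config()].
#' @param seed Integer seed (strain noise and random damage mode).
#' @param p_fiber,p_ecm Material parameters for the surrogate.
#' @param field Optional pre-computed `strain_field` (e.g. imported); when
#'   supplied the surrogate is skipped.
#' @return A list: `grid` (damaged), `field`, `seeds`, `halo`.
#' @export
seed_damage <- function(grid, config = sim_config(), seed = 1,
                        p_fiber = fiber_params(), p_ecm = ecm_params(),
                        field = NULL) {
  if (config$damage_fraction == 0) {
    return(list(grid = grid, field = field,
                seeds = tibble::tibble(x = integer(0), y = integer(0)),
                halo = tibble::tibble(x = integer(0), y = integer(0),
                                      type = character(0))))
  }
  if (config$damage_mode == "random") {
    seeds <- damage_random(grid, config$damage_fraction, seed)
  } else {
    if (is.null(field)) {
      field <- strain_surrogate(grid, stretch = config$stretch,
                                p_fiber = p_fiber, p_ecm = p_ecm, seed = seed)
    }
    seeds <- damage_select(field, grid, config$damage_fraction)
  }
  halo <- damage_expand(grid, seeds)
  grid <- apply_damage(grid, halo, config$collagen_damaged)
  list(grid = grid, field = field, seeds = seeds, halo = halo)
}

#' Run one regeneration simulation
#'
#' Seeds damage on the grid (unless `damage_fraction` is 0), initializes the
#' agents and advances `config$ticks` hourly ticks. Deterministic for a
#' fixed seed.
#'
#' @param grid An undamaged `tissue_grid`.
#' @param config A [sim_config()].
#' @param seed Integer seed covering strain noise, agent placement and all
#'   per-tick stochasticity.
#' @param p_fiber,p_ecm Material parameters for the strain surrogate.
#' @param field Optional externally computed `strain_field`.
#' @return A `regen_sim`: list with `census` (tibble, one row per tick
#'   including tick 0), `grid` (endpoint `tissue_grid`), `initial_fibrils`,
#'   `clearance_time_h`, `repair_complete_time_h`, `config`, `seed`.
#' @export
simulate_regeneration <- function(grid, config = sim_config(), seed = 1,
                                  p_fiber = fiber_params(),
                                  p_ecm = ecm_params(), field = NULL) {
  dmg <- seed_damage(grid, config, seed, p_fiber, p_ecm, field)
  state <- sim_init(dmg$grid, config, seed)
  for (t in seq_len(config$ticks)) {
    sim_step(state)
    # once fully quiescent the remaining census rows are constant: fill
    # them and stop stepping (the grid can no longer change)
    if (t < config$ticks && t %% 8L == 0L && sim_quiescent(state)) {
      rows <- (t + 2L):(config$ticks + 1L)
      last <- state$log[t + 1L, ]
      state$log[rows, ] <- matrix(last, length(rows), length(last), byrow = TRUE)
      state$log[rows, "tick"] <- (t + 1L):config$ticks
      state$tick <- config$ticks
      break
    }
  }
  census <- tibble::as_tibble(as.data.frame(state$log))
  structure(
    list(
      census = census,
      grid = sim_grid(state),
      initial_fibrils = state$initial_fibrils,
      clearance_time_h = clearance_time(census),
      repair_complete_time_h = repair_time(census, state$initial_fibrils),
      config = config,
      seed = seed
    ),
    class = "regen_sim"
  )
}

#' @export
print.regen_sim <- function(x, ...) {
  endpoint <- tail(x$census, 1)
  cat(sprintf(
    "<regen_sim> %d ticks | fibrils %d -> %d | clearance %s h, repair %s h\n",
    max(x$census$tick), x$initial_fibrils, endpoint$fibril_count,
    format(x$clearance_time_h), format(x$repair_complete_time_h)
  ))
  invisible(x)
}

#' @exportS3Method
#' @export
tidy.regen_sim <- function(x, ...) x$census

#' @exportS3Method
#' @export
glance.regen_sim <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(initial_fibrils = x$initial_fibrils,
                   clearance_time_h = x$clearance_time_h,
                   repair_complete_time_h = x$repair_complete_time_h,
                   seed = x$seed),
    tg_composition(x$grid)
  )
}

#' Run replicate simulations
#'
#' Runs `n` independent replicates with distinct child seeds drawn from the
#' master seed; both strain noise and agent placement are re-sampled per
#' replicate.
#'
#' @inheritParams simulate_regeneration
#' @param n Number of replicates.
#' @param keep_grids Keep endpoint grids (needed for representative-geometry
#'   selection in coupled runs).
#' @return A `regen_replicates`: `census` (long tibble with `rep` column),
#'   `endpoints` (per-replicate endpoint composition and timing metrics),
#'   `grids` (list or NULL), `initial_fibrils`, `config`.
#' @export
simulate_replicates <- function(grid, config = sim_config(), n = config$replicates,
                                seed = 1, p_fiber = fiber_params(),
                                p_ecm = ecm_params(), keep_grids = FALSE) {
  seeds <- child_seeds(seed, n)
  runs <- lapply(seq_len(n), function(i) {
    simulate_regeneration(grid, config, seed = seeds[i],
                          p_fiber = p_fiber, p_ecm = p_ecm)
  })
  census <- dplyr::bind_rows(
    purrr::imap(runs, ~ dplyr::mutate(.x$census, rep = .y, .before = 1))
  )
  endpoints <- purrr::imap_dfr(runs, function(r, i) {
    dplyr::bind_cols(
      tibble::tibble(rep = i, seed = r$seed,
                     clearance_time_h = r$clearance_time_h,
                     repair_complete_time_h = r$repair_complete_time_h),
      tg_composition(r$grid)
    )
  })
  structure(
    list(
      census = census,
      endpoints = endpoints,
      grids = if (keep_grids) lapply(runs, `[[`, "grid"),
      initial_fibrils = runs[[1]]$initial_fibrils,
      config = config,
      seed = seed
    ),
    class = "regen_replicates"
  )
}

#' @export
print.regen_replicates <- function(x, ...) {
  cat(sprintf(
    "<regen_replicates> %d replicates | initial fibrils %d | endpoint %.1f +/- %.1f\n",
    nrow(x$endpoints), x$initial_fibrils,
    mean(x$endpoints$fibril_count), sd(x$endpoints$fibril_count)
  ))
  invisible(x)
}

#' @exportS3Method
#' @export
tidy.regen_replicates <- function(x, ...) x$census

#' @exportS3Method
#' @export
glance.regen_replicates <- function(x, ...) {
  tibble::tibble(
    n_replicates = nrow(x$endpoints),
    initial_fibrils = x$initial_fibrils,
    fibril_mean = mean(x$endpoints$fibril_count),
    fibril_sd = sd(x$endpoints$fibril_count),
    ecm_mean = mean(x$endpoints$ecm_count),
    ecm_sd = sd(x$endpoints$ecm_count),
    muscle_fraction_mean = mean(x$endpoints$muscle_fraction),
    ecm_fraction_mean = mean(x$endpoints$ecm_fraction),
    clearance_time_mean_h = mean(x$endpoints$clearance_time_h),
    repair_complete_mean_h = mean(x$endpoints$repair_complete_time_h)
  )
}

#' Replicate-mean census time course
#'
#' @param x A `regen_replicates` (or its long census tibble).
#' @return A tibble of per-tick means across replicates for every census
#'   column, plus `macrophages = PM + AM` and `SC = SC_q + SC_a`.
#' @export
census_mean <- function(x) {
  census <- if (inherits(x, "regen_replicates")) x$census else x
  census |>
    dplyr::group_by(.data$tick) |>
    dplyr::summarise(dplyr::across(-dplyr::any_of("rep"), mean),
                     .groups = "drop") |>
    dplyr::mutate(macrophages = .data$PM + .data$AM,
                  SC = .data$SC_q + .data$SC_a)
}

# --- Time-series metrics ----------------------------------------------------

#' Damaged-fibril clearance time of a census
#'
#' @param census A census tibble (one run).
#' @return First tick (>= 1) at which the damaged-fibril count reaches zero,
#'   or `NA` if damage never occurred or never cleared.
#' @export
clearance_time <- function(census) {
  if (max(census$DF) == 0) return(NA_real_)
  hit <- which(census$tick >= 1 & census$DF == 0)
  if (!length(hit)) return(NA_real_)
  census$tick[hit[1]]
}

#' Fibril repair-completion time of a census
#'
#' @param census A census tibble (one run).
#' @param initial Pre-injury fibril count.
#' @return First tick (>= 1) at which the fibril count is restored to the
#'   pre-injury level, or `NA` if never (damage-free runs return `NA`).
#' @export
repair_time <- function(census, initial) {
  if (max(census$DF) == 0) return(NA_real_)
  low <- which(census$fibril_count < initial)
  if (!length(low)) return(NA_real_) # clearance never removed a fibril
  hit <- which(census$tick > census$tick[low[1]] & census$fibril_count >= initial)
  if (!length(hit)) return(NA_real_)
  census$tick[hit[1]]
}

#' Peak tick of a census column
#'
#' @param mean_census Tibble from [census_mean()].
#' @param col Column name.
#' @return Tick at which the replicate-mean series attains its maximum
#'   (first tick on ties).
#' @export
peak_tick <- function(mean_census, col) {
  mean_census$tick[which.max(mean_census[[col]])]
}

#' Decline onset of a census column
#'
#' Smooths the replicate-mean series with a centered rolling mean, locates
#' its global maximum, and returns the first later tick at which the
#' smoothed series strictly decreases.
#'
#' @param mean_census Tibble from [census_mean()].
#' @param col Column name (e.g. `"SC"`).
#' @param window Rolling-mean window (ticks, odd).
#' @return Tick of decline onset (`NA` if the series never declines).
#' @export
decline_onset <- function(mean_census, col, window = 9) {
  v <- mean_census[[col]]
  sm <- roll_mean(v, window)
  mx <- which.max(sm)
  if (mx >= length(sm)) return(NA_real_)
  later <- (mx + 1L):length(sm)
  dec <- later[sm[later] < sm[later - 1L]]
  if (!length(dec)) return(NA_real_)
  mean_census$tick[dec[1]]
}

# Centered rolling mean with partial windows at the edges.
roll_mean <- function(v, window) {
  half <- (window - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
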