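# Experiment drivers: damage and satellite-cell sweeps, material
# sensitivity of the strain surrogate, and report summaries.
#
# Sweeps use common random numbers: every level runs the same vector of
# replicate child seeds, a paired design that sharpens ordering
# comparisons between levels.

#' Damage-level sweep
#'
#' Runs replicate simulations at each seeded damage fraction and
#' summarises endpoint fibril counts, clearance success and timing.
#'
#' @param grid Undamaged `tissue_grid`.
#' @param config A [sim_config()] (its `damage_fraction` is overridden).
#' @param fractions Damage fractions to sweep.
#' @param replicates Replicates per level.
#' @param seed Master seed (shared across levels).
#' @param p_fiber,p_ecm Constitutive parameters for the surrogate.
#' @return A tibble, one row per fraction: endpoint fibril mean/sd,
#'   endpoint ECM mean, residual damaged fibrils, clearance success
#'   fraction and mean clearance/repair times.
#' @export
sweep_damage <- function(grid, config = sim_config(),
                         fractions = c(0, 0.05, 0.10, 0.15, 0.20),
                         replicates = config$replicates, seed = 1,
                         p_fiber = fiber_params(), p_ecm = ecm_params()) {
  stopifnot(all(fractions >= 0 & fractions <= 1))
  purrr::map_dfr(fractions, function(f) {
    cfg <- config
    cfg$damage_fraction <- f
    reps <- simulate_replicates(grid, cfg, n = replicates, seed = seed,
                                p_fiber = p_fiber, p_ecm = p_ecm)
    final_df <- reps$census |>
      dplyr::filter(.data$tick == max(.data$tick)) |>
      dplyr::pull("DF")
    tibble::tibble(
      damage_fraction = f,
      initial_fibrils = reps$initial_fibrils,
      fibril_mean = mean(reps$endpoints$fibril_count),
      fibril_sd = sd(reps$endpoints$fibril_count),
      ecm_mean = mean(reps$endpoints$ecm_count),
      residual_damaged_mean = mean(final_df),
      clearance_success = mean(!is.na(reps$endpoints$clearance_time_h)),
      clearance_time_mean_h = mean(reps$endpoints$clearance_time_h, na.rm = TRUE),
      repair_complete_mean_h = mean(reps$endpoints$repair_complete_time_h, na.rm = TRUE)
    )
  })
}

#' Satellite-cell count sweep
#'
#' Runs replicate simulations at fixed initial SC counts (overriding the
#' density formula) and summarises endpoint recovery.
#'
#' @inheritParams sweep_damage
#' @param sc_counts Initial SC counts to sweep.
#' @return A tibble, one row per SC count: endpoint fibril mean/sd,
#'   recovery fraction (replicates that restored the pre-injury count) and
#'   mean recovery time (`Inf` if no replicate recovered).
#' @export
sweep_sc <- function(grid, config = sim_config(),
                     sc_counts = c(4, 5, 7, 10, 13),
                     replicates = config$replicates, seed = 1,
                     p_fiber = fiber_params(), p_ecm = ecm_params()) {
  stopifnot(all(sc_counts >= 0))
  purrr::map_dfr(sc_counts, function(k) {
    cfg <- config
    cfg$sc_count <- as.integer(k)
    reps <- simulate_replicates(grid, cfg, n = replicates, seed = seed,
                                p_fiber = p_fiber, p_ecm = p_ecm)
    rec <- reps$endpoints$repair_complete_time_h
    tibble::tibble(
      sc_count = k,
      initial_fibrils = reps$initial_fibrils,
      fibril_mean = mean(reps$endpoints$fibril_count),
      fibril_sd = sd(reps$endpoints$fibril_count),
      ecm_mean = mean(reps$endpoints$ecm_count),
      recovered = mean(!is.na(rec)),
      recovery_time_mean_h = if (all(is.na(rec))) Inf else mean(rec, na.rm = TRUE)
    )
  })
}

#' Material-parameter sensitivity of the surrogate strain field
#'
#' Perturbs each constitutive parameter by `+/- delta` in both materials
#' (paired noise: the same seed, hence identical lognormal draws) and
#' reports the percent change in the maximum and minimum fibril strain.
#'
#' @param grid A `tissue_grid`.
#' @param p_fiber,p_ecm Baseline `constitutive_params`.
#' @param delta Relative perturbation (default 0.10).
#' @param stretch Imposed stretch.
#' @param seed Noise seed (shared across evaluations).
#' @param parameters Parameters to perturb.
#' @return A tibble with one row per (parameter, direction): the perturbed
#'   input value and percent changes in max/min strain.
#' @export
material_sensitivity <- function(grid, p_fiber = fiber_params(),
                                 p_ecm = ecm_params(), delta = 0.10,
                                 stretch = 0.30, seed = 1,
                                 parameters = c("c1", "c3", "c4", "c5", "K", "density")) {
  base <- strain_surrogate(grid, stretch, p_fiber, p_ecm, seed = seed)
  v <- base$values[!is.na(base$values)]
  base_max <- max(v); base_min <- min(v)
  perturb <- function(p, name, fac) {
    args <- unclass(p)[c("c1", "c2", "c3", "c4", "c5", "K", "lambda_m", "density")]
    args[[name]] <- args[[name]] * fac
    do.call(constitutive_params, args)
  }
  purrr::map_dfr(parameters, function(par) {
    purrr::map_dfr(c(1 + delta, 1 - delta), function(fac) {
      f2 <- strain_surrogate(grid, stretch,
                             perturb(p_fiber, par, fac),
                             perturb(p_ecm, par, fac), seed = seed)
      v2 <- f2$values[!is.na(f2$values)]
      tibble::tibble(
        parameter = par,
        model_value = unclass(p_fiber)[[par]],
        input_value = unclass(p_fiber)[[par]] * fac,
        pct_change_max_strain = 100 * (max(v2) - base_max) / base_max,
        pct_change_min_strain = 100 * (min(v2) - base_min) / base_min
      )
    })
  })
}

#' Summarise iteration results into report tables
#'
#' Recomputes mean +/- SD summaries from the raw per-replicate records of
#' one or more iteration results and assembles report tables for census
#' trajectories, endpoint composition, and timing.
#'
#' @param results A `regen_iteration`/`regen_replicates`, a
#'   `regen_coupled`, or a list of such objects.
#' @return A list of tibbles: `summary` (per iteration), `trajectories`
#'   (replicate-mean census per tick), `endpoints` (raw per-replicate
#'   endpoint records).
#' @export
summarize_runs <- function(results) {
  items <- if (inherits(results, "regen_coupled")) {
    results$iterations
  } else if (inherits(results, "regen_replicates")) {
    list(results)
  } else {
    as.list(results)
  }
  if (!length(items)) {
    return(list(summary = tibble::tibble(), trajectories = tibble::tibble(),
                endpoints = tibble::tibble()))
  }
  summary <- purrr::imap_dfr(items, function(it, i) {
    iter <- it$iteration %||% i
    ep <- it$endpoints
    tibble::tibble(
      iteration = iter,
      n_replicates = nrow(ep),
      initial_fibrils = it$initial_fibrils,
      fibril_mean = mean(ep$fibril_count), fibril_sd = sd(ep$fibril_count),
      ecm_mean = mean(ep$ecm_count), ecm_sd = sd(ep$ecm_count),
      muscle_fraction_mean = mean(ep$muscle_fraction),
      ecm_fraction_mean = mean(ep$ecm_fraction),
      mean_fiber_csa = mean(ep$mean_fiber_csa),
      clearance_time_mean_h = mean(ep$clearance_time_h, na.rm = TRUE),
      repair_complete_time_mean_h = mean(ep$repair_complete_time_h, na.rm = TRUE)
    )
  })
  trajectories <- purrr::imap_dfr(items, function(it, i) {
    dplyr::mutate(census_mean(it), iteration = it$iteration %||% i, .before = 1)
  })
  endpoints <- purrr::imap_dfr(items, function(it, i) {
    dplyr::mutate(it$endpoints, iteration = it$iteration %||% i, .before = 1)
  })
  list(summary = summary, trajectories = trajectories, endpoints = endpoints)
}

#' Write report tables and a run manifest to a directory
#'
#' @param results As for [summarize_runs()].
#' @param dir Output directory (created if needed).
#' @param config Optional `sim_config` recorded in the manifest.
#' @param seed Optional master seed recorded in the manifest.
#' @return The directory path, invisibly.
#' @export
write_report <- function(results, dir, config = NULL, seed = NULL) {
  rep <- summarize_runs(results)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(rep$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(rep$trajectories, file.path(dir, "trajectories.csv"), row.names = FALSE)
  write.csv(rep$endpoints, file.path(dir, "endpoints.csv"), row.names = FALSE)
  manifest <- c(
    sprintf("written: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (!is.null(seed)) sprintf("seed: %s", seed),
    if (!is.null(config)) {
      flat <- unlist(unclass(config))
      sprintf("%s: %s", names(flat), as.character(flat))
    }
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
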