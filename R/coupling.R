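# Coupled strain -> damage -> regeneration iterations.
#
# One iteration: compute a strain field on the current geometry, seed the
# highest-strain fibrils as damage (with necrosis expansion), run replicate
# regeneration simulations, summarise, and select the representative
# endpoint geometry (the replicate whose endpoint fibril count is nearest
# the replicate mean). Repeated iterations feed each representative
# geometry into a fresh strain computation, emulating monthly bouts of
# eccentric damage; constitutive parameters are held fixed across
# iterations and between the TD and CP milieus.

#' Run one damage-regeneration iteration
#'
#' @param grid Undamaged `tissue_grid` for this iteration.
#' @param config A [sim_config()].
#' @param replicates Number of replicate simulations.
#' @param seed Master seed; replicate child seeds derive from it.
#' @param p_fiber,p_ecm Constitutive parameters for the strain surrogate.
#' @param strain_table Optional path to an external strain CSV (see
#'   [strain_import()]); replaces the surrogate.
#' @param iteration Iteration index recorded in the result.
#' @return A `regen_iteration`: the `regen_replicates` fields plus
#'   `iteration`, `grid` (representative endpoint), `representative`
#'   (replicate index), and a one-row `summary` tibble.
#' @export
run_iteration <- function(grid, config = sim_config(),
                          replicates = config$replicates, seed = 1,
                          p_fiber = fiber_params(), p_ecm = ecm_params(),
                          strain_table = NULL, iteration = 1L) {
  if (!is.null(strain_table)) {
    field <- strain_import(strain_table, grid)
    seeds <- child_seeds(seed, replicates)
    runs <- lapply(seq_len(replicates), function(i) {
      simulate_regeneration(grid, config, seed = seeds[i],
                            p_fiber = p_fiber, p_ecm = p_ecm, field = field)
    })
    reps <- collect_replicates(runs, config, seed, keep_grids = TRUE)
  } else {
    reps <- simulate_replicates(grid, config, n = replicates, seed = seed,
                                p_fiber = p_fiber, p_ecm = p_ecm,
                                keep_grids = TRUE)
  }
  ep <- reps$endpoints$fibril_count
  # representative geometry: endpoint fibril count nearest the mean,
  # ties broken toward the lower replicate index (lower seed)
  rep_i <- which.min(abs(ep - mean(ep)))
  out <- reps
  out$iteration <- as.integer(iteration)
  out$representative <- rep_i
  out$grid <- reps$grids[[rep_i]]
  out$summary <- dplyr::bind_cols(
    tibble::tibble(iteration = as.integer(iteration)),
    glance.regen_replicates(reps)
  )
  class(out) <- c("regen_iteration", "regen_replicates")
  out
}

# Shared assembly of replicate runs (used when a fixed imported field
# bypasses simulate_replicates).
collect_replicates <- function(runs, config, seed, keep_grids = FALSE) {
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
    list(census = census, endpoints = endpoints,
         grids = if (keep_grids) lapply(runs, `[[`, "grid"),
         initial_fibrils = runs[[1]]$initial_fibrils,
         config = config, seed = seed),
    class = "regen_replicates"
  )
}

#' @export
print.regen_iteration <- function(x, ...) {
  cat(sprintf(
    "<regen_iteration %d> %d replicates | fibrils %d -> %.0f +/- %.0f (rep. %d)\n",
    x$iteration, nrow(x$endpoints), x$initial_fibrils,
    mean(x$endpoints$fibril_count), sd(x$endpoints$fibril_count),
    x$representative
  ))
  invisible(x)
}

#' @exportS3Method
#' @export
glance.regen_iteration <- function(x, ...) x$summary

#' Run coupled damage-regeneration cycles
#'
#' Iterates [run_iteration()]: each cycle's representative endpoint
#' geometry seeds the next cycle, with strain recomputed on the evolved
#' geometry. Three iterations emulate three months of monthly eccentric
#' damage bouts.
#'
#' @inheritParams run_iteration
#' @param n_iterations Number of damage-regeneration cycles.
#' @return A `regen_coupled`: list of `regen_iteration` objects plus a
#'   combined `summary` tibble.
#' @export
run_coupled <- function(grid, config = sim_config(), n_iterations = 3,
                        replicates = config$replicates, seed = 1,
                        p_fiber = fiber_params(), p_ecm = ecm_params()) {
  stopifnot(n_iterations >= 1)
  seeds <- child_seeds(seed, n_iterations)
  iterations <- vector("list", n_iterations)
  cur <- grid
  for (k in seq_len(n_iterations)) {
    if (sum(is_fibril(cur$label)) == 0) {
      warning("all fibers vanished before iteration ", k, "; stopping early")
      iterations <- iterations[seq_len(k - 1L)]
      break
    }
    lost <- sum(tabulate(cur$label[is_fibril(cur$label)], cur$n_fibers) == 0)
    if (lost > 0) {
      warning(sprintf("iteration %d starts with %d vanished fiber(s) (atrophy)",
                      k, lost))
    }
    it <- run_iteration(cur, config, replicates = replicates, seed = seeds[k],
                        p_fiber = p_fiber, p_ecm = p_ecm, iteration = k)
    iterations[[k]] <- it
    cur <- reset_grid(it$grid)
  }
  structure(
    list(iterations = iterations,
         summary = dplyr::bind_rows(lapply(iterations, `[[`, "summary")),
         config = config, seed = seed),
    class = "regen_coupled"
  )
}

# Prepare an endpoint grid to seed the next iteration: drop stale flags
# (the new bout starts from resolved tissue).
reset_grid <- function(grid) {
  grid$damaged[] <- FALSE
  grid$needs_repair[] <- FALSE
  grid
}

#' @export
print.regen_coupled <- function(x, ...) {
  cat(sprintf("<regen_coupled> %d iterations\n", length(x$iterations)))
  print(x$summary[, c("iteration", "initial_fibrils", "fibril_mean",
                      "fibril_sd", "ecm_fraction_mean")])
  invisible(x)
}

#' @exportS3Method
#' @export
tidy.regen_coupled <- function(x, ...) {
  dplyr::bind_rows(lapply(x$iterations, function(it) {
    dplyr::mutate(it$census, iteration = it$iteration, .before = 1)
  }))
}

#' @exportS3Method
#' @export
glance.regen_coupled <- function(x, ...) x$summary
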