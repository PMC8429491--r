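# ggplot2 visualisations for grids, strain fields, runs and sweeps.

#' @describeIn tg_composition Plot a tissue grid as a label raster.
#' @param object,x A `tissue_grid`.
#' @param ... Unused.
#' @exportS3Method
#' @export
autoplot.tissue_grid <- function(object, ...) {
  df <- tidy(object)
  df$class <- dplyr::case_when(
    df$label == ECM_CODE ~ "ECM",
    df$label == EMPTY_CODE ~ "cleared",
    df$damaged ~ "damaged fibril",
    TRUE ~ "fibril"
  )
  df$fiber <- ifelse(is_fibril(df$label), df$label, NA_integer_)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$fiber)),
                         data = df[df$class %in% c("fibril", "damaged fibril"), ],
                         show.legend = FALSE) +
    ggplot2::geom_raster(data = df[df$class == "ECM", ], fill = "grey85") +
    ggplot2::geom_raster(data = df[df$class == "damaged fibril", ],
                         fill = "black", alpha = 0.45) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
#' @export
autoplot.strain_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$strain)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "strain") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Census time-course plot
#'
#' Mean (and, with multiple replicates, a +/-1 SD ribbon) of selected
#' census series over time.
#'
#' @param x A `regen_sim`, `regen_replicates`, or long census tibble.
#' @param series Census columns to show.
#' @return A ggplot object.
#' @export
plot_census <- function(x, series = c("N", "PM", "AM", "SC_q", "SC_a", "DF")) {
  census <- if (inherits(x, c("regen_sim", "regen_replicates"))) tidy(x) else x
  has_reps <- "rep" %in% names(census)
  long <- census |>
    tidyr::pivot_longer(dplyr::all_of(series), names_to = "series",
                        values_to = "count")
  if (has_reps) {
    long <- long |>
      dplyr::group_by(.data$tick, .data$series) |>
      dplyr::summarise(mean = mean(.data$count), sd = sd(.data$count),
                       .groups = "drop")
    ggplot2::ggplot(long, ggplot2::aes(.data$tick, .data$mean,
                                       colour = .data$series)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd,
                                        fill = .data$series),
                           alpha = 0.15, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = "count") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$tick, .data$count,
                                       colour = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (h)", y = "count") +
      ggplot2::theme_minimal()
  }
}

#' @exportS3Method
#' @export
autoplot.regen_sim <- function(object, ...) plot_census(object)

#' @exportS3Method
#' @export
autoplot.regen_replicates <- function(object, ...) plot_census(object)

#' Fibril-count trajectories across iterations
#'
#' @param x A `regen_coupled`.
#' @return A ggplot object: replicate-mean fibril count per tick, one panel
#'   per iteration.
#' @export
plot_fibril_trajectory <- function(x) {
  stopifnot(inherits(x, "regen_coupled"))
  traj <- summarize_runs(x)$trajectories
  ggplot2::ggplot(traj, ggplot2::aes(.data$tick, .data$fibril_count)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~iteration, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (h)", y = "mean fibril count") +
    ggplot2::theme_minimal()
}

#' Sweep curve plot
#'
#' @param sweep A tibble from [sweep_damage()] or [sweep_sc()].
#' @return A ggplot object of endpoint fibril mean +/- SD against the
#'   swept variable.
#' @export
plot_sweep <- function(sweep) {
  xvar <- if ("damage_fraction" %in% names(sweep)) "damage_fraction" else "sc_count"
  ggplot2::ggplot(sweep, ggplot2::aes(.data[[xvar]], .data$fibril_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$fibril_mean - .data$fibril_sd,
      ymax = .data$fibril_mean + .data$fibril_sd
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = gsub("_", " ", xvar), y = "endpoint fibril count") +
    ggplot2::theme_minimal()
}
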