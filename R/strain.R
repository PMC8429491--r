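# Strain fields and strain-based damage.
#
# The full nonlinear equilibrium solve of an eccentrically stretched bundle
# is out of scope; its only downstream role is ranking strain across the
# section. The surrogate reproduces the two robust features of that
# ranking: (1) outer fibers -- especially corner fibers -- carry the
# highest strain, and (2) strain scales inversely with the tangent
# stiffness of the material at the working stretch (dominated by the
# along-fiber modulus c5 above the transition stretch). External strain
# tables from a finite-element solve can be imported instead.

new_strain_field <- function(values, source) {
  structure(list(values = values, source = source), class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<strain_field> %s, %d fibril px, range [%.4g, %.4g]\n",
              x$source, length(v), min(v), max(v)))
  invisible(x)
}

#' @exportS3Method
#' @export
tidy.strain_field <- function(x, ...) {
  keep <- which(!is.na(x$values))
  H <- nrow(x$values)
  out <- tibble::tibble(
    px = (keep - 1L) %/% H,
    py = (keep - 1L) %% H,
    strain = x$values[keep]
  )
  names(out)[1:2] <- c("x", "y")
  out
}

# Tangent stiffness proxy at the working stretch (> lambda_m): the linear
# fiber branch contributes c5 exactly; the Mooney-Rivlin ground substance
# contributes ~2 c1 (its linearised shear modulus scale); near
# incompressibility couples the bulk modulus in only weakly. c3, c4 and
# density do not enter above lambda_m.
tangent_stiffness <- function(p_fiber, p_ecm) {
  mean(c(p_fiber$c5, p_ecm$c5)) +
    2 * mean(c(p_fiber$c1, p_ecm$c1)) +
    0.01 * mean(c(p_fiber$K, p_ecm$K))
}

#' Surrogate per-pixel strain field for an eccentric stretch
#'
#' Assigns each fibril pixel a strain equal to the imposed stretch scaled by
#' (a) a boundary-exposure weight of its fiber (distance of the fiber
#' centroid to the bundle boundary, with corner amplification), (b) a
#' within-fiber edge weight (strain concentrates at the fiber periphery,
#' where the compliant matrix interface is), (c) a compliance weight
#' (inverse tangent stiffness at the working stretch, normalised to 1 at
#' the default material parameters), and (d) seeded multiplicative
#' lognormal noise.
#'
#' @param grid A `tissue_grid`.
#' @param stretch Imposed fiber stretch (default 0.30, i.e. 30% eccentric
#'   lengthening).
#' @param p_fiber,p_ecm `constitutive_params` for the two materials.
#' @param seed Integer seed for the noise (deterministic field per seed).
#' @param noise_sd Lognormal sigma of the multiplicative noise.
#' @param corner_amp Amplification factor for fibers near region corners.
#' @param edge_amp Within-fiber periphery amplification: pixel weight falls
#'   from 1 at the fiber boundary to `1 - edge_amp` in the deep interior.
#' @return A `strain_field` (values `NA` off fibril pixels).
#' @export
strain_surrogate <- function(grid, stretch = 0.30,
                             p_fiber = fiber_params(), p_ecm = ecm_params(),
                             seed = 1, noise_sd = 0.05, corner_amp = 0.75,
                             edge_amp = 0.5) {
  stopifnot(stretch > 0)
  label <- grid$label
  H <- nrow(label); W <- ncol(label)
  fib_idx <- which(is_fibril(label))
  if (!length(fib_idx)) stop_("grid has no fibril pixels")
  row <- ((fib_idx - 1L) %% H) + 1L
  col <- ((fib_idx - 1L) %/% H) + 1L
  fid <- label[fib_idx]

  occ <- label != EMPTY_CODE
  occ_row <- ((which(occ) - 1L) %% H) + 1L
  occ_col <- ((which(occ) - 1L) %/% H) + 1L
  rr <- range(occ_row); cc <- range(occ_col)

  cy <- tapply(row, fid, mean)
  cx <- tapply(col, fid, mean)
  ids <- as.integer(names(cy))
  d_edge <- pmin(cy - rr[1], rr[2] - cy, cx - cc[1], cc[2] - cx)
  corners <- rbind(c(rr[1], cc[1]), c(rr[1], cc[2]), c(rr[2], cc[1]), c(rr[2], cc[2]))
  d_corner <- apply(sqrt(outer(cy, corners[, 1], "-")^2 +
                           outer(cx, corners[, 2], "-")^2), 1, min)
  scale_len <- 0.15 * min(diff(rr), diff(cc)) + 1
  w_b <- exp(-d_edge / scale_len) * (1 + corner_amp * exp(-d_corner / (2 * scale_len)))
  w_b <- w_b / max(w_b)
  w_fiber <- setNames(w_b, ids)

  t_ref <- tangent_stiffness(fiber_params(), ecm_params())
  w_c <- t_ref / tangent_stiffness(p_fiber, p_ecm)

  # within-fiber periphery weighting: distance of each fibril pixel to the
  # nearest non-fibril (matrix interface) pixel
  d_iface <- dist4(!is_fibril(label))[fib_idx]
  w_px <- (1 - edge_amp) + edge_amp * exp(-(d_iface - 1) / 2)

  noise <- local_seed(seed, {
    exp(stats::rnorm(length(fib_idx), -0.5 * noise_sd^2, noise_sd))
  })
  values <- matrix(NA_real_, H, W)
  values[fib_idx] <- stretch * w_fiber[as.character(fid)] * w_px * w_c * noise
  new_strain_field(values, "surrogate")
}

#' Import an external per-element strain table
#'
#' Registers element-center strains onto the grid by nearest-pixel matching:
#' every fibril pixel receives the strain of its nearest element center
#' (Euclidean distance in grid coordinates). Pixels farther than `max_dist`
#' from any center inherit their fiber's mean mapped strain.
#'
#' @param path CSV with header `x,y,strain`; coordinates are 0-based grid
#'   coordinates (y downward), floating point allowed.
#' @param grid A `tissue_grid`.
#' @param max_dist Maximum registration distance (default `Inf`: all pixels
#'   map to the nearest center).
#' @return A `strain_field`.
#' @export
strain_import <- function(path, grid, max_dist = Inf) {
  if (!file.exists(path)) stop_("file not found: ", path)
  df <- tryCatch(read.csv(path), error = function(e)
    stop_("parse error in ", path, ": ", conditionMessage(e)))
  if (nrow(df) == 0) stop_("empty strain table: ", path)
  if (!all(c("x", "y", "strain") %in% names(df))) {
    stop_("strain table must have columns x,y,strain")
  }
  H <- nrow(grid$label); W <- ncol(grid$label)
  oob <- which(df$x < -0.5 | df$x > W - 0.5 | df$y < -0.5 | df$y > H - 0.5)
  if (length(oob)) {
    stop_("element centers outside grid bounds at record(s) ",
          paste(head(oob, 10), collapse = ", "))
  }
  fib_idx <- which(is_fibril(grid$label))
  if (!length(fib_idx)) stop_("grid has no fibril pixels")
  px <- (fib_idx - 1L) %/% H # 0-based x
  py <- (fib_idx - 1L) %% H  # 0-based y
  values <- matrix(NA_real_, H, W)
  strain <- numeric(length(fib_idx))
  mapped <- logical(length(fib_idx))
  chunk <- 4000L
  for (s in seq(1L, length(fib_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(fib_idx))
    d2 <- outer(px[s:e], df$x, "-")^2 + outer(py[s:e], df$y, "-")^2
    j <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_along(j), j)]
    strain[s:e] <- df$strain[j]
    mapped[s:e] <- sqrt(dmin) <= max_dist
  }
  if (!all(mapped)) {
    fid <- grid$label[fib_idx]
    fm <- tapply(strain[mapped], fid[mapped], mean)
    fill <- fm[as.character(fid[!mapped])]
    fill[is.na(fill)] <- mean(strain[mapped])
    strain[!mapped] <- fill
  }
  values[fib_idx] <- strain
  new_strain_field(values, "imported")
}

#' Export a strain field to the strain CSV dialect
#'
#' Writes one row per fibril pixel with header `x,y,strain` (0-based grid
#' coordinates, y downward), the same dialect [strain_import()] reads.
#'
#' @param field A `strain_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
strain_export <- function(field, path) {
  write.csv(tidy(field), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select damaged fibril pixels from a strain field
#'
#' Marks the `ceiling(damage_fraction * fibril_count)` fibril pixels with the
#' highest strain as damage seeds; ties are broken by fixed lexicographic
#' pixel order (ascending x, then y).
#'
#' @param field A `strain_field` aligned to `grid`.
#' @param grid A `tissue_grid`.
#' @param damage_fraction Fraction of fibril pixels to damage, in [0, 1].
#' @return A tibble of 0-based `x`, `y` seed coordinates.
#' @export
damage_select <- function(field, grid, damage_fraction = 0.10) {
  stopifnot(damage_fraction >= 0, damage_fraction <= 1)
  H <- nrow(grid$label)
  fib_idx <- which(is_fibril(grid$label))
  k <- ceiling(damage_fraction * length(fib_idx))
  if (k == 0) return(tibble::tibble(x = integer(0), y = integer(0)))
  s <- field$values[fib_idx]
  if (anyNA(s)) stop_("strain field undefined on some fibril pixels")
  px <- (fib_idx - 1L) %/% H
  py <- (fib_idx - 1L) %% H
  ord <- order(-s, px, py)
  take <- ord[seq_len(k)]
  tibble::tibble(x = px[take], y = py[take])
}

#' Random damage placement (optional mode)
#'
#' Seeds damage uniformly at random across fibril pixels instead of by
#' strain ranking; exploratory alternative to [damage_select()].
#'
#' @inheritParams damage_select
#' @param seed Integer seed.
#' @return A tibble of 0-based `x`, `y` seed coordinates.
#' @export
damage_random <- function(grid, damage_fraction = 0.10, seed = 1) {
  stopifnot(damage_fraction >= 0, damage_fraction <= 1)
  H <- nrow(grid$label)
  fib_idx <- which(is_fibril(grid$label))
  k <- ceiling(damage_fraction * length(fib_idx))
  take <- local_seed(seed, fib_idx[sample.int(length(fib_idx), k)])
  tibble::tibble(x = (take - 1L) %/% H, y = (take - 1L) %% H)
}

#' Expand damage seeds to a necrosis halo
#'
#' Adds the von Neumann (4-) neighborhood of every damaged fibril pixel:
#' neighboring fibril and ECM pixels are marked damaged too, emulating
#' focal autolysis around ruptured fibrils. Neighbors off the occupied
#' region are clipped. Idempotent when re-applied without new seeds.
#'
#' @param grid A `tissue_grid`.
#' @param damaged Tibble of 0-based `x`, `y` damaged fibril coordinates.
#' @return A tibble of 0-based `x`, `y`, `type` (`"fibril"`/`"ecm"`)
#'   covering the union of seeds and halo.
#' @export
damage_expand <- function(grid, damaged) {
  H <- nrow(grid$label); W <- ncol(grid$label)
  if (nrow(damaged) == 0) {
    return(tibble::tibble(x = integer(0), y = integer(0), type = character(0)))
  }
  idx <- rc_idx(damaged$y + 1L, damaged$x + 1L, H)
  if (!all(is_fibril(grid$label[idx]))) {
    stop_("damage seeds must be fibril pixels")
  }
  nb <- vn_neighbors(idx, H, W)
  all_idx <- unique(c(idx, unlist(nb, use.names = FALSE)))
  all_idx <- all_idx[!is.na(all_idx)]
  lab <- grid$label[all_idx]
  keep <- lab != EMPTY_CODE
  all_idx <- all_idx[keep]; lab <- lab[keep]
  tibble::tibble(
    x = (all_idx - 1L) %/% H,
    y = (all_idx - 1L) %% H,
    type = ifelse(lab == ECM_CODE, "ecm", "fibril")
  ) |> dplyr::arrange(.data$x, .data$y)
}

#' Apply damage marks to a grid
#'
#' Sets the damaged flag on the given pixels; damaged ECM has its collagen
#' density reduced (damage signal for fibroblasts).
#'
#' @param grid A `tissue_grid`.
#' @param damage Tibble with `x`, `y` (0-based) as from [damage_expand()].
#' @param collagen_damaged Collagen density assigned to damaged ECM.
#' @return The modified `tissue_grid`.
#' @export
apply_damage <- function(grid, damage, collagen_damaged = 0.2) {
  if (nrow(damage) == 0) return(grid)
  H <- nrow(grid$label)
  idx <- rc_idx(damage$y + 1L, damage$x + 1L, H)
  grid$damaged[idx] <- TRUE
  ecm <- idx[grid$label[idx] == ECM_CODE]
  grid$collagen[ecm] <- collagen_damaged
  grid
}
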