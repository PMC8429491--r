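# Reading and writing tissue grids.
#
# Two on-disk dialects, selected by file extension:
#   * long CSV  (x,y,label,owner,collagen_density,damaged,needs_repair) --
#     full round-trip including flags and the owner map;
#   * label-mask PNG (uint8 codes: 0 = EMPTY, 1..n_fibers = FIBRIL,
#     255 = ECM) -- labels only.
# Both carry a plain-text sidecar header "<path>.meta" with key: value
# metadata (width, height, n_fibers, pixel_area, slice_thickness).
# Coordinates are 0-based (x, y), y increasing downward.

meta_path <- function(path) paste0(path, ".meta")

write_sidecar <- function(grid, path) {
  lines <- c(
    sprintf("width: %d", ncol(grid$label)),
    sprintf("height: %d", nrow(grid$label)),
    sprintf("n_fibers: %d", grid$n_fibers),
    sprintf("pixel_area: %.10g", grid$pixel_area),
    sprintf("slice_thickness: %.10g", grid$slice_thickness),
    "coordinates: 0-based x,y; y increases downward"
  )
  writeLines(lines, meta_path(path))
}

read_sidecar <- function(path) {
  mp <- meta_path(path)
  if (!file.exists(mp)) return(NULL)
  lines <- readLines(mp, warn = FALSE)
  kv <- strsplit(lines, ":\\s*")
  out <- list()
  for (p in kv) if (length(p) >= 2) out[[p[[1]]]] <- paste(p[-1], collapse = ":")
  out
}

#' Write a tissue grid to disk
#'
#' @param grid A `tissue_grid`.
#' @param path Output path; `.csv` writes the full long-format dialect,
#'   `.png` writes a label mask (labels only; damage/repair flags are
#'   dropped with a warning if set). A plain-text metadata sidecar
#'   `<path>.meta` is written alongside either format.
#' @return `path`, invisibly.
#' @export
tg_write <- function(grid, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- tidy(grid)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "png") {
    if (any(grid$damaged) || any(grid$needs_repair)) {
      warning("PNG label mask drops damage/repair flags; use CSV for full state")
    }
    png::writePNG(grid$label / 255, path)
  } else {
    stop_("unsupported grid format: .", ext, " (use .csv or .png)")
  }
  write_sidecar(grid, path)
  invisible(path)
}

#' Read a tissue grid from disk
#'
#' @param path Path to a `.csv` (long format) or `.png` (label mask) grid.
#'   Metadata is taken from the `<path>.meta` sidecar when present.
#' @param n_fibers Number of fibers; required if no sidecar exists.
#' @return A `tissue_grid`.
#' @export
tg_read <- function(path, n_fibers = NULL) {
  if (!file.exists(path)) stop_("file not found: ", path)
  meta <- read_sidecar(path)
  n_fibers <- n_fibers %||% (if (!is.null(meta$n_fibers)) as.integer(meta$n_fibers))
  if (is.null(n_fibers)) {
    stop_("n_fibers unknown: supply n_fibers= or provide a ", meta_path(path), " sidecar")
  }
  pixel_area <- as.numeric(meta$pixel_area %||% 6.45)
  slice_thickness <- as.numeric(meta$slice_thickness %||% 50)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tg_read_csv(path, meta, n_fibers, pixel_area, slice_thickness)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    label <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
    bad <- which(!(label == EMPTY_CODE | label == ECM_CODE |
                     (label >= 1L & label <= n_fibers)))
    if (length(bad)) {
      stop_(sprintf("unknown label code %d at pixel x=%d, y=%d",
                    label[bad[1]], (bad[1] - 1L) %/% nrow(label),
                    (bad[1] - 1L) %% nrow(label)))
    }
    new_tissue_grid(
      label = label, owner = label,
      collagen = ifelse(label == ECM_CODE, 1.0, 0.0),
      damaged = matrix(FALSE, nrow(label), ncol(label)),
      needs_repair = matrix(FALSE, nrow(label), ncol(label)),
      n_fibers = n_fibers, pixel_area = pixel_area,
      slice_thickness = slice_thickness
    )
  } else {
    stop_("unsupported grid format: .", ext, " (use .csv or .png)")
  }
}

tg_read_csv <- function(path, meta, n_fibers, pixel_area, slice_thickness) {
  if (file.size(path) == 0) stop_("no pixels: ", path, " is empty")
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_("parse error in ", path, ": ", conditionMessage(e))
  )
  if (nrow(df) == 0) stop_("no pixels: ", path, " has no records")
  required <- c("x", "y", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_("parse error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("x", "y", "label")) {
    bad <- which(is.na(suppressWarnings(as.integer(df[[col]]))))
    if (length(bad)) {
      stop_(sprintf("parse error: non-integer %s in record %d", col, bad[1]))
    }
  }
  if (is.null(df$owner)) df$owner <- df$label
  if (is.null(df$collagen_density)) {
    df$collagen_density <- ifelse(df$label == ECM_CODE, 1.0, 0.0)
  }
  if (is.null(df$damaged)) df$damaged <- FALSE
  if (is.null(df$needs_repair)) df$needs_repair <- FALSE

  W <- if (!is.null(meta$width)) as.integer(meta$width) else max(df$x) + 1L
  H <- if (!is.null(meta$height)) as.integer(meta$height) else max(df$y) + 1L
  oob <- which(df$x < 0 | df$x >= W | df$y < 0 | df$y >= H)
  if (length(oob)) {
    stop_(sprintf("parse error: coordinates out of bounds in record %d (x=%d, y=%d)",
                  oob[1], df$x[oob[1]], df$y[oob[1]]))
  }
  valid_code <- function(v) v == EMPTY_CODE | v == ECM_CODE |
    (v >= 1L & v <= n_fibers)
  bad <- which(!valid_code(df$label))
  if (length(bad)) {
    stop_(sprintf("unknown label code %d in record %d", df$label[bad[1]], bad[1]))
  }
  bad <- which(!valid_code(df$owner))
  if (length(bad)) {
    stop_(sprintf("unknown owner code %d in record %d", df$owner[bad[1]], bad[1]))
  }
  idx <- rc_idx(df$y + 1L, df$x + 1L, H)
  if (anyDuplicated(idx)) {
    stop_(sprintf("parse error: duplicate pixel in record %d", anyDuplicated(idx)))
  }
  label <- matrix(EMPTY_CODE, H, W); label[idx] <- as.integer(df$label)
  owner <- matrix(EMPTY_CODE, H, W); owner[idx] <- as.integer(df$owner)
  collagen <- matrix(0, H, W); collagen[idx] <- df$collagen_density
  damaged <- matrix(FALSE, H, W); damaged[idx] <- as.logical(df$damaged)
  needs_repair <- matrix(FALSE, H, W); needs_repair[idx] <- as.logical(df$needs_repair)
  new_tissue_grid(label, owner, collagen, damaged, needs_repair,
                  n_fibers, pixel_area, slice_thickness)
}
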