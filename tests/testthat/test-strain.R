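test_that("surrogate field is symmetric for a symmetric bundle", {
  g <- symmetric_bundle()
  f <- strain_surrogate(g, seed = 5, noise_sd = 0.05)
  df <- tidy(f)
  df$fiber <- g$label[myoregen:::rc_idx(df$y + 1L, df$x + 1L, nrow(g$label))]
  means <- tapply(df$strain, df$fiber, mean)
  # four-fold symmetry up to the multiplicative noise (SE ~ 0.5% per fiber)
  expect_lt(diff(range(means)) / mean(means), 0.05)
})

test_that("corner fibers carry more strain than interior fibers", {
  g <- tg_generate(seed = 1)
  f <- strain_surrogate(g, seed = 2)
  df <- tidy(f)
  H <- nrow(g$label)
  df$fiber <- g$label[myoregen:::rc_idx(df$y + 1L, df$x + 1L, H)]
  cent <- dplyr::summarise(dplyr::group_by(df, .data$fiber),
                           x = mean(.data$x), y = mean(.data$y),
                           strain = mean(.data$strain))
  w <- ncol(g$label); h <- H
  corner_d <- pmin(sqrt(cent$x^2 + cent$y^2),
                   sqrt((w - cent$x)^2 + cent$y^2),
                   sqrt(cent$x^2 + (h - cent$y)^2),
                   sqrt((w - cent$x)^2 + (h - cent$y)^2))
  center_d <- sqrt((cent$x - w / 2)^2 + (cent$y - h / 2)^2)
  corner_fiber <- which.min(corner_d)
  center_fiber <- which.min(center_d)
  expect_gt(cent$strain[corner_fiber], cent$strain[center_fiber])
})

test_that("along-fiber modulus dominates surrogate strain sensitivity", {
  g <- small_bundle()
  tab <- material_sensitivity(g, seed = 4)
  by_par <- tapply(abs(tab$pct_change_max_strain), tab$parameter, max)
  expect_gt(by_par[["c5"]], 1) # c5 changes strain appreciably ...
  others <- by_par[setdiff(names(by_par), "c5")]
  expect_true(all(others < by_par[["c5"]]))
  # signs: stiffening decreases max strain, softening increases it
  up <- tab[tab$parameter == "c5" & tab$input_value > tab$model_value, ]
  dn <- tab[tab$parameter == "c5" & tab$input_value < tab$model_value, ]
  expect_lt(up$pct_change_max_strain, 0)
  expect_gt(dn$pct_change_max_strain, 0)
  # density is unused by the surrogate
  expect_equal(tab$pct_change_max_strain[tab$parameter == "density"], c(0, 0))
})

test_that("imported strain tables register by nearest element center", {
  g <- symmetric_bundle()
  H <- nrow(g$label)
  fib_idx <- which(myoregen:::is_fibril(g$label))
  px <- (fib_idx - 1L) %/% H
  py <- (fib_idx - 1L) %% H

  # two centers: left and right halves -> step field split at the bisector
  path <- withr::local_tempfile(fileext = ".csv")
  centers <- data.frame(x = c(4, 18), y = c(11, 11), strain = c(0.1, 0.3))
  write.csv(centers, path, row.names = FALSE)
  f <- strain_import(path, g)
  # brute-force nearest-neighbor oracle
  d2 <- outer(px, centers$x, "-")^2 + outer(py, centers$y, "-")^2
  oracle <- centers$strain[max.col(-d2, ties.method = "first")]
  expect_equal(f$values[fib_idx], oracle)

  # a single center gives a uniform field
  write.csv(centers[1, ], path, row.names = FALSE)
  f1 <- strain_import(path, g)
  expect_true(all(f1$values[fib_idx] == 0.1))

  # identity mapping: one center per pixel reproduces the table
  tab <- data.frame(x = px, y = py, strain = runif(length(px)))
  write.csv(tab, path, row.names = FALSE)
  fid <- strain_import(path, g)
  expect_equal(fid$values[fib_idx], tab$strain)

  # errors
  writeLines("x,y,strain", path)
  expect_error(strain_import(path, g), "empty")
  write.csv(data.frame(x = 999, y = 0, strain = 1), path, row.names = FALSE)
  expect_error(strain_import(path, g), "outside grid bounds")
})

test_that("strain export round-trips through import", {
  g <- symmetric_bundle()
  f <- strain_surrogate(g, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  strain_export(f, path)
  f2 <- strain_import(path, g)
  expect_equal(f2$values, f$values, tolerance = 1e-12)
})

test_that("damage selection takes the exact top-strain pixels", {
  g <- symmetric_bundle()
  f <- strain_surrogate(g, seed = 7)
  n_fib <- sum(myoregen:::is_fibril(g$label))
  sel <- damage_select(f, g, 0.10)
  expect_identical(nrow(sel), as.integer(ceiling(0.1 * n_fib)))
  H <- nrow(g$label)
  chosen <- f$values[myoregen:::rc_idx(sel$y + 1L, sel$x + 1L, H)]
  others <- setdiff(which(myoregen:::is_fibril(g$label)),
                    myoregen:::rc_idx(sel$y + 1L, sel$x + 1L, H))
  expect_gte(min(chosen), max(f$values[others]))

  expect_identical(nrow(damage_select(f, g, 0)), 0L)

  # all-equal strains: ties broken by lexicographic (x, y) order
  f$values[!is.na(f$values)] <- 1
  sel_tie <- damage_select(f, g, 0.05)
  fib_idx <- which(myoregen:::is_fibril(g$label))
  ord <- order((fib_idx - 1L) %/% H, (fib_idx - 1L) %% H)
  expected <- fib_idx[ord][seq_len(nrow(sel_tie))]
  expect_identical(myoregen:::rc_idx(sel_tie$y + 1L, sel_tie$x + 1L, H), expected)
})

test_that("necrosis expansion is the clipped von Neumann closure", {
  g <- symmetric_bundle()
  H <- nrow(g$label)
  # an interior fibril pixel: itself plus its 4 neighbors
  seed_px <- tibble::tibble(x = 5L, y = 5L)
  halo <- damage_expand(g, seed_px)
  expect_setequal(paste(halo$x, halo$y),
                  paste(c(5, 5, 6, 5, 4), c(5, 4, 5, 6, 5)))

  # two adjacent seeds: union of neighborhoods, 8 distinct pixels
  halo2 <- damage_expand(g, tibble::tibble(x = c(5L, 6L), y = c(5L, 5L)))
  expect_identical(nrow(halo2), 8L)
  # set-union oracle
  nb <- function(x, y) cbind(c(x, x, x + 1, x, x - 1), c(y, y - 1, y, y + 1, y))
  oracle <- unique(rbind(nb(5, 5), nb(6, 5)))
  expect_setequal(paste(halo2$x, halo2$y), paste(oracle[, 1], oracle[, 2]))

  # monotone and idempotent on re-application of the same fibril seeds
  fib_seeds <- halo2[halo2$type == "fibril", c("x", "y")]
  halo3 <- damage_expand(g, fib_seeds)
  expect_true(all(paste(halo2$x, halo2$y) %in% paste(halo3$x, halo3$y)))

  # a seed at the fiber/region margin keeps only existing neighbors
  edge <- damage_expand(g, tibble::tibble(x = 1L, y = 1L))
  expect_true(all(edge$x >= 0 & edge$y >= 0))
  expect_lte(nrow(edge), 5L)
})

test_that("applying damage lowers collagen on damaged ECM", {
  g <- symmetric_bundle()
  halo <- damage_expand(g, tibble::tibble(x = 10L, y = 5L))
  expect_true(any(halo$type == "ecm"))
  g2 <- apply_damage(g, halo, collagen_damaged = 0.2)
  H <- nrow(g$label)
  idx <- myoregen:::rc_idx(halo$y + 1L, halo$x + 1L, H)
  expect_true(all(g2$damaged[idx]))
  ecm_idx <- idx[halo$type == "ecm"]
  expect_true(all(g2$collagen[ecm_idx] == 0.2))
})
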