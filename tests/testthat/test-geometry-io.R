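test_that("CSV round-trip preserves the full grid state", {
  g <- small_bundle()
  # give it nontrivial state
  idx <- which(myoregen:::is_fibril(g$label))[1:10]
  g$damaged[idx] <- TRUE
  g$needs_repair[idx[1:5]] <- TRUE
  ecm1 <- which(g$label == myoregen:::ECM_CODE)[1:7]
  g$collagen[ecm1] <- 0.2

  path <- withr::local_tempfile(fileext = ".csv")
  tg_write(g, path)
  g2 <- tg_read(path)
  expect_identical(g2$label, g$label)
  expect_identical(g2$owner, g$owner)
  expect_identical(g2$damaged, g$damaged)
  expect_identical(g2$needs_repair, g$needs_repair)
  expect_equal(g2$collagen, g$collagen)
  expect_identical(g2$n_fibers, g$n_fibers)
  expect_equal(g2$pixel_area, g$pixel_area)
  expect_equal(g2$slice_thickness, g$slice_thickness)
})

test_that("PNG label mask round-trips labels and metadata", {
  g <- small_bundle()
  path <- withr::local_tempfile(fileext = ".png")
  tg_write(g, path)
  g2 <- tg_read(path)
  expect_identical(g2$label, g$label)
  expect_identical(g2$n_fibers, g$n_fibers)
  # flags are dropped with a warning
  g$damaged[which(myoregen:::is_fibril(g$label))[1]] <- TRUE
  expect_warning(tg_write(g, path), "flags")
})

test_that("malformed grid files produce informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("x,y,label", "0,0,99"), path)
  expect_error(tg_read(path, n_fibers = 20), "unknown label code 99")

  file.create(path2 <- withr::local_tempfile(fileext = ".csv"))
  expect_error(tg_read(path2, n_fibers = 20), "no pixels")

  writeLines(c("x,y,label", "0,0,1", "0,0,2"), path)
  expect_error(tg_read(path, n_fibers = 20), "duplicate pixel")

  writeLines(c("x,y,label", "5,0,1"), path)
  writeLines(c("width: 3", "height: 3", "n_fibers: 2"), paste0(path, ".meta"))
  expect_error(tg_read(path), "out of bounds")

  writeLines(c("x,y", "0,0"), path)
  expect_error(tg_read(path, n_fibers = 2), "missing column")
})
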