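test_that("synthetic bundle meets calibration targets and is deterministic", {
  g <- tg_generate(n_fibers = 20, target_fibrils = 9864,
                   target_ecm_fraction = 0.158, seed = 1)
  comp <- tg_composition(g)
  expect_equal(comp$fibril_count, 9864, tolerance = 0.01) # within 1%
  expect_lt(abs(comp$ecm_fraction - 0.158), 0.005)
  expect_identical(tg_generate(seed = 1)$label, g$label)

  g2 <- tg_generate(n_fibers = 1, target_fibrils = 100,
                    target_ecm_fraction = 0.3, seed = 0)
  comp2 <- tg_composition(g2)
  expect_identical(comp2$fibril_count, 100L)
  expect_lt(abs(comp2$ecm_fraction - 0.3), 0.005)
  # the single fiber is wrapped by ECM: no fibril pixel sits on the canvas
  # edge or next to EMPTY canvas
  lab <- g2$label
  H <- nrow(lab); W <- ncol(lab)
  fib_idx <- which(myoregen:::is_fibril(lab))
  rows <- ((fib_idx - 1L) %% H) + 1L
  cols <- ((fib_idx - 1L) %/% H) + 1L
  expect_true(all(rows > 1 & rows < H & cols > 1 & cols < W))
  nb <- myoregen:::vn_neighbors(fib_idx, H, W)
  for (d in nb) expect_false(any(lab[d] == 0L))
})

test_that("generated fibers are 4-connected and mutually separated", {
  g <- small_bundle()
  expect_silent(tg_validate(g))
  for (f in seq_len(g$n_fibers)) {
    idx <- which(g$label == f)
    expect_gt(length(idx), 0)
    comp <- myoregen:::flood_components(idx, nrow(g$label), ncol(g$label))
    expect_identical(max(comp), 1L)
  }
})

test_that("generator calibration holds across seeds", {
  fr <- vapply(1:10, function(s) {
    tg_composition(tg_generate(n_fibers = 6, target_fibrils = 1600,
                               target_ecm_fraction = 0.22, seed = s))$ecm_fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.22), 0.005)
})

test_that("infeasible generator targets fail loudly", {
  # ECM budget too small to wrap any region holding 1000 fibrils
  expect_error(tg_generate(n_fibers = 4, target_fibrils = 1000,
                           target_ecm_fraction = 0.02, seed = 1),
               "infeasible")
  expect_error(tg_generate(target_ecm_fraction = 1.2), "between 0 and 1")
})

test_that("composition arithmetic matches hand counts", {
  g <- counting_grid(9864L, 1855L)
  comp <- tg_composition(g)
  expect_identical(comp$fibril_count, 9864L)
  expect_identical(comp$ecm_count, 1855L)
  expect_equal(comp$muscle_fraction, 9864 / 11719)
  expect_equal(comp$ecm_fraction + comp$muscle_fraction, 1)
  expect_equal(comp$mean_fiber_csa, 9864 * 6.45 / 20)

  all_ecm <- counting_grid(0L, 50L)
  expect_equal(tg_composition(all_ecm)$muscle_fraction, 0)
})

test_that("damaged pixels count under their current label", {
  g <- small_bundle()
  before <- tg_composition(g)
  idx <- which(myoregen:::is_fibril(g$label))[1:25]
  g$damaged[idx] <- TRUE
  expect_identical(tg_composition(g), before)
})
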