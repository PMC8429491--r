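census0 <- list(N = 0, PM = 0, AM = 0, Fb = 0, DE = 0)

test_that("secretion rates match their printed per-hour equations", {
  r0 <- cytokine_rates(census0)
  expect_equal(r0$rate[r0$factor == "IGF1"], 0)
  expect_equal(r0$rate[r0$factor == "TGFb"], 0)
  expect_equal(r0$rate[r0$factor == "HGF"], 0)
  expect_equal(r0$rate[r0$factor == "TNFa"], 3.21e-12)
  expect_equal(r0$rate[r0$factor == "IL6"], 2.91e-12)

  r1 <- cytokine_rates(list(N = 0, PM = 0, AM = 100, Fb = 0, DE = 0))
  expect_equal(r1$rate[r1$factor == "IGF1"], 1.76e-2)
  expect_equal(r1$rate[r1$factor == "TGFb"], 0.875)

  r2 <- cytokine_rates(list(N = 0, PM = 0, AM = 0, Fb = 0, DE = 1000))
  expect_equal(r2$rate[r2$factor == "HGF"], 1.49e-4)

  r3 <- cytokine_rates(list(N = 3, PM = 7, AM = 0, Fb = 11, DE = 0))
  expect_equal(r3$rate[r3$factor == "TNFa"],
               3.21e-12 + 5.8e-12 * 3 + 1.25e-9 * 7 + 4.9e-18 * 11)
  expect_equal(r3$rate[r3$factor == "IL6"],
               2.91e-12 + 1.25e-12 * 3 + 1.25e-12 * 7)

  expect_error(cytokine_rates(list(N = -1, PM = 0, AM = 0, Fb = 0, DE = 0)),
               "nonnegative")
})

test_that("pools grow affinely under a frozen census", {
  census <- list(N = 5, PM = 2, AM = 4, Fb = 9, DE = 100)
  rates <- cytokine_rates(census)
  st <- cytokine_state()
  for (k in 1:24) st <- cytokines_update(st, census)
  expect_equal(unname(st$pools), rates$rate * 24, tolerance = 1e-12)
  # nonnegativity and gradient bookkeeping
  expect_true(all(st$pools >= 0))
  expect_true(gradient_positive(st, "IGF1"))
  expect_false(gradient_positive(cytokine_state(), "IGF1")) # no snapshot yet
})

test_that("decay is applied after secretion", {
  census <- list(N = 0, PM = 0, AM = 10, Fb = 0, DE = 0)
  st <- cytokines_update(cytokine_state(), census, decay = 0.5)
  expect_equal(st$pools[["TGFb"]], 8.75e-3 * 10 * exp(-0.5))
})

test_that("local deposits conserve mass, also under diffusion", {
  st <- cytokine_state(10, 10)
  st <- deposit_local(st, x = 3, y = 4, factor = "IL6", amount = 2)
  st <- deposit_local(st, x = 7, y = 1, factor = "IL6", amount = 5)
  expect_equal(sum(st$local$IL6), 7)
  expect_equal(st$pools[["IL6"]], 7)
  expect_equal(st$local$IL6[5, 4], 2) # row y+1, col x+1

  st0 <- deposit_local(st, 3, 4, "IL6", 0)
  expect_identical(st0$local$IL6, st$local$IL6)

  # diffusion kernel conserves mass (reflecting boundaries)
  for (k in 1:20) st <- cytokines_update(st, census0, diffusion = 0.3)
  expect_equal(sum(st$local$IL6), 7, tolerance = 1e-12)

  expect_error(deposit_local(st, x = 50, y = 0, factor = "IL6", amount = 1),
               "outside grid")
})

test_that("Moore arg-max search honors the fixed tie-break order", {
  st <- cytokine_state(9, 9)
  # uniform (all-zero) field: first neighbor in fixed order is north
  expect_equal(local_max_neighbor(st, "IL6", x = 4, y = 4), list(x = 4, y = 3))
  # single peaked field: returns the peak
  st <- deposit_local(st, x = 5, y = 5, factor = "IL6", amount = 3)
  expect_equal(local_max_neighbor(st, "IL6", x = 4, y = 4), list(x = 5, y = 5))
  # exhaustive-scan oracle from a corner (clipped neighborhood)
  expect_equal(local_max_neighbor(st, "IL6", x = 0, y = 0), list(x = 1, y = 0))
})
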