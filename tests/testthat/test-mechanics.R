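test_that("fiber stress response evaluates its three branches", {
  p <- constitutive_params(c3 = 2, c4 = 60, lambda_m = 1.2)
  expect_equal(fiber_stress(0.9, p), 0)
  expect_equal(fiber_stress(1, p), 0)
  expect_equal(fiber_stress(1.1, p), 2 * (exp(6) - 1)) # toe region
  expect_equal(fiber_stress(1.3, p), p$c5 * 1.3 + p$c6) # linear region
})

test_that("stress response is continuous at both branch points", {
  # parameter sweep: continuity must hold for any valid parameter set
  for (c3 in c(0.5, 2, 10)) for (c4 in c(10, 60)) for (lm in c(1.03, 1.06, 1.2)) {
    p <- constitutive_params(c3 = c3, c4 = c4, c5 = 600, lambda_m = lm)
    # identity stretch: the toe branch vanishes exactly
    expect_lt(abs(fiber_stress(1 + 1e-12, p)), 1e-8)
    expect_identical(fiber_stress(1, p), 0)
    # transition stretch: both branch formulas agree there by construction
    expect_equal(p$c3 * (exp(p$c4 * (lm - 1)) - 1), p$c5 * lm + p$c6)
    expect_equal(fiber_stress(lm - 1e-9, p), fiber_stress(lm + 1e-9, p),
                 tolerance = 1e-5)
  }
})

test_that("energy and stress are mutually consistent", {
  p <- fiber_params()
  # lambda * dF2/dlambda equals the stress response (central differences)
  lam <- seq(1.0005, p$lambda_m - 0.0005, length.out = 100)
  h <- 1e-6
  dF <- (fiber_energy(lam + h, p) - fiber_energy(lam - h, p)) / (2 * h)
  expect_equal(lam * dF, fiber_stress(lam, p), tolerance = 1e-6)

  # and on the linear branch
  lam2 <- seq(p$lambda_m + 0.01, 1.4, length.out = 50)
  dF2 <- (fiber_energy(lam2 + h, p) - fiber_energy(lam2 - h, p)) / (2 * h)
  expect_equal(lam2 * dF2, fiber_stress(lam2, p), tolerance = 1e-6)
})

test_that("toe-region energy matches a quadrature oracle", {
  p <- constitutive_params(c3 = 2, c4 = 60)
  # F2(l) = integral from 1 to l of stress(s)/s ds
  oracle <- stats::integrate(function(s) fiber_stress(s, p) / s, 1, 1.05,
                             rel.tol = 1e-10)$value
  expect_equal(fiber_energy(1.05, p), oracle, tolerance = 1e-6)
  expect_equal(fiber_energy(1, p), 0)
  expect_equal(fiber_energy(0.8, p), 0)
})

test_that("derived c6 enforces the printed continuity relation", {
  p <- constitutive_params(c3 = 2, c4 = 60, c5 = 600, lambda_m = 1.06)
  expect_equal(p$c5 * p$lambda_m + p$c6,
               p$c3 * (exp(p$c4 * (p$lambda_m - 1)) - 1))
})

test_that("active tension behaves like a length-dependent elastance", {
  a <- active_params() # Tmax 135.7, Ca0max 4.35, B 4.75, l0 1.58, refl 2.04
  expect_equal(active_tension(a$l0, a), 0)
  expect_equal(active_tension(1.2, a), 0) # below slack length
  expect_equal(active_tension(2.0, active_params(Ct = 0)), 0)

  # independent evaluation of the standard elastance form at optimal length
  eca50 <- a$Ca0_max / sqrt(exp(a$B * (a$refl - a$l0)) - 1)
  expected <- a$Tmax * a$Ca0_max^2 / (a$Ca0_max^2 + eca50^2)
  ta <- active_tension(a$refl, a)
  expect_equal(ta, expected)
  expect_gt(ta, 0)
  expect_lte(ta, a$Tmax)

  # monotone nondecreasing on [l0, refl]
  ls <- seq(a$l0, a$refl, length.out = 50)
  expect_true(all(diff(active_tension(ls, a)) >= -1e-12))

  # the literal printed reading is exposed but differs
  expect_false(isTRUE(all.equal(active_tension(a$refl, a, form = "literal"), ta)))
})
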