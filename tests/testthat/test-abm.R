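test_that("initial satellite-cell seeding follows the density formula", {
  g20 <- counting_grid(200L, 100L) # composition irrelevant; 20 fibers, 50 um
  expect_identical(initial_sc_count(sim_config(sc_per_fiber_per_10um = 0.10), g20), 10L)
  expect_identical(initial_sc_count(sim_config(sc_per_fiber_per_10um = 0.04), g20), 4L)

  # fractional counts use stochastic rounding: 1 fiber, 10 um, density 0.10
  g1 <- counting_grid(20L, 10L, n_fibers = 1L)
  g1$slice_thickness <- 10
  cfg <- sim_config(sc_per_fiber_per_10um = 0.10)
  draws <- vapply(1:400, function(s) {
    set.seed(s)
    initial_sc_count(cfg, g1)
  }, integer(1))
  expect_true(all(draws %in% c(0L, 1L)))
  expect_equal(mean(draws), 0.1, tolerance = 0.35) # Bernoulli(0.1) mean
})

test_that("initial placement puts SCs on border fibrils and support cells on ECM", {
  g <- small_bundle()
  st <- sim_init(g, sim_config(), seed = 11)
  H <- st$H
  border <- myoregen:::border_fibrils(st)
  sc_idx <- myoregen:::rc_idx(st$s_y + 1L, st$s_x + 1L, H)
  expect_true(all(sc_idx %in% border))
  for (idx in list(
    myoregen:::rc_idx(st$n_y + 1L, st$n_x + 1L, H),
    myoregen:::rc_idx(st$m_y + 1L, st$m_x + 1L, H),
    myoregen:::rc_idx(st$f_y + 1L, st$f_x + 1L, H)
  )) {
    expect_true(all(st$label[idx] == myoregen:::ECM_CODE))
  }
  cen <- sim_census(st)
  expect_identical(cen$SC_q + cen$SC_a, length(st$s_x))
  expect_identical(cen$N, length(st$n_x))
})

test_that("division probability chain matches its closed form", {
  expect_equal(sc_division_prob(0, 0.5), 0.5)
  expect_equal(sc_division_prob(1, 0.5), 0.4)
  expect_equal(sc_division_prob(2, 0.5), 0.32)
  expect_equal(sc_division_prob(3, 0.5), 0.256)
  expect_equal(sc_division_prob(4, 0.5), 0.3072 * 0.5)
  expect_equal(sc_division_prob(7, 0.5), 0.3072 * 0.5) # chain saturates
})

test_that("an undamaged grid is invariant over a full simulated month", {
  g <- small_bundle()
  cfg <- sim_config(damage_fraction = 0, ticks = 672L)
  r <- simulate_regeneration(g, cfg, seed = 5)
  expect_identical(r$grid$label, g$label)
  expect_identical(r$grid$owner, g$owner)
  cen <- r$census
  expect_true(all(cen$fibril_count == cen$fibril_count[1]))
  expect_true(all(cen$DF == 0))
  expect_true(all(cen$SC_a == 0)) # no HGF, SCs stay quiescent
  expect_true(all(cen$AM == 0))   # no damage was ever seen
  expect_true(is.na(r$clearance_time_h))
})

test_that("runs are bit-reproducible for a fixed seed", {
  g <- small_bundle()
  cfg <- sim_config(ticks = 120L)
  r1 <- simulate_regeneration(g, cfg, seed = 77)
  r2 <- simulate_regeneration(g, cfg, seed = 77)
  expect_identical(r1$census, r2$census)
  expect_identical(r1$grid$label, r2$grid$label)
  r3 <- simulate_regeneration(g, cfg, seed = 78)
  expect_false(identical(r1$census, r3$census))
})

test_that("census equals agent-list and grid tallies every tick", {
  g <- small_bundle()
  cfg <- sim_config(ticks = 60L)
  dmg <- seed_damage(g, cfg, seed = 13)
  st <- sim_init(dmg$grid, cfg, seed = 13)
  for (t in 1:60) {
    sim_step(st)
    cen <- sim_census(st)
    expect_identical(cen$N, length(st$n_x))
    expect_identical(cen$PM + cen$AM, length(st$m_x))
    expect_identical(cen$SC_q + cen$SC_a, length(st$s_x))
    expect_identical(cen$MB, length(st$b_x))
    expect_identical(cen$DF, sum(st$damaged & myoregen:::is_fibril(st$label)))
    expect_identical(cen$DE, sum(st$damaged & st$label == myoregen:::ECM_CODE))
    # label partition: every pixel is fibril, ECM or EMPTY
    expect_identical(
      cen$fibril_count + cen$ecm_count + sum(st$label == myoregen:::EMPTY_CODE),
      st$H * st$W
    )
  }
})

test_that("damage never increases once inflammation begins", {
  g <- small_bundle()
  cfg <- sim_config(ticks = 150L)
  r <- simulate_regeneration(g, cfg, seed = 21)
  total_damage <- r$census$DF + r$census$DE
  expect_true(all(diff(total_damage) <= 0))
})

test_that("no M2 exists before the last damaged object is cleared", {
  g <- small_bundle()
  cfg <- sim_config(ticks = 250L)
  r <- simulate_regeneration(g, cfg, seed = 31)
  cen <- r$census
  first_am <- match(TRUE, cen$AM > 0)
  last_dmg <- max(which(cen$DF + cen$DE > 0))
  expect_false(is.na(first_am)) # the switch did happen in this run
  expect_gt(first_am, last_dmg)
})

test_that("satellite cells stay quiescent and repair nothing without HGF", {
  g <- small_bundle()
  # HGF is driven by damaged ECM; block activation with a huge threshold
  cfg <- sim_config(ticks = 100L, hgf_threshold = Inf)
  r <- simulate_regeneration(g, cfg, seed = 41)
  expect_true(all(r$census$SC_a == 0))
  # clearance proceeds but no fibril is ever restored
  expect_true(all(diff(r$census$fibril_count) <= 0))
})

test_that("a neutrophil clears an adjacent damaged ECM pixel and recruits", {
  g <- symmetric_bundle()
  H <- nrow(g$label)
  # damage one ECM pixel by hand (septum pixel at 0-based x=11, y=5)
  idx <- myoregen:::rc_idx(5L + 1L, 11L + 1L, H)
  expect_identical(g$label[idx], myoregen:::ECM_CODE)
  g$damaged[idx] <- TRUE
  g$collagen[idx] <- 0.2
  cfg <- sim_config(neutrophil_clear_p = 1, macrophage_delay_h = 1000,
                    sc_count = 0L, ticks = 5L)
  st <- sim_init(g, cfg, seed = 3)
  # place one neutrophil right next to the damaged pixel
  st$n_x[1] <- 10L; st$n_y[1] <- 5L
  n_before <- length(st$n_x)
  il6_before <- st$cy$pools[["IL6"]]
  sim_step(st)
  expect_identical(st$label[idx], myoregen:::EMPTY_CODE) # cleared that tick
  expect_false(st$damaged[idx])
  expect_true(st$needs_repair[idx])
  expect_gt(st$cy$pools[["IL6"]], il6_before) # IL-6 deposited
  expect_gte(length(st$n_x), n_before)        # proliferation can only add
})

test_that("hypertrophy never merges two fibers", {
  g <- small_bundle()
  cfg <- sim_config(ticks = 300L, hypertrophy_p = 0.5) # aggressive growth
  r <- simulate_regeneration(g, cfg, seed = 51)
  expect_true(myoregen:::tg_fibers_separated(r$grid))
})
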