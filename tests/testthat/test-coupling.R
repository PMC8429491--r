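small_cfg <- function(...) sim_config(ticks = 250L, ...)

test_that("a single-replicate iteration is its own representative", {
  g <- small_bundle()
  it <- run_iteration(g, small_cfg(), replicates = 1, seed = 9)
  expect_identical(it$representative, 1L)
  expect_identical(it$grid$label, it$grids[[1]]$label)
  expect_identical(nrow(it$endpoints), 1L)
})

test_that("the representative endpoint is nearest the replicate mean", {
  g <- small_bundle()
  it <- run_iteration(g, small_cfg(), replicates = 4, seed = 9)
  ep <- it$endpoints$fibril_count
  expect_identical(it$representative, which.min(abs(ep - mean(ep))))
})

test_that("coupled runs are reproducible and chain representative grids", {
  g <- small_bundle()
  c1 <- run_coupled(g, small_cfg(), n_iterations = 2, replicates = 3, seed = 17)
  c2 <- run_coupled(g, small_cfg(), n_iterations = 2, replicates = 3, seed = 17)
  expect_identical(tidy(c1), tidy(c2))
  expect_identical(c1$summary, c2$summary)
  # iteration 2 starts from iteration 1's representative endpoint count
  expect_identical(c1$summary$initial_fibrils[2],
                   c1$iterations[[1]]$endpoints$fibril_count[
                     c1$iterations[[1]]$representative])
  # one iteration reduces to run_iteration with the same derived seed
  it1 <- run_iteration(g, small_cfg(), replicates = 3,
                       seed = myoregen:::child_seeds(17, 1)[1])
  expect_identical(c1$iterations[[1]]$endpoints$fibril_count,
                   it1$endpoints$fibril_count)
})

test_that("composition closure holds for every replicate endpoint", {
  g <- small_bundle()
  it <- run_iteration(g, small_cfg(), replicates = 3, seed = 23)
  expect_equal(it$endpoints$muscle_fraction + it$endpoints$ecm_fraction,
               rep(1, 3))
})

test_that("an imported strain table can drive an iteration", {
  g <- small_bundle()
  f <- strain_surrogate(g, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  strain_export(f, path)
  it <- run_iteration(g, small_cfg(), replicates = 1, seed = 5,
                      strain_table = path)
  expect_s3_class(it, "regen_iteration")
  expect_lt(tail(it$census$fibril_count, 1), it$initial_fibrils * 1.05)
})

test_that("zero damage leaves the sweep endpoint exactly at the initial count", {
  g <- small_bundle()
  tab <- sweep_damage(g, small_cfg(), fractions = c(0, 0.10),
                      replicates = 2, seed = 31)
  expect_equal(tab$fibril_mean[tab$damage_fraction == 0], tab$initial_fibrils[1])
  expect_equal(tab$fibril_sd[tab$damage_fraction == 0], 0)
  expect_identical(tab$residual_damaged_mean[1], 0)
})

test_that("endpoint recovery does not improve with more damage", {
  # replicate-mean endpoint fibril count over increasing seeded damage,
  # paired seeds across levels; adjacent levels separated by less than the
  # replicate-mean standard error are allowed to tie within that noise
  g <- tg_generate(seed = 7)
  tab <- sweep_damage(g, sim_config(), fractions = c(0.05, 0.10, 0.15, 0.20),
                      replicates = 6, seed = 47)
  se <- max(tab$fibril_sd) / sqrt(6)
  expect_true(all(diff(tab$fibril_mean) <= 2 * se))
  # and the ends of the range are unambiguous
  expect_gt(tab$fibril_mean[1], tab$fibril_mean[4])
})

test_that("report summaries recompute exactly from raw replicate records", {
  g <- small_bundle()
  it <- run_iteration(g, small_cfg(), replicates = 3, seed = 29)
  rep <- summarize_runs(it)
  expect_equal(rep$summary$fibril_mean, mean(it$endpoints$fibril_count),
               tolerance = 1e-9)
  expect_equal(rep$summary$fibril_sd, sd(it$endpoints$fibril_count),
               tolerance = 1e-9)
  expect_true(all(c("clearance_time_mean_h", "repair_complete_time_mean_h")
                  %in% names(rep$summary)))

  # empty input -> empty report, no error
  empty <- summarize_runs(list())
  expect_identical(nrow(empty$summary), 0L)

  dir <- withr::local_tempdir()
  write_report(it, dir, config = small_cfg(), seed = 29)
  disk <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(disk$fibril_mean, rep$summary$fibril_mean, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "manifest.txt")))
})

test_that("tidiers and plots return well-formed objects", {
  g <- small_bundle()
  r <- simulate_regeneration(g, sim_config(ticks = 50L), seed = 7)
  expect_s3_class(tidy(r), "tbl_df")
  expect_identical(nrow(tidy(r)), 51L)
  expect_s3_class(glance(r), "tbl_df")
  expect_s3_class(autoplot(g), "ggplot")
  expect_s3_class(autoplot(strain_surrogate(g, seed = 1)), "ggplot")
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(plot_sweep(tibble::tibble(sc_count = 1:2, fibril_mean = c(1, 2),
                                            fibril_sd = c(0, 0))), "ggplot")
})
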