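test_that("pulse equilibrium is the periodic post-cut block state", {
  f <- equilibrium_forest(10000, rotation_plan(40, 10))
  expect_equal(sort(f$ages), c(0, 10, 20, 30))
  expect_equal(f$areas, rep(2500, 4))
  expect_equal(f$total_area, 10000)
  # smoothed mode: uniform one-year classes
  fs <- equilibrium_forest(10000, rotation_plan(40, mode = "smoothed"))
  expect_equal(fs$ages, 1:40)
  expect_equal(fs$areas, rep(250, 40))
  # empty forest
  expect_equal(equilibrium_forest(0, rotation_plan(40))$total_area, 0)
  expect_error(rotation_plan(45, 10), "divisible")
})

test_that("pulse equilibrium is the attractor of advance+cut from a uniform start", {
  # iterate the raw mechanics from a uniform age structure; after the original
  # cohorts have cycled through, the mature-area series must coincide with the
  # series started from the closed-form equilibrium state
  plan <- rotation_plan(40, 10, first_cut_year = 2010)
  from_uniform <- mature_series(plan, 10000, 2010, 2120,
                                initial_forest = cohort_forest(1:40, rep(250, 40)))
  from_eq <- mature_series(plan, 10000, 2010, 2120)
  tail_years <- from_eq$year >= 2060
  expect_equal(from_uniform$mature_area[tail_years],
               from_eq$mature_area[tail_years], tolerance = 1e-9)
})

test_that("aging conserves area and shifts every cohort by one year", {
  f <- cohort_forest(c(33, 5), c(4000, 6000))
  g <- advance_year(f)
  expect_equal(g$ages, c(34L, 6L))
  expect_equal(g$total_area, f$total_area)
  h <- Reduce(function(x, .) advance_year(x), 1:10, f)
  expect_equal(h$ages, f$ages + 10L)
})

test_that("mature area sums cohorts at or beyond the maturity age", {
  fs <- equilibrium_forest(10000, rotation_plan(40, mode = "smoothed"))
  expect_equal(mature_area(fs, 34), 7 * 250) # ages 34..40
  expect_equal(carrying_capacity(mature_area(fs, 34), 300), 5.8333,
               tolerance = 1e-4)
  all_mature <- cohort_forest(c(50, 80), c(1, 2))
  expect_equal(mature_area(all_mature, 34), 3)
  expect_equal(mature_area(cohort_forest(1L, 20000), 34), 0)
})

test_that("clearcut removes over-age cohorts, replants, and reports mfcr", {
  f <- cohort_forest(c(10, 20, 30, 40), rep(2500, 4))
  res <- apply_clearcut(f, rotation_plan(40), maturity_age = 34)
  expect_equal(res$event$mfcr, 1) # only mature block is the one cut
  expect_equal(res$event$area_cut, 2500)
  expect_equal(res$forest$total_area, 10000, tolerance = 1e-6)
  expect_true(0L %in% res$forest$ages)
  # nothing over-age: no cut
  g <- cohort_forest(c(14, 24, 34, 44), rep(2500, 4))
  res2 <- apply_clearcut(g, rotation_plan(70), maturity_age = 34)
  expect_equal(res2$event$mfcr, 0)
  expect_equal(res2$event$area_cut, 0)
  expect_identical(res2$forest$areas, g$areas)
})

test_that("mature series schedules events and conserves area", {
  # unmanaged: constant
  s0 <- mature_series(NULL, 10000, 2010, 2050)
  expect_true(all(s0$mature_area == 10000))
  expect_true(all(s0$mfcr == 0))
  # R=70 pulse: cut events at 2020, 2030, 2040, 2050
  s <- mature_series(rotation_plan(70, 10, 2020), 10000, 2010, 2050)
  expect_equal(s$year[s$area_cut > 0], c(2020, 2030, 2040, 2050))
  expect_true(all(s$mfcr >= 0 & s$mfcr <= 1))
  # periodicity from the equilibrium state
  long <- mature_series(rotation_plan(70, 10, 2020), 10000, 2010, 2100)
  expect_equal(long$mature_area[long$year %in% 2021:2030],
               long$mature_area[long$year %in% 2031:2040], tolerance = 1e-9)
})

test_that("time-averaged mature area grows with rotation age in both modes", {
  for (mode in c("pulse", "smoothed")) {
    avg <- sapply(c(40, 50, 60, 70), function(r) {
      s <- mature_series(rotation_plan(r, 10, 2020, mode = mode),
                         10000, 2010, 2050)
      mean(s$mature_area)
    })
    expect_true(all(diff(avg) > 0))
  }
})

test_that("smoothed mode matches its closed-form mature fraction", {
  for (r in c(40, 50, 60, 70)) {
    f <- equilibrium_forest(10000, rotation_plan(r, mode = "smoothed"))
    expect_equal(mature_area(f, 34) / 10000, (r - 34 + 1) / r,
                 tolerance = 1e-12)
  }
})
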