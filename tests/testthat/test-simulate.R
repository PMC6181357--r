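test_that("the unmanaged equilibrium is a fixed point of the step", {
  state <- list(t = 0, tn = TN_EQ, on = MOC_MAX)
  s1 <- step_nest(state, P, MOC_MAX, dt = 0.125)
  expect_lt(abs(s1$on - MOC_MAX), 1e-9)
  expect_lt(abs(s1$tn - TN_EQ), 1e-9)
})

test_that("extinction is absorbing and nests decay without pairs", {
  s <- list(t = 0, tn = 50, on = 0)
  s1 <- step_nest(s, P, MOC_MAX, dt = 0.125)
  expect_equal(s1$on, 0)
  expect_equal(s1$tn, 50 - 50 / P$nlf * 0.125, tolerance = 1e-12)
  # whole-run version: occupancy identically zero, nests decay monotonically
  cfg <- scenario_config("dead", 2000, 2060, P, initial_on = 0, initial_tn = 40)
  tr <- simulate_scenario(cfg)
  expect_true(all(tr$on == 0))
  expect_true(all(diff(tr$tn) < 0))
  expect_lt(tr$tn[nrow(tr)], 40 * exp(-59 / P$nlf) * 1.1)
})

test_that("overly large steps are rejected rather than silently clamped", {
  s <- list(t = 0, tn = 10, on = 5)
  expect_error(step_nest(s, P, 0, dt = 10), "instability")
})

test_that("a run started at capacity stays there", {
  tr <- simulate_scenario(build_unmanaged_2010())
  expect_true(all(abs(tr$on - MOC_MAX) < 1e-3 * MOC_MAX))
  expect_true(all(abs(tr$tn - TN_EQ) < 1e-3 * TN_EQ))
})

test_that("occupancy never exceeds capacity in unmanaged runs", {
  tr <- simulate_scenario(build_burete_base())
  expect_true(all(tr$on <= tr$moc + 1e-9))
  expect_true(all(tr$on >= 0) && all(tr$tn >= 0))
})

test_that("stocks are non-negative in every built-in scenario", {
  for (id in list_scenarios()) {
    tr <- simulate_scenario(id)
    expect_true(all(tr$on >= 0), label = paste(id, "on >= 0"))
    expect_true(all(tr$tn >= 0), label = paste(id, "tn >= 0"))
    expect_true(all(is.finite(tr$on)) && all(is.finite(tr$tn)),
                label = paste(id, "finite"))
  }
})

test_that("halving the step changes annual values by less than 0.1% of capacity", {
  for (id in c("cut70_noprot", "cut50_noprot", "cut40_noprot", "cut40_prot")) {
    cfg <- build_scenario(id)
    a <- simulate_scenario(cfg)
    cfg$dt <- cfg$dt / 2
    b <- simulate_scenario(cfg)
    expect_lt(max(abs(a$on - b$on)) / MOC_MAX, 1e-3)
    expect_lt(max(abs(a$tn - b$tn)) / TN_EQ, 1e-3)
  }
})

test_that("the Euler trajectory matches an independent lsoda integration", {
  b <- simulate_scenario(build_burete_base())
  oracle <- lsoda_unmanaged(1, 1, MOC_MAX, P, times = 1890:2018)
  expect_lt(max(abs(b$on - oracle[, "on"])) / MOC_MAX, 5e-3)
  expect_lt(max(abs(b$tn - oracle[, "tn"])) / TN_EQ, 5e-3)
})

test_that("nest protection never lowers occupancy, pointwise", {
  for (r in c(40, 50, 60, 70)) {
    no <- simulate_scenario(build_managed(r, protection = FALSE))
    yes <- simulate_scenario(build_managed(r, protection = TRUE))
    expect_true(all(yes$on >= no$on - 1e-9), label = paste("rotation", r))
  }
})

test_that("reported flows are consistent with the sampled state and pulses", {
  tr <- simulate_scenario(build_managed(50))
  expect_equal(tr$nb, tr$on * P$nbr, tolerance = 1e-12)
  expect_equal(tr$ndr, tr$tn / P$nlf, tolerance = 1e-12)
  pos <- tr$moc > 0
  expect_equal(tr$onir[pos],
               tr$anr[pos] * tr$occ_ratio[pos] * (tr$tn - tr$on)[pos] * P$cr,
               tolerance = 1e-12)
  # logged pulse amounts match the events table exactly
  ev <- attr(tr, "events")
  expect_equal(tr$nlfc_pulse[match(ev$year, tr$year)], ev$nests_lost)
  expect_equal(sum(tr$nlfc_pulse), sum(ev$nests_lost))
})
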