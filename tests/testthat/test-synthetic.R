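test_that("profiles are deterministic in the seed and respect their ranges", {
  expect_identical(generate_profile(1), generate_profile(1))
  expect_false(identical(generate_profile(1), generate_profile(2)))
  for (s in 1:100) {
    p <- generate_profile(s)
    expect_lt(p$vt1_frac, p$vt2_frac)
    expect_gte(p$vo2max_cycle, 59); expect_lte(p$vo2max_cycle, 68)
    expect_gte(p$peak_power, 260); expect_lte(p$peak_power, 315)
    expect_gte(p$swim_lt2_speed, 1.25); expect_lte(p$swim_lt2_speed, 1.35)
    expect_lt(p$swim_lt1_speed, p$swim_lt2_speed)
  }
})

test_that("cycle ramp follows the 100 W + 5 W / 12 s schedule", {
  p <- generate_profile(1)
  tr <- generate_cycle_trace(p, noise_sd = 0, seed = 1)
  wr <- function(t) tr$intensity[tr$time == t]
  expect_equal(wr(0), 100)
  # one step after 12 s, another after 24 s
  proto <- attr(tr, "protocol")
  expect_equal(triseason:::schedule_intensity(proto, 12), 105)
  expect_equal(triseason:::schedule_intensity(proto, 24), 110)
  expect_error(generate_cycle_trace(p, noise_sd = -1), "non-negative")
  # determinism of the noisy trace
  expect_identical(generate_cycle_trace(p, 1.5, seed = 9),
                   generate_cycle_trace(p, 1.5, seed = 9))
})

test_that("run protocol starts at 12.1 km/h with 0.3 km/h stages of 200 m", {
  p <- generate_profile(2)
  tr <- generate_run_trace(p, noise_sd = 0, seed = 1)
  proto <- attr(tr, "protocol")
  expect_equal(proto$speeds[1], 12.1)
  expect_equal(proto$speeds[2], 12.4)
  expect_equal(proto$durations[1], 200 / (12.1 / 3.6))
  expect_equal(tr$intensity[1], 12.1)
})

test_that("lactate curves have 7 ascending stages anchored at baseline", {
  for (s in c(1, 5, 9)) {
    p <- generate_profile(s)
    lc <- generate_lactate_curve(p, seed = s)
    expect_equal(nrow(lc), 7)
    expect_true(all(diff(lc$speed) > 0))
    expect_equal(lc$lactate[1], p$baseline_lactate)
  }
  # lognormal noise keeps lactate positive and is seed-stable
  p <- generate_profile(3)
  a <- generate_lactate_curve(p, seed = 4, noise_sd = 0.1)
  expect_identical(a, generate_lactate_curve(p, seed = 4, noise_sd = 0.1))
  expect_true(all(a$lactate > 0))
})

test_that("generated seasons track the plan and conserve session minutes", {
  p <- generate_profile(4)
  plan <- season_plan(rep(10, 12),
                      data.frame(z1 = 82, z2 = 6, z3 = 12)[rep(1, 12), ])
  s <- generate_season(p, plan, seed = 11)
  wk <- summarize_weeks(s)
  expect_equal(nrow(wk), 12)
  expect_gte(mean(wk$hours), 9.5); expect_lte(mean(wk$hours), 10.5)
  # weekly targets realized within +/-2 percentage points
  expect_true(all(abs(wk$time_z1 - 82) <= 2))
  expect_true(all(abs(wk$time_z2 - 6) <= 2))
  expect_true(all(abs(wk$time_z3 - 12) <= 2))
  # per-session zone minutes sum to the session duration used in hours
  zm <- as.matrix(s[, paste0("z", 1:8)])
  expect_equal(sum(zm) / 60, sum(wk$hours))
  expect_identical(generate_season(p, plan, seed = 11),
                   generate_season(p, plan, seed = 11))
})

test_that("a degenerate forced plan emits exactly the forced session", {
  p <- generate_profile(5)
  plan <- season_plan(1, data.frame(z1 = 100, z2 = 0, z3 = 0))
  forced <- session_row("run", c(60, 0, 0, 0, 0, 0, 0, 0))
  out <- generate_season(p, plan, seed = 1, forced_sessions = forced)
  expect_equal(as.data.frame(out), as.data.frame(forced))
})

test_that("the default season plan shows paper-like volume structure", {
  plan <- default_season_plan()
  expect_equal(nrow(plan), 50)
  expect_equal(mean(plan$hours), 12.2, tolerance = 0.05)
  expect_gt(max(plan$hours), 15)
  expect_true(all(abs(rowSums(plan[, c("z1", "z2", "z3")]) - 100) < 0.01))
  p <- generate_profile(6)
  s <- generate_season(p, plan, seed = 2)
  wk <- summarize_weeks(s)
  expect_gt(max(wk$hours), 15)
})

test_that("anthropometric series drift downward with a final rebound", {
  p <- generate_profile(7)
  a <- generate_anthro_series(p, seed = 3)
  expect_equal(nrow(a), 5)
  s6 <- sum_skinfolds(a)
  expect_lt(s6[4], s6[1])
  expect_identical(a, generate_anthro_series(p, seed = 3))
})
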