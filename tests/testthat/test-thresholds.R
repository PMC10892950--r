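test_that("bin_trace averages windows and handles degenerate widths", {
  tr <- make_trace(time = 1:10, vo2 = 1:10)
  b <- bin_trace(tr, 5)
  expect_equal(b$vo2, c(3, 8))
  # constant trace: any bin width returns the constant
  trc <- make_trace(time = seq(0, 100, 5), vo2 = 42)
  expect_true(all(abs(bin_trace(trc, 17)$vo2 - 42) < 1e-12))
  # bin wider than the trace: one bin, the global mean
  b1 <- bin_trace(tr, 1000)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$vo2, mean(1:10))
  expect_error(bin_trace(tr, 0))
})

test_that("detect_vo2max matches the exhaustive sliding-window oracle", {
  # constant trace
  trc <- make_trace(time = seq(0, 120, 5), vo2 = 60)
  expect_equal(detect_vo2max(trc), 60)
  # linear ramp 30 -> 60 over 10 min: best window is the final minute
  tt <- seq(0, 600, 5)
  trl <- make_trace(time = tt, vo2 = 30 + 30 * tt / 600)
  expect_equal(detect_vo2max(trl), oracle_vo2max(trl))
  expect_equal(detect_vo2max(trl), mean(c(57, 60)))
  expect_error(detect_vo2max(make_trace(time = c(0, 30), vo2 = 50)), "shorter")
  # 100 random traces against the brute force
  set.seed(421)
  for (i in 1:100) {
    n <- sample(30:100, 1)
    tt <- cumsum(runif(n, 2, 8)); tt <- tt - tt[1]
    if (max(tt) < 70) tt <- tt * 80 / max(tt)
    tr <- make_trace(time = tt, vo2 = runif(n, 30, 70))
    expect_equal(detect_vo2max(tr), oracle_vo2max(tr), tolerance = 1e-10)
  }
})

test_that("a noiseless plateau planted at 63.9 mL/kg/min is recovered exactly", {
  p <- generate_profile(1)
  p$vo2max_cycle <- 63.9
  tr <- generate_cycle_trace(p, noise_sd = 0, seed = 1)
  expect_equal(detect_vo2max(tr), 63.9)
})

test_that("noiseless planted ventilatory thresholds are recovered exactly", {
  for (s in 1:10) {
    p <- generate_profile(s)
    for (gen in list(generate_cycle_trace, generate_run_trace)) {
      tr <- gen(p, 0, s)
      tru <- planted_truth(tr)
      v1 <- detect_vt1(tr)
      v2 <- detect_vt2(tr, vt1 = v1)
      expect_true(v1$detected); expect_true(v2$detected)
      expect_equal(v1$intensity, tru$vt1$intensity)
      expect_equal(v2$intensity, tru$vt2$intensity)
      expect_equal(v1$vo2, tru$vt1$vo2, tolerance = 1e-8)
      expect_equal(v1$hr, tru$vt1$hr, tolerance = 1e-8)
      expect_equal(detect_vo2max(tr), tru$vo2max)
      expect_lte(v1$vo2, v2$vo2)
    }
  }
})

test_that("a planted VT1 of 155 W and VT2 of 200 W are reported verbatim", {
  p <- generate_profile(1)
  p$vo2max_cycle <- 59.8
  p$peak_power <- 260
  t_pk <- 12 * (260 - 100) / 5
  v <- p$vo2max_cycle
  frac_at <- function(t1) (8 + (t1 / t_pk) * (v - 8)) / v
  p$vt1_frac <- frac_at(132)   # work rate 155 W
  p$vt2_frac <- frac_at(240)   # work rate 200 W
  tr <- generate_cycle_trace(p, noise_sd = 0, seed = 1)
  tru <- planted_truth(tr)
  expect_equal(tru$vt1$intensity, 155)
  expect_equal(tru$vt2$intensity, 200)
  v1 <- detect_vt1(tr)
  v2 <- detect_vt2(tr, vt1 = v1)
  expect_equal(v1$intensity, 155)
  expect_equal(v2$intensity, 200)
})

test_that("flat traces yield a not-detected signal, not an error", {
  tr <- make_trace(time = seq(0, 400, 5), vo2 = seq(30, 60, length.out = 81))
  v1 <- detect_vt1(tr)
  expect_false(v1$detected)
  expect_match(v1$reason, "VT1")
  # trace truncated before the planted VT2: VE/VCO2 never rises
  p <- generate_profile(2)
  full <- generate_cycle_trace(p, 0, 1)
  tru <- planted_truth(full)
  cut <- full[full$time < tru$vt2$time - 30, ]
  cut <- triseason:::new_gas_trace(cut, "bike", attr(full, "body_mass"),
                                   attr(full, "protocol"), NULL)
  v2 <- detect_vt2(cut, vt1 = detect_vt1(cut))
  expect_false(v2$detected)
})

test_that("VT2 never precedes VT1 across random noisy traces", {
  for (s in 1:50) {
    p <- generate_profile(s + 300)
    tr <- generate_cycle_trace(p, noise_sd = 1.0, seed = s)
    v1 <- detect_vt1(tr)
    v2 <- detect_vt2(tr, vt1 = v1)
    if (v1$detected && v2$detected) {
      expect_gte(v2$time, v1$time)
      expect_gte(v2$intensity, v1$intensity)
    }
  }
})

test_that("the fixed-rise lactate rules follow their hand-worked example", {
  curve <- triseason:::new_lactate_curve(
    tibble::tibble(stage = 1:7,
                   speed = seq(1.0, 1.3, length.out = 7),
                   lactate = c(1.0, 1.1, 1.2, 1.8, 3.2, 5.5, 8.0),
                   hr = seq(150, 180, length.out = 7)), NULL)
  lt <- detect_lactate_thresholds(curve)
  expect_equal(lt$lt1$stage, 4)
  expect_equal(lt$lt2$stage, 5)
  expect_equal(lt$lt1$lactate, 1.5)
  expect_equal(lt$lt2$lactate, 2.8)
  # interpolated LT1 speed: crossing 1.5 between stages 3 and 4
  expect_equal(lt$lt1$speed, 1.1 + 0.05 * (1.5 - 1.2) / (1.8 - 1.2))

  flat <- triseason:::new_lactate_curve(
    tibble::tibble(stage = 1:7, speed = seq(1, 1.3, length.out = 7),
                   lactate = rep(1, 7), hr = 150), NULL)
  ltf <- detect_lactate_thresholds(flat)
  expect_false(ltf$lt1$detected)
  expect_false(ltf$lt2$detected)
  expect_error(detect_lactate_thresholds(curve[1:3, ]))
})

test_that("raising the rise criteria never moves a threshold earlier", {
  for (s in 1:20) {
    p <- generate_profile(s)
    lc <- generate_lactate_curve(p, seed = s)
    base <- detect_lactate_thresholds(lc, 0.5, 1.0)
    harder <- detect_lactate_thresholds(lc, 0.8, 1.5)
    if (harder$lt1$detected) expect_gte(harder$lt1$stage, base$lt1$stage)
    if (harder$lt2$detected && base$lt2$detected) {
      expect_gte(harder$lt2$stage, base$lt2$stage)
    }
  }
})

test_that("planted lactate thresholds are recovered within 0.02 m/s", {
  for (s in 1:20) {
    p <- generate_profile(s)
    lc <- generate_lactate_curve(p, seed = s)
    tru <- planted_truth(lc)
    lt <- detect_lactate_thresholds(lc)
    expect_true(lt$lt1$detected); expect_true(lt$lt2$detected)
    expect_lt(abs(lt$lt1$speed - tru$lt1_speed), 0.02)
    expect_lt(abs(lt$lt2$speed - tru$lt2_speed), 0.02)
    expect_lte(lt$lt1$speed, lt$lt2$speed)
  }
})
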