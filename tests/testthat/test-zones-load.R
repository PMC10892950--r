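test_that("zone models anchor the triphasic boundaries at the thresholds", {
  rep <- make_report("run", vt1 = 13.3, vt2 = 15.1)
  zm <- build_zone_model(rep, "run")
  z <- zm$zones
  expect_equal(nrow(z), 8)
  expect_equal(z$upper[3], 13.3)   # phase 1 ends at VT1
  expect_equal(z$lower[6], 15.1)   # phase 3 starts at VT2
  expect_equal(z$phase, c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L))
  # contiguous, non-overlapping bounds
  expect_equal(z$lower[-1], z$upper[-8])
  # swapped thresholds are rejected
  bad <- make_report("run", vt1 = 15.1, vt2 = 13.3)
  expect_error(build_zone_model(bad, "run"), "exceed")
  expect_error(build_zone_model(rep, "run", score_table = c(5, 4, 3, 2, 1, 1, 1, 1)),
               "non-decreasing")
  expect_error(build_zone_model(rep, "bike"), "no thresholds")
})

test_that("random reports always give 8 contiguous zones in three phase runs", {
  set.seed(99)
  for (i in 1:100) {
    vt1 <- runif(1, 10, 14); vt2 <- vt1 + runif(1, 0.5, 3)
    zm <- build_zone_model(make_report("run", vt1 = vt1, vt2 = vt2), "run")
    z <- zm$zones
    expect_equal(z$lower[-1], z$upper[-8])
    expect_true(all(diff(z$phase) >= 0))
    expect_lte(z$upper[3], vt1 + 1e-12)
    expect_equal(z$lower[6], vt2)
    expect_true(all(diff(z$eco_score) >= 0))
  }
})

test_that("session ECOs multiply minutes, zone score and discipline factor", {
  s60 <- session_row("run", c(60, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(session_eco(s60), 60)                       # run factor 1.0
  expect_equal(session_eco(session_row("bike", c(60, rep(0, 7)))), 30)
  expect_equal(session_eco(session_row("swim", c(60, rep(0, 7)))), 45)
  # multi-zone session: sum of per-zone products
  multi <- session_row("run", c(30, 0, 0, 0, 10, 0, 0, 0))
  expect_equal(session_eco(multi), 30 * 1 + 10 * 8)
  expect_error(session_eco(session_row("run", c(-5, rep(0, 7)))), "negative")
  # discipline mismatch against a zone model
  zm <- build_zone_model(make_report("run"), "run")
  expect_error(session_eco(session_row("bike", c(60, rep(0, 7))), zm),
               "does not match")
})

test_that("ECO is linear in minutes and ordered run >= swim >= bike", {
  set.seed(7)
  for (i in 1:25) {
    minutes <- runif(8, 0, 40)
    ecos <- vapply(c("run", "swim", "bike"), function(d) {
      session_eco(session_row(d, minutes))
    }, numeric(1))
    expect_gte(ecos[["run"]], ecos[["swim"]])
    expect_gte(ecos[["swim"]], ecos[["bike"]])
    # scaling minutes scales ECOs; concatenation adds
    expect_equal(session_eco(session_row("run", 3 * minutes)), 3 * ecos[["run"]])
    half <- session_eco(session_row("run", minutes / 2))
    expect_equal(2 * half, ecos[["run"]])
    # naive per-minute re-summation oracle
    expect_equal(ecos[["swim"]],
                 oracle_eco(minutes, default_score_table(), 0.75))
  }
})

test_that("the polarization index follows its closed form and guards", {
  expect_equal(polarization_index(80, 5, 15), log10(240))
  expect_equal(polarization_index(70, 25, 5), log10(14))
  expect_gt(polarization_index(80, 5, 15), 2)    # polarized
  expect_lt(polarization_index(70, 25, 5), 2)    # non-polarized
  expect_true(is.na(polarization_index(90, 0, 10)))
  expect_error(polarization_index(105, -10, 5), "negative")
  # 1000 random triples against direct formula evaluation
  set.seed(11)
  for (i in 1:1000) {
    x <- runif(3); x <- 100 * x / sum(x)
    expect_equal(polarization_index(x[1], x[2], x[3]),
                 log10(x[1] * x[3] / x[2]))
  }
  # shifting time out of z2 into z3 (or z1) raises the index
  expect_gt(polarization_index(85, 5, 10), polarization_index(85, 10, 5))
  expect_lt(polarization_index(80, 10, 10), polarization_index(80, 5, 15))
})

test_that("TID classification uses a strict 2.00 cut-off", {
  expect_equal(classify_tid(2.13), "polarized")
  expect_equal(classify_tid(1.92), "non-polarized")
  expect_equal(classify_tid(2.00), "non-polarized")
  expect_true(is.na(classify_tid(NA_real_)))
  expect_equal(classify_tid(c(1.92, 2.08, 2.13)),
               c("non-polarized", "polarized", "polarized"))
})

test_that("weekly summaries aggregate time, ECOs and TID correctly", {
  wk <- summarize_week(session_row("run", c(60, rep(0, 7))))
  expect_equal(wk$hours, 1)
  expect_equal(wk$ecos_total, 60)
  expect_equal(c(wk$time_z1, wk$time_z2, wk$time_z3), c(100, 0, 0))
  expect_true(is.na(wk$polarization_index))

  # 480 / 36 / 72 phase minutes -> 81.6 / 6.1 / 12.2 % of time
  s <- session_row("run", c(480, 0, 0, 36, 0, 72, 0, 0))
  wk2 <- summarize_week(s)
  expect_equal(wk2$time_z1, 100 * 480 / 588, tolerance = 1e-12)
  expect_equal(wk2$time_z2, 100 * 36 / 588, tolerance = 1e-12)
  expect_equal(wk2$time_z3, 100 * 72 / 588, tolerance = 1e-12)
  expect_equal(round(c(wk2$time_z1, wk2$time_z2, wk2$time_z3), 1),
               c(81.6, 6.1, 12.2))
  expect_equal(wk2$time_z1 + wk2$time_z2 + wk2$time_z3, 100)
  expect_equal(wk2$eco_z1 + wk2$eco_z2 + wk2$eco_z3, 100)

  # splitting any session in half leaves the weekly summary unchanged
  halves <- dplyr::bind_rows(
    session_row("run", c(240, 0, 0, 18, 0, 36, 0, 0)),
    session_row("run", c(240, 0, 0, 18, 0, 36, 0, 0)))
  wk3 <- summarize_week(halves)
  for (col in setdiff(names(wk2), "n_sessions")) {
    expect_equal(wk3[[col]], wk2[[col]], tolerance = 1e-12)
  }

  empty <- summarize_week(session_row("run")[0, ], week = 4L)
  expect_equal(empty$hours, 0)
  expect_true(is.na(empty$polarization_index))

  # strength sessions carry no load and no TID minutes
  strength <- session_row("strength", rep(0, 8))
  wk4 <- summarize_week(dplyr::bind_rows(s, strength))
  expect_equal(wk4$ecos_total, wk2$ecos_total)
  expect_equal(wk4$time_z1, wk2$time_z1)
})

test_that("season summaries compute the Table-style statistic set", {
  one <- summarize_week(session_row("run", c(480, 0, 0, 36, 0, 72, 0, 0)))
  fifty <- dplyr::bind_rows(replicate(50, one, simplify = FALSE))
  fifty$week <- 1:50
  ss <- summarize_season(fifty)
  expect_equal(ss$ecos_sd, 0)
  expect_equal(ss$hours_sd, 0)
  expect_equal(ss$ecos_mean, one$ecos_total)

  # sample SD over two weeks of 10 and 14 hours
  two <- dplyr::bind_rows(
    summarize_week(session_row("run", c(600, rep(0, 7)))),
    summarize_week(session_row("run", c(840, rep(0, 7)), week = 2L)))
  s2 <- summarize_season(two)
  expect_equal(s2$hours_mean, 12)
  expect_equal(s2$hours_sd, sd(c(10, 14)))
  expect_equal(round(s2$hours_sd, 2), 2.83)

  # constant (80, 5, 15) weeks: season PI is exactly log10(240)
  wk_pol <- summarize_week(session_row("run", c(80, 0, 0, 5, 0, 15, 0, 0)))
  season_pol <- dplyr::bind_rows(replicate(10, wk_pol, simplify = FALSE))
  season_pol$week <- 1:10
  expect_equal(summarize_season(season_pol)$polarization_index, log10(240))
})
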